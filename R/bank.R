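#' Construct a single polytomous item
#'
#' Bundles the parameters of one graded response model (GRM) or generalized
#' partial credit model (GPCM) item: a discrimination slope, the ordered
#' category thresholds (GRM difficulty parameters \eqn{b_{jt}} or GPCM step
#' parameters \eqn{\delta_{jv}}), and the logistic scaling constant `D`.
#'
#' @param item_id Character identifier, unique within a bank.
#' @param a Positive discrimination parameter.
#' @param thresholds Numeric vector of length `m - 1`. For GRM items these
#'   must be nondecreasing; GPCM step parameters are unrestricted.
#' @param model `"GRM"` or `"GPCM"`.
#' @param scale_id Identifier of the source scale (short form) the item
#'   belongs to; used by the evaluation harness.
#' @param D Positive logistic scaling constant (1 by default; 1.7 gives the
#'   normal-ogive metric).
#' @return An object of class `item_params` with fields `item_id`,
#'   `scale_id`, `model`, `m` (number of categories), `a`, `thresholds`, `D`.
#' @examples
#' it <- item_params("SAS_C3", a = 1.26,
#'                   thresholds = c(-2.111, -0.191, 1.250, 3.602))
#' grm_category_probs(0, it)
#' @export
item_params <- function(item_id, a, thresholds, model = c("GRM", "GPCM"),
                        scale_id = "bank", D = 1) {
  model <- match.arg(model)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0)
    stop("'a' must be a single positive number")
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D <= 0)
    stop("'D' must be a single positive number")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || anyNA(thresholds))
    stop("'thresholds' must be a numeric vector with at least one element")
  if (model == "GRM" && is.unsorted(thresholds))
    stop("GRM thresholds must be nondecreasing for item ", item_id)
  structure(
    list(item_id = as.character(item_id), scale_id = as.character(scale_id),
         model = model, m = length(thresholds) + 1L, a = a,
         thresholds = thresholds, D = D),
    class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("<%s item '%s' (%s)>: m = %d, a = %.3f, D = %g\n",
              x$model, x$item_id, x$scale_id, x$m, x$a, x$D))
  cat("  thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assemble an item bank
#'
#' An item bank is an ordered collection of [item_params()] objects with
#' unique ids, stored as a data frame with one row per item and padded
#' threshold columns `b1 ... bK`.
#'
#' @param items A list of `item_params` objects, or a data frame with columns
#'   `item_id`, `scale_id`, `model`, `m`, `a`, `D`, `b1`, ..., `bK`
#'   (threshold columns beyond an item's `m - 1` are `NA`).
#' @param provenance Free-text note on where the bank came from.
#' @return An object of class `item_bank` (a data frame).
#' @export
item_bank <- function(items, provenance = "") {
  if (is.data.frame(items)) return(as_item_bank(items, provenance))
  if (inherits(items, "item_params")) items <- list(items)
  if (!length(items)) stop("an item bank must contain at least one item")
  stopifnot(all(vapply(items, inherits, logical(1), "item_params")))
  K <- max(vapply(items, function(it) it$m - 1L, integer(1)))
  bmat <- matrix(NA_real_, length(items), K)
  for (i in seq_along(items))
    bmat[i, seq_len(items[[i]]$m - 1L)] <- items[[i]]$thresholds
  df <- data.frame(
    item_id  = vapply(items, `[[`, character(1), "item_id"),
    scale_id = vapply(items, `[[`, character(1), "scale_id"),
    model    = vapply(items, `[[`, character(1), "model"),
    m        = vapply(items, `[[`, integer(1), "m"),
    a        = vapply(items, `[[`, numeric(1), "a"),
    D        = vapply(items, `[[`, numeric(1), "D"),
    stringsAsFactors = FALSE)
  colnames(bmat) <- paste0("b", seq_len(K))
  df <- cbind(df, as.data.frame(bmat))
  as_item_bank(df, provenance)
}

#' Coerce a data frame to an item bank
#'
#' @param df Data frame in the layout described under [item_bank()].
#' @param provenance Free-text provenance note.
#' @return An `item_bank` object.
#' @export
as_item_bank <- function(df, provenance = "") {
  needed <- c("item_id", "scale_id", "model", "m", "a", "D")
  if (!all(needed %in% names(df)))
    stop("item bank needs columns: ", paste(needed, collapse = ", "))
  if (!nrow(df)) stop("an item bank must contain at least one item")
  if (anyDuplicated(df$item_id))
    stop("item_ids must be unique")
  if (!all(df$model %in% c("GRM", "GPCM")))
    stop("model must be 'GRM' or 'GPCM'")
  if (any(df$m < 2L)) stop("every item needs m >= 2 categories")
  if (any(df$a <= 0) || any(df$D <= 0)) stop("a and D must be positive")
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- paste0("b", seq_along(bcols))  # enforce order b1, b2, ...
  if (length(bcols) < max(df$m) - 1L)
    stop("too few threshold columns for the stated category counts")
  for (j in seq_len(nrow(df))) {
    b <- as.numeric(df[j, bcols])[seq_len(df$m[j] - 1L)]
    if (anyNA(b)) stop("missing thresholds for item ", df$item_id[j])
    if (df$model[j] == "GRM" && is.unsorted(b))
      stop("GRM thresholds must be nondecreasing for item ", df$item_id[j])
  }
  df$item_id <- as.character(df$item_id)
  df$scale_id <- as.character(df$scale_id)
  df$m <- as.integer(df$m)
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("item_bank", "data.frame"))
}

#' Extract one item from a bank
#'
#' @param bank An `item_bank`.
#' @param i Row index or item id.
#' @return An `item_params` object.
#' @export
bank_item <- function(bank, i) {
  if (is.character(i)) i <- match(i, bank$item_id)
  if (is.na(i) || i < 1L || i > nrow(bank)) stop("no such item in the bank")
  item_params(bank$item_id[i], a = bank$a[i],
              thresholds = item_thresholds(bank, i),
              model = bank$model[i], scale_id = bank$scale_id[i],
              D = bank$D[i])
}

# thresholds of row i without constructing an item_params
item_thresholds <- function(bank, i) {
  as.numeric(bank[i, paste0("b", seq_len(bank$m[i] - 1L))])
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank: %d items, %d scale(s), models: %s>\n",
              nrow(x), length(unique(x$scale_id)),
              paste(unique(x$model), collapse = "/")))
  NextMethod()
}

#' Read / write an item bank as delimited text
#'
#' The file layout is `item_id,scale_id,model,m,a,D,b1,...,bK` with unused
#' threshold columns left blank.
#'
#' @param path File path.
#' @param sep Field separator (comma by default).
#' @return `read_item_bank()` returns an `item_bank`;
#'   `write_item_bank()` invisibly returns `path`.
#' @export
read_item_bank <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"D" %in% names(df)) df$D <- 1
  as_item_bank(df, provenance = path)
}

#' @rdname read_item_bank
#' @param bank An `item_bank`.
#' @export
write_item_bank <- function(bank, path, sep = ",") {
  utils::write.table(as.data.frame(bank), path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a respondent-by-item response matrix
#'
#' Delimited text with a header; the first column holds respondent ids and
#' the remaining columns one item each. Empty cells are missing responses.
#' Likert files are conventionally coded 1..m; internally categories are
#' 0..m-1, so codes are shifted down by `likert_base` on read.
#'
#' @param path File path.
#' @param likert_base Integer code of the lowest category in the file
#'   (default 1; use 0 for files already 0-based).
#' @param sep Field separator.
#' @return An integer matrix of 0-based category codes with respondent ids as
#'   row names and item ids as column names.
#' @export
read_responses <- function(path, likert_base = 1L, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  ids <- as.character(df[[1L]])
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "integer"
  X <- X - as.integer(likert_base)
  if (any(X < 0L, na.rm = TRUE))
    stop("negative category codes after shifting; check 'likert_base'")
  rownames(X) <- ids
  X
}

#' @rdname read_responses
#' @param X 0-based integer response matrix.
#' @export
write_responses <- function(X, path, likert_base = 1L, sep = ",") {
  out <- data.frame(respondent_id = rownames(X) %||% seq_len(nrow(X)),
                    X + as.integer(likert_base), check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a response matrix against a bank; returns the matrix with columns
# reordered to match the bank. Codes must lie in [0, m_j - 1] or be NA.
check_responses <- function(X, bank) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != nrow(bank))
      stop("response matrix has ", ncol(X), " columns but the bank has ",
           nrow(bank), " items")
    colnames(X) <- bank$item_id
  }
  missing_items <- setdiff(bank$item_id, colnames(X))
  if (length(missing_items))
    stop("response matrix lacks items: ",
         paste(utils::head(missing_items, 5), collapse = ", "))
  X <- X[, bank$item_id, drop = FALSE]
  for (j in seq_len(nrow(bank))) {
    bad <- !is.na(X[, j]) & (X[, j] < 0L | X[, j] >= bank$m[j])
    if (any(bad))
      stop("item ", bank$item_id[j], " has codes outside [0, ",
           bank$m[j] - 1L, "]")
  }
  X
}
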