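#' Specification for a synthetic item bank and cohort
#'
#' Defines the study conditions the generator emulates: a multi-scale ordinal
#' item bank with a given category layout, discriminations from a truncated
#' normal distribution, ordered thresholds over a stated span, a
#' standard-normal latent trait, and optional planted structure (group DIF
#' shifts, weak low-loading items) for screening-power experiments.
#'
#' The default layout mirrors a seven-instrument questionnaire battery:
#' 16 items with 7 categories, 10 and 20 items with 4 categories, and
#' 11/16/11/14 items with 5 categories (98 items in total); discriminations
#' average 1.26 (SD 0.31) within \[0.87, 2.36\] and thresholds span
#' \[-2.4, 3.6\].
#'
#' @param scale_layout List of `c(n_items, n_categories)` pairs, one per
#'   scale.
#' @param scale_ids Names for the scales (defaults to `S1`, `S2`, ...).
#' @param a_range Truncation interval for discriminations.
#' @param a_mean,a_sd Mean and SD of the (untruncated) discrimination
#'   distribution.
#' @param threshold_span Interval the ordered thresholds are drawn over.
#' @param min_gap Minimum spacing between adjacent thresholds (avoids
#'   near-degenerate categories).
#' @param n_respondents Cohort size.
#' @param theta_mean,theta_sd Latent trait prior.
#' @param dif_items,dif_shift,dif_a_factor Planted-DIF plan: item ids whose
#'   focal-group thresholds are shifted by `dif_shift` and/or discrimination
#'   multiplied by `dif_a_factor`.
#' @param weak_items,weak_attenuation Planted weak items: ids whose
#'   discrimination is multiplied by `weak_attenuation` (low loadings).
#' @param seed Integer seed; mandatory so every draw is reproducible.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(scale_layout = list(c(16, 7), c(10, 4), c(20, 4),
                                           c(11, 5), c(16, 5), c(11, 5),
                                           c(14, 5)),
                       scale_ids = NULL,
                       a_range = c(0.87, 2.36), a_mean = 1.26, a_sd = 0.31,
                       threshold_span = c(-2.4, 3.6), min_gap = 0.2,
                       n_respondents = 885L, theta_mean = 0, theta_sd = 1,
                       dif_items = character(0), dif_shift = 0,
                       dif_a_factor = 1,
                       weak_items = character(0), weak_attenuation = 0.15,
                       seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is mandatory for reproducibility")
  if (is.null(scale_ids)) scale_ids <- paste0("S", seq_along(scale_layout))
  stopifnot(length(scale_ids) == length(scale_layout))
  for (sl in scale_layout) {
    if (length(sl) != 2L || sl[1L] < 1L || sl[2L] < 2L)
      stop("each layout entry must be c(n_items >= 1, n_categories >= 2)")
    width <- diff(threshold_span) - (sl[2L] - 2L) * min_gap
    if (width <= 0)
      stop("threshold span too narrow for ", sl[2L] - 1L,
           " thresholds with min_gap ", min_gap)
  }
  if (diff(a_range) < 0 || a_range[1L] <= 0) stop("invalid 'a_range'")
  structure(list(scale_layout = scale_layout, scale_ids = scale_ids,
                 a_range = a_range, a_mean = a_mean, a_sd = a_sd,
                 threshold_span = threshold_span, min_gap = min_gap,
                 n_respondents = as.integer(n_respondents),
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 dif_items = dif_items, dif_shift = dif_shift,
                 dif_a_factor = dif_a_factor, weak_items = weak_items,
                 weak_attenuation = weak_attenuation,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  n_items <- sum(vapply(x$scale_layout, `[`, numeric(1), 1L))
  cat(sprintf("<synth_spec: %d scales, %d items, N = %d, seed %d>\n",
              length(x$scale_layout), n_items, x$n_respondents, x$seed))
  invisible(x)
}

# inverse-CDF draw from a truncated normal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic item bank
#'
#' Discriminations are drawn from the spec's truncated normal;
#' thresholds are drawn uniformly (with the minimum gap enforced) and
#' sorted ascending within the spec's span. Items named in `weak_items`
#' get their discrimination attenuated. Deterministic under the spec seed.
#'
#' @param spec A [synth_spec()].
#' @param model `"GRM"` or `"GPCM"` item family.
#' @param D Logistic scaling constant.
#' @return An `item_bank`.
#' @export
generate_bank <- function(spec, model = "GRM", D = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  items <- list()
  for (s in seq_along(spec$scale_layout)) {
    n_it <- spec$scale_layout[[s]][1L]
    m <- spec$scale_layout[[s]][2L]
    for (k in seq_len(n_it)) {
      id <- paste0(spec$scale_ids[s], "_", k)
      a <- rtruncnorm(1L, spec$a_mean, spec$a_sd, spec$a_range[1L],
                      spec$a_range[2L])
      if (id %in% spec$weak_items) a <- a * spec$weak_attenuation
      # uniform draws on a narrowed span, sorted, then spread by min_gap
      lo <- spec$threshold_span[1L]
      hi <- spec$threshold_span[2L] - (m - 2L) * spec$min_gap
      b <- sort(stats::runif(m - 1L, lo, hi)) +
        spec$min_gap * (seq_len(m - 1L) - 1L)
      items[[length(items) + 1L]] <-
        item_params(id, a = a, thresholds = b, model = model,
                    scale_id = spec$scale_ids[s], D = D)
    }
  }
  item_bank(items, provenance = sprintf("synthetic (seed %d)", spec$seed))
}

#' Generate latent trait values
#'
#' `n` draws from the spec's normal trait prior; deterministic under the
#' spec seed (offset so the draws are independent of the bank's).
#'
#' @param n Number of respondents (defaults to `spec$n_respondents`).
#' @param spec A [synth_spec()].
#' @return Numeric vector of length `n`.
#' @export
generate_thetas <- function(n = spec$n_respondents, spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (n < 1L) stop("n must be >= 1")
  set.seed(spec$seed + 1L)
  stats::rnorm(n, spec$theta_mean, spec$theta_sd)
}

#' Simulate ordinal responses from an item bank
#'
#' Each cell is drawn from the item's model-implied category distribution at
#' the respondent's trait value.
#'
#' @param bank An `item_bank`.
#' @param thetas Per-respondent latent trait values.
#' @param seed Optional integer seed (set for reproducibility).
#' @return Integer matrix of 0-based codes, respondents in rows, item ids as
#'   column names.
#' @export
simulate_responses <- function(bank, thetas, seed = NULL) {
  bank <- as_bank(bank)
  if (!is.null(seed)) set.seed(seed)
  N <- length(thetas)
  X <- matrix(NA_integer_, N, nrow(bank),
              dimnames = list(sprintf("r%04d", seq_len(N)), bank$item_id))
  for (j in seq_len(nrow(bank))) {
    P <- if (bank$model[j] == "GRM")
      grm_prob_matrix(thetas, bank$a[j], item_thresholds(bank, j), bank$D[j])
    else
      gpcm_prob_matrix(thetas, bank$a[j], item_thresholds(bank, j),
                       bank$D[j])
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(N)
    X[, j] <- as.integer(rowSums(u > cum))  # count of cumulative bins passed
  }
  X
}

#' Generate a full synthetic dataset
#'
#' Bank, traits and responses in one call, with derived seeds (spec seed for
#' the bank, +1 for traits, +2 for responses) so each piece is independently
#' reproducible.
#'
#' @param spec A [synth_spec()].
#' @inheritParams generate_bank
#' @return A list with `bank`, `thetas`, `responses`, `spec`.
#' @export
generate_dataset <- function(spec, model = "GRM", D = 1) {
  bank <- generate_bank(spec, model = model, D = D)
  thetas <- generate_thetas(spec$n_respondents, spec)
  responses <- simulate_responses(bank, thetas, seed = spec$seed + 2L)
  list(bank = bank, thetas = thetas, responses = responses, spec = spec)
}

#' Plant differential item functioning into a bank
#'
#' Returns a reference/focal pair of banks: the focal copy has the target
#' items' thresholds shifted by `shift` (uniform DIF) and/or discrimination
#' multiplied by `a_factor` (non-uniform DIF); the reference bank is
#' untouched. A shift or factor that would break GRM threshold ordering is
#' an error.
#'
#' @param bank An `item_bank`.
#' @param items Item ids to modify (must exist in the bank).
#' @param shift Threshold shift applied to the focal group.
#' @param a_factor Multiplier on the focal-group discrimination (`> 0`).
#' @return A list with `reference` and `focal` banks and the `plan`.
#' @export
inject_dif <- function(bank, items, shift = 0, a_factor = 1) {
  bank <- as_bank(bank)
  idx <- match(items, bank$item_id)
  if (anyNA(idx)) stop("unknown items: ",
                       paste(items[is.na(idx)], collapse = ", "))
  if (a_factor <= 0) stop("'a_factor' must be positive")
  focal <- bank
  for (j in idx) {
    b <- item_thresholds(focal, j) + shift
    if (focal$model[j] == "GRM" && is.unsorted(b))
      stop("shift breaks threshold ordering for item ", focal$item_id[j])
    focal[j, paste0("b", seq_len(focal$m[j] - 1L))] <- b
    focal[j, "a"] <- focal$a[j] * a_factor
  }
  list(reference = bank, focal = as_item_bank(as.data.frame(focal),
                                              provenance = "planted DIF"),
       plan = list(items = items, shift = shift, a_factor = a_factor))
}

#' Simulate responses under group-specific banks
#'
#' Respondents in the focal group answer the focal bank, the rest the
#' reference bank — the generating process behind a planted-DIF experiment.
#'
#' @param banks A `reference`/`focal` pair as returned by [inject_dif()].
#' @param thetas Per-respondent trait values.
#' @param group Logical or two-level vector; `TRUE` / second level = focal.
#' @param seed Optional integer seed.
#' @return Integer 0-based response matrix.
#' @export
simulate_group_responses <- function(banks, thetas, group, seed = NULL) {
  focal <- if (is.logical(group)) group else factor(group) ==
    levels(factor(group))[2L]
  if (!is.null(seed)) set.seed(seed)
  Xr <- simulate_responses(banks$reference, thetas)
  Xf <- simulate_responses(banks$focal, thetas)
  Xr[focal, ] <- Xf[focal, ]
  Xr
}
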