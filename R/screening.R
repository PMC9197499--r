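#' First-principal-component loadings of an item set
#'
#' Loadings of each item on the first principal component of the item
#' Pearson correlation matrix (pairwise-complete), i.e. the first eigenvector
#' scaled by the square root of the first eigenvalue, oriented so that the
#' majority of loadings are positive. Items with zero variance cannot be
#' correlated and come back as `NA` (they are flagged, not silently
#' dropped).
#'
#' @param X Numeric respondent-by-item matrix (ordinal codes are used as
#'   given).
#' @return Named numeric vector of loadings (`NA` for constant items).
#' @export
pca_first_loadings <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 items")
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  ok <- !is.na(sds) & sds > 0
  loadings <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  if (sum(ok) >= 2L) {
    R <- stats::cor(X[, ok, drop = FALSE], use = "pairwise.complete.obs")
    R[is.na(R)] <- 0
    e <- eigen(R, symmetric = TRUE)
    v <- e$vectors[, 1L]
    if (mean(v > 0) < 0.5 || (mean(v > 0) == 0.5 && sum(v) < 0)) v <- -v
    loadings[ok] <- v * sqrt(max(e$values[1L], 0))
  }
  loadings
}

#' Partition items by a first-component loading threshold
#'
#' Items whose loading is strictly below `threshold` (or undefined) are
#' dropped; a loading exactly at the threshold is retained.
#'
#' @param loadings Named loadings as from [pca_first_loadings()].
#' @param threshold Retention cutoff (default 0.4).
#' @return A list with `retained` and `dropped` item-id vectors and the
#'   `loadings` themselves.
#' @export
apply_loading_filter <- function(loadings, threshold = 0.4) {
  drop <- is.na(loadings) | loadings < threshold
  list(retained = names(loadings)[!drop], dropped = names(loadings)[drop],
       loadings = loadings, threshold = threshold)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' \eqn{KMO = \sum r^2 / (\sum r^2 + \sum q^2)} over off-diagonal entries,
#' where `r` are the raw correlations and `q` the anti-image partial
#' correlations obtained from the inverse correlation matrix. A singular
#' correlation matrix is ridge-regularized (with a warning) before
#' inversion.
#'
#' @param X A respondent-by-item matrix, or a correlation matrix (square,
#'   symmetric, unit diagonal).
#' @return KMO value in \[0, 1\].
#' @export
kmo <- function(X) {
  X <- as.matrix(X)
  is_cor <- nrow(X) == ncol(X) && all(abs(diag(X) - 1) < 1e-8) &&
    isTRUE(all.equal(X, t(X), tolerance = 1e-8))
  R <- if (is_cor) X else stats::cor(X, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("correlation matrix has missing entries")
  S <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; ridge-regularizing")
    solve(R + diag(1e-6, nrow(R)))
  })
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)            # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Eigenvalue-based unidimensionality summary
#'
#' `unidim_summary()` applies the two conventional screening rules to a set
#' of correlation-matrix eigenvalues: the ratio of the first to the second
#' eigenvalue should exceed 4, and the first component should account for
#' more than 20% of the total variance (`eigen1 / n_items * 100`).
#' `unidimensionality_check()` computes the eigenvalues from data first.
#'
#' @param eigenvalues Eigenvalues in descending order (at least 2).
#' @param n_items Number of items the eigenvalues refer to (defaults to
#'   `length(eigenvalues)`, correct when the full spectrum is supplied).
#' @param ratio_cut,variance_cut Pass thresholds (4 and 20).
#' @return A list of class `unidim_summary`: `eigen1`, `eigen2`, `ratio`,
#'   `variance_pct`, `pass_ratio`, `pass_variance`, `pass`.
#' @examples
#' unidim_summary(c(35.631, 6.107), n_items = 93)
#' @export
unidim_summary <- function(eigenvalues, n_items = length(eigenvalues),
                           ratio_cut = 4, variance_cut = 20) {
  if (length(eigenvalues) < 2L) stop("need at least two eigenvalues")
  e1 <- eigenvalues[1L]; e2 <- eigenvalues[2L]
  ratio <- e1 / e2
  vpct <- e1 / n_items * 100
  structure(list(eigen1 = e1, eigen2 = e2, ratio = ratio,
                 variance_pct = vpct, pass_ratio = ratio > ratio_cut,
                 pass_variance = vpct > variance_cut,
                 pass = ratio > ratio_cut && vpct > variance_cut),
            class = "unidim_summary")
}

#' @rdname unidim_summary
#' @param X Respondent-by-item matrix.
#' @export
unidimensionality_check <- function(X, ratio_cut = 4, variance_cut = 20) {
  X <- as.matrix(X)
  if (ncol(X) < 3L) stop("need at least 3 items")
  R <- stats::cor(X, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("correlation matrix has missing entries")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  out <- unidim_summary(ev, n_items = ncol(X), ratio_cut = ratio_cut,
                        variance_cut = variance_cut)
  out$eigenvalues <- ev
  out
}

#' @export
print.unidim_summary <- function(x, ...) {
  cat(sprintf(
    "eigenvalues %.3f / %.3f  ratio %.2f (%s)  first-factor variance %.2f%% (%s)\n",
    x$eigen1, x$eigen2, x$ratio, if (x$pass_ratio) "pass" else "fail",
    x$variance_pct, if (x$pass_variance) "pass" else "fail"))
  invisible(x)
}

#' Drop weakly discriminating items from a calibrated bank
#'
#' Items with discrimination strictly below `threshold` are dropped;
#' `a` exactly at the threshold is retained.
#'
#' @param x An `irt_fit` or an `item_bank`.
#' @param threshold Minimum discrimination (default 0.8).
#' @return A list with `retained` (an `item_bank`) and `dropped` (data frame
#'   of `item_id`, `a`).
#' @export
apply_discrimination_filter <- function(x, threshold = 0.8) {
  bank <- if (inherits(x, "irt_fit")) x$bank else as_bank(x)
  drop <- bank$a < threshold
  dropped <- data.frame(item_id = bank$item_id[drop], a = bank$a[drop],
                        stringsAsFactors = FALSE)
  retained <- if (all(drop)) NULL else bank[!drop, , drop = FALSE]
  list(retained = retained, dropped = dropped, threshold = threshold)
}

#' Differential item functioning scan by ordinal logistic regression
#'
#' For each item, compares nested (proportional-odds) logistic regressions of
#' the item response on the trait anchor: `M1: item ~ trait` versus
#' `M3: item ~ trait + group + trait:group`, so that uniform and non-uniform
#' DIF are covered jointly. The effect size is the change in McFadden's
#' pseudo-R-squared, \eqn{\Delta R^2 = R^2(M3) - R^2(M1)} with
#' \eqn{R^2 = 1 - \ell/\ell_0}; an item is flagged when
#' \eqn{\Delta R^2} strictly exceeds `threshold`. Dichotomous (or collapsed)
#' items fall back to binomial logistic regression; items whose
#' proportional-odds fit fails are dichotomized at the median with a
#' warning.
#'
#' @param X 0-based response matrix.
#' @param group Two-level grouping vector (e.g. gender), one per respondent.
#' @param trait Per-person trait anchor (typically full-bank EAP scores).
#' @param threshold Flagging cutoff on the R-squared change (default 0.02).
#' @return A data frame of class `dif_result`: `item_id`, `delta_r2`,
#'   `flagged`.
#' @export
dif_scan <- function(X, group, trait, threshold = 0.02) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
  group <- factor(group)
  if (nlevels(group) != 2L || any(tabulate(group) == 0L))
    stop("'group' must have exactly two nonempty levels")
  if (length(group) != nrow(X) || length(trait) != nrow(X))
    stop("'group' and 'trait' must have one entry per respondent")
  delta <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    d <- data.frame(y = X[, j], trait = trait, group = group)
    d <- d[stats::complete.cases(d), ]
    obs <- sort(unique(d$y))
    d$y <- factor(match(d$y, obs) - 1L, ordered = TRUE)
    delta[j] <- tryCatch(
      dif_delta_r2(d),
      error = function(e) {
        warning("proportional-odds fit failed for item ", colnames(X)[j],
                "; dichotomizing at the median")
        d$y <- factor(as.integer(as.integer(as.character(d$y)) >
                                   stats::median(as.integer(as.character(d$y)))))
        dif_delta_r2(d)
      })
  }
  structure(data.frame(item_id = colnames(X), delta_r2 = delta,
                       flagged = delta > threshold,
                       stringsAsFactors = FALSE),
            class = c("dif_result", "data.frame"))
}

# McFadden delta-R2 between trait-only and trait+group+interaction models
dif_delta_r2 <- function(d) {
  if (nlevels(d$y) < 2L) return(0)
  if (nlevels(d$y) == 2L) {
    d$y <- as.integer(as.character(d$y))
    ll0 <- as.numeric(stats::logLik(stats::glm(y ~ 1, binomial(), d)))
    ll1 <- as.numeric(stats::logLik(stats::glm(y ~ trait, binomial(), d)))
    ll3 <- as.numeric(stats::logLik(stats::glm(y ~ trait * group, binomial(),
                                               d)))
  } else {
    ll0 <- as.numeric(stats::logLik(MASS::polr(y ~ 1, data = d)))
    ll1 <- as.numeric(stats::logLik(MASS::polr(y ~ trait, data = d)))
    ll3 <- as.numeric(stats::logLik(MASS::polr(y ~ trait * group, data = d)))
  }
  r1 <- 1 - ll1 / ll0
  r3 <- 1 - ll3 / ll0
  max(r3 - r1, 0)
}

#' Build a screened, calibrated item bank from raw responses
#'
#' The full screening pipeline in its fixed order: (1) first-component
#' loading filter on the raw responses; (2) KMO and eigenvalue
#' unidimensionality checks on the retained items; (3) GRM and GPCM
#' calibration with AIC/BIC model selection (or a single stated model);
#' (4) discrimination filter on the calibrated bank; (5) DIF scan against
#' full-bank EAP trait scores (single pass, no purification) when a grouping
#' variable is supplied; (6) final recalibration of the retained items.
#'
#' @param X 0-based response matrix.
#' @param group Optional two-level grouping vector for the DIF scan.
#' @param model `"both"` (compare GRM and GPCM), `"GRM"` or `"GPCM"`.
#' @param loading_threshold,disc_threshold,dif_threshold Screening cutoffs
#'   (0.4, 0.8, 0.02).
#' @param ... Passed on to [fit_irt()] (e.g. `tol`, `max_iter`).
#' @return A list of class `bank_build`: `bank` (final `item_bank`), `fit`
#'   (final `irt_fit`), `model` (selected family), `loadings`, `kmo`,
#'   `unidim`, `dif`, and `dropped` (data frame of `item_id`, `reason` with
#'   codes `LOW_LOADING`, `LOW_DISCRIMINATION`, `DIF`).
#' @export
build_item_bank <- function(X, group = NULL, model = c("both", "GRM", "GPCM"),
                            loading_threshold = 0.4, disc_threshold = 0.8,
                            dif_threshold = 0.02, ...) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))

  loadings <- pca_first_loadings(X)
  lf <- apply_loading_filter(loadings, loading_threshold)
  dropped <- data.frame(item_id = lf$dropped,
                        reason = rep("LOW_LOADING", length(lf$dropped)),
                        stringsAsFactors = FALSE)
  X1 <- X[, lf$retained, drop = FALSE]

  kmo_val <- kmo(X1)
  unidim <- unidimensionality_check(X1)

  if (model == "both") {
    fg <- fit_irt(X1, "GRM", ...)
    fp <- fit_irt(X1, "GPCM", ...)
    model <- select_model(fg, fp)
    fit <- if (model == "GRM") fg else fp
  } else {
    fit <- fit_irt(X1, model, ...)
  }

  df <- apply_discrimination_filter(fit, disc_threshold)
  if (nrow(df$dropped))
    dropped <- rbind(dropped, data.frame(item_id = df$dropped$item_id,
                                         reason = "LOW_DISCRIMINATION",
                                         stringsAsFactors = FALSE))
  keep <- setdiff(colnames(X1), df$dropped$item_id)

  dif <- NULL
  if (!is.null(group)) {
    trait <- eap_scores(X1, fit$bank, fit$grid)$theta
    dif <- dif_scan(X1[, keep, drop = FALSE], group, trait, dif_threshold)
    if (any(dif$flagged)) {
      dropped <- rbind(dropped,
                       data.frame(item_id = dif$item_id[dif$flagged],
                                  reason = "DIF", stringsAsFactors = FALSE))
      keep <- setdiff(keep, dif$item_id[dif$flagged])
    }
  }

  final_fit <- fit_irt(X[, keep, drop = FALSE], model, ...)
  structure(list(bank = final_fit$bank, fit = final_fit, model = model,
                 loadings = loadings, kmo = kmo_val, unidim = unidim,
                 dif = dif, dropped = dropped),
            class = "bank_build")
}

#' @export
print.bank_build <- function(x, ...) {
  cat(sprintf("<bank_build: %d items retained (%s), %d dropped>\n",
              nrow(x$bank), x$model, nrow(x$dropped)))
  cat(sprintf("  KMO %.3f | ", x$kmo))
  print(x$unidim)
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  invisible(x)
}
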