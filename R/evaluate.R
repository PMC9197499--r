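#' Score a cohort on one fixed scale (short form)
#'
#' EAP trait estimates and information-based standard errors using only the
#' items of one fixed scale, as a paper-and-pencil short form would be
#' scored. Respondents with no observed response on the subset are excluded
#' (their ids are recorded in the `excluded` attribute).
#'
#' @param X 0-based response matrix covering the bank.
#' @param bank An `item_bank`.
#' @param scale_items Character vector of item ids forming the scale.
#' @param grid A [prior_grid()].
#' @return Data frame (`id`, `theta`, `se`, `reliability = 1 - se^2`), with
#'   attributes `mean_se`, `mr` (cohort marginal reliability) and `excluded`.
#' @export
fixed_scale_eval <- function(X, bank, scale_items, grid = prior_grid()) {
  bank <- as_bank(bank)
  if (!length(scale_items)) stop("'scale_items' must be nonempty")
  missing_items <- setdiff(scale_items, bank$item_id)
  if (length(missing_items))
    stop("items not in bank: ", paste(missing_items, collapse = ", "))
  sub <- bank[match(scale_items, bank$item_id), , drop = FALSE]
  X <- check_responses(X, bank)[, scale_items, drop = FALSE]
  all_missing <- rowSums(!is.na(X)) == 0L
  excluded <- rownames(X)[all_missing] %||% which(all_missing)
  X <- X[!all_missing, , drop = FALSE]
  sc <- eap_scores(X, sub, grid)
  out <- data.frame(id = sc$id, theta = sc$theta, se = sc$se,
                    reliability = 1 - sc$se^2, stringsAsFactors = FALSE)
  attr(out, "mean_se") <- mean(sc$se)
  attr(out, "mr") <- marginal_reliability(sc$se)
  attr(out, "excluded") <- excluded
  out
}

#' Score a cohort by fixed-length adaptive testing
#'
#' Runs the post-hoc adaptive test with a fixed-length stop rule for every
#' respondent and returns per-person estimates in the same layout as
#' [fixed_scale_eval()], so the two arms can be compared at equal test
#' length.
#'
#' @inheritParams fixed_scale_eval
#' @param L Test length (`L <=` bank size).
#' @param full_theta Optional precomputed full-bank EAP estimates.
#' @return Data frame (`id`, `theta`, `se`, `reliability`) with attributes
#'   `mean_se`, `mr` and `cohort` (the underlying `cohort_sim`).
#' @export
fixed_length_cat_eval <- function(X, bank, L, grid = prior_grid(),
                                  full_theta = NULL) {
  bank <- as_bank(bank)
  if (L > nrow(bank))
    stop("L = ", L, " exceeds the bank size ", nrow(bank))
  sim <- simulate_cohort(X, bank, stop_rule("length", length = L), grid,
                         full_theta = full_theta)
  per <- sim$per_person
  out <- data.frame(id = per$id, theta = per$theta, se = per$se,
                    reliability = 1 - per$se^2, stringsAsFactors = FALSE)
  attr(out, "mean_se") <- sim$mean_se
  attr(out, "mr") <- sim$mr
  attr(out, "cohort") <- sim
  out
}

#' Percent change between two positive quantities
#'
#' `direction = "decrease"` gives `(before - after) / before * 100` (e.g. a
#' drop in measurement error); `"increase"` gives
#' `(after - before) / before * 100` (e.g. a reliability gain). Values are
#' returned unrounded; reports round to one decimal.
#'
#' @param before,after Positive values (`before > 0`).
#' @param direction `"decrease"` or `"increase"`.
#' @return Percent change.
#' @examples
#' percent_change(0.34, 0.28, "decrease")  # 17.6 after rounding
#' @export
percent_change <- function(before, after, direction = c("decrease",
                                                        "increase")) {
  direction <- match.arg(direction)
  if (any(before <= 0)) stop("'before' must be positive")
  if (direction == "decrease") (before - after) / before * 100
  else (after - before) / before * 100
}

#' Paired t statistic and Cohen's d for matched differences
#'
#' \eqn{t = \bar{d} / (s_d / \sqrt{n})} and the paired effect size
#' \eqn{d = t / \sqrt{n}} (the standardized mean difference of the pairs).
#' Zero-variance differences yield an infinite `t` (or `NA` when every
#' difference is exactly zero, with `d = 0` by convention).
#'
#' @param diffs Per-person paired differences (length `>= 2`).
#' @return A list with `t`, `d`, `n`, `p` (two-sided).
#' @examples
#' cohens_d_from_t(44.54, 885)  # 1.50
#' @export
paired_effect <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 paired differences")
  m <- mean(diffs); s <- stats::sd(diffs)
  if (s == 0) {
    t <- if (m == 0) NA_real_ else Inf * sign(m)
    d <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) NA_real_ else 0
  } else {
    t <- m / (s / sqrt(n))
    d <- t / sqrt(n)
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  list(t = t, d = d, n = n, p = p)
}

#' @rdname paired_effect
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @export
cohens_d_from_t <- function(t, n) t / sqrt(n)

#' Means, SDs and correlations of aligned trait-estimate sets
#'
#' @param theta_sets Named list of per-person estimate vectors, all the same
#'   length (`>= 3`) and aligned by respondent.
#' @return A list of class `est_cor` with `means`, `sds` and the Pearson
#'   correlation matrix `cor`; printed as a lower-triangle table.
#' @export
estimate_correlations <- function(theta_sets) {
  if (is.null(names(theta_sets)) || any(names(theta_sets) == ""))
    stop("'theta_sets' must be a fully named list")
  lens <- lengths(theta_sets)
  if (length(unique(lens)) != 1L)
    stop("estimate vectors are misaligned (unequal lengths)")
  if (lens[1L] < 3L) stop("need at least 3 respondents")
  M <- do.call(cbind, theta_sets)
  structure(list(means = colMeans(M), sds = apply(M, 2L, stats::sd),
                 cor = stats::cor(M), n = nrow(M)),
            class = "est_cor")
}

#' @export
print.est_cor <- function(x, digits = 2, ...) {
  cat(sprintf("<est_cor: %d respondents, %d estimate sets>\n", x$n,
              length(x$means)))
  hdr <- rbind(Mean = x$means, SD = x$sds)
  print(round(hdr, digits))
  C <- x$cor
  C[upper.tri(C, diag = TRUE)] <- NA
  cat("lower-triangle correlations:\n")
  print(round(C, digits), na.print = "")
  invisible(x)
}

#' Mean adaptive-test length at a fixed accuracy target
#'
#' Runs the SE-threshold stop rule over the cohort and reports the mean
#' number of items used, i.e. how long the adaptive test must be to match a
#' fixed form's achieved accuracy. Respondents who exhaust the bank before
#' reaching the target are counted in `n_exhausted`.
#'
#' @inheritParams fixed_scale_eval
#' @param target_se Positive SE target (e.g. a fixed scale's achieved mean
#'   SE).
#' @param full_theta Optional precomputed full-bank EAP estimates.
#' @return A list with `target_se`, `mean_items`, `sd_items`, `n_exhausted`
#'   and the full `cohort_sim` as `cohort`.
#' @export
equal_accuracy_length <- function(X, bank, target_se, grid = prior_grid(),
                                  full_theta = NULL) {
  if (target_se <= 0) stop("'target_se' must be positive")
  sim <- simulate_cohort(X, bank, stop_rule("se", se_target = target_se),
                         grid, full_theta = full_theta)
  list(target_se = target_se, mean_items = sim$mean_items,
       sd_items = sim$sd_items,
       n_exhausted = sum(sim$per_person$stopped_by == "BANK_EXHAUSTED"),
       cohort = sim)
}

#' Compare adaptive testing against fixed short forms at equal length
#'
#' For each named scale, scores the cohort twice: with the fixed scale
#' ([fixed_scale_eval()]) and with a fixed-length adaptive test of the same
#' length ([fixed_length_cat_eval()]). Produces the two standard comparison
#' tables: per-person measurement error (information-based SE) and
#' per-person reliability (`1 - se^2`), each with means, SDs, the percent
#' change, the paired t statistic and Cohen's d (`t / sqrt(n)`).
#'
#' @inheritParams fixed_scale_eval
#' @param scales Named list of item-id vectors, one per fixed scale.
#' @return A list of class `cat_pp_comparison` with data frames `error` and
#'   `reliability` (columns `scale`, `length`, `pp_mean`, `pp_sd`,
#'   `cat_mean`, `cat_sd`, `pct_change`, `t`, `d`), plus `theta_sets` (named
#'   per-person estimates: full bank, each scale, each CAT length) for
#'   correlation tables.
#' @export
compare_same_length <- function(X, bank, scales, grid = prior_grid()) {
  bank <- as_bank(bank)
  if (is.null(names(scales))) stop("'scales' must be a named list")
  X <- check_responses(X, bank)
  full <- eap_scores(X, bank, grid)
  theta_sets <- list(all = full$theta)
  err <- rel <- NULL
  for (s in names(scales)) {
    pp <- fixed_scale_eval(X, bank, scales[[s]], grid)
    L <- length(scales[[s]])
    ct <- fixed_length_cat_eval(X, bank, L, grid, full_theta = full$theta)
    if (nrow(pp) != nrow(ct))
      ct <- ct[match(pp$id, ct$id), , drop = FALSE]
    pe_err <- paired_effect(pp$se - ct$se)
    pe_rel <- paired_effect(ct$reliability - pp$reliability)
    err <- rbind(err, data.frame(
      scale = s, length = L, pp_mean = mean(pp$se), pp_sd = stats::sd(pp$se),
      cat_mean = mean(ct$se), cat_sd = stats::sd(ct$se),
      pct_change = percent_change(mean(pp$se), mean(ct$se), "decrease"),
      t = pe_err$t, d = pe_err$d, stringsAsFactors = FALSE))
    rel <- rbind(rel, data.frame(
      scale = s, length = L, pp_mean = mean(pp$reliability),
      pp_sd = stats::sd(pp$reliability), cat_mean = mean(ct$reliability),
      cat_sd = stats::sd(ct$reliability),
      pct_change = percent_change(mean(pp$reliability),
                                  mean(ct$reliability), "increase"),
      t = pe_rel$t, d = pe_rel$d, stringsAsFactors = FALSE))
    theta_sets[[s]] <- pp$theta[match(full$id, pp$id)]
    theta_sets[[paste0("cat_", L, "_", s)]] <- ct$theta
  }
  structure(list(error = err, reliability = rel, theta_sets = theta_sets,
                 n = nrow(X)),
            class = "cat_pp_comparison")
}

#' @export
print.cat_pp_comparison <- function(x, digits = 2, ...) {
  cat("Measurement error at equal test length (fixed form vs CAT):\n")
  e <- x$error
  e$pct_change <- round(e$pct_change, 1)
  print(cbind(e[1:2], round(e[-(1:2)], digits)), row.names = FALSE)
  cat("\nMeasurement reliability at equal test length:\n")
  r <- x$reliability
  r$pct_change <- round(r$pct_change, 1)
  print(cbind(r[1:2], round(r[-(1:2)], digits)), row.names = FALSE)
  invisible(x)
}

#' Equal-accuracy length table
#'
#' For each fixed scale, takes its achieved cohort mean SE as the adaptive
#' test's stop target and reports the mean adaptive length next to the fixed
#' length.
#'
#' @inheritParams compare_same_length
#' @return Data frame: `scale`, `target_se`, `pp_length`, `cat_length`,
#'   `n_exhausted`.
#' @export
equal_accuracy_table <- function(X, bank, scales, grid = prior_grid()) {
  bank <- as_bank(bank)
  X <- check_responses(X, bank)
  full_theta <- eap_scores(X, bank, grid)$theta
  out <- NULL
  for (s in names(scales)) {
    pp <- fixed_scale_eval(X, bank, scales[[s]], grid)
    target <- attr(pp, "mean_se")
    ea <- equal_accuracy_length(X, bank, target, grid,
                                full_theta = full_theta)
    out <- rbind(out, data.frame(
      scale = s, target_se = target, pp_length = length(scales[[s]]),
      cat_length = ea$mean_items, n_exhausted = ea$n_exhausted,
      stringsAsFactors = FALSE))
  }
  out
}
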