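#' Quadrature grid over the latent-trait prior
#'
#' Equally spaced nodes with standard-normal density weights, normalized to
#' sum to one. Used both by the EM calibration and by EAP scoring.
#'
#' @param n_points Number of nodes (default 61).
#' @param range Interval covered by the nodes (default `c(-4, 4)`).
#' @param mean,sd Prior mean and standard deviation.
#' @return An object of class `prior_grid` with `nodes` and `weights`.
#' @export
prior_grid <- function(n_points = 61L, range = c(-4, 4), mean = 0, sd = 1) {
  if (n_points < 2L) stop("need at least 2 nodes")
  nodes <- seq(range[1L], range[2L], length.out = n_points)
  w <- stats::dnorm(nodes, mean, sd)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "prior_grid")
}

#' @export
print.prior_grid <- function(x, ...) {
  cat(sprintf("<prior_grid: %d nodes on [%g, %g]>\n", length(x$nodes),
              min(x$nodes), max(x$nodes)))
  invisible(x)
}

# ---- fast internal bank representation -------------------------------------

bank_mats <- function(bank) {
  J <- nrow(bank)
  K <- max(bank$m) - 1L
  thr <- lapply(seq_len(J), function(j) item_thresholds(bank, j))
  grm <- bank$model == "GRM"
  # padded threshold matrix for the GRM info kernel (Inf => category prob 0)
  B <- matrix(Inf, J, K)
  for (j in seq_len(J)) B[j, seq_len(bank$m[j] - 1L)] <- thr[[j]]
  # padded cumulative-step matrix for the GPCM kernel (NA => masked)
  CS <- matrix(NA_real_, J, K + 1L)
  for (j in which(!grm)) CS[j, seq_len(bank$m[j])] <- cumsum(c(0, thr[[j]]))
  list(ids = bank$item_id, model = bank$model, a = bank$a, D = bank$D,
       m = bank$m, thr = thr, grm = grm, B = B, CS = CS)
}

# information of every bank item at a single theta, fully vectorized
fast_bank_info <- function(mats, theta) {
  J <- length(mats$a)
  info <- numeric(J)
  aD <- mats$a * mats$D
  if (any(mats$grm)) {
    g <- which(mats$grm)
    Pstar <- stats::plogis(aD[g] * (theta - mats$B[g, , drop = FALSE]))
    dPs <- aD[g] * Pstar * (1 - Pstar)
    P <- cbind(1, Pstar) - cbind(Pstar, 0)
    dP <- cbind(0, dPs) - cbind(dPs, 0)
    info[g] <- rowSums((dP * dP / pmax(P, 1e-300)) * (P > 0))
  }
  if (any(!mats$grm)) {
    p <- which(!mats$grm)
    CS <- mats$CS[p, , drop = FALSE]
    Tt <- col(CS)                      # t + 1
    S <- aD[p] * (theta * Tt - CS)
    S[is.na(S)] <- -Inf
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    Pm <- E / rowSums(E)
    sc <- Tt - 1
    mu <- rowSums(Pm * sc)
    info[p] <- aD[p]^2 * (rowSums(Pm * sc * sc) - mu^2)
  }
  info
}

# per-item K x m matrices of log category probabilities over the grid nodes
grid_logprobs <- function(mats, nodes) {
  lapply(seq_along(mats$a), function(j) {
    P <- if (mats$model[j] == "GRM")
      grm_prob_matrix(nodes, mats$a[j], mats$thr[[j]], mats$D[j])
    else gpcm_prob_matrix(nodes, mats$a[j], mats$thr[[j]], mats$D[j])
    log(pmax(P, 1e-300))
  })
}

#' Expected a posteriori (EAP) trait estimate
#'
#' Posterior mean of the latent trait on the prior grid,
#' \eqn{\hat\theta = \sum_k \theta_k w_k L_k / \sum_k w_k L_k}. The reported
#' standard error is the information-based \eqn{1/\sqrt{\sum_i I_i(\hat\theta)}}
#' over the answered items (the posterior standard deviation is returned
#' alongside as `posterior_sd`). With no observed responses the estimate is
#' the prior mean with infinite information-based SE.
#'
#' @param pattern Integer vector of 0-based codes aligned with `items`;
#'   `NA` = missing/not administered.
#' @param items An `item_bank` (or list of `item_params`).
#' @param grid A [prior_grid()].
#' @return A list with `theta`, `se`, `posterior_sd`, `n_items`.
#' @export
eap_estimate <- function(pattern, items, grid = prior_grid()) {
  bank <- as_bank(items)
  if (length(pattern) != nrow(bank))
    stop("pattern length must equal the number of items")
  mats <- bank_mats(bank)
  LP <- grid_logprobs(mats, grid$nodes)
  eap_kernel(pattern, mats, LP, grid)
}

eap_kernel <- function(pattern, mats, LP, grid) {
  obs <- which(!is.na(pattern))
  logpost <- log(grid$weights)
  for (j in obs) logpost <- logpost + LP[[j]][, pattern[j] + 1L]
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  theta <- sum(grid$nodes * w)
  psd <- sqrt(max(sum(grid$nodes^2 * w) - theta^2, 0))
  if (length(obs)) {
    ti <- sum(fast_bank_info(mats, theta)[obs])
    se <- if (ti > 0) 1 / sqrt(ti) else Inf
  } else se <- Inf
  list(theta = theta, se = se, posterior_sd = psd, n_items = length(obs))
}

#' EAP scores for a whole cohort
#'
#' @param X 0-based response matrix (columns matching `bank$item_id`, or
#'   unnamed in bank order).
#' @param bank An `item_bank`.
#' @param grid A [prior_grid()].
#' @return Data frame with one row per respondent: `id`, `theta`, `se`
#'   (information-based), `posterior_sd`, `n_items`.
#' @export
eap_scores <- function(X, bank, grid = prior_grid()) {
  bank <- as_bank(bank)
  X <- check_responses(X, bank)
  mats <- bank_mats(bank)
  LP <- grid_logprobs(mats, grid$nodes)
  N <- nrow(X); K <- length(grid$nodes)
  LL <- matrix(log(grid$weights), K, N)
  for (j in seq_len(ncol(X))) {
    obs <- which(!is.na(X[, j]))
    if (length(obs))
      LL[, obs] <- LL[, obs] + LP[[j]][, X[obs, j] + 1L, drop = FALSE]
  }
  mx <- apply(LL, 2L, max)
  W <- exp(sweep(LL, 2L, mx))
  W <- sweep(W, 2L, colSums(W), `/`)
  theta <- drop(crossprod(W, grid$nodes))
  psd <- sqrt(pmax(drop(crossprod(W, grid$nodes^2)) - theta^2, 0))
  # information-based SE at each person's theta, only over observed items
  info <- numeric(N)
  for (j in seq_len(ncol(X))) {
    obs <- !is.na(X[, j])
    if (any(obs))
      info[obs] <- info[obs] + info_kernel(theta[obs], mats$model[j],
                                           mats$a[j], mats$thr[[j]],
                                           mats$D[j])
  }
  n_items <- rowSums(!is.na(X))
  se <- ifelse(info > 0, 1 / sqrt(info), Inf)
  data.frame(id = rownames(X) %||% as.character(seq_len(N)), theta = theta,
             se = se, posterior_sd = psd, n_items = n_items,
             stringsAsFactors = FALSE)
}

#' Maximum-information item selection
#'
#' Returns the unadministered item with the largest Fisher information at the
#' current trait estimate; ties go to the earliest bank position. When every
#' item has been used, a classed error (`polycat_bank_exhausted`) is raised.
#'
#' @param theta_hat Current trait estimate.
#' @param bank An `item_bank`.
#' @param administered Character vector of already-used item ids (or integer
#'   positions).
#' @return The selected item id.
#' @export
select_next_item <- function(theta_hat, bank, administered = character(0)) {
  bank <- as_bank(bank)
  used <- if (is.numeric(administered)) as.integer(administered)
          else match(administered, bank$item_id)
  cand <- setdiff(seq_len(nrow(bank)), used)
  if (!length(cand))
    stop(structure(class = c("polycat_bank_exhausted", "error", "condition"),
                   list(message = "item bank exhausted", call = sys.call())))
  info <- fast_bank_info(bank_mats(bank), theta_hat)[cand]
  bank$item_id[cand[which.max(info)]]
}

#' Stop rules for adaptive testing
#'
#' Three termination criteria: `"se"` stops once the information-based
#' standard error falls to `se_target` or below; `"length"` stops after a
#' fixed number of items; `"all"` administers the entire bank.
#'
#' @param kind `"se"`, `"length"` or `"all"`.
#' @param se_target Positive SE target (required for `kind = "se"`).
#' @param length Positive item count (required for `kind = "length"`).
#' @return An object of class `stop_rule`.
#' @examples
#' stop_rule("se", se_target = 0.4)
#' stop_rule("length", length = 16)
#' stop_rule("all")
#' @export
stop_rule <- function(kind = c("se", "length", "all"), se_target = NULL,
                      length = NULL) {
  kind <- match.arg(kind)
  if (kind == "se") {
    if (is.null(se_target) || se_target <= 0)
      stop("kind = 'se' needs a positive 'se_target'")
    length <- NULL
  } else if (kind == "length") {
    if (is.null(length) || length < 1L)
      stop("kind = 'length' needs a positive 'length'")
    length <- as.integer(length)
    se_target <- NULL
  } else {
    se_target <- NULL; length <- NULL
  }
  structure(list(kind = kind, se_target = se_target, length = length),
            class = "stop_rule")
}

#' @export
print.stop_rule <- function(x, ...) {
  cat(switch(x$kind,
             se = sprintf("<stop_rule: SE(theta) <= %g>\n", x$se_target),
             length = sprintf("<stop_rule: fixed length %d>\n", x$length),
             all = "<stop_rule: administer all items>\n"))
  invisible(x)
}

#' Post-hoc (real-data) adaptive test for one respondent
#'
#' Replays a respondent's recorded answers through the adaptive loop: start
#' at the prior mean, select the unadministered item with maximum information
#' at the current estimate, read the recorded answer, re-estimate by EAP, and
#' stop when the rule fires. Items the respondent never answered (`NA`) are
#' treated as unavailable and skipped by the selector. The loop is fully
#' deterministic. At least one item is administered before any SE stop check.
#'
#' @param pattern The respondent's complete observed 0-based responses,
#'   aligned with `bank` (or named by item id).
#' @param bank An `item_bank`.
#' @param rule A [stop_rule()].
#' @param grid A [prior_grid()].
#' @return An object of class `cat_result`: `administered` (item ids in
#'   order), `responses`, `theta_hat`, `se_final`, `posterior_sd`,
#'   `theta_trajectory`, `se_trajectory`, `stopped_by` (one of `TARGET_MET`,
#'   `BANK_EXHAUSTED`, `LENGTH_REACHED`).
#' @export
run_cat_posthoc <- function(pattern, bank, rule, grid = prior_grid()) {
  bank <- as_bank(bank)
  stopifnot(inherits(rule, "stop_rule"))
  if (!is.null(names(pattern))) pattern <- pattern[bank$item_id]
  if (length(pattern) != nrow(bank))
    stop("pattern must cover every bank item")
  if (rule$kind == "length" && rule$length > nrow(bank))
    stop("fixed length ", rule$length, " exceeds the bank size ", nrow(bank))
  mats <- bank_mats(bank)
  LP <- grid_logprobs(mats, grid$nodes)
  res <- cat_kernel(as.integer(pattern), mats, LP, grid, rule)
  res$administered <- bank$item_id[res$administered]
  class(res) <- "cat_result"
  res
}

# the adaptive loop on precomputed structures; pattern is 0-based integer
cat_kernel <- function(pattern, mats, LP, grid, rule, min_items = 1L) {
  avail <- which(!is.na(pattern))
  logw <- log(grid$weights)
  logpost <- logw
  theta <- sum(grid$nodes * grid$weights)
  administered <- integer(0)
  th_traj <- numeric(0); se_traj <- numeric(0)
  se <- Inf; psd <- 1
  stopped <- NULL
  repeat {
    if (rule$kind == "length" && length(administered) >= rule$length) {
      stopped <- "LENGTH_REACHED"; break
    }
    cand <- setdiff(avail, administered)
    if (!length(cand)) { stopped <- "BANK_EXHAUSTED"; break }
    info <- fast_bank_info(mats, theta)[cand]
    nxt <- cand[which.max(info)]     # first max = lowest bank position
    administered <- c(administered, nxt)
    logpost <- logpost + LP[[nxt]][, pattern[nxt] + 1L]
    w <- exp(logpost - max(logpost)); w <- w / sum(w)
    theta <- sum(grid$nodes * w)
    psd <- sqrt(max(sum(grid$nodes^2 * w) - theta^2, 0))
    ti <- sum(fast_bank_info(mats, theta)[administered])
    se <- if (ti > 0) 1 / sqrt(ti) else Inf
    th_traj <- c(th_traj, theta); se_traj <- c(se_traj, se)
    if (rule$kind == "se" && length(administered) >= min_items &&
        se <= rule$se_target) { stopped <- "TARGET_MET"; break }
  }
  list(administered = administered,
       responses = pattern[administered],
       theta_hat = theta, se_final = se, posterior_sd = psd,
       theta_trajectory = th_traj, se_trajectory = se_traj,
       stopped_by = stopped)
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf(
    "<cat_result: %d items, theta = %.3f, SE = %.3f, stopped by %s>\n",
    length(x$administered), x$theta_hat, x$se_final, x$stopped_by))
  cat("  sequence:", paste(utils::head(x$administered, 10), collapse = ", "),
      if (length(x$administered) > 10) "..." else "", "\n")
  invisible(x)
}

#' Post-hoc adaptive-test simulation over a cohort
#'
#' Runs [run_cat_posthoc()] for every respondent and aggregates the
#' stop-rule-table quantities: mean and SD of items used, cohort mean of the
#' per-person information-based SE, marginal reliability
#' \eqn{MR = 1 - \overline{SE}^2}, and the Pearson correlation between the
#' adaptive trait estimates and the full-bank ("all items") EAP estimates.
#'
#' @param X 0-based response matrix covering the bank.
#' @param bank An `item_bank`.
#' @param rule A [stop_rule()].
#' @param grid A [prior_grid()].
#' @param full_theta Optional precomputed full-bank EAP estimates (as from
#'   [eap_scores()]`$theta`), to avoid recomputing across rules.
#' @return An object of class `cohort_sim` with `per_person` (data frame:
#'   `id`, `n_items`, `theta`, `se`, `posterior_sd`, `stopped_by`),
#'   `mean_items`, `sd_items`, `mean_se`, `mr`, `corr_with_full`, `rule`.
#' @export
simulate_cohort <- function(X, bank, rule, grid = prior_grid(),
                            full_theta = NULL) {
  bank <- as_bank(bank)
  X <- check_responses(X, bank)
  if (nrow(X) < 2L) stop("need at least 2 respondents for a cohort")
  mats <- bank_mats(bank)
  LP <- grid_logprobs(mats, grid$nodes)
  if (is.null(full_theta)) full_theta <- eap_scores(X, bank, grid)$theta
  N <- nrow(X)
  n_items <- integer(N); theta <- numeric(N); se <- numeric(N)
  psd <- numeric(N); stopped <- character(N)
  for (i in seq_len(N)) {
    r <- cat_kernel(X[i, ], mats, LP, grid, rule)
    n_items[i] <- length(r$administered)
    theta[i] <- r$theta_hat; se[i] <- r$se_final
    psd[i] <- r$posterior_sd; stopped[i] <- r$stopped_by
  }
  per <- data.frame(id = rownames(X) %||% as.character(seq_len(N)),
                    n_items = n_items, theta = theta, se = se,
                    posterior_sd = psd, stopped_by = stopped,
                    stringsAsFactors = FALSE)
  structure(list(per_person = per,
                 mean_items = mean(n_items), sd_items = stats::sd(n_items),
                 mean_se = mean(se), mr = marginal_reliability(se),
                 corr_with_full = stats::cor(theta, full_theta),
                 rule = rule),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  lab <- switch(x$rule$kind,
                se = sprintf("SE(theta) = %g", x$rule$se_target),
                length = sprintf("length = %d", x$rule$length),
                all = "All")
  cat(sprintf(
    "%-18s items used %.2f (SD %.2f)  mean SE %.2f  MR %.2f  r(full) %.2f\n",
    lab, x$mean_items, x$sd_items, x$mean_se, x$mr, x$corr_with_full))
  invisible(x)
}
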