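#' Cumulative category probability of a graded response model item
#'
#' For a GRM item, `grm_cumulative()` returns the probability of scoring in
#' category `t` or higher,
#' \deqn{P(X \ge t) = \frac{1}{1 + \exp[-D a (\theta - b_t)]},}
#' with the boundary conventions \eqn{P(X \ge 0) = 1} and
#' \eqn{P(X \ge m) = 0}.
#'
#' @param theta Latent trait value(s).
#' @param item An [item_params()] object with `model = "GRM"`.
#' @param t Category index, `0 <= t <= m` (scores run 0..m-1).
#' @return Probability (vectorized over `theta`).
#' @export
grm_cumulative <- function(theta, item, t) {
  item <- as_item(item)
  if (item$model != "GRM") stop("grm_cumulative() needs a GRM item")
  if (length(t) != 1L || t != round(t) || t < 0 || t > item$m)
    stop("category index t must be an integer in [0, m]")
  if (t == 0) return(rep(1, length(theta)))
  if (t == item$m) return(rep(0, length(theta)))
  stats::plogis(item$D * item$a * (theta - item$thresholds[t]))
}

#' Category response probabilities
#'
#' `grm_category_probs()` gives the GRM category probabilities as adjacent
#' differences of cumulative probabilities,
#' \eqn{P(X = t) = P(X \ge t) - P(X \ge t + 1)}.
#' `gpcm_category_probs()` gives the GPCM probabilities
#' \deqn{P(X = t) = \frac{\exp \sum_{v=0}^{t} D a (\theta - \delta_v)}
#'                      {\sum_{h=0}^{m-1} \exp \sum_{v=0}^{h} D a (\theta - \delta_v)}}
#' with \eqn{\delta_0 \equiv 0}, computed with log-sum-exp normalization so
#' that extreme arguments do not overflow. `category_probs()` dispatches on
#' the item's model.
#'
#' @inheritParams grm_cumulative
#' @return For a single `theta`, a vector of `m` probabilities summing to 1;
#'   for a vector `theta`, a `length(theta) x m` matrix.
#' @export
grm_category_probs <- function(theta, item) {
  item <- as_item(item)
  if (item$model != "GRM") stop("grm_category_probs() needs a GRM item")
  P <- grm_prob_matrix(theta, item$a, item$thresholds, item$D)
  if (length(theta) == 1L) drop(P) else P
}

#' @rdname grm_category_probs
#' @export
gpcm_category_probs <- function(theta, item) {
  item <- as_item(item)
  if (item$model != "GPCM") stop("gpcm_category_probs() needs a GPCM item")
  P <- gpcm_prob_matrix(theta, item$a, item$thresholds, item$D)
  if (length(theta) == 1L) drop(P) else P
}

#' @rdname grm_category_probs
#' @export
category_probs <- function(theta, item) {
  item <- as_item(item)
  if (item$model == "GRM") grm_category_probs(theta, item)
  else gpcm_category_probs(theta, item)
}

# --- internal probability kernels (vectorized over theta) -------------------

# length(theta) x m matrix of GRM category probabilities
grm_prob_matrix <- function(theta, a, b, D) {
  if (is.unsorted(b)) stop("GRM thresholds must be nondecreasing")
  Pstar <- stats::plogis(D * a * outer(theta, b, `-`))  # n x (m-1)
  P <- cbind(1, Pstar) - cbind(Pstar, 0)
  pmax(P, 0)  # guard tiny negative round-off at tied thresholds
}

# length(theta) x m matrix of GPCM category probabilities (log-sum-exp safe)
gpcm_prob_matrix <- function(theta, a, delta, D) {
  csum <- cumsum(c(0, delta))                    # cumulative step locations
  m <- length(csum)
  # s_t(theta) = D a [ (t+1) theta - csum_t ], t = 0..m-1
  S <- D * a * (outer(theta, seq_len(m)) - matrix(csum, length(theta), m,
                                                  byrow = TRUE))
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

as_item <- function(item) {
  if (inherits(item, "item_params")) return(item)
  if (inherits(item, "item_bank")) {
    if (nrow(item) != 1L)
      stop("expected a single item; got a bank of ", nrow(item))
    return(bank_item(item, 1L))
  }
  stop("'item' must be an item_params object or a one-row item_bank")
}

# coerce a bank-or-list-of-items argument to an item_bank
as_bank <- function(items) {
  if (inherits(items, "item_bank")) return(items)
  if (inherits(items, "item_params")) return(item_bank(list(items)))
  if (is.list(items)) return(item_bank(items))
  stop("'items' must be an item_bank, an item_params, or a list of them")
}

#' Fisher information of one item
#'
#' The information a polytomous item carries about the latent trait,
#' \eqn{I(\theta) = \sum_t P_t'(\theta)^2 / P_t(\theta)}. For the GRM the
#' category derivatives are differences of cumulative-curve derivatives
#' \eqn{D a P^*(1-P^*)}; for the GPCM the sum collapses to
#' \eqn{(D a)^2 \mathrm{Var}(T \mid \theta)} where `T` is the category score.
#'
#' @inheritParams grm_cumulative
#' @return Nonnegative information value(s), vectorized over `theta`.
#' @export
item_information <- function(theta, item) {
  item <- as_item(item)
  info_kernel(theta, item$model, item$a, item$thresholds, item$D)
}

info_kernel <- function(theta, model, a, thr, D) {
  if (model == "GRM") {
    Pstar <- stats::plogis(D * a * outer(theta, thr, `-`))
    dPstar <- D * a * Pstar * (1 - Pstar)
    P <- cbind(1, Pstar) - cbind(Pstar, 0)
    dP <- cbind(0, dPstar) - cbind(dPstar, 0)
    ok <- P > 0
    rowSums(ifelse(ok, dP^2 / pmax(P, .Machine$double.xmin), 0))
  } else {
    P <- gpcm_prob_matrix(theta, a, thr, D)
    scores <- seq_len(ncol(P)) - 1
    mu <- drop(P %*% scores)
    (D * a)^2 * (drop(P %*% scores^2) - mu^2)
  }
}

#' Test information, standard error and marginal reliability
#'
#' `test_information()` sums [item_information()] over a set of items.
#' `standard_error()` is the information-based standard error
#' \eqn{SE(\theta) = 1 / \sqrt{\sum_i I_i(\theta)}}; it returns `Inf` (not an
#' error) when the items carry no information at `theta`.
#' `marginal_reliability()` converts a cohort of per-person standard errors
#' into the marginal reliability
#' \eqn{MR = 1 - \overline{SE}^2}, with \eqn{\overline{SE}} the cohort mean.
#'
#' @inheritParams grm_cumulative
#' @param items An `item_bank` (or list of `item_params`); must be nonempty.
#' @return `test_information()` and `standard_error()` are vectorized over
#'   `theta`; `marginal_reliability()` returns a single number `<= 1`.
#' @examples
#' marginal_reliability(rep(0.30, 885))  # 0.91
#' @export
test_information <- function(theta, items) {
  bank <- as_bank(items)
  info <- numeric(length(theta))
  for (j in seq_len(nrow(bank)))
    info <- info + info_kernel(theta, bank$model[j], bank$a[j],
                               item_thresholds(bank, j), bank$D[j])
  info
}

#' @rdname test_information
#' @export
standard_error <- function(theta, items) {
  info <- test_information(theta, items)
  ifelse(info > 0, 1 / sqrt(info), Inf)
}

#' @rdname test_information
#' @param se_values Vector of positive per-person standard errors.
#' @export
marginal_reliability <- function(se_values) {
  if (!length(se_values)) stop("'se_values' must be nonempty")
  1 - mean(se_values)^2
}

#' Log-likelihood of one response pattern
#'
#' Sum over observed items of the log category probability at `theta`.
#' Missing entries (`NA`) are skipped; an all-missing pattern contributes a
#' log-likelihood of 0 (with a warning).
#'
#' @param pattern Integer vector of 0-based category codes, aligned with
#'   `items`; `NA` marks a missing response.
#' @inheritParams test_information
#' @param theta Single latent trait value.
#' @return The log-likelihood (a nonpositive number).
#' @export
response_loglik <- function(pattern, theta, items) {
  bank <- as_bank(items)
  if (length(pattern) != nrow(bank))
    stop("pattern length must equal the number of items")
  obs <- which(!is.na(pattern))
  if (!length(obs)) {
    warning("all responses missing; log-likelihood is 0")
    return(0)
  }
  ll <- 0
  for (j in obs) {
    x <- pattern[j]
    if (x < 0L || x >= bank$m[j])
      stop("code ", x, " outside [0, ", bank$m[j] - 1L, "] for item ",
           bank$item_id[j])
    p <- category_probs(theta, bank_item(bank, j))[x + 1L]
    ll <- ll + log(p)
  }
  ll
}
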