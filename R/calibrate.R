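#' Calibrate a polytomous item bank by marginal maximum likelihood
#'
#' Fits the graded response model (GRM) or generalized partial credit model
#' (GPCM) to an ordinal response matrix with the Bock-Aitkin EM algorithm:
#' the latent trait is integrated over a fixed rectangular quadrature grid
#' under a standard-normal prior (which also identifies the latent scale),
#' the E-step forms posterior node weights per respondent, and the M-step
#' updates each item by quasi-Newton maximization of its expected
#' complete-data log-likelihood. Discriminations are kept positive and GRM
#' thresholds ordered by an unconstrained reparameterisation (log slope;
#' first threshold plus log gaps), so no post-hoc sorting is ever needed.
#'
#' Items whose observed responses skip a category are collapsed onto the
#' observed categories (with a warning); items with no response variance are
#' excluded from the fit and reported in `$excluded`.
#'
#' @param X Integer matrix of 0-based category codes, respondents in rows,
#'   items in columns (column names become item ids); `NA` = missing.
#' @param model `"GRM"` or `"GPCM"`.
#' @param n_quadrature Number of quadrature nodes (default 61).
#' @param quad_range Quadrature interval (default `c(-4, 4)`).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the change in marginal log-likelihood.
#' @param D Logistic scaling constant applied to every item.
#' @param verbose Print the log-likelihood trace while fitting.
#' @return An object of class `irt_fit` with components `bank` (the
#'   estimated [item_bank()]), `loglik`, `loglik_trace`, `n_respondents`,
#'   `n_parameters`, `converged`, `iterations`, `excluded`, `collapsed`,
#'   `grid`, `model`, and `call`. Methods: `print`, `summary`, `coef`,
#'   `logLik` (so `AIC()`/`BIC()` work), `predict` (EAP trait scores),
#'   `plot` (test information and SE curves), `simulate`.
#' @seealso [fit_indices()], [select_model()], [eap_estimate()]
#' @examples
#' spec <- synth_spec(scale_layout = list(c(6, 4)), n_respondents = 300,
#'                    seed = 7)
#' dat <- generate_dataset(spec)
#' fit <- fit_irt(dat$responses, model = "GRM", tol = 1e-3)
#' coef(fit)
#' @export
fit_irt <- function(X, model = c("GRM", "GPCM"), n_quadrature = 61L,
                    quad_range = c(-4, 4), max_iter = 500L, tol = 1e-4,
                    D = 1, verbose = FALSE) {
  model <- match.arg(toupper(model[1L]), c("GRM", "GPCM"))
  if (n_quadrature < 11L) stop("use at least 11 quadrature nodes")
  if (tol <= 0) stop("'tol' must be positive")
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
  N <- nrow(X)
  item_ids <- colnames(X)

  # per-item category bookkeeping: collapse unobserved categories
  keep <- logical(ncol(X))
  collapsed <- character(0)
  codes <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    obs <- sort(unique(X[!is.na(X[, j]), j]))
    if (length(obs) < 2L) next      # degenerate item
    if (sum(!is.na(X[, j])) < 2L) next
    keep[j] <- TRUE
    full <- seq.int(min(0L, obs[1L]), obs[length(obs)])
    if (!identical(obs, seq.int(0L, length(obs) - 1L))) {
      collapsed <- c(collapsed, item_ids[j])
      X[, j] <- match(X[, j], obs) - 1L
    }
    codes[[j]] <- seq.int(0L, length(obs) - 1L)
  }
  excluded <- item_ids[!keep]
  if (length(excluded))
    warning("excluding degenerate item(s): ",
            paste(excluded, collapse = ", "))
  if (length(collapsed))
    warning("collapsed unobserved categories for: ",
            paste(collapsed, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  item_ids <- item_ids[keep]
  J <- ncol(X)
  if (!J) stop("no calibratable items")
  m <- vapply(seq_len(J), function(j) length(codes[[which(keep)[j]]]),
              integer(1))

  grid <- prior_grid(n_quadrature, quad_range)
  nodes <- grid$nodes; logw <- log(grid$weights)
  K <- length(nodes)

  # starting values: a = 1, thresholds from inverse-logistic sample
  # cumulative proportions (clamped, minimally spaced)
  a <- rep(1, J)
  thr <- vector("list", J)
  for (j in seq_len(J)) {
    x <- X[!is.na(X[, j]), j]
    p <- vapply(seq_len(m[j] - 1L), function(t) mean(x >= t), numeric(1))
    p <- pmin(pmax(p, 0.005), 0.995)
    b <- -stats::qlogis(p) / D
    b <- cummax(b + 1e-3 * (seq_along(b) - 1L))  # enforce increasing start
    thr[[j]] <- b
  }

  xm <- X + 1L  # 1-based category index, NA kept
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    # E-step: log-likelihood of each respondent at each node
    LL <- matrix(0, K, N)
    LP <- vector("list", J)
    for (j in seq_len(J)) {
      P <- if (model == "GRM") grm_prob_matrix(nodes, a[j], thr[[j]], D)
           else gpcm_prob_matrix(nodes, a[j], thr[[j]], D)
      LP[[j]] <- log(pmax(P, 1e-300))
      obs <- which(!is.na(xm[, j]))
      LL[, obs] <- LL[, obs] + LP[[j]][, xm[obs, j], drop = FALSE]
    }
    LJ <- LL + logw
    mx <- apply(LJ, 2L, max)
    W <- exp(sweep(LJ, 2L, mx))
    marg <- colSums(W)
    ll <- sum(mx + log(marg))
    loglik_trace <- c(loglik_trace, ll)
    if (verbose) message(sprintf("iter %3d  loglik %.6f", iter, ll))
    post <- sweep(W, 2L, marg, `/`)            # K x N posterior weights

    if (ll - prev_ll < tol && iter > 1L) { converged <- TRUE; break }
    if (iter >= max_iter) break
    prev_ll <- ll

    # M-step: per-item expected counts and quasi-Newton update
    for (j in seq_len(J)) {
      obs <- which(!is.na(xm[, j]))
      ind <- matrix(0, length(obs), m[j])
      ind[cbind(seq_along(obs), xm[obs, j])] <- 1
      R <- post[, obs, drop = FALSE] %*% ind    # K x m expected counts
      par0 <- pack_params(model, a[j], thr[[j]])
      nll <- function(par) {
        pt <- unpack_params(model, par, m[j])
        P <- if (model == "GRM") grm_prob_matrix(nodes, pt$a, pt$thr, D)
             else gpcm_prob_matrix(nodes, pt$a, pt$thr, D)
        -sum(R * log(pmax(P, 1e-300)))
      }
      opt <- try(stats::optim(par0, nll, method = "BFGS",
                              control = list(maxit = 30L)), silent = TRUE)
      if (!inherits(opt, "try-error") && is.finite(opt$value) &&
          opt$value <= nll(par0) + 1e-10) {
        pt <- unpack_params(model, opt$par, m[j])
        a[j] <- pt$a; thr[[j]] <- pt$thr
      }
    }
  }

  items <- lapply(seq_len(J), function(j)
    item_params(item_ids[j], a = a[j], thresholds = thr[[j]], model = model,
                scale_id = "bank", D = D))
  bank <- item_bank(items, provenance = sprintf(
    "MML-EM %s fit, N = %d, %d nodes on [%g, %g]", model, N, K,
    quad_range[1L], quad_range[2L]))

  structure(
    list(bank = bank, model = model, loglik = ll,
         loglik_trace = loglik_trace, n_respondents = N,
         n_parameters = sum(m), converged = converged, iterations = iter,
         excluded = excluded, collapsed = collapsed, grid = grid,
         data_dim = dim(X), call = match.call()),
    class = "irt_fit")
}

# monotone reparameterisation: GRM thresholds as (b1, log gaps)
pack_params <- function(model, a, thr) {
  if (model == "GRM" && length(thr) > 1L)
    c(log(a), thr[1L], log(pmax(diff(thr), 1e-6)))
  else c(log(a), thr)
}

unpack_params <- function(model, par, m) {
  a <- exp(par[1L])
  rest <- par[-1L]
  thr <- if (model == "GRM" && m > 2L)
    cumsum(c(rest[1L], exp(rest[-1L])))
  else rest
  list(a = a, thr = thr)
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("<irt_fit: %s, %d items, N = %d>\n", x$model, nrow(x$bank),
              x$n_respondents))
  cat(sprintf("  logLik %.2f on %d item parameters; %s in %d EM iterations\n",
              x$loglik, x$n_parameters,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.irt_fit <- function(object, ...) {
  bank <- object$bank
  K <- max(bank$m) - 1L
  out <- as.matrix(bank[, c("a", paste0("b", seq_len(K)))])
  rownames(out) <- bank$item_id
  out
}

#' @export
logLik.irt_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters,
            nobs = object$n_respondents, class = "logLik")
}

#' @export
summary.irt_fit <- function(object, ...) {
  fi <- fit_indices(-2 * object$loglik, object$n_parameters,
                    object$n_respondents)
  out <- list(fit = object, indices = fi,
              a_summary = summary(object$bank$a))
  class(out) <- "summary.irt_fit"
  out
}

#' @export
print.summary.irt_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  -2LL = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$indices$neg2ll, x$indices$aic, x$indices$bic))
  cat("  discrimination summary:\n")
  print(x$a_summary)
  invisible(x)
}

#' @export
predict.irt_fit <- function(object, newdata, ...) {
  eap_scores(newdata, object$bank, object$grid)
}

#' @export
plot.irt_fit <- function(x, theta = seq(-4, 4, length.out = 161), ...) {
  info <- test_information(theta, x$bank)
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(theta, info, type = "l", xlab = expression(theta),
                 ylab = "Test information", main = "Bank information", ...)
  graphics::plot(theta, 1 / sqrt(pmax(info, 1e-12)), type = "l",
                 xlab = expression(theta), ylab = expression(SE(theta)),
                 main = "Standard error", ...)
  invisible(x)
}

#' @export
simulate.irt_fit <- function(object, nsim = 1, seed = NULL, thetas = NULL,
                             ...) {
  if (is.null(thetas)) thetas <- stats::rnorm(object$n_respondents)
  simulate_responses(object$bank, thetas, seed = seed)
}

#' Count free item parameters of a bank
#'
#' Each item contributes one discrimination and `m - 1` thresholds, so a
#' bank's free parameter count is \eqn{\sum_j m_j}.
#'
#' @param bank An `item_bank`, or `NULL`/empty for 0.
#' @return Integer parameter count.
#' @examples
#' count_free_parameters(NULL)  # 0
#' @export
count_free_parameters <- function(bank) {
  if (is.null(bank) || !length(bank) || !nrow(bank)) return(0L)
  sum(as.integer(bank$m))
}

#' Information criteria from a deviance
#'
#' `AIC = -2LL + 2p` and `BIC = -2LL + p log N`. Exposed separately from
#' [fit_irt()] so that printed deviances can be converted to information
#' criteria without refitting.
#'
#' @param neg2ll Deviance (-2 log-likelihood).
#' @param p Number of free parameters (`p >= 0`).
#' @param N Number of respondents (`N >= 1`).
#' @return A list of class `fit_indices` with `neg2ll`, `aic`, `bic`.
#' @examples
#' fit_indices(192627.34, 471, 885)
#' @export
fit_indices <- function(neg2ll, p, N) {
  if (p < 0 || N < 1) stop("need p >= 0 and N >= 1")
  structure(list(neg2ll = neg2ll, aic = neg2ll + 2 * p,
                 bic = neg2ll + p * log(N)),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("-2LL = %.2f  AIC = %.1f  BIC = %.1f\n", x$neg2ll, x$aic,
              x$bic))
  invisible(x)
}

#' Choose between two calibrated models
#'
#' Compares two [fit_irt()] results on the same data by AIC (smaller is
#' better). If AIC and BIC disagree, AIC decides and a warning notes the
#' disagreement; an exact tie returns `"GRM"` as the default family.
#'
#' @param fit_grm,fit_gpcm `irt_fit` objects fitted to identical data.
#' @return `"GRM"` or `"GPCM"`.
#' @export
select_model <- function(fit_grm, fit_gpcm) {
  stopifnot(inherits(fit_grm, "irt_fit"), inherits(fit_gpcm, "irt_fit"))
  if (!identical(fit_grm$data_dim, fit_gpcm$data_dim))
    stop("the two fits are not on identically shaped data")
  fa <- fit_indices(-2 * fit_grm$loglik, fit_grm$n_parameters,
                    fit_grm$n_respondents)
  fb <- fit_indices(-2 * fit_gpcm$loglik, fit_gpcm$n_parameters,
                    fit_gpcm$n_respondents)
  aic_pick <- if (fa$aic <= fb$aic) fit_grm$model else fit_gpcm$model
  bic_pick <- if (fa$bic <= fb$bic) fit_grm$model else fit_gpcm$model
  if (aic_pick != bic_pick)
    warning("AIC and BIC disagree; following AIC (", aic_pick, ")")
  if (fa$aic == fb$aic && fa$bic == fb$bic)
    message("information criteria tie; defaulting to GRM")
  aic_pick
}
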