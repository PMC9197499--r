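test_that("the prior grid is a proper discrete distribution", {
  g <- prior_grid()
  expect_length(g$nodes, 61)
  expect_true(all(g$weights > 0))
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
})

test_that("EAP returns the prior mean with no data and respects symmetry", {
  bank <- toy_bank(5)
  e <- eap_estimate(rep(NA_integer_, 5), bank)
  expect_equal(e$theta, 0, tolerance = 1e-12)
  expect_equal(e$se, Inf)
  expect_equal(e$posterior_sd, 1, tolerance = 0.01)
  # mirrored dichotomous items answered in opposite directions cancel out
  mirror <- item_bank(list(dich_item("p", a = 1.3, b = 0.9),
                           dich_item("q", a = 1.3, b = -0.9)))
  e2 <- eap_estimate(c(1L, 0L), mirror)
  expect_equal(e2$theta, 0, tolerance = 1e-10)
})

test_that("EAP matches a dense-grid numerical-integration oracle", {
  bank <- toy_bank(5, m = 4, seed = 2)
  patterns <- list(c(0L, 1L, 3L, 2L, 1L), c(2L, NA, 1L, NA, 0L))
  extreme <- list(c(3L, 3L, 3L, 3L, 3L), c(0L, 0L, 0L, 0L, 0L))
  # oracle: 10001-point trapezoid integration with its own logistic code
  oracle <- function(pattern) {
    th <- seq(-4, 4, length.out = 10001)
    lik <- rep(1, length(th))
    for (j in which(!is.na(pattern))) {
      a <- bank$a[j]
      b <- as.numeric(bank[j, paste0("b", 1:3)])
      cum <- cbind(1, plogis(a * outer(th, b, `-`)), 0)
      lik <- lik * (cum[, pattern[j] + 1] - cum[, pattern[j] + 2])
    }
    post <- lik * dnorm(th)
    w <- c(0.5, rep(1, length(th) - 2), 0.5)   # trapezoid weights
    sum(w * th * post) / sum(w * post)
  }
  for (p in patterns) {
    e <- eap_estimate(p, bank)
    expect_equal(e$theta, oracle(p), tolerance = 1e-4)
  }
  # extreme patterns push the posterior toward the grid edge, where the
  # default 61-node resolution leaves ~1e-3 discretization error; refining
  # the grid recovers the oracle, showing the error is pure quadrature
  for (p in extreme) {
    expect_equal(eap_estimate(p, bank, prior_grid(801))$theta, oracle(p),
                 tolerance = 1e-4)
    expect_equal(eap_estimate(p, bank)$theta, oracle(p), tolerance = 2e-3)
  }
})

test_that("cohort EAP scoring agrees with the per-person estimator", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(6, 4)),
                                     n_respondents = 40, seed = 13))
  sc <- eap_scores(dat$responses, dat$bank)
  for (i in c(1, 17, 40)) {
    e <- eap_estimate(dat$responses[i, ], dat$bank)
    expect_equal(sc$theta[i], e$theta, tolerance = 1e-12)
    expect_equal(sc$se[i], e$se, tolerance = 1e-12)
  }
})

test_that("maximum-information selection picks the dominant item", {
  base <- lapply(1:5, function(j)
    item_params(paste0("e", j), a = 1.1, thresholds = c(-0.5, 0.5)))
  hot <- item_params("hot", a = 2.2, thresholds = c(-0.5, 0.5))
  bank <- item_bank(c(base, list(hot)))
  # brute-force information table over the bank
  info <- vapply(seq_len(nrow(bank)), function(j)
    item_information(0.1, bank_item(bank, j)), numeric(1))
  expect_equal(which.max(info), 6L)
  expect_equal(select_next_item(0.1, bank), "hot")
  # ties break to the lowest bank position
  expect_equal(select_next_item(0.1, bank, administered = "hot"), "e1")
  # exhaustion raises the classed signal
  expect_error(select_next_item(0, bank, administered = bank$item_id),
               class = "polycat_bank_exhausted")
})

test_that("stop rules validate their fields", {
  expect_s3_class(stop_rule("se", se_target = 0.4), "stop_rule")
  expect_error(stop_rule("se"), "se_target")
  expect_error(stop_rule("length"), "length")
  expect_error(stop_rule("se", se_target = -0.1), "positive")
})

test_that("the ALL rule administers everything and reproduces full EAP", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(8, 4)),
                                     n_respondents = 10, seed = 17))
  r <- run_cat_posthoc(dat$responses[3, ], dat$bank, stop_rule("all"))
  expect_length(r$administered, 8)
  expect_equal(sort(r$administered), sort(dat$bank$item_id))
  full <- eap_estimate(dat$responses[3, ], dat$bank)
  expect_equal(r$theta_hat, full$theta, tolerance = 1e-12)
  expect_equal(r$stopped_by, "BANK_EXHAUSTED")
})

test_that("SE-threshold stopping is correct and monotone in the target", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(20, 5)),
                                     n_respondents = 25, seed = 19))
  for (i in 1:10) {
    r <- run_cat_posthoc(dat$responses[i, ], dat$bank,
                         stop_rule("se", se_target = 0.5))
    if (r$stopped_by == "TARGET_MET") {
      expect_lte(r$se_final, 0.5)
      if (length(r$se_trajectory) > 1)
        expect_true(all(r$se_trajectory[-length(r$se_trajectory)] > 0.5))
    } else expect_equal(r$stopped_by, "BANK_EXHAUSTED")
  }
  # stricter targets never shorten the test
  for (i in 1:5) {
    n3 <- length(run_cat_posthoc(dat$responses[i, ], dat$bank,
                                 stop_rule("se", 0.3))$administered)
    n5 <- length(run_cat_posthoc(dat$responses[i, ], dat$bank,
                                 stop_rule("se", 0.5))$administered)
    expect_gte(n3, n5)
  }
})

test_that("fixed-length runs stop exactly at length and validate bounds", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(9, 4)),
                                     n_respondents = 6, seed = 23))
  r <- run_cat_posthoc(dat$responses[1, ], dat$bank,
                       stop_rule("length", length = 4))
  expect_length(r$administered, 4)
  expect_equal(r$stopped_by, "LENGTH_REACHED")
  expect_error(run_cat_posthoc(dat$responses[1, ], dat$bank,
                               stop_rule("length", length = 10)),
               "exceeds the bank size")
})

test_that("missing recorded answers make items unavailable, not imputed", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(7, 4)),
                                     n_respondents = 4, seed = 29))
  pat <- dat$responses[2, ]
  pat[c(2, 5)] <- NA
  r <- run_cat_posthoc(pat, dat$bank, stop_rule("all"))
  expect_length(r$administered, 5)
  expect_false(any(dat$bank$item_id[c(2, 5)] %in% r$administered))
})

test_that("the adaptive loop is deterministic", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(10, 4)),
                                     n_respondents = 8, seed = 31))
  r1 <- run_cat_posthoc(dat$responses[1, ], dat$bank, stop_rule("se", 0.5))
  r2 <- run_cat_posthoc(dat$responses[1, ], dat$bank, stop_rule("se", 0.5))
  expect_identical(r1, r2)
  # duplicated respondents yield identical trajectories in a cohort
  X <- dat$responses[c(1, 1, 3, 3), ]
  sim <- simulate_cohort(X, dat$bank, stop_rule("se", 0.6))
  pp <- sim$per_person
  expect_equal(pp$theta[1], pp$theta[2])
  expect_equal(pp$n_items[3], pp$n_items[4])
})

test_that("cohort simulation under ALL is the self-comparison baseline", {
  dat <- generate_dataset(synth_spec(scale_layout = list(c(8, 4)),
                                     n_respondents = 30, seed = 37))
  sim <- simulate_cohort(dat$responses, dat$bank, stop_rule("all"))
  expect_equal(sim$mean_items, 8)
  expect_equal(sim$sd_items, 0)
  expect_equal(sim$corr_with_full, 1, tolerance = 1e-12)
  expect_equal(sim$mr, 1 - sim$mean_se^2, tolerance = 1e-12)
  expect_error(simulate_cohort(dat$responses[1, , drop = FALSE], dat$bank,
                               stop_rule("all")), "at least 2")
})
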