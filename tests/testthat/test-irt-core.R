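test_that("GRM cumulative probabilities follow the logistic form", {
  it <- dich_item(a = 2, b = 0)
  expect_equal(grm_cumulative(1, it, 1), 1 / (1 + exp(-2)), tolerance = 1e-10)
  # logistic symmetry: theta at a threshold gives exactly 0.5
  it2 <- sas_c3()
  for (t in 1:4)
    expect_equal(grm_cumulative(it2$thresholds[t], it2, t), 0.5)
  # boundary conventions and range checking
  expect_equal(grm_cumulative(0.3, it2, 0), 1)
  expect_equal(grm_cumulative(0.3, it2, 5), 0)
  expect_error(grm_cumulative(0, it2, 6), "category index")
  expect_error(grm_cumulative(0, it2, -1), "category index")
})

test_that("published-example cumulative values match a high-precision oracle", {
  # frozen from an independent arbitrary-precision evaluation of
  # 1/(1+exp(-1.26*(0 - b_t))) at the four thresholds
  expected <- c(0.934616111858, 0.559876289476, 0.171504769975,
                0.010576164001)
  it <- sas_c3()
  got <- vapply(1:4, function(t) grm_cumulative(0, it, t), numeric(1))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("GRM category probabilities are cumulative differences", {
  it <- sas_c3()
  # frozen full category vectors from the independent differencing oracle
  expect_equal(grm_category_probs(-2, it),
               c(0.465091884071, 0.442059587480, 0.076465651213,
                 0.015523566260, 0.000859310976), tolerance = 1e-10)
  expect_equal(grm_category_probs(0, it),
               c(0.065383888142, 0.374739822382, 0.388371519501,
                 0.160928605975, 0.010576164001), tolerance = 1e-10)
  expect_equal(grm_category_probs(2, it),
               c(0.005597288405, 0.053890140709, 0.220404044086,
                 0.602836414027, 0.117272112773), tolerance = 1e-10)
  # dichotomous symmetry
  expect_equal(grm_category_probs(0, dich_item()), c(0.5, 0.5))
})

test_that("GPCM probabilities match the direct summation oracle", {
  it <- item_params("g", a = 1.5, thresholds = c(-1, 0, 1), model = "GPCM")
  # frozen from independent term-by-term exponent sums at theta = 0.5
  expect_equal(gpcm_category_probs(0.5, it),
               c(0.024961927696, 0.236832175946, 0.501373720412,
                 0.236832175946), tolerance = 1e-10)
  # log-sum-exp stability: extreme arguments neither overflow nor NaN
  far <- gpcm_category_probs(500, it)
  expect_true(all(is.finite(far)))
  expect_equal(sum(far), 1, tolerance = 1e-12)
  expect_equal(which.max(far), 4L)
})

test_that("category probabilities are proper distributions (property sweep)", {
  for (s in 1:30) {
    model <- if (s %% 2) "GRM" else "GPCM"
    it <- random_item(model, s)
    for (theta in c(-3.7, -1, 0.3, 2.9)) {
      p <- category_probs(theta, it)
      expect_length(p, it$m)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("GRM cumulative curves decrease in t and increase in theta", {
  for (s in seq(1, 9, 2)) {
    it <- random_item("GRM", s)
    cums <- vapply(1:(it$m - 1), function(t) grm_cumulative(0.37, it, t),
                   numeric(1))
    expect_true(all(diff(cums) < 0))
    grid <- seq(-3, 3, 0.5)
    for (t in 1:(it$m - 1))
      expect_true(all(diff(grm_cumulative(grid, it, t)) > 0))
  }
})

test_that("GPCM with two categories reduces to the GRM", {
  for (b in c(-1.3, 0, 0.8)) {
    g <- item_params("g", a = 1.4, thresholds = b, model = "GRM")
    p <- item_params("p", a = 1.4, thresholds = b, model = "GPCM")
    theta <- seq(-4, 4, 0.25)
    expect_equal(grm_category_probs(theta, g), gpcm_category_probs(theta, p),
                 tolerance = 1e-14)
    expect_equal(item_information(theta, g), item_information(theta, p),
                 tolerance = 1e-12)
  }
})

test_that("item information matches the finite-difference oracle", {
  it <- sas_c3()
  for (theta in -3:3)
    expect_equal(item_information(theta, it), fd_information(theta, it),
                 tolerance = 1e-6)
  gp <- item_params("g", a = 1.5, thresholds = c(-1, 0, 1), model = "GPCM")
  for (theta in -3:3)
    expect_equal(item_information(theta, gp), fd_information(theta, gp),
                 tolerance = 1e-6)
  # dichotomous closed form a^2 P (1-P)
  expect_equal(item_information(0, dich_item()), 0.25, tolerance = 1e-12)
  # nonnegativity sweep
  for (s in 11:20)
    expect_true(all(item_information(seq(-4, 4, 0.5),
                                     random_item("GRM", s)) >= 0))
})

test_that("test information is additive over items", {
  bank <- toy_bank(6)
  expect_equal(test_information(0.4, bank[1, ]),
               item_information(0.4, bank_item(bank, 1)))
  two <- item_bank(list(dich_item("a1"), dich_item("a2")))
  expect_equal(test_information(0.7, two),
               2 * item_information(0.7, dich_item()))
  # brute-force accumulation oracle over a larger synthetic bank
  big <- generate_bank(synth_spec(seed = 5))
  manual <- sum(vapply(seq_len(nrow(big)), function(j)
    item_information(0, bank_item(big, j)), numeric(1)))
  expect_equal(test_information(0, big), manual, tolerance = 1e-12)
})

test_that("standard error is the reciprocal root of test information", {
  two <- item_bank(list(dich_item("a1", a = 2, b = 0),
                        dich_item("a2", a = 2, b = 0)))
  # each item gives 4 * 0.25 = 1 at theta 0, so total information 2
  expect_equal(standard_error(0, two), 1 / sqrt(2))
  # adding an item never increases SE
  bank <- toy_bank(8)
  ses <- vapply(1:8, function(k) standard_error(0.5, bank[1:k, ]),
                numeric(1))
  expect_true(all(diff(ses) < 0))
  # no information => infinite SE, not an error
  far <- item_bank(list(dich_item("f", a = 30, b = 0)))
  expect_equal(standard_error(-30, far), Inf)
})

test_that("marginal reliability is one minus squared mean SE", {
  expect_equal(marginal_reliability(rep(0.30, 885)), 0.91)
  expect_equal(marginal_reliability(rep(0.48, 885)), 0.7696)
  expect_equal(marginal_reliability(rep(0, 10)), 1)
  expect_error(marginal_reliability(numeric(0)), "nonempty")
})

test_that("response log-likelihood sums observed item terms", {
  it <- dich_item()
  expect_equal(response_loglik(1L, 0, item_bank(list(it))), log(0.5))
  two <- item_bank(list(dich_item("a1"), dich_item("a2")))
  expect_equal(response_loglik(c(1L, 1L), 0, two), 2 * log(0.5))
  # term-by-term oracle on a 5-item pattern
  bank <- toy_bank(5)
  pattern <- c(0L, 2L, 3L, 1L, 2L)
  manual <- sum(vapply(1:5, function(j)
    log(category_probs(0.8, bank_item(bank, j))[pattern[j] + 1]),
    numeric(1)))
  expect_equal(response_loglik(pattern, 0.8, bank), manual,
               tolerance = 1e-12)
  # all-missing pattern: zero with a warning
  expect_warning(ll <- response_loglik(rep(NA_integer_, 5), 0, bank),
                 "missing")
  expect_equal(ll, 0)
})

test_that("item and bank constructors enforce their invariants", {
  expect_error(item_params("x", a = -1, thresholds = 0), "positive")
  expect_error(item_params("x", a = 1, thresholds = c(1, 0)),
               "nondecreasing")
  expect_error(item_bank(list()), "at least one")
  expect_error(item_bank(list(dich_item("a"), dich_item("a"))), "unique")
  # GPCM step parameters need no ordering
  expect_s3_class(item_params("x", a = 1, thresholds = c(1, -1),
                              model = "GPCM"), "item_params")
})

test_that("bank and response files round-trip through delimited text", {
  bank <- toy_bank(4)
  f <- tempfile(fileext = ".csv")
  write_item_bank(bank, f)
  back <- read_item_bank(f)
  expect_equal(back$a, bank$a, tolerance = 1e-12)
  expect_equal(back$item_id, bank$item_id)
  X <- simulate_responses(bank, c(-1, 0, 1), seed = 2)
  g <- tempfile(fileext = ".csv")
  write_responses(X, g)            # written 1-based, read back shifted
  expect_equal(unname(read_responses(g)), unname(X))
  unlink(c(f, g))
})
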