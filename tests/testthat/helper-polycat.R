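# shared fixtures, all built in code

# the published example item: 5 categories, a = 1.26
sas_c3 <- function(D = 1)
  item_params("SAS_C3", a = 1.26,
              thresholds = c(-2.111, -0.191, 1.250, 3.602), D = D)

dich_item <- function(id = "d1", a = 1, b = 0, D = 1)
  item_params(id, a = a, thresholds = b, D = D)

# small deterministic GRM bank with varied slopes and locations
toy_bank <- function(n_items = 6, m = 4, seed = 1) {
  set.seed(seed)
  items <- lapply(seq_len(n_items), function(j)
    item_params(paste0("it", j), a = runif(1, 0.9, 2.2),
                thresholds = sort(runif(m - 1, -2, 2.5))))
  item_bank(items)
}

# random item of either family for property sweeps
random_item <- function(model, seed) {
  set.seed(seed)
  m <- sample(2:7, 1)
  a <- runif(1, 0.5, 2.5)
  thr <- if (model == "GRM") sort(runif(m - 1, -3, 3)) else runif(m - 1, -3, 3)
  item_params(paste0(model, seed), a = a, thresholds = thr, model = model,
              D = sample(c(1, 1.7), 1))
}

# finite-difference Fisher information oracle (independent of closed forms)
fd_information <- function(theta, item, h = 1e-5) {
  P0 <- category_probs(theta, item)
  dP <- (category_probs(theta + h, item) - category_probs(theta - h, item)) /
    (2 * h)
  sum(dP^2 / P0)
}
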