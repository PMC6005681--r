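test_that("van Rossum distance matches the closed form and the oracle", {
  tau <- 0.008
  # identical trains
  expect_equal(van_rossum_distance(c(0.1, 0.2), c(0.1, 0.2), tau), 0)
  # two single spikes dt apart: sqrt(tau * (1 - exp(-dt/tau)))
  for (dt in c(0.001, 0.008, 0.05)) {
    expect_equal(van_rossum_distance(0.1, 0.1 + dt, tau),
                 sqrt(tau * (1 - exp(-dt / tau))), tolerance = 1e-12)
  }
  # saturation at sqrt(tau) for widely separated spikes
  expect_equal(van_rossum_distance(0.1, 0.9, tau), sqrt(tau),
               tolerance = 1e-4)
  # numerical-integration oracle on random trains (independent route)
  set.seed(4)
  for (i in 1:3) {
    a <- sort(runif(6, 0, 0.3)); b <- sort(runif(9, 0, 0.3))
    expect_equal(van_rossum_distance(a, b, tau),
                 numeric_van_rossum(a, b, tau), tolerance = 0.01)
  }
  expect_error(van_rossum_distance(0.1, 0.2, -1), "tau")
})

test_that("rcorr is a normalized, symmetric similarity", {
  tau <- 0.008
  set.seed(5)
  a <- sort(runif(12, 0, 0.5))
  expect_equal(rcorr(a, a, tau), 1, tolerance = 1e-12)
  # far-separated single spikes have negligible overlap
  expect_lt(rcorr(0.05, 0.45, tau), 1e-6)
  # symmetry on random trains
  b <- sort(runif(7, 0, 0.5))
  expect_equal(rcorr(a, b, tau), rcorr(b, a, tau), tolerance = 1e-12)
  expect_gte(rcorr(a, b, tau), 0)
  expect_lte(rcorr(a, b, tau), 1)
  # empty train undefined
  expect_true(is.na(rcorr(numeric(0), a, tau)))
  # oracle agreement for the normalized inner product
  num <- numeric_filter_inner(a, b, tau) /
    sqrt(numeric_filter_inner(a, a, tau) * numeric_filter_inner(b, b, tau))
  expect_equal(rcorr(a, b, tau), num, tolerance = 0.01)
})

test_that("separable classes reach the clamp ceiling on every metric", {
  set.seed(7)
  u <- poisson_unit(100, 1, n_go = 12, n_nogo = 12)
  for (metric in c("fr", "van_rossum", "kmeans")) {
    cfg <- classifier_config(metric = metric, n_iterations = 30, seed = 3)
    res <- classify_template(u, cfg, tau_s = 0.008)
    expect_equal(res$by_depth$dprime, dprime_ceiling(), tolerance = 1e-6,
                 label = metric)
  }
  # Rcorr normalizes rate away, so its ceiling case is a timing contrast:
  # equal-count classes locked to opposite phases
  go <- lapply(1:12, function(i) seq(0.005, 0.995, by = 0.05))
  nogo <- lapply(1:12, function(i) seq(0.030, 0.98, by = 0.05))
  ut <- make_unit(c(go, nogo), type = rep(c("go", "nogo"), c(12, 12)),
                  depth_db = rep(c(0, NA), c(12, 12)))
  cfg <- classifier_config(metric = "rcorr", n_iterations = 30, seed = 3)
  expect_equal(classify_template(ut, cfg, tau_s = 0.004)$by_depth$dprime,
               dprime_ceiling(), tolerance = 1e-6)
})

test_that("uninformative units score near zero", {
  # enough trials that the realized class means are close (the classifier
  # sees the finite sample, so small n would show its sampling d')
  set.seed(8)
  u <- poisson_unit(20, 20, n_go = 60, n_nogo = 60)
  for (metric in c("fr", "van_rossum")) {
    cfg <- classifier_config(metric = metric, n_iterations = 200, seed = 4)
    res <- classify_template(u, cfg, tau_s = 0.016)
    expect_lt(abs(res$by_depth$dprime), 0.3, label = metric)
  }
  expect_error(classify_template(poisson_unit(10, 10, 3, 3),
                                 classifier_config(n_iterations = 2)),
               ">= 4 trials")
})

test_that("FR-metric classification matches brute-force nearest-class-mean", {
  # enumerate all template splits exactly; compare pooled hit/fa with the
  # Monte-Carlo estimate from the implementation (tie-free counts)
  go_counts <- c(10, 16, 12, 18)
  nogo_counts <- c(2, 8, 4, 6)
  mk <- function(n) (seq_len(n) - 0.5) / n * 0.9
  u <- make_unit(c(lapply(go_counts, mk), lapply(nogo_counts, mk)),
                 type = rep(c("go", "nogo"), c(4, 4)),
                 depth_db = rep(c(0, NA), c(4, 4)))
  combs <- combn(4, 2)
  hits <- 0; fas <- 0; n_go_t <- 0; n_nogo_t <- 0
  for (i in seq_len(ncol(combs))) for (j in seq_len(ncol(combs))) {
    tg <- combs[, i]; tn <- combs[, j]
    mu_g <- mean(go_counts[tg]); mu_n <- mean(nogo_counts[tn])
    test_go <- go_counts[-tg]; test_nogo <- nogo_counts[-tn]
    hits <- hits + sum(abs(test_go - mu_g) < abs(test_go - mu_n)) +
      0.5 * sum(abs(test_go - mu_g) == abs(test_go - mu_n))
    fas <- fas + sum(abs(test_nogo - mu_g) < abs(test_nogo - mu_n)) +
      0.5 * sum(abs(test_nogo - mu_g) == abs(test_nogo - mu_n))
    n_go_t <- n_go_t + 2; n_nogo_t <- n_nogo_t + 2
  }
  expected_d <- compute_dprime(hits / n_go_t, fas / n_nogo_t)
  cfg <- classifier_config(metric = "fr", n_iterations = 3000, seed = 11)
  res <- classify_template(u, cfg)
  expect_equal(res$by_depth$dprime, expected_d, tolerance = 0.1)
})

test_that("classifier d-prime is invariant to trial order and time shifts", {
  set.seed(12)
  u <- poisson_unit(40, 10, n_go = 10, n_nogo = 10)
  cfg <- classifier_config(metric = "van_rossum", n_iterations = 150,
                           seed = 5)
  d1 <- classify_template(u, cfg, tau_s = 0.032)$by_depth$dprime
  perm <- sample(nrow(u$trials))
  u2 <- u
  u2$trials <- u$trials[perm, ]; u2$trials$trial <- seq_len(nrow(u$trials))
  u2$spikes <- u$spikes[perm]
  d2 <- classify_template(u2, cfg, tau_s = 0.032)$by_depth$dprime
  expect_lt(abs(d1 - d2), 0.35)
  u3 <- u
  u3$spikes <- lapply(u$spikes, function(s) s + 0.05)
  d3 <- classify_template(u3, cfg, tau_s = 0.032)$by_depth$dprime
  expect_lt(abs(d1 - d3), 0.35)
  expect_lte(max(d1, d2, d3), dprime_ceiling() + 1e-9)
})

test_that("tau optimization obeys its grid and tie-break rules", {
  # deterministic, perfectly separable trains: identical within class
  go <- lapply(1:10, function(i) seq(0.01, 0.99, length.out = 30))
  nogo <- lapply(1:10, function(i) c(0.25, 0.75))
  u <- make_unit(c(go, nogo), type = rep(c("go", "nogo"), c(10, 10)),
                 depth_db = rep(c(0, NA), c(10, 10)))
  cfg1 <- classifier_config(metric = "van_rossum", tau_s = 0.016,
                            n_iterations = 20, seed = 6)
  o1 <- optimize_tau(u, cfg1, go_depth = 0)
  expect_equal(o1$tau_s, 0.016)
  # every tau at ceiling -> tie-break to the smallest (2 ms)
  cfg2 <- classifier_config(metric = "van_rossum", n_iterations = 20,
                            seed = 7)
  o2 <- optimize_tau(u, cfg2, go_depth = 0)
  expect_equal(o2$tau_s, 0.002)
  expect_true(all(abs(o2$grid$dprime - dprime_ceiling()) < 1e-6))
  expect_error(optimize_tau(u, classifier_config(metric = "fr"), 0), "tau")
})

test_that("timing-only codes are read out at matched tau", {
  # classes share rate; Go spikes cluster at 10 ms-scale preferred times
  set.seed(14)
  hits <- 0
  for (k in 1:3) {
    pref <- seq(0.05, 0.95, by = 0.1)
    go <- lapply(1:10, function(i)
      sort(pmax(0, rnorm(10, pref, 0.004))))
    nogo <- lapply(1:10, function(i) sort(runif(10, 0, 1)))
    u <- make_unit(c(go, nogo), type = rep(c("go", "nogo"), c(10, 10)),
                   depth_db = rep(c(0, NA), c(10, 10)))
    cfg <- classifier_config(metric = "van_rossum", n_iterations = 40,
                             seed = 20 + k)
    o <- optimize_tau(u, cfg, go_depth = 0)
    if (o$tau_s <= 0.032) hits <- hits + 1
  }
  expect_gte(hits, 2)
})
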