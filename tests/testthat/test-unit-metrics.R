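test_that("spontaneous rate averages the 200 ms pre-poke window", {
  # two spikes in every pre-poke window -> 10 Hz
  sp <- lapply(1:6, function(i) c(-0.55, -0.45, 0.1, 0.2))
  u <- make_unit(sp, type = rep(c("go", "nogo"), 3),
                 depth_db = rep(c(0, NA), 3))
  expect_equal(spontaneous_rate(u), 10)
  u0 <- make_unit(lapply(1:4, function(i) c(0.1)), rep("go", 4), rep(0, 4))
  expect_equal(spontaneous_rate(u0), 0)
  set.seed(1)
  up <- poisson_unit(10, 10, 250, 250, spont_hz = 20)
  expect_lt(abs(spontaneous_rate(up) - 20), 1)
})

test_that("best-window d-prime matches the z-difference on constructed counts", {
  # deterministic spike counts: Go mean shifted by exactly one pooled SD
  mk <- function(n) sort(runif(n, 0, 0.999))
  set.seed(5)
  go_counts <- rep(c(12, 14), 10)    # mean 13, sd 1.026
  nogo_counts <- rep(c(11, 13), 10)  # mean 12, same sd
  u <- make_unit(c(lapply(go_counts, mk), lapply(nogo_counts, mk)),
                 type = rep(c("go", "nogo"), c(20, 20)),
                 depth_db = rep(c(0, NA), c(20, 20)))
  nf <- best_window_dprime(u, windows_ms = 1000)
  sd_pool <- sd(rep(c(12, 14), 10))  # equal within both conditions
  expect_equal(nf$dprime, 1 / sd_pool, tolerance = 1e-10)
  expect_equal(nf$fr, 13); expect_equal(nf$fr_nogo, 12)
})

test_that("suppressed units report positive d-prime; degenerate counts flag", {
  mk <- function(n) if (n == 0) numeric(0) else sort(runif(n, 0, 0.999))
  set.seed(6)
  u <- make_unit(c(lapply(rep(c(2, 4), 8), mk), lapply(rep(c(10, 12), 8), mk)),
                 type = rep(c("go", "nogo"), c(16, 16)),
                 depth_db = rep(c(0, NA), c(16, 16)))
  nf <- best_window_dprime(u, windows_ms = 1000)
  expect_gt(nf$dprime, 0)
  # identical counts everywhere -> pooled SD 0 -> d' defined as 0, flagged
  ud <- make_unit(lapply(1:8, function(i) c(0.1, 0.5)),
                  type = rep(c("go", "nogo"), 4),
                  depth_db = rep(c(0, NA), 4))
  nfd <- best_window_dprime(ud, windows_ms = 1000)
  expect_equal(nfd$dprime, 0)
  expect_true(nfd$degenerate)
})

test_that("monotonicity index classifies by the 50% cutoff", {
  expect_equal(monotonicity_index(c(0, -6, -12), c(20, 15, 10)),
               list(mi = 100, class = "increasing"))
  # MI exactly 50 -> decreasing class (boundary belongs to decreasing)
  expect_equal(monotonicity_index(c(0, -6), c(10, 20))$class, "decreasing")
  expect_equal(monotonicity_index(c(0, -6), c(10, 20))$mi, 50)
  # depth-independent FR -> MI = 100
  expect_equal(monotonicity_index(c(0, -6, -12), c(7, 7, 7))$mi, 100)
  expect_true(is.na(monotonicity_index(c(0, -6), c(0, 0))$mi))
  expect_error(monotonicity_index(c(-3, -6), c(1, 2)), "0 dB")
})

test_that("vector strength matches its defining cases", {
  f <- 64
  # perfect phase locking
  expect_equal(vector_strength((0:99) / f, f)$vs, 1, tolerance = 1e-12)
  # antiphase pair cancels
  expect_equal(vector_strength(c(0, 1 / (2 * f)), f)$vs, 0, tolerance = 1e-12)
  # uniform phases: small VS, not significant (null behavior over seeds)
  set.seed(42)
  bad <- 0
  for (i in 1:40) {
    v <- vector_strength(runif(1000, 0, 10), f)
    if (v$vs >= 0.06 || v$significant) bad <- bad + 1
  }
  expect_lte(bad, 1)
  # empty train flagged
  expect_true(is.na(vector_strength(numeric(0), f)$vs))
  # invariance to shifts by whole periods
  s <- runif(200, 0, 0.5)
  expect_equal(vector_strength(s, f)$vs,
               vector_strength(s + 5 / f, f)$vs, tolerance = 1e-9)
})

test_that("unit CV matches Poisson and gamma-Poisson oracles", {
  ui <- make_unit(lapply(1:10, function(i) c(0.1, 0.6)),
                  type = rep(c("go", "nogo"), 5),
                  depth_db = rep(c(0, NA), 5))
  expect_equal(unit_cv(ui, window_ms = 1000)$cv, 0)
  set.seed(9)
  up <- poisson_unit(25, 25, 400, 400)
  expect_lt(abs(unit_cv(up, window_ms = 1000)$cv - 0.2), 0.03)
})

test_that("neurometric threshold interpolates the bracketing pair", {
  r <- neurometric_threshold(c(-9, -6), c(0.5, 1.5))
  expect_equal(r$threshold_db, -7.5)
  expect_equal(r$flag, "ok")
  expect_equal(neurometric_threshold(c(-9, -6, -3), c(0.4, 1, 2))$threshold_db,
               -6)
  expect_equal(neurometric_threshold(c(-9, -6), c(0.2, 0.9))$flag,
               "undefined")
  r2 <- neurometric_threshold(c(-12, -6, 0), c(1.4, 2, 3))
  expect_equal(r2$flag, "ceiling")
  expect_equal(r2$threshold_db, -12)
  # non-adjacent bracketing: greatest d' below 1 and smallest above 1
  r3 <- neurometric_threshold(c(-12, -9, -6, -3), c(0.2, 0.8, 0.6, 1.2))
  expect_equal(r3$threshold_db, -9 + (1 - 0.8) * (-3 - -9) / (1.2 - 0.8))
  # scale invariance of the underlying d' (recompute from scaled FRs)
  counts <- c(5, 7, 9, 11); sdp <- sd(counts)
  expect_equal((mean(2 * counts) - 2 * 5) / sd(2 * counts),
               (mean(counts) - 5) / sdp)
})

test_that("choice probability equals the rank-sum oracle and its properties", {
  # identical FR distributions (all ties) -> exactly 0.5
  u_tie <- make_unit(lapply(1:12, function(i) c(0.1, 0.2, 0.3)),
                     type = rep("go", 12), depth_db = rep(-6, 12),
                     choice = rep(c("spout", "repoke"), 6))
  expect_equal(choice_probability(u_tie, hit_range = c(0, 1))$cp, 0.5)
  # complete separation -> 1
  mk <- function(n) sort(runif(n, 0, 0.39))
  set.seed(3)
  spikes <- c(lapply(8:11, mk), lapply(1:4, mk))
  u_sep <- make_unit(spikes, type = rep("go", 8), depth_db = rep(-6, 8),
                     choice = rep(c("spout", "repoke"), each = 4))
  expect_equal(choice_probability(u_sep, hit_range = c(0, 1))$cp, 1)
  # brute-force pairwise U oracle on random data with ties
  set.seed(10)
  counts <- rpois(18, 4)
  spikes <- lapply(counts, function(n) if (n == 0) numeric(0) else
    sort(runif(n, 0, 0.39)))
  choice <- rep(c("spout", "repoke"), c(8, 10))
  u <- make_unit(spikes, type = rep("go", 18), depth_db = rep(-6, 18),
                 choice = choice)
  cp <- choice_probability(u, hit_range = c(0, 1))
  x <- counts[choice == "spout"]; y <- counts[choice == "repoke"]
  u_brute <- sum(vapply(x, function(a)
    sum(a > y) + 0.5 * sum(a == y), numeric(1)))
  expect_equal(cp$cp, u_brute / (length(x) * length(y)))
  # rank-negation flips CP
  u_neg <- u
  u_neg$spikes <- lapply(max(counts) - counts, function(n)
    if (n <= 0) numeric(0) else sort(runif(n, 0, 0.39)))
  expect_equal(choice_probability(u_neg, hit_range = c(0, 1))$cp, 1 - cp$cp,
               tolerance = 1e-12)
  # low-power flag
  u_lp <- make_unit(spikes[1:6], type = rep("go", 6), depth_db = rep(-6, 6),
                    choice = c("spout", rep("repoke", 5)))
  expect_true(choice_probability(u_lp, hit_range = c(0, 1))$low_power)
})

test_that("unit metrics table is tidy and keyed", {
  cfg <- cohort_config(seed = 2)
  ses <- generate_session(cfg, "a1", "Ctl", 256, n_trials = 120, seed = 1)
  units <- lapply(1:3, function(i)
    generate_unit(cfg, ses, draw_unit_tuning(cfg, "Ctl", seed = i),
                  unit_id = paste0("u", i), seed = 10 + i))
  tab <- unit_metrics_table(units)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("unit_id", "animal_id", "group", "rate_hz",
                    "best_window_ms", "max_dprime", "threshold_db", "mi",
                    "vs", "cv", "spont_hz") %in% names(tab)))
  expect_true(all(tab$best_window_ms %in% seq(25, 1000, 25)))
  expect_true(all(tab$max_dprime >= 0))
  expect_true(all(tab$vs >= 0 & tab$vs <= 1))
})
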