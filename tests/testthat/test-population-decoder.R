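# Small shared cohort for decoder tests (one session, strongly driven units)
local_units <- local({
  set.seed(100)
  cfg <- cohort_config(seed = 100, n_trials_per_session = 120)
  ses <- generate_session(cfg, "a1", "Ctl", 256, seed = 1)
  lapply(1:14, function(i)
    generate_unit(cfg, ses, draw_unit_tuning(cfg, "Ctl", seed = i),
                  unit_id = paste0("u", i), seed = 50 + i))
})

test_that("tensor construction conserves counts and bins half-open", {
  # single unit: population response equals the unit's own binned counts
  u <- local_units[[1]]
  tensor <- build_population_tensor(list(u), 256, require_threshold = FALSE)
  raw <- tensor$units[[u$unit_id]]$raw
  # conservation: summed bins equal window spike counts trial by trial
  all_counts <- do.call(rbind, raw[order(names(raw))])
  expect_equal(sum(all_counts), sum(trial_counts(u, c(0, 0.4))))
  # a spike exactly on a bin edge lands in the later bin
  ue <- make_unit(list(c(0.010, 0.0105), c(0.02)), type = c("go", "nogo"),
                  depth_db = c(0, NA))
  te <- build_population_tensor(list(ue), 256, require_threshold = FALSE)
  g <- te$units[["u-test"]]$raw[["0"]]
  expect_equal(g[1, 11], 2L)  # both spikes in bin [0.010, 0.011)
  expect_equal(sum(g), 2L)
  expect_error(build_population_tensor(local_units, 512), "no units")
})

test_that("tensor inclusion requires a defined FR threshold", {
  set.seed(7)
  flat <- poisson_unit(10, 10, n_go = 20, n_nogo = 20)
  expect_error(build_population_tensor(list(flat), 256),
               "no units passed")
  both <- build_population_tensor(c(local_units, list(flat)), 256,
                                  require_threshold = FALSE)
  expect_equal(length(both$units), 15)
})

test_that("byte-identical classes decode at chance; separable at ceiling", {
  set.seed(20)
  # shuffled-label null: permute each unit's go-0/nogo labels so the two
  # classes are draws from one distribution (byte-identical class contents
  # would couple train and test through the shared row pool instead)
  null_units <- lapply(local_units, function(u) {
    keep <- u$trials$type == "nogo" |
      (u$trials$type == "go" & u$trials$depth_db == 0)
    u$trials <- u$trials[keep, ]
    u$spikes <- u$spikes[keep]
    perm <- sample(nrow(u$trials))
    u$trials[, c("type", "depth_db")] <- u$trials[perm, c("type", "depth_db")]
    u
  })
  nt <- build_population_tensor(null_units, 256, require_threshold = FALSE)
  r0 <- decode(nt, 0, decoder_config(n_iterations = 40, seed = 2))
  expect_lt(abs(r0$dprime_mean), 0.35)
  # strongly separable population: large rate contrast, no gain noise
  set.seed(21)
  sep <- lapply(1:8, function(i) {
    u <- poisson_unit(80, 10, n_go = 30, n_nogo = 30)
    u$unit_id <- paste0("sep", i)
    u
  })
  ts <- build_population_tensor(sep, 256, require_threshold = FALSE)
  rs <- decode(ts, 0, decoder_config(n_iterations = 40, seed = 3))
  expect_equal(rs$dprime_mean, dprime_ceiling(), tolerance = 1e-6)
  expect_equal(rs$dprime_sd, 0, tolerance = 1e-6)
})

test_that("decoder d-prime is bounded and invariant to unit relabeling", {
  tensor <- build_population_tensor(local_units, 256,
                                    require_threshold = FALSE)
  cfg <- decoder_config(n_iterations = 60, seed = 9)
  r1 <- decode(tensor, 0, cfg)
  expect_lte(r1$dprime_mean, dprime_ceiling())
  t2 <- tensor
  perm <- rev(seq_along(t2$units))
  t2$units <- t2$units[perm]
  t2$meta <- t2$meta[perm, ]
  r2 <- decode(t2, 0, cfg)
  # same units, same seed, different order: two Monte-Carlo estimates of the
  # same quantity; allow ~3 SE of the difference
  se_diff <- sqrt(r1$dprime_sd^2 + r2$dprime_sd^2) / sqrt(60)
  expect_lt(abs(r1$dprime_mean - r2$dprime_mean), max(3 * se_diff, 0.3))
})

test_that("pure-noise units do not improve decoding", {
  set.seed(30)
  tensor <- build_population_tensor(local_units, 256,
                                    require_threshold = FALSE)
  noise <- lapply(1:6, function(i) {
    u <- poisson_unit(15, 15, n_go = 30, n_nogo = 30)
    u$unit_id <- paste0("noise", i)
    u
  })
  t_aug <- build_population_tensor(c(local_units, noise), 256,
                                   require_threshold = FALSE)
  cfg <- decoder_config(n_iterations = 40, seed = 4)
  r_base <- decode(tensor, 0, cfg)
  r_aug <- decode(t_aug, 0, cfg)
  mc <- 3 * sqrt(r_base$dprime_sd^2 + r_aug$dprime_sd^2) / sqrt(40)
  expect_lt(r_aug$dprime_mean - r_base$dprime_mean, max(mc, 0.35))
})

test_that("unit-count curve runs per fraction and tracks the full decode", {
  tensor <- build_population_tensor(local_units, 256,
                                    require_threshold = FALSE)
  cfg <- decoder_config(n_iterations = 25, seed = 5)
  cur <- unit_count_curve(tensor, 0, fractions = c(0.3, 1), config = cfg)
  expect_equal(cur$n_units, c(4, 14))
  full <- decode(tensor, 0, cfg)
  expect_lt(abs(cur$dprime_mean[2] - full$dprime_mean),
            3 * full$dprime_sd / sqrt(25) + 0.3)
  expect_error(unit_count_curve(tensor, 0, fractions = 0.001, config = cfg),
               "< 1 unit")
})

test_that("monotonic-subpopulation decode respects class membership", {
  tensor <- build_population_tensor(local_units, 256,
                                    require_threshold = FALSE)
  counts <- table(tensor$meta$monotonic_class)
  cls <- names(counts)[which.max(counts)]
  n_avail <- max(counts)
  r <- mi_subpopulation_decode(tensor, 0, class = cls, n = min(5, n_avail),
                               config = decoder_config(n_iterations = 10,
                                                       seed = 6))
  expect_s3_class(r, "decoder_result")
  expect_equal(r$monotonic_class, cls)
  expect_error(
    mi_subpopulation_decode(tensor, 0, class = cls, n = n_avail + 1,
                            config = decoder_config(n_iterations = 5)),
    "available")
})

test_that("population CV matches the Poisson oracle and flags zero trials", {
  # Poisson bins: population-summed counts with mean lambda per 1 ms bin
  set.seed(40)
  units <- lapply(1:10, function(i) {
    u <- poisson_unit(500, 500, n_go = 15, n_nogo = 15, duration = 0.4)
    u$unit_id <- paste0("p", i)
    u
  })
  tensor <- build_population_tensor(units, 256, require_threshold = FALSE)
  pcv <- population_cv(tensor, classes = "nogo", seed = 2)
  # lambda = 10 units * 500 Hz * 1 ms = 5 per bin -> CV ~ 1/sqrt(5)
  expect_lt(abs(median(pcv$cv) - 1 / sqrt(5)), 0.05)
  # constant equal counts in every bin -> CV 0 (one spike per bin per unit)
  # one spike in every 1 ms bin on every trial: pooled normalization cannot
  # be applied (zero variance), so use the per-bin option
  ue <- make_unit(list(seq(0.0005, 0.3995, by = 0.001),
                       seq(0.0005, 0.3995, by = 0.001)),
                  type = c("go", "nogo"), depth_db = c(0, NA))
  te <- build_population_tensor(list(ue), 256, require_threshold = FALSE,
                                normalization = "per_bin")
  expect_equal(population_cv(te, seed = 1)$cv, c(0, 0))
})

test_that("svm_linear solves a deterministic max-margin problem", {
  # classic separable 2-D points: boundary between the two support planes
  x <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  y <- c("a", "a", "b", "b")
  fit <- svm_linear(x, y, cost = 10)
  expect_equal(predict(fit, x), factor(y, levels = c("a", "b")))
  # margin midpoint at x1 = 1 regardless of x2
  expect_equal(as.character(predict(fit, rbind(c(0.9, 0.5), c(1.1, 0.5)))),
               c("a", "b"))
  expect_lt(abs(fit$w[2]), 0.05)
  # determinism
  fit2 <- svm_linear(x, y, cost = 10)
  expect_identical(fit$w, fit2$w)
  expect_error(svm_linear(x, rep("a", 4)), "two classes")
})
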