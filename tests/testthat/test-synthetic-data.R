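cfg <- cohort_config(seed = 11)

test_that("session generator honors the Nogo mix and the psychometric truth", {
  s <- generate_session(cfg, "a1", "Ctl", 256, n_trials = 10000, seed = 5)
  p_hat <- mean(s$trials$type == "nogo")
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(p_hat - 0.30), 3 * se)
  # saturated observer: threshold far below easiest depth, no guess/lapse
  cfg2 <- cfg
  cfg2$psych$threshold_db <- -40
  cfg2$psych$guess <- 0
  cfg2$psych$lapse <- 0
  s2 <- generate_session(cfg2, "a1", "Ctl", 256, n_trials = 500, seed = 5)
  go <- s2$trials[s2$trials$type == "go", ]
  expect_true(all(go$outcome == "hit"))
  nogo <- s2$trials[s2$trials$type == "nogo", ]
  expect_true(all(nogo$outcome == "cr"))
  expect_error(generate_session(cfg, "a1", "Ctl", 1000), "ground truth")
})

test_that("generated hit rates track the ground-truth psychometric function", {
  s <- generate_session(cfg, "a1", "HL", 512, n_trials = 8000, seed = 9)
  ht <- session_hit_table(s)
  gt <- cfg$psych[cfg$psych$group == "HL" & cfg$psych$rate_hz == 512, ]
  expected <- psych_truth_p(ht$depth_db, gt$threshold_db, gt$slope,
                            gt$guess, gt$lapse)
  se <- sqrt(expected * (1 - expected) / ht$n_go)
  expect_true(all(abs(ht$hit_rate - expected) < 4 * se))
})

test_that("sinusoidally modulated Poisson units phase lock at kappa/2", {
  # VS limit of r(t) = r0*(1 + kappa*sin(2*pi*f*t)) is kappa/2
  cfg3 <- cfg
  cfg3$unit$kappa <- 0.8
  cfg3$unit$driven_hz <- c(Ctl = 60, HL = 60)
  cfg3$unit$gain_cv <- c(Ctl = 0.05, HL = 0.05)
  ses <- generate_session(cfg3, "a1", "Ctl", 64, n_trials = 400, seed = 2)
  tun <- draw_unit_tuning(cfg3, "Ctl", seed = 3)
  tun$kappa <- 0.8; tun$onset_gain <- 0
  u <- generate_unit(cfg3, ses, tun, seed = 4)
  full <- which(u$trials$type == "go" & u$trials$depth_db == 0)
  st <- unlist(u$spikes[full], use.names = FALSE)
  st <- st[st >= 0 & st < 1]
  expect_gt(length(st), 3000)
  expect_lt(abs(vector_strength(st, 64)$vs - 0.4), 0.03)
})

test_that("gamma-gain dispersion obeys the law of total variance", {
  # At high counts the trial-FR CV converges to the gain CV
  cfg4 <- cfg
  cfg4$unit$gain_cv <- c(Ctl = 0.5, HL = 0.5)
  ses <- generate_session(cfg4, "a1", "Ctl", 256, n_trials = 600, seed = 7)
  tun <- list(monotonic_class = "increasing", spont_hz = 0, base_hz = 400,
              depth_gain = 0, kappa = 0, onset_gain = 0, onset_tau_s = 0.05,
              gain_cv = 0.5)
  u <- generate_unit(cfg4, ses, tun, seed = 8)
  counts <- lengths(lapply(u$spikes, function(s) s[s >= 0 & s < 1]))
  # law of total variance: CV = sqrt(cv_g^2 + 1/lambda) ~ 0.502 at lambda=400
  expect_lt(abs(sd(counts) / mean(counts) - 0.5), 0.05)
})

test_that("depth-independent tuning yields flat neurometric functions", {
  ses <- generate_session(cfg, "a1", "Ctl", 256, n_trials = 250, seed = 21)
  tun <- list(monotonic_class = "increasing", spont_hz = 5, base_hz = 20,
              depth_gain = 0, kappa = 0, onset_gain = 0, onset_tau_s = 0.05,
              gain_cv = 0.2)
  u <- generate_unit(cfg, ses, tun, seed = 22)
  nf <- best_window_dprime(u)
  # best window is chosen to maximize d', so allow the selection bias
  expect_lt(max(nf$dprime), 0.8)
  expect_error(generate_unit(cfg, ses, within(tun, kappa <- 2)), "kappa")
})

test_that("cohort generation is deterministic and bookkept", {
  small <- cohort_config(n_animals = 1, units_per_animal = c(2, 2),
                        rates_hz = c(256), n_sessions_per_rate = 1,
                        n_trials_per_session = 60, seed = 99)
  c1 <- generate_cohort(small)
  c2 <- generate_cohort(small)
  expect_identical(c1, c2)
  m <- c1$manifest
  expect_equal(nrow(m), length(c1$sessions) + length(c1$units) +
                 length(c1$efr) + length(c1$abr))
  expect_equal(sum(m$kind == "unit"), 4)       # 2 units x 2 groups
  expect_equal(sum(m$kind == "session"), 2)
  # child seeds are recorded and distinct
  expect_false(any(duplicated(m$seed)))
})

test_that("HL preset yields higher unit CV than Ctl at matched rates", {
  meds <- sapply(1:3, function(k) {
    sapply(c("Ctl", "HL"), function(g) {
      ses <- generate_session(cfg, "a1", g, 256, n_trials = 150,
                              seed = 30 + k)
      cvs <- vapply(1:8, function(i) {
        tun <- draw_unit_tuning(cfg, g, seed = 100 * k + i)
        unit_cv(generate_unit(cfg, ses, tun, seed = 200 * k + i))$cv
      }, numeric(1))
      median(cvs)
    })
  })
  expect_true(all(meds["HL", ] > meds["Ctl", ]))
})

test_that("sessions and units round-trip through plain-text files", {
  ses <- generate_session(cfg, "a1", "Ctl", 128, n_trials = 50, seed = 41)
  p <- tempfile(fileext = ".tsv")
  write_session_tsv(ses, p)
  back <- read_session_tsv(p)
  expect_equal(back$trials$outcome, ses$trials$outcome)
  expect_equal(back$rate_hz, 128)
  tun <- draw_unit_tuning(cfg, "Ctl", seed = 42)
  u <- generate_unit(cfg, ses, tun, seed = 43)
  p2 <- tempfile(fileext = ".tsv")
  write_unit_tsv(u, p2)
  back2 <- read_unit_tsv(p2)
  expect_equal(lengths(back2$spikes), lengths(u$spikes))
  expect_equal(unlist(back2$spikes), unlist(u$spikes), tolerance = 1e-9)
})
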