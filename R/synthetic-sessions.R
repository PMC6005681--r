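#' Cohort configuration for the synthetic-data generator
#'
#' Bundles the ground truth that the generator emulates: a Go-Nogo AM
#' detection task run at four modulation rates with 30% unmodulated Nogo
#' trials, normal-hearing (Ctl) and conductive-hearing-loss (HL) groups,
#' rate-coded cortical units with weak phase locking and group-dependent
#' trial-to-trial gain variability (HL > Ctl), and sinusoidal
#' envelope-following waveforms in noise.
#'
#' Psychometric ground truth per (group, rate) is the location (dB re 100%)
#' and scale of a cumulative-Gaussian hit function plus guess (false-alarm)
#' and lapse rates. Default locations follow the published group structure:
#' the two groups are equivalent at 64 Hz and the HL deficit grows with rate;
#' guess 0.27 and lapse 0.03 are the published medians. EFR parameters are
#' identical across groups (brainstem processing is unaffected); ABR click
#' thresholds differ by ~39 dB.
#'
#' @param n_animals animals per group (default 4, the scaled-down desk cohort).
#' @param units_per_animal integer range (length-2) of unit counts per animal;
#'   the experiment's range was 80-285, the desk-scale default is c(40, 40).
#' @param rates_hz modulation rates tested.
#' @param n_sessions_per_rate behavioral sessions per animal and rate.
#' @param n_trials_per_session trials per session.
#' @param psych data.frame of psychometric ground truth with columns
#'   `group`, `rate_hz`, `threshold_db` (cumulative-Gaussian location),
#'   `slope` (scale, dB), `guess`, `lapse`; defaults supplied.
#' @param p_nogo Nogo interleaving probability (0.30 in the task).
#' @param unit list of unit-tuning priors: `spont_hz` (named by group),
#'   `driven_hz` baseline driven rate (named by group), `depth_gain`
#'   multiplicative FR change at full depth, `p_increasing` probability of the
#'   monotonically increasing class, `kappa` phase-locking modulation index in
#'   \[0,1\], `onset_gain` and `onset_tau_s` amplitude (re baseline) and decay
#'   of the depth-scaled transient that increasing units fire at the
#'   unmodulated-to-AM transition, `gain_cv` trial-to-trial gamma-gain CV
#'   (named by group, HL > Ctl), and `hl_rate_fidelity`, the rate-dependent
#'   encoding-fidelity attenuation of HL cortex (effective modulation depth
#'   seen by an HL unit is `m * fidelity(rate)`; 1 for Ctl at all rates).
#' @param efr list of EFR generator parameters: `a_max` sinusoid amplitude at
#'   0 dB depth (uV), `k` exponential depth coefficient (per dB), `noise_sd`
#'   white-noise SD (uV), `fs`, `onset_s`, `stim_s` stimulus duration.
#' @param abr list of ABR generator parameters: `threshold_db_spl` (named by
#'   group), `amp_per_db` growth of peak amplitude per dB above threshold,
#'   `noise_sd`, `fs`.
#' @param level_rove logical; rove presentation level over 45-57 dB SPL.
#' @param choice_coupling coupling in \[0,1\] between unit gain and behavioral
#'   choice; 0 (default) makes spiking and choice independent so choice
#'   probability is 0.5 under the null.
#' @param seed master seed; every generated object stores a derived child seed.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_animals = 4,
                          units_per_animal = c(40, 40),
                          rates_hz = c(64, 128, 256, 512),
                          n_sessions_per_rate = 3,
                          n_trials_per_session = 200,
                          psych = default_psych_truth(rates_hz),
                          p_nogo = 0.30,
                          unit = list(
                            spont_hz = c(Ctl = 8, HL = 5),
                            driven_hz = c(Ctl = 15, HL = 10),
                            depth_gain = 1.4,
                            p_increasing = 0.517,
                            kappa = 0.2,
                            onset_gain = 3, onset_tau_s = 0.05,
                            gain_cv = c(Ctl = 0.30, HL = 0.55),
                            hl_rate_fidelity = c("64" = 1, "128" = 0.85,
                                                 "256" = 0.55, "512" = 0.3)),
                          efr = list(a_max = 1.0, k = 0.15, noise_sd = 2.8,
                                     fs = 8192, onset_s = 0.01, stim_s = 0.27),
                          abr = list(threshold_db_spl = c(Ctl = 25, HL = 64),
                                     amp_per_db = 0.15, noise_sd = 0.1,
                                     fs = 24414),
                          level_rove = FALSE,
                          choice_coupling = 0,
                          seed = 1L) {
  # JSON round-trips deliver named lists where named vectors went in
  delist <- function(l) lapply(l, function(el) if (is.list(el)) unlist(el)
                               else el)
  unit <- delist(unit); efr <- delist(efr); abr <- delist(abr)
  stopifnot(n_animals >= 1,
            length(units_per_animal) == 2,
            all(units_per_animal >= 1),
            units_per_animal[1] <= units_per_animal[2],
            all(rates_hz > 0),
            p_nogo > 0, p_nogo < 1,
            all(c("group", "rate_hz", "threshold_db", "slope",
                  "guess", "lapse") %in% names(psych)),
            all(psych$guess >= 0 & psych$guess <= 1),
            all(psych$lapse >= 0 & psych$lapse <= 1),
            all(psych$slope > 0),
            all(unit$gain_cv > 0),
            unit$kappa >= 0, unit$kappa <= 1,
            choice_coupling >= 0, choice_coupling <= 1)
  structure(list(n_animals = n_animals,
                 units_per_animal = as.integer(units_per_animal),
                 rates_hz = rates_hz,
                 n_sessions_per_rate = n_sessions_per_rate,
                 n_trials_per_session = n_trials_per_session,
                 psych = psych, p_nogo = p_nogo, unit = unit, efr = efr,
                 abr = abr, level_rove = level_rove,
                 choice_coupling = choice_coupling,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default psychometric ground truth per group and rate
#'
#' Thresholds (cumulative-Gaussian locations, dB re 100%) chosen once from the
#' published group structure: Ctl and HL equivalent at 64 Hz, HL markedly worse
#' at 128-512 Hz with the deficit largest at 512 Hz.
#'
#' @param rates_hz rates to cover (subset of 64/128/256/512; other rates are
#'   interpolated on the published exponential trend).
#' @return data.frame with columns group, rate_hz, threshold_db, slope,
#'   guess, lapse.
#' @export
default_psych_truth <- function(rates_hz = c(64, 128, 256, 512)) {
  base <- data.frame(
    group = rep(c("Ctl", "HL"), each = 4),
    rate_hz = rep(c(64, 128, 256, 512), 2),
    threshold_db = c(-12.0, -11.2, -9.9, -7.7,
                     -11.7, -8.9, -5.7, -2.5))
  out <- base[base$rate_hz %in% rates_hz, , drop = FALSE]
  if (!all(rates_hz %in% base$rate_hz))
    stop("default psychometric truth covers rates 64/128/256/512 Hz only")
  out$slope <- 2.0
  out$guess <- 0.27
  out$lapse <- 0.03
  rownames(out) <- NULL
  out
}

#' Ground-truth hit probability of the synthetic observer
#'
#' `P(hit | depth) = guess + (1 - guess - lapse) * Phi((depth - location)/scale)`;
#' the false-alarm probability on Nogo trials is `guess`.
#'
#' @param depth_db Go depth(s) in dB re 100%.
#' @param threshold_db,slope cumulative-Gaussian location and scale (dB).
#' @param guess,lapse guess (false-alarm) and lapse rates.
#' @return hit probability vector.
#' @export
psych_truth_p <- function(depth_db, threshold_db, slope, guess, lapse) {
  guess + (1 - guess - lapse) * pnorm((depth_db - threshold_db) / slope)
}

# Five Go depths on the task's 3 dB grid, 0 to -12 dB. The set brackets all
# of the default ground-truth thresholds (-12.0 to -2.5 dB), always contains
# 0 dB (full modulation anchors the monotonicity index, the pattern
# classifier and the decoder's fully-modulated class), and is identical
# across groups and rates so group comparisons are on matched grids.
bracket_depths <- function(threshold_db, n = 5, step = 3) {
  seq(0, by = -step, length.out = n)
}

#' Generate one synthetic Go-Nogo behavioral session
#'
#' Trials are Nogo (unmodulated) with probability `config$p_nogo`, otherwise
#' Go at a depth drawn uniformly from five depths bracketing the group's
#' ground-truth threshold at the given rate. Go responses are Bernoulli with
#' the [psych_truth_p()] hit probability; Nogo false alarms occur with the
#' guess probability. Response latencies are log-normal with group-invariant
#' parameters and carry no analysis meaning.
#'
#' @param config a [cohort_config()].
#' @param animal_id animal identifier string (e.g. "Ctl-1").
#' @param group "Ctl" or "HL".
#' @param rate_hz modulation rate; must have ground truth in `config$psych`.
#' @param n_trials number of trials (default from config).
#' @param seed RNG seed recorded in the session.
#' @param depths optional explicit Go depth set (dB re 100%).
#' @return object of class `am_session`: list with `animal_id`, `group`,
#'   `rate_hz`, `level_db_spl`, `seed` and `trials`, a data.frame with columns
#'   `trial`, `type` ("go"/"nogo"), `depth_db` (NA on Nogo), `response`
#'   ("spout"/"repoke"), `outcome` ("hit"/"miss"/"fa"/"cr"), `latency_s`,
#'   `level_db_spl`.
#' @export
generate_session <- function(config, animal_id, group, rate_hz,
                             n_trials = config$n_trials_per_session,
                             seed = config$seed, depths = NULL) {
  stopifnot(inherits(config, "cohort_config"), n_trials >= 1)
  gt <- config$psych[config$psych$group == group &
                     config$psych$rate_hz == rate_hz, ]
  if (nrow(gt) != 1)
    stop("no psychometric ground truth for group ", group, " at ",
         rate_hz, " Hz")
  if (is.null(depths)) depths <- bracket_depths(gt$threshold_db)
  with_seed(seed, {
    type <- ifelse(runif(n_trials) < config$p_nogo, "nogo", "go")
    depth_db <- rep(NA_real_, n_trials)
    ngo <- sum(type == "go")
    depth_db[type == "go"] <- sample(depths, ngo, replace = TRUE)
    p_resp <- ifelse(type == "nogo", gt$guess,
                     psych_truth_p(depth_db, gt$threshold_db, gt$slope,
                                   gt$guess, gt$lapse))
    resp <- runif(n_trials) < p_resp
    outcome <- ifelse(type == "go",
                      ifelse(resp, "hit", "miss"),
                      ifelse(resp, "fa", "cr"))
    level <- if (isTRUE(config$level_rove))
      sample(seq(45, 57, by = 3), n_trials, replace = TRUE)
    else rep(if (group == "HL") 90 else 45, n_trials)
    trials <- data.frame(
      trial = seq_len(n_trials), type = type, depth_db = depth_db,
      response = ifelse(resp, "spout", "repoke"),
      outcome = outcome,
      latency_s = rlnorm(n_trials, meanlog = log(0.35), sdlog = 0.3),
      level_db_spl = level)
    structure(list(animal_id = animal_id, group = group, rate_hz = rate_hz,
                   depths = depths, level_db_spl = level[1],
                   seed = as.integer(seed), trials = trials),
              class = "am_session")
  })
}

#' @export
print.am_session <- function(x, ...) {
  tab <- table(x$trials$outcome)
  cat(sprintf("Go-Nogo AM session: %s (%s), %g Hz, %d trials (%s)\n",
              x$animal_id, x$group, x$rate_hz, nrow(x$trials),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Observed false-alarm rate of a session
#' @param session an `am_session`.
#' @return proportion of Nogo trials answered at the spout.
#' @export
session_fa_rate <- function(session) {
  tr <- session$trials
  nogo <- tr[tr$type == "nogo", ]
  if (nrow(nogo) == 0) return(NA_real_)
  mean(nogo$outcome == "fa")
}

#' Per-depth hit counts of a session
#' @param session an `am_session`.
#' @return data.frame with depth_db, n_go, n_hit, hit_rate (sorted by depth).
#' @export
session_hit_table <- function(session) {
  go <- session$trials[session$trials$type == "go", ]
  depths <- sort(unique(go$depth_db))
  out <- data.frame(
    depth_db = depths,
    n_go = vapply(depths, function(d) sum(go$depth_db == d), integer(1)),
    n_hit = vapply(depths, function(d)
      sum(go$depth_db == d & go$outcome == "hit"), integer(1)))
  out$hit_rate <- out$n_hit / out$n_go
  out
}

#' Write / read a session trial table as TSV
#'
#' The TSV carries the trial table plus header metadata columns (animal,
#' group, rate, seed) so a session round-trips through plain text.
#'
#' @param session an `am_session`.
#' @param path file path.
#' @export
write_session_tsv <- function(session, path) {
  tr <- session$trials
  tr$animal_id <- session$animal_id
  tr$group <- session$group
  tr$rate_hz <- session$rate_hz
  tr$seed <- session$seed
  write.table(tr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  tr <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  meta <- tr[1, c("animal_id", "group", "rate_hz", "seed")]
  keep <- setdiff(names(tr), c("animal_id", "group", "rate_hz", "seed"))
  go <- tr$depth_db[tr$type == "go"]
  structure(list(animal_id = meta$animal_id, group = meta$group,
                 rate_hz = meta$rate_hz,
                 depths = sort(unique(go[!is.na(go)])),
                 level_db_spl = tr$level_db_spl[1],
                 seed = meta$seed, trials = tr[, keep]),
            class = "am_session")
}
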