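#' Draw tuning parameters for one synthetic cortical unit
#'
#' Units are rate coders: firing rate depends on AM depth through a monotone
#' function, with both signs present in the population (the experiment found
#' 51.7% of units increased FR with depth and 48.3% decreased). Phase locking
#' at the modulation rate is weak (`kappa` scales a sinusoidal rate modulation
#' whose amplitude grows with linear modulation depth). Trial-to-trial
#' variability is a multiplicative gamma gain whose CV is group dependent
#' (HL > Ctl), the minimal doubly stochastic process that can exceed Poisson
#' variability.
#'
#' @param config a [cohort_config()].
#' @param group "Ctl" or "HL".
#' @param seed RNG seed.
#' @return list of tuning parameters: `monotonic_class` ("increasing" or
#'   "decreasing"), `spont_hz`, `base_hz`, `depth_gain`, `kappa`, `gain_cv`.
#' @export
draw_unit_tuning <- function(config, group, seed = NULL) {
  u <- config$unit
  with_seed(seed, {
    cls <- if (runif(1) < u$p_increasing) "increasing" else "decreasing"
    list(monotonic_class = cls,
         # per-unit heterogeneity around the group means
         spont_hz = rgamma(1, shape = 16, rate = 16 / u$spont_hz[[group]]),
         base_hz = rgamma(1, shape = 16, rate = 16 / u$driven_hz[[group]]),
         depth_gain = u$depth_gain,
         kappa = u$kappa,
         onset_gain = if (cls == "increasing") u$onset_gain %||% 0 else 0,
         onset_tau_s = u$onset_tau_s %||% 0.05,
         gain_cv = u$gain_cv[[group]],
         rate_fidelity = if (group == "HL") u$hl_rate_fidelity else NULL)
  })
}

# Depth-dependent mean driven rate (Hz) of a tuned unit. Increasing units
# scale up by (1 + gain*m); decreasing units are suppressed by at most 95%
# of baseline at full modulation so rates stay positive. `fidelity`
# attenuates the effective modulation depth (HL encoding deficit at fast
# rates).
unit_rate_at_depth <- function(tuning, depth_db, fidelity = 1) {
  m <- depth_db_to_fraction(depth_db) * fidelity
  g <- if (tuning$monotonic_class == "increasing") tuning$depth_gain
       else -min(tuning$depth_gain, 0.95)
  tuning$base_hz * pmax(1 + g * m, 0.05)
}

# Rate-dependent encoding fidelity of a unit (1 unless the HL preset says
# otherwise for this modulation rate).
unit_fidelity <- function(tuning, rate_hz) {
  fid <- tuning$rate_fidelity[[as.character(rate_hz)]]
  if (is.null(fid) || is.na(fid)) 1 else fid
}

# One inhomogeneous-Poisson spike train with rate
# r(t) = rate_mean * (1 + kappa_eff * sin(2*pi*f*t)) + onset_hz * exp(-t/tau)
# on [t0, t1), generated by thinning (exact, no time discretization).
sinusoidal_poisson <- function(rate_mean, kappa_eff, f, t0, t1,
                               onset_hz = 0, onset_tau_s = 0.05) {
  if ((rate_mean <= 0 && onset_hz <= 0) || t1 <= t0) return(numeric(0))
  rmax <- rate_mean * (1 + abs(kappa_eff)) + max(onset_hz, 0)
  n <- rpois(1, rmax * (t1 - t0))
  if (n == 0) return(numeric(0))
  t <- sort(runif(n, t0, t1))
  if (kappa_eff == 0 && onset_hz == 0) return(t)
  lam <- rate_mean * (1 + kappa_eff * sin(2 * pi * f * t)) +
    onset_hz * exp(-pmax(t, 0) / onset_tau_s)
  t[runif(n) < lam / rmax]
}

#' Generate one synthetic cortical unit recorded during a behavioral session
#'
#' Spike times are in seconds relative to the unmodulated-to-AM transition
#' (t = 0). The trial timeline (fringe condition) is: nose poke and stimulus
#' onset at t = -0.4 s, unmodulated fringe on \[-0.4, 0), AM (Go) or continued
#' unmodulated noise (Nogo) on \[0, 1.0). Spontaneous activity fills the 200 ms
#' pre-poke window \[-0.6, -0.4). Within the stimulus the trial rate is
#' `G_trial * r_depth * (1 + kappa * m * sin(2*pi*f*t))` with `G_trial` a
#' gamma gain of mean 1 and CV set by the group preset; monotonically
#' increasing units additionally fire a depth-scaled transient
#' `G_trial * onset_gain * base_hz * m * exp(-t/onset_tau_s)` at the
#' unmodulated-to-AM transition (cortical neurons respond briskly to envelope
#' transitions, which is why short FR analysis windows anchored at the AM
#' onset are most informative). The pre-poke rate is the unit's spontaneous
#' rate (no gain).
#'
#' If `config$choice_coupling > 0`, the trial gain is tilted up on trials
#' where the animal went to the spout, creating nonzero choice probability;
#' at the default 0, spiking and choice are independent.
#'
#' @param config a [cohort_config()].
#' @param session the [generate_session()] output the unit is recorded in.
#' @param tuning unit tuning from [draw_unit_tuning()].
#' @param unit_id identifier string.
#' @param seed RNG seed recorded in the unit.
#' @param isolation "single" or "multi".
#' @return object of class `am_unit`: list with ids, `group`, `rate_hz`,
#'   `tuning`, `isolation`, `window = c(-0.6, 1.0)`, `nose_poke_s = -0.4`,
#'   `trials` (data.frame trial/type/depth_db/choice), `spikes` (list of
#'   sorted numeric vectors, one per trial), `seed`.
#' @export
generate_unit <- function(config, session, tuning, unit_id = "u1",
                          seed = config$seed, isolation = "multi") {
  stopifnot(inherits(session, "am_session"))
  if (tuning$kappa < 0 || tuning$kappa > 1) stop("kappa must be in [0, 1]")
  if (tuning$spont_hz < 0 || tuning$base_hz < 0) stop("rates must be >= 0")
  tr <- session$trials
  f <- session$rate_hz
  cc <- config$choice_coupling
  shape <- 1 / tuning$gain_cv^2
  with_seed(seed, {
    spikes <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      g <- rgamma(1, shape = shape, rate = shape)
      if (cc > 0)
        g <- g * exp(cc * (if (tr$response[i] == "spout") 0.5 else -0.5))
      pre <- sinusoidal_poisson(tuning$spont_hz, 0, f, -0.6, -0.4)
      fringe <- sinusoidal_poisson(g * tuning$base_hz, 0, f, -0.4, 0)
      if (tr$type[i] == "go") {
        fid <- unit_fidelity(tuning, f)
        m <- depth_db_to_fraction(tr$depth_db[i]) * fid
        stim <- sinusoidal_poisson(
          g * unit_rate_at_depth(tuning, tr$depth_db[i], fidelity = fid),
          tuning$kappa * m, f, 0, 1.0,
          onset_hz = g * (tuning$onset_gain %||% 0) * tuning$base_hz * m,
          onset_tau_s = tuning$onset_tau_s %||% 0.05)
      } else {
        stim <- sinusoidal_poisson(g * tuning$base_hz, 0, f, 0, 1.0)
      }
      spikes[[i]] <- sort(c(pre, fringe, stim))
    }
    structure(list(unit_id = unit_id, animal_id = session$animal_id,
                   group = session$group, rate_hz = f, tuning = tuning,
                   isolation = isolation, window = c(-0.6, 1.0),
                   nose_poke_s = -0.4,
                   trials = data.frame(trial = tr$trial, type = tr$type,
                                       depth_db = tr$depth_db,
                                       choice = tr$response),
                   spikes = spikes, seed = as.integer(seed)),
              class = "am_unit")
  })
}

#' @export
print.am_unit <- function(x, ...) {
  cat(sprintf(
    "Cortical unit %s (%s, %s, %s): %d trials at %g Hz, %.1f spikes/trial\n",
    x$unit_id, x$animal_id, x$group, x$tuning$monotonic_class,
    nrow(x$trials), x$rate_hz, mean(lengths(x$spikes))))
  invisible(x)
}

#' Per-trial spike counts of a unit in a time window
#'
#' @param unit an `am_unit`.
#' @param window length-2 numeric window (seconds relative to AM onset),
#'   half-open `[window[1], window[2])`.
#' @return integer vector, one count per trial.
#' @export
trial_counts <- function(unit, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  vapply(unit$spikes, function(s)
    sum(s >= window[1] & s < window[2]), integer(1))
}

#' Write / read a unit's spike data as a long-format TSV
#'
#' One row per spike (`trial`, `t`), preceded by the trial table; the two
#' tables share the file via a `record` column. Plain text stands in for the
#' HDF5 schema used with real recordings.
#'
#' @param unit an `am_unit`.
#' @param path file path.
#' @export
write_unit_tsv <- function(unit, path) {
  tr <- unit$trials
  tr$record <- "trial"
  n <- lengths(unit$spikes)
  sp <- data.frame(record = "spike",
                   trial = rep(tr$trial, n),
                   t = unlist(unit$spikes, use.names = FALSE))
  meta <- data.frame(record = "meta", unit_id = unit$unit_id,
                     animal_id = unit$animal_id, group = unit$group,
                     rate_hz = unit$rate_hz, isolation = unit$isolation,
                     seed = unit$seed)
  con <- file(path, "w")
  on.exit(close(con))
  write.table(meta, con, sep = "\t", row.names = FALSE, quote = FALSE)
  cat("#\n", file = con)
  write.table(tr, con, sep = "\t", row.names = FALSE, quote = FALSE)
  cat("#\n", file = con)
  write.table(sp, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_unit_tsv
#' @export
read_unit_tsv <- function(path) {
  chunks <- strsplit(paste(readLines(path), collapse = "\n"), "\n#\n")[[1]]
  meta <- read.table(text = chunks[1], sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  tr <- read.table(text = chunks[2], sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  sp <- read.table(text = chunks[3], sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  spikes <- lapply(tr$trial, function(i) sort(sp$t[sp$trial == i]))
  structure(list(unit_id = meta$unit_id, animal_id = meta$animal_id,
                 group = meta$group, rate_hz = meta$rate_hz, tuning = NULL,
                 isolation = meta$isolation, window = c(-0.6, 1.0),
                 nose_poke_s = -0.4,
                 trials = tr[, c("trial", "type", "depth_db", "choice")],
                 spikes = spikes, seed = meta$seed),
            class = "am_unit")
}
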