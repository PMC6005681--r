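#' Generate a synthetic envelope-following response (EFR) waveform
#'
#' Emulates the averaged evoked potential to AM noise: a sinusoid at the
#' modulation rate during the stimulus, amplitude `a(depth) = a_max *
#' exp(k * depth_db)` (an exponential in dB depth, saturating at full
#' modulation), plus white noise representing the residual after sweep
#' averaging. The unmodulated condition has zero sinusoidal amplitude, so its
#' spectral peak estimates the noise floor. Group presets are identical:
#' conductive hearing loss leaves brainstem temporal processing intact when
#' stimuli are presented at equal sensation level.
#'
#' @param config a [cohort_config()] (fields `efr$a_max`, `efr$k`,
#'   `efr$noise_sd`, `efr$fs`, `efr$onset_s`, `efr$stim_s`).
#' @param stimulus an [am_stimulus()]; `depth_db = NA` for the unmodulated
#'   condition.
#' @param seed RNG seed recorded in the output.
#' @param n_sweeps number of averaged sweeps (metadata).
#' @param electrode_config electrode configuration label (1 or 2; metadata).
#' @return object of class `efr_recording`: `waveform` (uV), `fs`, `rate_hz`,
#'   `depth_db`, `onset_s`, `offset_s`, `n_sweeps`, `electrode_config`, `seed`.
#' @export
generate_efr <- function(config, stimulus, seed = config$seed,
                         n_sweeps = 1000,
                         electrode_config = if (stimulus$rate_hz > 100) 2 else 1) {
  p <- config$efr
  if (p$fs <= 2 * stimulus$rate_hz)
    stop("efr fs (", p$fs, ") too low for a ", stimulus$rate_hz, " Hz rate")
  onset <- p$onset_s
  offset <- onset + p$stim_s
  dur <- offset + onset
  n <- round(dur * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  a <- if (is_unmodulated(stimulus$depth_db)) 0
       else p$a_max * exp(p$k * stimulus$depth_db)
  with_seed(seed, {
    w <- rnorm(n, sd = p$noise_sd)
    stim <- t >= onset & t < offset
    w[stim] <- w[stim] + a * sin(2 * pi * stimulus$rate_hz * (t[stim] - onset))
    structure(list(waveform = w, fs = p$fs, rate_hz = stimulus$rate_hz,
                   depth_db = stimulus$depth_db, onset_s = onset,
                   offset_s = offset, n_sweeps = n_sweeps,
                   electrode_config = electrode_config,
                   seed = as.integer(seed)),
              class = "efr_recording")
  })
}

#' Generate synthetic click-evoked ABR traces across a level ladder
#'
#' Each trace holds a 5 ms pre-click baseline followed by the response. Above
#' the programmed click threshold the response is a gaussian-windowed
#' deflection whose peak amplitude grows linearly with level re threshold and
#' whose latency shortens with level; below threshold only noise remains.
#'
#' @param config a [cohort_config()] (fields `abr$threshold_db_spl`,
#'   `abr$amp_per_db`, `abr$noise_sd`, `abr$fs`).
#' @param group "Ctl" or "HL" (selects the programmed threshold).
#' @param levels_db_spl descending level ladder (default 90 down to 20 by 10).
#' @param seed RNG seed.
#' @return object of class `abr_traces`: list with `traces` (matrix, one row
#'   per level), `levels_db_spl`, `fs`, `baseline_s = 0.005`, `group`,
#'   `true_threshold_db_spl`, `seed`.
#' @export
generate_abr_traces <- function(config, group,
                                levels_db_spl = seq(90, 20, by = -10),
                                seed = config$seed) {
  p <- config$abr
  thr <- p$threshold_db_spl[[group]]
  baseline_s <- 0.005
  dur <- 0.015
  n <- round(dur * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  with_seed(seed, {
    traces <- matrix(rnorm(length(levels_db_spl) * n, sd = p$noise_sd),
                     nrow = length(levels_db_spl))
    for (i in seq_along(levels_db_spl)) {
      sl <- levels_db_spl[i] - thr
      if (sl <= 0) next
      amp <- p$amp_per_db * sl
      lat <- baseline_s + 0.0032 - 0.00001 * sl   # peak latency, s after click
      traces[i, ] <- traces[i, ] +
        amp * exp(-((t - lat) / 0.0004)^2) -
        0.6 * amp * exp(-((t - lat - 0.0009) / 0.0005)^2)
    }
    structure(list(traces = traces, levels_db_spl = levels_db_spl, fs = p$fs,
                   baseline_s = baseline_s, group = group,
                   true_threshold_db_spl = thr, seed = as.integer(seed)),
              class = "abr_traces")
  })
}

#' Generate a complete synthetic cohort
#'
#' Produces, for every animal of both hearing-status groups: behavioral
#' sessions (per rate), cortical unit recordings attached to those sessions,
#' EFR waveforms across depths (plus the unmodulated condition) per rate, and
#' click ABR traces. All child seeds derive deterministically from the master
#' seed, so the same configuration reproduces byte-identical output.
#'
#' @param config a [cohort_config()].
#' @param efr_depths EFR depth set in dB re 100%.
#' @return object of class `am_cohort`: list with `config`, `sessions`,
#'   `units`, `efr`, `abr` (flat lists) and `manifest` (data.frame of every
#'   generated object with its seed).
#' @export
generate_cohort <- function(config, efr_depths = c(0, -3, -6, -9, -12, -15)) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_animals < 1) stop("cohort needs at least one animal per group")
  sessions <- list(); units <- list(); efr <- list(); abr <- list()
  manifest <- list()
  k <- 0  # global child index
  nxt <- function() { k <<- k + 1; child_seed(config$seed, k) }
  for (group in c("Ctl", "HL")) {
    for (a in seq_len(config$n_animals)) {
      animal_id <- sprintf("%s-%d", group, a)
      n_units <- if (config$units_per_animal[1] == config$units_per_animal[2])
        config$units_per_animal[1]
      else with_seed(nxt(), sample(config$units_per_animal[1]:
                                     config$units_per_animal[2], 1))
      # spread this animal's units evenly over the tested rates
      unit_rates <- rep(config$rates_hz, length.out = n_units)
      ui <- 0
      for (rate in config$rates_hz) {
        rate_sessions <- list()
        for (s in seq_len(config$n_sessions_per_rate)) {
          ses <- generate_session(config, animal_id, group, rate, seed = nxt())
          ses$session_id <- sprintf("%s-r%d-s%d", animal_id, rate, s)
          sessions[[ses$session_id]] <- ses
          rate_sessions[[s]] <- ses
          manifest[[length(manifest) + 1]] <- data.frame(
            kind = "session", id = ses$session_id, animal_id = animal_id,
            group = group, rate_hz = rate, seed = ses$seed)
        }
        for (j in which(unit_rates == rate)) {
          ui <- ui + 1
          ses <- rate_sessions[[1 + (ui %% length(rate_sessions))]]
          tuning <- draw_unit_tuning(config, group, seed = nxt())
          uid <- sprintf("%s-u%03d", animal_id, j)
          u <- generate_unit(config, ses, tuning, unit_id = uid, seed = nxt())
          units[[uid]] <- u
          manifest[[length(manifest) + 1]] <- data.frame(
            kind = "unit", id = uid, animal_id = animal_id, group = group,
            rate_hz = rate, seed = u$seed)
        }
        for (d in c(efr_depths, NA_real_)) {
          stim <- am_stimulus(rate, d, fringe = FALSE,
                              duration_s = config$efr$stim_s)
          rec <- generate_efr(config, stim, seed = nxt())
          rec$animal_id <- animal_id; rec$group <- group
          eid <- sprintf("%s-efr-r%d-%s", animal_id, rate,
                         if (is.na(d)) "unmod" else paste0(d, "dB"))
          efr[[eid]] <- rec
          manifest[[length(manifest) + 1]] <- data.frame(
            kind = "efr", id = eid, animal_id = animal_id, group = group,
            rate_hz = rate, seed = rec$seed)
        }
      }
      tr <- generate_abr_traces(config, group, seed = nxt())
      tr$animal_id <- animal_id
      aid <- sprintf("%s-abr", animal_id)
      abr[[aid]] <- tr
      manifest[[length(manifest) + 1]] <- data.frame(
        kind = "abr", id = aid, animal_id = animal_id, group = group,
        rate_hz = NA_real_, seed = tr$seed)
    }
  }
  structure(list(config = config, sessions = sessions, units = units,
                 efr = efr, abr = abr,
                 manifest = do.call(rbind, manifest)),
            class = "am_cohort")
}

#' @export
print.am_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Synthetic AM cohort: %d animals/group, %d sessions, %d units, %d EFR, %d ABR (seed %d)\n",
    x$config$n_animals, sum(m$kind == "session"), sum(m$kind == "unit"),
    sum(m$kind == "efr"), sum(m$kind == "abr"), x$config$seed))
  invisible(x)
}
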