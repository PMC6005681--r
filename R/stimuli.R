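#' AM stimulus parameterization
#'
#' Describes one amplitude-modulated broadband-noise stimulus as used in the
#' Go-Nogo detection task. Modulation depth is expressed in dB re 100%
#' (0 dB = fully modulated; more negative = shallower); the unmodulated Nogo
#' signal is represented by `depth_db = NA` rather than by -Inf so that trial
#' tables stay finite.
#'
#' In `fringe` mode the stimulus has a 200 ms linear onset ramp followed by a
#' 200 ms unmodulated lead-in, so the unmodulated-to-AM transition occurs at
#' `am_onset_s = 0.4`. In no-fringe mode the stimulus is cosine-gated over
#' 25 ms and modulation starts at stimulus onset.
#'
#' @param rate_hz modulation rate in Hz (> 0); the task used 64, 128, 256 and
#'   512 Hz.
#' @param depth_db modulation depth in dB re 100% (<= 0), or `NA` for the
#'   unmodulated Nogo signal.
#' @param level_db_spl nominal presentation level (metadata only).
#' @param fringe logical; `TRUE` for the ramp + unmodulated-fringe onset.
#' @param duration_s total stimulus duration in seconds.
#' @return an object of class `am_stimulus`.
#' @examples
#' am_stimulus(256, -6)
#' am_stimulus(256, NA)  # Nogo
#' @export
am_stimulus <- function(rate_hz, depth_db, level_db_spl = 45,
                        fringe = TRUE, duration_s = if (fringe) 1.4 else 1.0) {
  stopifnot(rate_hz > 0, duration_s > 0)
  if (!is_unmodulated(depth_db) && depth_db > 0)
    stop("depth_db must be <= 0 dB re 100% (or NA for unmodulated)")
  am_onset_s <- if (fringe) 0.4 else 0
  if (am_onset_s >= duration_s)
    stop("duration_s must exceed the AM onset time")
  structure(list(rate_hz = rate_hz, depth_db = depth_db,
                 level_db_spl = level_db_spl, fringe = fringe,
                 duration_s = duration_s, am_onset_s = am_onset_s),
            class = "am_stimulus")
}

#' @export
print.am_stimulus <- function(x, ...) {
  depth <- if (is_unmodulated(x$depth_db)) "unmodulated (Nogo)"
           else sprintf("%g dB re 100%%", x$depth_db)
  cat(sprintf("AM stimulus: %g Hz, %s, %g dB SPL, %s, %.3g s\n",
              x$rate_hz, depth, x$level_db_spl,
              if (x$fringe) "fringe" else "no fringe", x$duration_s))
  invisible(x)
}

#' Convert modulation depth between dB re 100% and linear fraction
#'
#' The dB scale is the amplitude convention `depth_db = 20*log10(m)`, fixed by
#' the task's printed correspondences (-3, -6, -9 dB are 71%, 50%, 35% after
#' rounding). The unmodulated sentinel `NA` maps to `m = 0` and back.
#'
#' @param depth_db depth(s) in dB re 100% (<= 0 or `NA`).
#' @return linear modulation depth m in \[0, 1\].
#' @examples
#' depth_db_to_fraction(0)            # 1
#' depth_db_to_fraction(-6)           # 0.501...
#' round(100 * depth_db_to_fraction(c(-3, -6, -9)))  # 71 50 35
#' @export
depth_db_to_fraction <- function(depth_db) {
  stopifnot(is.numeric(depth_db) | all(is.na(depth_db)))
  bad <- !is.na(depth_db) & depth_db > 0
  if (any(bad))
    stop("positive depth_db (", paste(depth_db[bad], collapse = ", "),
         ") is not a valid modulation depth; use dB re 100% (<= 0)")
  m <- 10^(depth_db / 20)
  m[is.na(depth_db)] <- 0
  m
}

#' @rdname depth_db_to_fraction
#' @param m linear modulation depth(s) in \[0, 1\]; 0 maps to the unmodulated
#'   sentinel `NA`.
#' @export
fraction_to_depth_db <- function(m) {
  stopifnot(is.numeric(m), all(m >= 0 & m <= 1))
  out <- 20 * log10(m)
  out[m == 0] <- NA_real_
  out
}

#' Sample the amplitude envelope of an AM stimulus
#'
#' Returns the stimulus envelope e(t) sampled at `fs`. During the modulated
#' segment `e(t) = g * (1 + m*sin(2*pi*rate_hz*(t - am_onset_s)))` with the
#' power-equalizing gain `g = 1/sqrt(1 + m^2/2)`, so that the envelope RMS is
#' identical across modulation depths (the task's average-power control).
#' Fringe mode prepends the 200 ms linear onset ramp and the 200 ms
#' unmodulated lead-in; no-fringe mode applies a 25 ms cosine onset gate.
#'
#' @param stim an [am_stimulus()].
#' @param fs sampling rate in Hz; must exceed twice the modulation rate.
#' @return numeric vector of nonnegative envelope samples, with attributes
#'   `fs` and `t0 = 0`.
#' @export
am_envelope <- function(stim, fs = 48000) {
  stopifnot(inherits(stim, "am_stimulus"))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (fs <= 2 * stim$rate_hz)
    stop("fs must exceed twice the modulation rate (", stim$rate_hz, " Hz)")
  m <- depth_db_to_fraction(stim$depth_db)
  g <- 1 / sqrt(1 + m^2 / 2)
  # integer-index grid: k/fs is computed by one division per sample, so
  # boundary comparisons (e.g. t == am_onset_s) are not corrupted by the
  # accumulation error of seq(..., by = 1/fs)
  t <- (seq_len(round(stim$duration_s * fs)) - 1) / fs
  e <- rep(1, length(t))
  mod <- t >= stim$am_onset_s
  e[mod] <- g * (1 + m * sin(2 * pi * stim$rate_hz * (t[mod] - stim$am_onset_s)))
  if (stim$fringe) {
    ramp <- t < 0.2
    e[ramp] <- e[ramp] * t[ramp] / 0.2
  } else {
    gate <- t < 0.025
    e[gate] <- e[gate] * (1 - cos(pi * t[gate] / 0.025)) / 2
  }
  structure(pmax(e, 0), fs = fs, t0 = 0)
}

#' Synthesize a band-limited noise carrier modulated by an AM envelope
#'
#' Generates the full waveform (envelope times a Gaussian broadband-noise
#' carrier band-passed to 3.5-20 kHz). Analyses in this package operate on
#' envelopes and spike trains only; the carrier exists for completeness.
#'
#' @inheritParams am_envelope
#' @param seed optional RNG seed for the frozen-noise carrier.
#' @return numeric waveform vector with attribute `fs`.
#' @export
am_waveform <- function(stim, fs = 48000, seed = NULL) {
  e <- am_envelope(stim, fs)
  n <- length(e)
  carrier <- with_seed(seed, rnorm(n))
  # FFT brick-wall band-pass, 3.5-20 kHz
  sp <- fft(carrier)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sp[f < 3500 | f > 20000] <- 0
  carrier <- Re(fft(sp, inverse = TRUE)) / n
  carrier <- carrier / sd(carrier)
  structure(as.numeric(e) * carrier, fs = fs)
}

#' Serialize / deserialize a stimulus set as JSON
#'
#' @param stimuli list of [am_stimulus()] objects.
#' @param path file path.
#' @return `write_stimulus_set` returns `path` invisibly;
#'   `read_stimulus_set` returns a list of `am_stimulus` objects.
#' @export
write_stimulus_set <- function(stimuli, path) {
  recs <- lapply(stimuli, function(s) {
    s <- unclass(s)
    s$depth_db <- if (is_unmodulated(s$depth_db)) "unmodulated" else s$depth_db
    s
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    depth <- if (identical(r$depth_db, "unmodulated")) NA_real_ else r$depth_db
    am_stimulus(r$rate_hz, depth, r$level_db_spl, r$fringe, r$duration_s)
  })
}
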