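#' Spectral peak of an envelope-following response
#'
#' Computes the amplitude-normalized FFT (`2*|X(f)|/N`, rectangular window, no
#' taper) of the waveform between 10 ms after stimulus onset and 10 ms before
#' stimulus offset, and returns the maximum magnitude over frequency bins
#' within 3 Hz of the modulation rate.
#'
#' @param rec an `efr_recording` (waveform, fs, rate_hz, onset_s, offset_s).
#' @param band_hz half-width of the search band around the rate (default 3).
#' @param pad_s guard interval trimmed from each end of the stimulus
#'   (default 0.010 s).
#' @return peak amplitude (same units as the waveform).
#' @export
efr_fft_peak <- function(rec, band_hz = 3, pad_s = 0.010) {
  t0 <- rec$onset_s + pad_s
  t1 <- rec$offset_s - pad_s
  if (t1 - t0 < 1 / rec$rate_hz)
    stop("analysis window shorter than one modulation period")
  if (t1 - t0 < 2 / rec$rate_hz)
    warning("analysis window shorter than two modulation periods")
  i0 <- floor(t0 * rec$fs) + 1
  i1 <- floor(t1 * rec$fs)
  x <- rec$waveform[i0:i1]
  n <- length(x)
  amp <- 2 * Mod(fft(x)) / n
  freq <- (seq_len(n) - 1) * rec$fs / n
  sel <- freq >= rec$rate_hz - band_hz & freq <= rec$rate_hz + band_hz
  if (!any(sel)) sel <- which.min(abs(freq - rec$rate_hz))
  max(amp[sel])
}

#' EFR depth threshold at one modulation rate
#'
#' The noise floor is the spectral peak of the unmodulated recording.
#' Peak amplitudes across depths are normalized by the largest value and
#' fitted with an exponential in dB depth (`a(d) = A*exp(k*d)`, least
#' squares); the threshold is the lowest depth at which the amplitude reaches
#' twice the noise floor, read from the fitted curve (continuously between
#' tested depths) with the discrete lowest qualifying tested depth also
#' reported. Undefined when no depth qualifies.
#'
#' @param recs list of `efr_recording` objects at one rate across depths,
#'   including the unmodulated (`depth_db = NA`) condition.
#' @param rate_hz modulation rate (consistency check).
#' @return list: `threshold_db` (fitted; NA if undefined), `threshold_db_raw`
#'   (lowest qualifying tested depth), `noise_floor`, `amplitudes`
#'   (data.frame depth_db/amplitude/normalized), `fit` (A, k), `flag`.
#' @export
efr_threshold <- function(recs, rate_hz = recs[[1]]$rate_hz) {
  rates <- vapply(recs, function(r) r$rate_hz, numeric(1))
  if (!all(rates == rate_hz)) stop("recordings mix modulation rates")
  depth <- vapply(recs, function(r) r$depth_db, numeric(1))
  if (!any(is.na(depth))) stop("missing unmodulated (noise-floor) condition")
  if (sum(!is.na(depth)) < 3) stop("need >= 3 modulated depths")
  peaks <- vapply(recs, efr_fft_peak, numeric(1))
  floor_amp <- mean(peaks[is.na(depth)])
  d <- depth[!is.na(depth)]; a <- peaks[!is.na(depth)]
  o <- order(d); d <- d[o]; a <- a[o]
  norm <- a / max(a)
  fit <- tryCatch({
    lf <- lm(log(pmax(a, 1e-12)) ~ d)
    nl <- nls(a ~ A * exp(k * d),
              start = list(A = exp(coef(lf)[[1]]), k = coef(lf)[[2]]),
              control = list(maxiter = 200, warnOnly = TRUE),
              algorithm = "port")
    coef(nl)
  }, error = function(e) c(A = max(a), k = 0))
  A <- fit[["A"]]; k <- fit[["k"]]
  crit <- 2 * floor_amp
  qual <- d[a >= crit]
  thr_raw <- if (length(qual)) min(qual) else NA_real_
  thr_fit <- if (A * exp(k * max(d)) < crit || k <= 0) {
    NA_real_
  } else if (A * exp(k * min(d)) >= crit) {
    min(d)
  } else {
    min(max(log(crit / A) / k, min(d)), max(d))
  }
  flag <- if (is.na(thr_fit) && is.na(thr_raw)) "undefined" else "ok"
  list(threshold_db = thr_fit, threshold_db_raw = thr_raw,
       noise_floor = floor_amp,
       amplitudes = data.frame(depth_db = d, amplitude = a,
                               normalized = norm),
       fit = c(A = A, k = k), flag = flag)
}

#' Brainstem TMTF from EFR thresholds across rates
#'
#' Assembles per-rate EFR thresholds and fits the same exponential TMTF model
#' used for behavior ([fit_tmtf()]).
#'
#' @param thresholds data.frame with columns `rate_hz` and `threshold_db`.
#' @return a `tmtf_fit`.
#' @export
efr_tmtf <- function(thresholds) {
  fit_tmtf(thresholds$rate_hz, thresholds$threshold_db)
}

#' ABR click metrics: peak amplitude, latency, and threshold
#'
#' Per level, the peak amplitude is the maximum absolute deflection in the
#' post-click window and its latency the time of that peak after the click.
#' Threshold is the lowest level whose peak exceeds `k_sd` standard
#' deviations of the pre-click baseline (an explicit criterion standing in
#' for the visual detection endpoint used online). Amplitudes and latencies
#' are also reported against sensation level (level minus threshold).
#'
#' @param abr an `abr_traces` object (traces matrix by level, fs,
#'   baseline_s), or a plain list with those fields.
#' @param k_sd baseline-SD multiplier for the threshold criterion (default 3).
#' @return object of class `abr_result`: `by_level` data.frame
#'   (level_db_spl, peak_uv, latency_ms, sensation_level_db),
#'   `threshold_db_spl` (NA with flag "no-response" if nothing exceeds the
#'   criterion), `baseline_sd`, `flag`.
#' @export
abr_metrics <- function(abr, k_sd = 3) {
  tr <- abr$traces
  fs <- abr$fs
  nb <- floor(abr$baseline_s * fs)
  if (nb < 2) stop("no pre-stimulus baseline segment in the traces")
  base_sd <- sd(as.numeric(tr[, seq_len(nb)]))
  post <- (nb + 1):ncol(tr)
  peak <- apply(abs(tr[, post, drop = FALSE]), 1, max)
  lat_idx <- apply(abs(tr[, post, drop = FALSE]), 1, which.max)
  latency_ms <- 1000 * lat_idx / fs
  resp <- peak > k_sd * base_sd
  thr <- if (any(resp)) min(abr$levels_db_spl[resp]) else NA_real_
  by_level <- data.frame(level_db_spl = abr$levels_db_spl, peak_uv = peak,
                         latency_ms = latency_ms,
                         sensation_level_db = abr$levels_db_spl - thr)
  structure(list(by_level = by_level, threshold_db_spl = thr,
                 baseline_sd = base_sd, k_sd = k_sd,
                 flag = if (is.na(thr)) "no-response" else "ok"),
            class = "abr_result")
}

#' @export
print.abr_result <- function(x, ...) {
  cat(sprintf("ABR metrics: threshold %s dB SPL (criterion %g x baseline SD)\n",
              if (is.na(x$threshold_db_spl)) "undefined"
              else format(x$threshold_db_spl), x$k_sd))
  invisible(x)
}
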