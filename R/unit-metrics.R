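#' Spontaneous firing rate of a unit
#'
#' Mean rate in the 200 ms window immediately before the nose poke, averaged
#' over trials.
#'
#' @param unit an `am_unit`.
#' @return rate in Hz.
#' @export
spontaneous_rate <- function(unit) {
  if (is.null(unit$nose_poke_s))
    stop("unit lacks nose-poke alignment")
  w <- c(unit$nose_poke_s - 0.2, unit$nose_poke_s)
  mean(trial_counts(unit, w)) / 0.2
}

# FR (Hz) per trial over a window of given length starting at AM onset.
window_rates <- function(unit, window_ms) {
  trial_counts(unit, c(0, window_ms / 1000)) / (window_ms / 1000)
}

# Per-depth |d'| of trial FRs: (mean Go(depth) - mean Nogo) / pooled SD,
# pooling within-condition SDs across all stimuli of the rate.
fr_dprime_at <- function(rates, trials) {
  conds <- split(rates, ifelse(trials$type == "nogo", "nogo",
                               as.character(trials$depth_db)))
  ns <- lengths(conds)
  vs <- vapply(conds, var, numeric(1))
  df <- sum(ns - 1)
  sd_pool <- if (df > 0) sqrt(sum((ns - 1) * vs, na.rm = TRUE) / df) else 0
  nogo_mean <- mean(conds[["nogo"]])
  depths <- sort(as.numeric(setdiff(names(conds), "nogo")))
  dp <- vapply(depths, function(d) {
    mu <- mean(conds[[as.character(d)]])
    if (sd_pool == 0) 0 else abs(mu - nogo_mean) / sd_pool
  }, numeric(1))
  list(depth_db = depths, dprime = dp, degenerate = sd_pool == 0,
       fr = vapply(depths, function(d) mean(conds[[as.character(d)]]),
                   numeric(1)),
       fr_nogo = nogo_mean)
}

#' Best-window firing-rate d-prime of a unit
#'
#' Computes mean FR over candidate windows of 25-1000 ms (25 ms steps)
#' starting at the unmodulated-to-AM transition, converts each window's
#' per-depth Go-versus-Nogo separation to `|d'| = |FR_Go - FR_Nogo| /
#' SD_pooled` (SD pooled within conditions across all stimuli of that rate),
#' and selects the window that maximizes the maximum |d'| over depths.
#' Reported d-prime values are nonnegative by convention, so units whose FR
#' decreases with depth score equally.
#'
#' @param unit an `am_unit`.
#' @param windows_ms candidate window lengths (default `seq(25, 1000, 25)`).
#' @param aggregate how to score a window: "max" (default) or "mean" |d'|
#'   over depths.
#' @return object of class `neurometric_fn`: `best_window_ms`, `depth_db`,
#'   `dprime`, `fr` (per-depth mean FR in the best window), `fr_nogo`,
#'   `degenerate` flag, plus unit metadata.
#' @export
best_window_dprime <- function(unit, windows_ms = seq(25, 1000, by = 25),
                               aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(windows_ms) >= 1)
  tr <- unit$trials
  if (min(table(ifelse(tr$type == "nogo", "nogo", tr$depth_db))) < 2)
    stop("need >= 2 trials per condition")
  best <- NULL; best_score <- -Inf; best_w <- windows_ms[1]
  for (w in windows_ms) {
    res <- fr_dprime_at(window_rates(unit, w), tr)
    score <- if (aggregate == "max") max(res$dprime) else mean(res$dprime)
    if (score > best_score) { best_score <- score; best <- res; best_w <- w }
  }
  structure(list(unit_id = unit$unit_id, animal_id = unit$animal_id,
                 group = unit$group, rate_hz = unit$rate_hz,
                 best_window_ms = best_w, depth_db = best$depth_db,
                 dprime = best$dprime, fr = best$fr, fr_nogo = best$fr_nogo,
                 degenerate = best$degenerate),
            class = "neurometric_fn")
}

#' @export
print.neurometric_fn <- function(x, ...) {
  cat(sprintf("Neurometric function %s (%g Hz), best window %d ms\n",
              x$unit_id, x$rate_hz, x$best_window_ms))
  print(data.frame(depth_db = x$depth_db, fr = round(x$fr, 2),
                   dprime = round(x$dprime, 3)))
  invisible(x)
}

#' Monotonicity index of a depth-rate function
#'
#' `MI = 100 * FR(0 dB) / max FR over depths`. Units with MI > 50% are
#' classified monotonically increasing, MI <= 50% monotonically decreasing.
#'
#' @param depth_db depths (must include 0 dB).
#' @param fr mean FR at each depth.
#' @return list with `mi` (percent) and `class` ("increasing"/"decreasing");
#'   `mi = NA` with class `NA` when the maximum FR is 0.
#' @export
monotonicity_index <- function(depth_db, fr) {
  stopifnot(length(depth_db) == length(fr), length(fr) >= 2)
  i0 <- which(depth_db == 0)
  if (length(i0) != 1) stop("FR at 0 dB (full depth) is required")
  mx <- max(fr)
  if (mx == 0) return(list(mi = NA_real_, class = NA_character_))
  mi <- 100 * fr[i0] / mx
  list(mi = mi, class = if (mi > 50) "increasing" else "decreasing")
}

#' Vector strength and Rayleigh test of phase locking
#'
#' `VS = |sum_j exp(2*pi*i*f*t_j)| / n`, 0 for uniform phases and 1 when all
#' spikes fall at the identical phase. Significance uses the Rayleigh
#' statistic `2*n*VS^2` against its large-sample chi-squared (2 df)
#' approximation at p < 0.001.
#'
#' @param spike_times spike times in seconds.
#' @param f modulation frequency in Hz.
#' @param alpha significance level (default 0.001).
#' @return list with `vs`, `rayleigh`, `p`, `significant`, `n`; `vs` is `NA`
#'   for an empty train.
#' @export
vector_strength <- function(spike_times, f, alpha = 0.001) {
  n <- length(spike_times)
  if (n == 0)
    return(list(vs = NA_real_, rayleigh = NA_real_, p = NA_real_,
                significant = FALSE, n = 0L))
  ph <- 2 * pi * f * spike_times
  vs <- Mod(sum(exp(1i * ph))) / n
  stat <- 2 * n * vs^2
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  list(vs = vs, rayleigh = stat, p = p, significant = p < alpha, n = n)
}

#' Trial-to-trial coefficient of variation of a unit
#'
#' Per stimulus condition, CV = SD of trial FRs / mean trial FR, with FRs
#' taken in the unit's best window. The unit-level summary is the CV at the
#' condition with maximal driven FR (a convention; all per-condition CVs are
#' returned so alternatives remain testable).
#'
#' @param unit an `am_unit`.
#' @param window_ms FR window; default uses [best_window_dprime()]'s choice.
#' @return list with `cv` (unit-level), `by_condition` data.frame
#'   (condition, mean_fr, cv), and `window_ms`.
#' @export
unit_cv <- function(unit, window_ms = NULL) {
  if (is.null(window_ms))
    window_ms <- best_window_dprime(unit)$best_window_ms
  rates <- window_rates(unit, window_ms)
  cond <- ifelse(unit$trials$type == "nogo", "nogo",
                 as.character(unit$trials$depth_db))
  sp <- split(rates, cond)
  if (any(lengths(sp) < 2)) stop("need >= 2 trials per condition")
  bc <- data.frame(condition = names(sp),
                   mean_fr = vapply(sp, mean, numeric(1)),
                   cv = vapply(sp, function(x)
                     if (mean(x) == 0) NA_real_ else sd(x) / mean(x),
                     numeric(1)))
  rownames(bc) <- NULL
  top <- bc[!is.na(bc$cv), ]
  cv <- if (nrow(top) == 0) NA_real_ else top$cv[which.max(top$mean_fr)]
  list(cv = cv, by_condition = bc, window_ms = window_ms)
}

#' Neurometric detection threshold by bracketing interpolation
#'
#' Requires at least one depth with d' > 1. Threshold is the depth (dB) at
#' which the line between the greatest d' below 1 and the smallest d' above 1
#' crosses d' = 1. If even the lowest tested depth exceeds d' = 1 the
#' threshold is that depth, flagged "ceiling". Units with no depth above
#' d' = 1 have no threshold (excluded from threshold analyses).
#'
#' @param depth_db tested depths (dB re 100%).
#' @param dprime nonnegative d-prime at each depth.
#' @return list with `threshold_db` (NA if undefined) and `flag`
#'   ("ok"/"ceiling"/"undefined").
#' @export
neurometric_threshold <- function(depth_db, dprime) {
  stopifnot(length(depth_db) == length(dprime))
  o <- order(depth_db)
  depth_db <- depth_db[o]; dprime <- dprime[o]
  if (!any(dprime > 1, na.rm = TRUE))
    return(list(threshold_db = NA_real_, flag = "undefined"))
  if (any(dprime == 1, na.rm = TRUE)) {
    return(list(threshold_db = min(depth_db[which(dprime == 1)]), flag = "ok"))
  }
  above <- which(dprime > 1)
  below <- which(dprime < 1)
  if (length(below) == 0 || min(above) == 1)
    return(list(threshold_db = depth_db[1], flag = "ceiling"))
  # bracketing pair: greatest d' below 1 and smallest d' above 1
  i_lo <- below[which.max(dprime[below])]
  i_hi <- above[which.min(dprime[above])]
  x1 <- depth_db[i_lo]; y1 <- dprime[i_lo]
  x2 <- depth_db[i_hi]; y2 <- dprime[i_hi]
  list(threshold_db = x1 + (1 - y1) * (x2 - x1) / (y2 - y1), flag = "ok")
}

#' Choice probability of a unit
#'
#' Area under the ROC comparing the unit's firing-rate distributions on
#' trials where the animal reported modulation (went to the spout) versus
#' trials where it did not, over a window relative to AM onset. Equals the
#' probability that a randomly drawn report-trial FR exceeds a randomly drawn
#' no-report FR, ties counted one half; 0.5 means no choice information.
#'
#' Only depths near the psychometric threshold are included (session hit rate
#' within `hit_range`), which guarantees both choice classes occur; Nogo
#' trials are excluded.
#'
#' @param unit an `am_unit`.
#' @param window length-2 window in seconds relative to AM onset; the
#'   conventional choices are `c(0, 0.4)` (stimulus-driven epoch) and
#'   `c(0.4, 0.8)` (choice epoch).
#' @param hit_range hit-rate band defining "depths around threshold"
#'   (default `c(0.2, 0.8)`).
#' @return list with `cp`, `n_report`, `n_noreport`, `depths_used`,
#'   `low_power` flag (TRUE when a choice class has < 5 trials); `cp` is `NA`
#'   when a class is empty.
#' @export
choice_probability <- function(unit, window = c(0, 0.4),
                               hit_range = c(0.2, 0.8)) {
  tr <- unit$trials
  go <- tr$type == "go"
  depths <- sort(unique(tr$depth_db[go]))
  hr <- vapply(depths, function(d) {
    idx <- go & tr$depth_db == d
    mean(tr$choice[idx] == "spout")
  }, numeric(1))
  use_depths <- depths[hr >= hit_range[1] & hr <= hit_range[2]]
  keep <- go & tr$depth_db %in% use_depths
  counts <- trial_counts(unit, window)[keep]
  report <- tr$choice[keep] == "spout"
  n1 <- sum(report); n2 <- sum(!report)
  if (n1 == 0 || n2 == 0)
    return(list(cp = NA_real_, n_report = n1, n_noreport = n2,
                depths_used = use_depths, low_power = TRUE))
  r <- rank(counts)               # midranks handle ties as 1/2
  u <- sum(r[report]) - n1 * (n1 + 1) / 2
  list(cp = u / (n1 * n2), n_report = n1, n_noreport = n2,
       depths_used = use_depths, low_power = min(n1, n2) < 5)
}

#' Tidy per-unit neurometric summary table
#'
#' One row per unit: best window, per-depth maximum d', FR-based threshold,
#' monotonicity, vector strength at full depth, CV, spontaneous rate.
#'
#' @param units list of `am_unit` objects.
#' @return data.frame keyed by unit_id/animal_id/group/rate_hz.
#' @export
unit_metrics_table <- function(units) {
  rows <- lapply(units, function(u) {
    nf <- best_window_dprime(u)
    thr <- neurometric_threshold(nf$depth_db, nf$dprime)
    mi <- monotonicity_index(nf$depth_db, nf$fr)
    cv <- unit_cv(u, window_ms = nf$best_window_ms)
    full <- which(u$trials$type == "go" & u$trials$depth_db == 0)
    vs <- if (length(full) > 0) {
      st <- unlist(u$spikes[full], use.names = FALSE)
      vector_strength(st[st >= 0 & st < 1], u$rate_hz)
    } else list(vs = NA_real_, significant = NA)
    data.frame(unit_id = u$unit_id, animal_id = u$animal_id, group = u$group,
               rate_hz = u$rate_hz, best_window_ms = nf$best_window_ms,
               max_dprime = max(nf$dprime), threshold_db = thr$threshold_db,
               threshold_flag = thr$flag, mi = mi$mi,
               monotonic_class = if (is.na(mi$mi)) NA_character_ else mi$class,
               vs = vs$vs, vs_significant = vs$significant,
               cv = cv$cv, spont_hz = spontaneous_rate(u))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
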