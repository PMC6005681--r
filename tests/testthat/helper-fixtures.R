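# Shared fixture builders. Everything is constructed in code; no data files.

# A bare am_session with a given trial table (bypasses the generator).
make_session <- function(trials, rate_hz = 256, animal_id = "test",
                         group = "Ctl") {
  go <- trials$depth_db[trials$type == "go"]
  structure(list(animal_id = animal_id, group = group, rate_hz = rate_hz,
                 depths = sort(unique(go[!is.na(go)])), level_db_spl = 45,
                 seed = 0L, trials = trials),
            class = "am_session")
}

# Trial table with exact per-depth hit counts and an exact FA count.
trials_from_counts <- function(depths, n_go, n_hit, n_nogo, n_fa) {
  rows <- list()
  for (i in seq_along(depths)) {
    hit <- c(rep("hit", n_hit[i]), rep("miss", n_go[i] - n_hit[i]))
    rows[[i]] <- data.frame(type = "go", depth_db = depths[i], outcome = hit)
  }
  rows[[length(rows) + 1]] <- data.frame(
    type = "nogo", depth_db = NA_real_,
    outcome = c(rep("fa", n_fa), rep("cr", n_nogo - n_fa)))
  tr <- do.call(rbind, rows)
  tr$trial <- seq_len(nrow(tr))
  tr$response <- ifelse(tr$outcome %in% c("hit", "fa"), "spout", "repoke")
  tr$latency_s <- 0.3
  tr$level_db_spl <- 45
  tr[, c("trial", "type", "depth_db", "response", "outcome", "latency_s",
         "level_db_spl")]
}

# A bare am_unit with explicit spike trains and trial labels.
make_unit <- function(spikes, type, depth_db, choice = NULL,
                      rate_hz = 256, unit_id = "u-test", group = "Ctl",
                      animal_id = "test") {
  n <- length(spikes)
  if (is.null(choice)) choice <- rep("spout", n)
  structure(list(unit_id = unit_id, animal_id = animal_id, group = group,
                 rate_hz = rate_hz,
                 tuning = NULL, isolation = "multi", window = c(-0.6, 1.0),
                 nose_poke_s = -0.4,
                 trials = data.frame(trial = seq_len(n), type = type,
                                     depth_db = depth_db, choice = choice),
                 spikes = spikes, seed = 0L),
            class = "am_unit")
}

# am_unit whose Go/Nogo trials are homogeneous Poisson at given rates over
# [0, duration); spontaneous spikes omitted unless spont_hz > 0.
poisson_unit <- function(rate_go, rate_nogo, n_go = 20, n_nogo = 20,
                         duration = 1, depth_go = 0, spont_hz = 0,
                         rate_hz = 256) {
  draw <- function(r) {
    n <- rpois(1, r * duration)
    s <- sort(runif(n, 0, duration))
    if (spont_hz > 0)
      s <- c(sort(runif(rpois(1, spont_hz * 0.2), -0.6, -0.4)), s)
    s
  }
  spikes <- c(lapply(seq_len(n_go), function(i) draw(rate_go)),
              lapply(seq_len(n_nogo), function(i) draw(rate_nogo)))
  make_unit(spikes,
            type = rep(c("go", "nogo"), c(n_go, n_nogo)),
            depth_db = rep(c(depth_go, NA_real_), c(n_go, n_nogo)),
            rate_hz = rate_hz)
}

# Numerical-integration oracle for the van Rossum inner product: trains
# filtered with the causal exponential on a fine grid, trapezoid integral.
# Independent of the package's closed-form path.
numeric_filter_inner <- function(a, b, tau, dt = tau / 400, t_max = NULL) {
  if (is.null(t_max)) t_max <- max(c(a, b, 0)) + 12 * tau
  grid <- seq(0, t_max, by = dt)
  f <- function(s) {
    out <- numeric(length(grid))
    for (t0 in s) out <- out + ifelse(grid >= t0, exp(-(grid - t0) / tau), 0)
    out
  }
  fa <- f(a); fb <- f(b)
  sum((fa * fb)[-1] + (fa * fb)[-length(grid)]) * dt / 2
}

numeric_van_rossum <- function(a, b, tau, ...) {
  sqrt(max(numeric_filter_inner(a, a, tau, ...) +
             numeric_filter_inner(b, b, tau, ...) -
             2 * numeric_filter_inner(a, b, tau, ...), 0))
}
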