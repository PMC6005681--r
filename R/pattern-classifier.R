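#' Configuration for the template-based spike-train pattern classifier
#'
#' @param metric one of "fr", "van_rossum", "kmeans", "rcorr".
#' @param tau_s decay-constant grid in seconds; default the powers-of-two
#'   2-512 ms grid.
#' @param n_iterations template resampling iterations (1000 with real data;
#'   tests scale this down).
#' @param K number of clusters for the K-means metric.
#' @param template_frac fraction of each class used to build templates (0.5).
#' @param compare "heldout" compares only the held-out trials to the
#'   templates (default; avoids training contamination), "all" compares every
#'   trial.
#' @param pool "pooled" accumulates hits/false alarms over all iterations
#'   before the d-prime transform (default); "per_iteration" averages
#'   per-iteration d-primes.
#' @param window analysis window in seconds relative to AM onset.
#' @param seed RNG seed.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(metric = c("fr", "van_rossum", "kmeans", "rcorr"),
                              tau_s = 2^(1:9) / 1000,
                              n_iterations = 1000, K = 2,
                              template_frac = 0.5,
                              compare = c("heldout", "all"),
                              pool = c("pooled", "per_iteration"),
                              window = c(0, 1), seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(all(tau_s > 0), n_iterations >= 1,
            template_frac > 0, template_frac < 1, K >= 2)
  structure(list(metric = metric, tau_s = tau_s,
                 n_iterations = as.integer(n_iterations), K = as.integer(K),
                 template_frac = template_frac,
                 compare = match.arg(compare), pool = match.arg(pool),
                 window = window, seed = as.integer(seed)),
            class = "classifier_config")
}

# Inner product of two causally exp-filtered spike trains,
# <f_a, f_b> = (tau/2) * sum_ij exp(-|a_i - b_j| / tau).  Exact (continuous
# time); the basis of both the van Rossum distance and Rcorr.
exp_filter_inner <- function(a, b, tau_s) {
  if (length(a) == 0 || length(b) == 0) return(0)
  (tau_s / 2) * sum(exp(-abs(outer(a, b, "-")) / tau_s))
}

#' van Rossum distance between two spike trains
#'
#' Each train is convolved with the causal unit-amplitude exponential kernel
#' `exp(-t/tau)` (t >= 0); the distance is the L2 norm of the difference of
#' the filtered functions. Computed in closed form from the kernel inner
#' products, which is the exact continuous-time value (no discretization).
#' Two single spikes `dt` apart give `sqrt(tau * (1 - exp(-dt/tau)))`,
#' saturating at `sqrt(tau)` for widely separated spikes.
#'
#' @param a,b sorted spike-time vectors (seconds).
#' @param tau_s kernel decay constant in seconds (> 0).
#' @return nonnegative distance.
#' @export
van_rossum_distance <- function(a, b, tau_s) {
  if (tau_s <= 0) stop("tau must be > 0")
  d2 <- exp_filter_inner(a, a, tau_s) + exp_filter_inner(b, b, tau_s) -
    2 * exp_filter_inner(a, b, tau_s)
  sqrt(max(d2, 0))
}

#' Rcorr spike-timing similarity between two spike trains
#'
#' Normalized inner product of the exponentially filtered trains,
#' `<f_a, f_b> / (||f_a|| * ||f_b||)`: 1 for identical trains, near 0 for
#' trains with no coincident structure at timescale tau. Nonnegative for the
#' causal exponential filter. Undefined (NA) if either train is empty; in
#' classification such pairs score similarity 0.
#'
#' @inheritParams van_rossum_distance
#' @return similarity in \[0, 1\], or NA for an empty train.
#' @export
rcorr <- function(a, b, tau_s) {
  if (tau_s <= 0) stop("tau must be > 0")
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  exp_filter_inner(a, b, tau_s) /
    sqrt(exp_filter_inner(a, a, tau_s) * exp_filter_inner(b, b, tau_s))
}

# Gram matrix of kernel inner products over a list of spike trains.
exp_filter_gram <- function(trains, tau_s) {
  n <- length(trains)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    G[i, j] <- G[j, i] <- exp_filter_inner(trains[[i]], trains[[j]], tau_s)
  }
  G
}

# Exponentially filtered trains evaluated on a regular grid (used only by the
# K-means metric, which needs explicit vectors). Step = min(tau/20, 1 ms).
filtered_matrix <- function(trains, tau_s, window) {
  step <- min(tau_s / 20, 0.001)
  grid <- seq(window[1], window[2], by = step)
  t(vapply(trains, function(s) {
    if (length(s) == 0) return(numeric(length(grid)))
    colSums(exp(-pmax(outer(-s, grid, "+"), 0) / tau_s) *
              (outer(s, grid, "<=")))
  }, numeric(length(grid))))
}

# Spike trains of a unit restricted to a window, split into the Go trials at
# one depth and the (shared) Nogo trials.
classifier_trains <- function(unit, go_depth, window) {
  clip <- function(s) s[s >= window[1] & s < window[2]]
  tr <- unit$trials
  go_idx <- which(tr$type == "go" & tr$depth_db == go_depth)
  nogo_idx <- which(tr$type == "nogo")
  list(go = lapply(unit$spikes[go_idx], clip),
       nogo = lapply(unit$spikes[nogo_idx], clip))
}

# One-depth classification loop shared by all four metrics. Returns pooled
# hit/fa proportions and the per-iteration proportions.
classify_one_depth <- function(go, nogo, config, tau_s) {
  n_go <- length(go); n_nogo <- length(nogo)
  if (n_go < 4 || n_nogo < 4)
    stop("classifier needs >= 4 trials per class (go: ", n_go,
         ", nogo: ", n_nogo, ")")
  metric <- config$metric
  trains <- c(go, nogo)
  is_go <- c(rep(TRUE, n_go), rep(FALSE, n_nogo))
  if (metric == "fr") {
    counts <- lengths(trains)
  } else if (metric %in% c("van_rossum", "rcorr")) {
    G <- exp_filter_gram(trains, tau_s)
  } else if (metric == "kmeans") {
    V <- filtered_matrix(trains, tau_s, config$window)
  }
  hits <- 0; fas <- 0; n_go_tested <- 0; n_nogo_tested <- 0
  dp_iter <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    tg <- sample(n_go, max(2, round(config$template_frac * n_go)))
    tn <- n_go + sample(n_nogo, max(2, round(config$template_frac * n_nogo)))
    test <- if (config$compare == "heldout")
      setdiff(seq_along(trains), c(tg, tn)) else seq_along(trains)
    if (length(test) == 0) next
    pred_go <- switch(
      metric,
      fr = {
        mu_g <- mean(counts[tg]); mu_n <- mean(counts[tn])
        abs(counts[test] - mu_g) < abs(counts[test] - mu_n) |
          (abs(counts[test] - mu_g) == abs(counts[test] - mu_n) &
             sample(c(TRUE, FALSE), length(test), replace = TRUE))
      },
      van_rossum = {
        # distance from each test trial to the *averaged filtered* template
        d2g <- diag(G)[test] - 2 * rowMeans(G[test, tg, drop = FALSE]) +
          mean(G[tg, tg])
        d2n <- diag(G)[test] - 2 * rowMeans(G[test, tn, drop = FALSE]) +
          mean(G[tn, tn])
        d2g < d2n
      },
      rcorr = {
        selfn <- sqrt(diag(G)[test])
        ng <- sqrt(mean(G[tg, tg])); nn <- sqrt(mean(G[tn, tn]))
        sg <- rowMeans(G[test, tg, drop = FALSE]) / (selfn * ng)
        sn <- rowMeans(G[test, tn, drop = FALSE]) / (selfn * nn)
        sg[!is.finite(sg)] <- 0; sn[!is.finite(sn)] <- 0
        sg > sn
      },
      kmeans = {
        tmpl <- c(tg, tn)
        centers <- rbind(colMeans(V[tg, , drop = FALSE]),
                         colMeans(V[tn, , drop = FALSE]))
        km <- suppressWarnings(
          kmeans(V[tmpl, , drop = FALSE], centers = centers, iter.max = 20))
        # label clusters by majority template membership
        go_frac <- vapply(seq_len(nrow(km$centers)), function(cl)
          mean(tmpl[km$cluster == cl] <= n_go), numeric(1))
        go_cluster <- which.max(go_frac)
        d2c <- vapply(seq_len(nrow(km$centers)), function(cl)
          rowSums(sweep(V[test, , drop = FALSE], 2, km$centers[cl, ])^2),
          numeric(length(test)))
        if (length(test) == 1) d2c <- matrix(d2c, nrow = 1)
        max.col(-d2c, ties.method = "first") == go_cluster
      })
    go_test <- is_go[test]
    h <- sum(pred_go & go_test); f <- sum(pred_go & !go_test)
    hits <- hits + h; fas <- fas + f
    n_go_tested <- n_go_tested + sum(go_test)
    n_nogo_tested <- n_nogo_tested + sum(!go_test)
    dp_iter[it] <- compute_dprime(
      if (sum(go_test) > 0) h / sum(go_test) else NA,
      if (sum(!go_test) > 0) f / sum(!go_test) else NA)
  }
  hit_rate <- hits / n_go_tested
  fa_rate <- fas / n_nogo_tested
  dprime <- if (config$pool == "pooled") compute_dprime(hit_rate, fa_rate)
            else mean(dp_iter, na.rm = TRUE)
  list(hit_rate = hit_rate, fa_rate = fa_rate, dprime = dprime)
}

#' Template-based pattern classification of a unit's responses
#'
#' For each Go depth (against the shared unmodulated Nogo class), each
#' iteration builds Go and Nogo templates by averaging a random half of each
#' class and classifies the held-out trials by which template they resemble
#' more under the configured metric: spike count (FR), van Rossum distance to
#' the averaged filtered template, Rcorr similarity, or nearest K-means
#' centroid of the filtered-train vectors. Hits (Go classified Go) and false
#' alarms (Nogo classified Go) are pooled over iterations and converted to
#' d-prime with the standard 0.05/0.95 clamp.
#'
#' @param unit an `am_unit`.
#' @param config a [classifier_config()].
#' @param go_depth single Go depth (dB) or NULL for all tested depths.
#' @param tau_s kernel time constant; defaults to the first grid value (use
#'   [optimize_tau()] to search the grid).
#' @return object of class `classifier_result`: data.frame `by_depth`
#'   (depth_db, hit_rate, fa_rate, dprime), `metric`, `tau_s`,
#'   `n_iterations`, plus unit metadata.
#' @export
classify_template <- function(unit, config, go_depth = NULL,
                              tau_s = config$tau_s[1]) {
  stopifnot(inherits(config, "classifier_config"))
  tr <- unit$trials
  depths <- sort(unique(tr$depth_db[tr$type == "go"]))
  if (!is.null(go_depth)) {
    stopifnot(go_depth %in% depths)
    depths <- go_depth
  }
  with_seed(config$seed, {
    rows <- lapply(depths, function(d) {
      cl <- classifier_trains(unit, d, config$window)
      res <- classify_one_depth(cl$go, cl$nogo, config, tau_s)
      data.frame(depth_db = d, hit_rate = res$hit_rate,
                 fa_rate = res$fa_rate, dprime = res$dprime)
    })
    structure(list(by_depth = do.call(rbind, rows), metric = config$metric,
                   tau_s = tau_s, n_iterations = config$n_iterations,
                   unit_id = unit$unit_id, rate_hz = unit$rate_hz,
                   group = unit$group),
              class = "classifier_result")
  })
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("Pattern classifier (%s, tau = %g ms) for %s at %g Hz:\n",
              x$metric, 1000 * x$tau_s, x$unit_id, x$rate_hz))
  print(transform(x$by_depth, dprime = round(dprime, 3)))
  invisible(x)
}

#' Optimize the classifier decay constant over the tau grid
#'
#' Runs [classify_template()] at every tau of the configured grid (2-512 ms
#' by default) and returns the tau maximizing d-prime at the requested depth;
#' ties break toward the smallest tau.
#'
#' @inheritParams classify_template
#' @param go_depth single Go depth (dB) at which d-prime is optimized.
#' @return list with `tau_s`, `result` (the winning `classifier_result`) and
#'   `grid` (data.frame tau_s/dprime).
#' @export
optimize_tau <- function(unit, config, go_depth) {
  if (length(config$tau_s) == 0) stop("empty tau grid")
  if (config$metric == "fr")
    stop("the FR metric does not depend on tau")
  res <- lapply(seq_along(config$tau_s), function(i) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, i)
    classify_template(unit, cfg, go_depth = go_depth, tau_s = config$tau_s[i])
  })
  dp <- vapply(res, function(r) r$by_depth$dprime[1], numeric(1))
  best <- which.max(dp + 1e-12 * rev(seq_along(dp)))  # ties -> smallest tau
  list(tau_s = config$tau_s[best], result = res[[best]],
       grid = data.frame(tau_s = config$tau_s, dprime = dp))
}
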