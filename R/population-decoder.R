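#' Build a pseudo-population tensor of binned spike counts
#'
#' Bins every unit's spike trains into half-open 1 ms bins (a spike exactly on
#' a bin edge lands in the later bin's interval) over a window relative to AM
#' onset, keyed by stimulus class ("nogo" or the Go depth in dB). Because the
#' units were recorded in different sessions, population "trials" are
#' pseudo-trials: trial indices are paired across units at random within each
#' stimulus class, re-randomized on every decoder iteration.
#'
#' Each unit's counts are normalized by z-scoring against the unit's own
#' mean/SD pooled over all its trials and bins, then taking absolute values
#' (per-bin z-scoring is available as an option), yielding a homogeneous
#' population. By default only units with a defined FR-based neurometric
#' threshold enter the tensor.
#'
#' @param units list of `am_unit` objects (single modulation rate).
#' @param rate_hz the modulation rate to select.
#' @param window analysis window in seconds relative to AM onset.
#' @param bin_width_ms bin width (default 1 ms).
#' @param require_threshold if TRUE (default) drop units without a defined
#'   FR-based threshold.
#' @param normalization "pooled" (default) or "per_bin".
#' @return object of class `pop_tensor`: per-unit raw and normalized binned
#'   count matrices by class, class trial counts, unit metadata (including
#'   monotonic class), bin grid.
#' @export
build_population_tensor <- function(units, rate_hz, window = c(0, 0.4),
                                    bin_width_ms = 1,
                                    require_threshold = TRUE,
                                    normalization = c("pooled", "per_bin")) {
  normalization <- match.arg(normalization)
  units <- Filter(function(u) u$rate_hz == rate_hz, units)
  if (length(units) == 0) stop("no units at ", rate_hz, " Hz")
  breaks <- seq(window[1], window[2], by = bin_width_ms / 1000)
  n_bin <- length(breaks) - 1
  keep <- list(); meta <- list()
  for (u in units) {
    nf <- tryCatch(best_window_dprime(u), error = function(e) NULL)
    thr <- if (is.null(nf)) list(threshold_db = NA_real_, flag = "undefined")
           else neurometric_threshold(nf$depth_db, nf$dprime)
    if (require_threshold && thr$flag == "undefined") next
    mi <- if (is.null(nf)) list(mi = NA_real_, class = NA_character_)
          else tryCatch(monotonicity_index(nf$depth_db, nf$fr),
                        error = function(e) list(mi = NA_real_,
                                                 class = NA_character_))
    cls <- ifelse(u$trials$type == "nogo", "nogo",
                  as.character(u$trials$depth_db))
    binned <- t(vapply(u$spikes, function(s) {
      h <- s[s >= window[1] & s < window[2]]
      tabulate(findInterval(h, breaks, left.open = FALSE), nbins = n_bin)
    }, integer(n_bin)))
    mu <- mean(binned); sdv <- sd(as.numeric(binned))
    if (normalization == "pooled") {
      if (is.na(sdv) || sdv == 0) next  # zero-variance unit: flagged out
      norm <- abs((binned - mu) / sdv)
    } else {
      mus <- colMeans(binned); sds <- apply(binned, 2, sd)
      sds[sds == 0] <- 1
      norm <- abs(sweep(sweep(binned, 2, mus), 2, sds, "/"))
    }
    keep[[u$unit_id]] <- list(
      raw = lapply(split(seq_len(nrow(binned)), cls),
                   function(i) binned[i, , drop = FALSE]),
      norm = lapply(split(seq_len(nrow(binned)), cls),
                    function(i) norm[i, , drop = FALSE]))
    meta[[u$unit_id]] <- data.frame(
      unit_id = u$unit_id, animal_id = u$animal_id, group = u$group,
      threshold_db = thr$threshold_db,
      monotonic_class = if (is.na(mi$mi)) NA_character_ else mi$class)
  }
  if (length(keep) == 0) stop("no units passed the tensor inclusion filter")
  classes <- Reduce(intersect, lapply(keep, function(k) names(k$raw)))
  structure(list(units = keep, meta = do.call(rbind, meta),
                 classes = classes, rate_hz = rate_hz, window = window,
                 bin_width_ms = bin_width_ms, n_bin = n_bin,
                 normalization = normalization),
            class = "pop_tensor")
}

#' @export
print.pop_tensor <- function(x, ...) {
  cat(sprintf(
    "Population tensor: %d units at %g Hz, %d x %g ms bins, classes: %s\n",
    length(x$units), x$rate_hz, x$n_bin, x$bin_width_ms,
    paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Decoder configuration
#'
#' @param n_iterations resampling iterations (250 with real data; tests scale
#'   this down).
#' @param cost SVM cost parameter C (default 1).
#' @param train_frac fraction of pseudo-trials used for training (0.8).
#' @param seed RNG seed.
#' @return object of class `decoder_config`.
#' @export
decoder_config <- function(n_iterations = 250, cost = 1, train_frac = 0.8,
                           seed = 1L) {
  stopifnot(n_iterations >= 1, cost > 0, train_frac > 0, train_frac < 1)
  structure(list(n_iterations = as.integer(n_iterations), cost = cost,
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "decoder_config")
}

# One pseudo-population draw: pair trials across units within each of the two
# classes (equalized trial counts), average normalized counts across units.
# Returns features (2T x n_bin) and labels.
pair_pseudo_trials <- function(tensor, go_class, unit_ids) {
  un <- tensor$units[unit_ids]
  t_per <- vapply(c(go_class, "nogo"), function(cl)
    min(vapply(un, function(u) nrow(u$norm[[cl]]), integer(1))), integer(1))
  T <- min(t_per)  # class counts equalized by subsampling
  feats <- vector("list", 2)
  for (ci in 1:2) {
    cl <- c(go_class, "nogo")[ci]
    acc <- matrix(0, T, tensor$n_bin)
    for (u in un) {
      idx <- sample(nrow(u$norm[[cl]]), T)
      acc <- acc + u$norm[[cl]][idx, , drop = FALSE]
    }
    feats[[ci]] <- acc / length(un)
  }
  list(x = rbind(feats[[1]], feats[[2]]),
       y = rep(c("go", "nogo"), each = T))
}

# One decoder iteration. Each unit's trials are split 80/20 *before*
# pseudo-trial pairing, so training and held-out pseudo-trials are built from
# disjoint unit-trials: pairing first and splitting afterwards would leave
# the two sides sharing a fixed per-class sum (every unit's trial set is
# exhausted by the pairing), anti-correlating train and test means. The split
# is per class, so degenerate single-class splits cannot arise.
decode_iteration <- function(tensor, go_class, unit_ids, config) {
  un <- tensor$units[unit_ids]
  classes <- c(go_class, "nogo")
  T <- min(vapply(classes, function(cl)
    min(vapply(un, function(u) nrow(u$norm[[cl]]), integer(1))), integer(1)))
  n_tr <- min(max(1, round(config$train_frac * T)), T - 1)
  xtr <- vector("list", 2); xte <- vector("list", 2)
  for (ci in 1:2) {
    cl <- classes[ci]
    acc_tr <- matrix(0, n_tr, tensor$n_bin)
    acc_te <- matrix(0, T - n_tr, tensor$n_bin)
    for (u in un) {
      idx <- sample(nrow(u$norm[[cl]]), T)
      acc_tr <- acc_tr + u$norm[[cl]][idx[seq_len(n_tr)], , drop = FALSE]
      acc_te <- acc_te + u$norm[[cl]][idx[(n_tr + 1):T], , drop = FALSE]
    }
    xtr[[ci]] <- acc_tr / length(un)
    xte[[ci]] <- acc_te / length(un)
  }
  ytr <- rep(c("go", "nogo"), each = n_tr)
  yte <- rep(c("go", "nogo"), each = T - n_tr)
  fit <- svm_linear(rbind(xtr[[1]], xtr[[2]]), ytr, cost = config$cost)
  pred <- predict(fit, rbind(xte[[1]], xte[[2]]))
  hit <- mean(pred[yte == "go"] == "go")
  fa <- mean(pred[yte == "nogo"] == "go")
  c(dprime = compute_dprime(hit, fa), hit = hit, fa = fa, redraws = 0)
}

#' Linear population decoding of Go versus Nogo
#'
#' Per iteration: re-pair pseudo-trials across units, split 80/20, fit the
#' cost-1 linear maximum-margin classifier on the training split, classify
#' the held-out 20%, and convert hit/false-alarm proportions to d-prime with
#' the 0.05/0.95 clamp. Reports mean and SD of d-prime over iterations.
#'
#' @param tensor a [build_population_tensor()] result.
#' @param go_depth Go depth in dB (a class of the tensor).
#' @param config a [decoder_config()].
#' @param unit_ids optional subset of units (default all).
#' @return object of class `decoder_result`: `dprime_mean`, `dprime_sd`,
#'   `hit_rate`, `fa_rate`, `n_units`, `n_iterations`, `go_depth`, `rate_hz`,
#'   `n_redraws`.
#' @export
decode <- function(tensor, go_depth, config = decoder_config(),
                   unit_ids = names(tensor$units)) {
  go_class <- as.character(go_depth)
  if (!go_class %in% tensor$classes)
    stop("tensor has no class at depth ", go_depth, " dB")
  stopifnot(length(unit_ids) >= 1)
  with_seed(config$seed, {
    it <- t(vapply(seq_len(config$n_iterations), function(i)
      decode_iteration(tensor, go_class, unit_ids, config), numeric(4)))
    structure(list(dprime_mean = mean(it[, "dprime"]),
                   dprime_sd = sd(it[, "dprime"]),
                   hit_rate = mean(it[, "hit"]), fa_rate = mean(it[, "fa"]),
                   n_units = length(unit_ids),
                   n_iterations = config$n_iterations,
                   go_depth = go_depth, rate_hz = tensor$rate_hz,
                   n_redraws = sum(it[, "redraws"])),
              class = "decoder_result")
  })
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf(
    "Population decoder: %g Hz, Go %g dB vs Nogo, %d units: d' = %.2f +/- %.2f (%d iterations)\n",
    x$rate_hz, x$go_depth, x$n_units, x$dprime_mean, x$dprime_sd,
    x$n_iterations))
  invisible(x)
}

#' Decoder performance as a function of unit count
#'
#' For each fraction of the unit pool (10-100% by default), every iteration
#' draws that many units without replacement, runs one decoder iteration, and
#' the mean and SD of d-prime over iterations are reported per fraction.
#'
#' @inheritParams decode
#' @param fractions unit-pool fractions to test.
#' @return data.frame: fraction, n_units, dprime_mean, dprime_sd.
#' @export
unit_count_curve <- function(tensor, go_depth, fractions = seq(0.1, 1, 0.1),
                             config = decoder_config()) {
  ids <- names(tensor$units)
  n_units <- vapply(fractions, function(f)
    as.integer(round(f * length(ids))), integer(1))
  if (any(n_units < 1)) stop("a fraction yields < 1 unit")
  go_class <- as.character(go_depth)
  with_seed(config$seed, {
    rows <- lapply(seq_along(fractions), function(k) {
      dp <- vapply(seq_len(config$n_iterations), function(i) {
        sub <- sample(ids, n_units[k])
        decode_iteration(tensor, go_class, sub, config)[["dprime"]]
      }, numeric(1))
      data.frame(fraction = fractions[k], n_units = n_units[k],
                 dprime_mean = mean(dp), dprime_sd = sd(dp))
    })
    do.call(rbind, rows)
  })
}

#' Decoding from one monotonic subpopulation
#'
#' Draws an equal number of units (default 10) of the requested monotonic
#' class (increasing or decreasing) on every iteration before the decoding
#' readout, to compare the contribution of the two depth-tuning classes.
#'
#' @inheritParams decode
#' @param class "increasing" or "decreasing".
#' @param n units drawn per iteration (default 10).
#' @return a `decoder_result` (with `monotonic_class` and `n` fields).
#' @export
mi_subpopulation_decode <- function(tensor, go_depth,
                                    class = c("increasing", "decreasing"),
                                    n = 10, config = decoder_config()) {
  class <- match.arg(class)
  ids <- tensor$meta$unit_id[!is.na(tensor$meta$monotonic_class) &
                               tensor$meta$monotonic_class == class]
  if (length(ids) < n)
    stop("only ", length(ids), " ", class, " units available, need ", n)
  go_class <- as.character(go_depth)
  with_seed(config$seed, {
    dp <- vapply(seq_len(config$n_iterations), function(i) {
      sub <- sample(ids, n)
      decode_iteration(tensor, go_class, sub, config)[["dprime"]]
    }, numeric(1))
    structure(list(dprime_mean = mean(dp), dprime_sd = sd(dp),
                   hit_rate = NA_real_, fa_rate = NA_real_, n_units = n,
                   n_iterations = config$n_iterations, go_depth = go_depth,
                   rate_hz = tensor$rate_hz, n_redraws = NA_real_,
                   monotonic_class = class),
              class = "decoder_result")
  })
}

#' Across-bin variability of the population-summed response
#'
#' For each pseudo-trial, spike counts are summed across units separately in
#' each bin; the trial's CV is the SD across bins divided by the mean across
#' bins of that population-summed count. Raw (un-normalized) counts are used.
#' Trials with zero mean are flagged and skipped.
#'
#' @param tensor a [build_population_tensor()] result.
#' @param classes stimulus classes to include (default all).
#' @param seed seed for the pseudo-trial pairing.
#' @return data.frame: class, trial, cv; attribute `n_skipped` counts
#'   zero-mean trials.
#' @export
population_cv <- function(tensor, classes = tensor$classes, seed = 1L) {
  with_seed(seed, {
    out <- list(); skipped <- 0
    for (cl in classes) {
      T <- min(vapply(tensor$units, function(u) nrow(u$raw[[cl]]),
                      integer(1)))
      acc <- matrix(0, T, tensor$n_bin)
      for (u in tensor$units) {
        idx <- sample(nrow(u$raw[[cl]]), T)
        acc <- acc + u$raw[[cl]][idx, , drop = FALSE]
      }
      mu <- rowMeans(acc)
      cv <- apply(acc, 1, sd) / mu
      zero <- mu == 0
      skipped <- skipped + sum(zero)
      out[[cl]] <- data.frame(class = cl, trial = which(!zero),
                              cv = cv[!zero])
    }
    structure(do.call(rbind, c(out, make.row.names = FALSE)),
              n_skipped = skipped)
  })
}
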