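#' Read a pipeline configuration from JSON
#'
#' The JSON may contain any [cohort_config()] argument (under `cohort`) plus
#' an `analysis` block: `decoder_iterations`, `classifier_iterations`,
#' `classifier_metric`, `run_classifier` (the per-unit pattern classifier is
#' expensive and off by default), `abr_k_sd`, and `stages` (subset of
#' "behavior", "units", "decode", "efr", "stats").
#'
#' @param path JSON file path.
#' @param seed optional master-seed override.
#' @return list with `cohort` (a `cohort_config`) and `analysis` settings.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- if (is.null(path)) list() else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_args <- raw$cohort %||% list()
  if (!is.null(seed)) cohort_args$seed <- seed
  if (!is.null(cohort_args$psych))
    cohort_args$psych <- as.data.frame(cohort_args$psych)
  ana <- raw$analysis %||% list()
  defaults <- list(decoder_iterations = 50, classifier_iterations = 50,
                   classifier_metric = "kmeans", run_classifier = FALSE,
                   # 5 baseline SDs: the peak statistic is a max over ~250
                   # samples, so 3 SDs would fire on noise alone
                   abr_k_sd = 5,
                   stages = c("behavior", "units", "decode", "efr", "stats"))
  for (nm in names(defaults))
    if (is.null(ana[[nm]])) ana[[nm]] <- defaults[[nm]]
  list(cohort = do.call(cohort_config, cohort_args), analysis = ana)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Behavioral stage: filter sessions, fit psychometrics, per-animal TMTFs.
stage_behavior <- function(cohort) {
  filt <- filter_sessions(cohort$sessions)
  fits <- lapply(filt$included, function(s) tryCatch(fit_psychometric(s),
                                                     error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  per_session <- do.call(rbind, lapply(fits, function(f)
    data.frame(animal_id = f$animal_id, group = f$group, rate_hz = f$rate_hz,
               threshold_db = f$threshold_db, threshold_flag = f$threshold_flag,
               location = f$par[1], scale = f$par[2], guess = f$par[3],
               lapse = f$par[4], fa_rate = f$fa_rate,
               max_dprime = f$dprime(0))))
  rownames(per_session) <- NULL
  ok <- per_session[per_session$threshold_flag != "undefined", ]
  agg <- stats::aggregate(threshold_db ~ animal_id + group + rate_hz,
                          data = ok, FUN = mean)
  tmtf <- do.call(rbind, lapply(split(agg, agg$animal_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    ft <- fit_tmtf(d$rate_hz, d$threshold_db)
    data.frame(animal_id = d$animal_id[1], group = d$group[1],
               A = ft$A, b = ft$b)
  }))
  if (!is.null(tmtf)) rownames(tmtf) <- NULL
  list(fits = fits, per_session = per_session, per_animal = agg,
       tmtf = tmtf, excluded = filt$excluded)
}

# Unit stage: tidy per-unit neurometric table.
stage_units <- function(cohort) unit_metrics_table(cohort$units)

# Optional per-unit pattern-classifier stage (scaled by iteration count).
stage_classify <- function(cohort, metric, n_iterations, seed) {
  rows <- lapply(cohort$units, function(u) {
    cfg <- classifier_config(metric = metric, n_iterations = n_iterations,
                             seed = child_seed(seed, u$seed))
    res <- tryCatch(classify_template(u, cfg, tau_s = 0.008),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    thr <- neurometric_threshold(res$by_depth$depth_db, res$by_depth$dprime)
    data.frame(unit_id = u$unit_id, group = u$group, rate_hz = u$rate_hz,
               metric = metric, threshold_db = thr$threshold_db,
               threshold_flag = thr$flag)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (!is.null(out)) rownames(out) <- NULL
  out
}

# Decoder stage: per (group, rate, depth) population d-prime + threshold.
stage_decode <- function(cohort, n_iterations, seed) {
  rows <- list(); thr_rows <- list()
  for (group in c("Ctl", "HL")) {
    for (rate in cohort$config$rates_hz) {
      units <- Filter(function(u) u$group == group && u$rate_hz == rate,
                      cohort$units)
      tensor <- tryCatch(build_population_tensor(units, rate),
                         error = function(e) NULL)
      if (is.null(tensor)) next
      depths <- sort(as.numeric(setdiff(tensor$classes, "nogo")))
      dp <- vapply(depths, function(d) {
        cfg <- decoder_config(n_iterations = n_iterations,
                              seed = child_seed(seed, round(rate + d * 100) +
                                                  (group == "HL") * 7))
        r <- decode(tensor, d, cfg)
        rows[[length(rows) + 1]] <<- data.frame(
          group = group, rate_hz = rate, depth_db = d,
          dprime_mean = r$dprime_mean, dprime_sd = r$dprime_sd,
          n_units = r$n_units)
        r$dprime_mean
      }, numeric(1))
      thr <- neurometric_threshold(depths, dp)
      thr_rows[[length(thr_rows) + 1]] <- data.frame(
        group = group, rate_hz = rate, threshold_db = thr$threshold_db,
        threshold_flag = thr$flag)
    }
  }
  list(by_depth = do.call(rbind, rows), thresholds = do.call(rbind, thr_rows))
}

# EFR/ABR stage: per-animal EFR thresholds by rate + ABR metrics.
stage_efr <- function(cohort, k_sd) {
  efr_rows <- list()
  key <- vapply(cohort$efr, function(r)
    paste(r$animal_id, r$rate_hz, sep = "|"), character(1))
  for (grp in split(cohort$efr, key)) {
    thr <- tryCatch(efr_threshold(grp), error = function(e) NULL)
    if (is.null(thr)) next
    efr_rows[[length(efr_rows) + 1]] <- data.frame(
      animal_id = grp[[1]]$animal_id, group = grp[[1]]$group,
      rate_hz = grp[[1]]$rate_hz, threshold_db = thr$threshold_db,
      threshold_db_raw = thr$threshold_db_raw, noise_floor = thr$noise_floor)
  }
  efr_tab <- do.call(rbind, efr_rows)
  abr_tab <- do.call(rbind, lapply(cohort$abr, function(a) {
    m <- abr_metrics(a, k_sd = k_sd)
    data.frame(animal_id = a$animal_id, group = a$group,
               threshold_db_spl = m$threshold_db_spl)
  }))
  rownames(abr_tab) <- NULL
  list(efr = efr_tab, abr = abr_tab)
}

# Group-statistics stage: bootstrap Ctl-vs-HL contrasts on unit metrics.
stage_stats <- function(unit_tab, seed, n_boot = 2000) {
  metrics <- c("max_fr" = "max_dprime", "spont_hz" = "spont_hz", "cv" = "cv")
  comps <- list(
    spont = bootstrap_group_diff(unit_tab$spont_hz, unit_tab$animal_id,
                                 unit_tab$group, n_boot = n_boot,
                                 seed = child_seed(seed, 101)),
    cv = bootstrap_group_diff(unit_tab$cv, unit_tab$animal_id,
                              unit_tab$group, n_boot = n_boot,
                              seed = child_seed(seed, 102)))
  comps
}

#' Run the full cohort pipeline
#'
#' Generates a synthetic cohort from the configuration and executes the
#' analysis stages in dependency order: session filtering and psychometric
#' fits with per-animal TMTFs; per-unit neurometrics; the population decoder
#' with per-depth d-prime and interpolated thresholds; EFR depth thresholds
#' and ABR click thresholds; and bootstrap group contrasts. The combined
#' summary table juxtaposes behavioral, EFR, and decoder thresholds per
#' group and rate (the study's closing comparison).
#'
#' @param config either a path to a JSON pipeline configuration, a
#'   `cohort_config`, or `NULL` for defaults.
#' @param out_dir optional directory; when given, every stage table is
#'   written as TSV and the manifest (with checksums) as JSON.
#' @param seed optional master-seed override.
#' @return object of class `am_run`: stage outputs, `summary` table, and
#'   `manifest`.
#' @export
run_cohort <- function(config = NULL, out_dir = NULL, seed = NULL) {
  if (inherits(config, "cohort_config")) {
    cfg <- list(cohort = config,
                analysis = read_pipeline_config(NULL)$analysis)
    if (!is.null(seed)) {
      args <- unclass(config); args$seed <- seed
      cfg$cohort <- do.call(cohort_config, args)
    }
  } else {
    cfg <- read_pipeline_config(config, seed = seed)
  }
  ana <- cfg$analysis
  master <- cfg$cohort$seed
  t0 <- Sys.time()
  log_line <- function(stage)
    message(sprintf("[%s] stage=%s seed=%d elapsed=%.1fs",
                    format(Sys.time(), "%H:%M:%S"), stage, master,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  cohort <- generate_cohort(cfg$cohort); log_line("generate")
  out <- list(config = cfg, cohort_manifest = cohort$manifest)
  if ("behavior" %in% ana$stages) {
    out$behavior <- stage_behavior(cohort); log_line("behavior")
  }
  if ("units" %in% ana$stages) {
    out$units <- stage_units(cohort); log_line("units")
  }
  if (isTRUE(ana$run_classifier)) {
    out$classifier <- stage_classify(cohort, ana$classifier_metric,
                                     ana$classifier_iterations, master)
    log_line("classify")
  }
  if ("decode" %in% ana$stages) {
    out$decode <- stage_decode(cohort, ana$decoder_iterations, master)
    log_line("decode")
  }
  if ("efr" %in% ana$stages) {
    out$efr <- stage_efr(cohort, ana$abr_k_sd); log_line("efr")
  }
  if ("stats" %in% ana$stages && !is.null(out$units)) {
    out$stats <- stage_stats(out$units, master); log_line("stats")
  }
  out$summary <- pipeline_summary(out)
  out$manifest <- list(seed = master,
                       generated = nrow(cohort$manifest),
                       stages = ana$stages,
                       artifacts = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name) {
      if (is.null(tab)) return(NULL)
      p <- file.path(out_dir, paste0(name, ".tsv"))
      write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
      p
    }
    paths <- c(wr(out$behavior$per_session, "psychometrics_sessions"),
               wr(out$behavior$per_animal, "psychometrics_thresholds"),
               wr(out$behavior$tmtf, "behavior_tmtf"),
               wr(out$units, "unit_metrics"),
               wr(out$classifier, "classifier_thresholds"),
               wr(out$decode$by_depth, "decoder_dprime"),
               wr(out$decode$thresholds, "decoder_thresholds"),
               wr(out$efr$efr, "efr_thresholds"),
               wr(out$efr$abr, "abr_thresholds"),
               wr(out$summary, "summary_triptych"))
    if (!is.null(out$stats))
      write_comparisons_json(out$stats,
                             file.path(out_dir, "group_comparisons.json"))
    out$manifest$artifacts <- data.frame(
      path = basename(paths),
      md5 = unname(tools::md5sum(paths)))
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(out, class = "am_run")
}

# Combined summary: behavioral / EFR / decoder threshold per group and rate.
pipeline_summary <- function(out) {
  beh <- if (!is.null(out$behavior))
    stats::aggregate(threshold_db ~ group + rate_hz,
                     data = out$behavior$per_animal, FUN = mean)
  efr <- if (!is.null(out$efr))
    stats::aggregate(threshold_db ~ group + rate_hz, data = out$efr$efr,
                     FUN = function(x) mean(x, na.rm = TRUE))
  dec <- out$decode$thresholds
  tab <- NULL
  if (!is.null(beh)) {
    names(beh)[3] <- "behavior_db"; tab <- beh
  }
  if (!is.null(efr)) {
    names(efr)[3] <- "efr_db"
    tab <- if (is.null(tab)) efr else merge(tab, efr, all = TRUE)
  }
  if (!is.null(dec)) {
    dec <- dec[, c("group", "rate_hz", "threshold_db")]
    names(dec)[3] <- "decoder_db"
    tab <- if (is.null(tab)) dec else merge(tab, dec, all = TRUE)
  }
  tab
}

#' @export
print.am_run <- function(x, ...) {
  cat("AM detection pipeline run (seed", x$manifest$seed, ")\n")
  if (!is.null(x$summary)) {
    cat("Summary thresholds (dB re 100%):\n")
    print(x$summary, digits = 3)
  }
  invisible(x)
}
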