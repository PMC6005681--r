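#' Signal-detection d-prime with floor/ceiling clamping
#'
#' `d' = z(hit) - z(fa)` after clamping both rates to \[0.05, 0.95\], so the
#' maximum attainable d-prime is `2 * qnorm(0.95) = 3.2897` and perfect
#' performance never yields an infinite value. The same transform is applied
#' to behavioral, classifier and decoder hit/false-alarm proportions so all
#' d-prime scales share one ceiling.
#'
#' @param hit_rate,fa_rate proportions in \[0, 1\] (vectorized).
#' @return d-prime value(s).
#' @examples
#' compute_dprime(0.95, 0.05)  # 3.2897
#' compute_dprime(1, 0)        # identical: the clamp
#' @export
compute_dprime <- function(hit_rate, fa_rate) {
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1, na.rm = TRUE))
    stop("hit and false-alarm rates must lie in [0, 1]")
  qnorm(pmin(pmax(hit_rate, 0.05), 0.95)) -
    qnorm(pmin(pmax(fa_rate, 0.05), 0.95))
}

#' Maximum d-prime attainable under the 0.05/0.95 clamp
#' @return `2 * qnorm(0.95)`, about 3.2897.
#' @export
dprime_ceiling <- function() 2 * qnorm(0.95)

#' Session inclusion filter for psychometric analysis
#'
#' Keeps sessions with a false-alarm rate strictly below 30%, at least 20
#' trials at every Go depth, and more than 100 Go trials in total. Dropped
#' sessions are returned with the reason for exclusion.
#'
#' @param sessions list of `am_session` objects.
#' @param fa_max false-alarm criterion (default 0.30, exclusive).
#' @param min_per_depth minimum Go trials per depth (default 20).
#' @param min_go_total minimum total Go trials, exclusive (default 100).
#' @return list with `included` (list of sessions) and `excluded`
#'   (data.frame of session index/id and reason).
#' @export
filter_sessions <- function(sessions, fa_max = 0.30, min_per_depth = 20,
                            min_go_total = 100) {
  if (length(sessions) == 0) stop("no sessions supplied")
  if (inherits(sessions, "am_session")) sessions <- list(sessions)
  reasons <- character(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ht <- session_hit_table(s)
    if (!is.na(session_fa_rate(s)) && session_fa_rate(s) >= fa_max)
      reasons[i] <- "false-alarm"
    else if (any(ht$n_go < min_per_depth) || sum(ht$n_go) <= min_go_total)
      reasons[i] <- "go-trials"
  }
  ids <- vapply(seq_along(sessions), function(i) {
    id <- sessions[[i]]$session_id
    if (is.null(id)) sprintf("session-%d", i) else id
  }, character(1))
  list(included = sessions[reasons == ""],
       excluded = data.frame(id = ids[reasons != ""],
                             reason = reasons[reasons != ""]))
}

# Negative penalized log-likelihood of the 4-parameter cumulative-Gaussian
# psychometric model. Go trials are binomial per depth; Nogo trials enter as
# binomial with p = guess, anchoring the guess parameter to the session's
# false-alarm rate. A light Beta(1.2, 12) penalty on guess/0.5 and lapse/0.5
# keeps both in [0, 0.5] without dominating the data.
psych_negll <- function(par, ht, n_nogo, n_fa) {
  mu <- par[1]; sigma <- par[2]; guess <- par[3]; lapse <- par[4]
  p <- psych_truth_p(ht$depth_db, mu, sigma, guess, lapse)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  g <- min(max(guess, 1e-9), 1 - 1e-9)
  ll <- sum(ht$n_hit * log(p) + (ht$n_go - ht$n_hit) * log(1 - p)) +
    n_fa * log(g) + (n_nogo - n_fa) * log(1 - g)
  pen <- dbeta(min(guess / 0.5, 1 - 1e-9), 1.2, 12, log = TRUE) +
    dbeta(min(lapse / 0.5, 1 - 1e-9), 1.2, 12, log = TRUE)
  -(ll + 0.5 * pen)
}

#' Fit a cumulative-Gaussian psychometric function to a session
#'
#' Penalized maximum-likelihood fit of hit proportion versus Go depth (dB re
#' 100%) with four parameters: location, scale, guess and lapse (each of the
#' latter two restricted to \[0, 0.5\]). The fitted proportion curve and the
#' session's false-alarm rate are transformed through [compute_dprime()] into
#' a d-prime-versus-depth function, from which the detection threshold
#' (d' = 1) is read.
#'
#' This is a point-estimate substitute for the Bayesian fitting used with the
#' original data (psignifit); the contract here is the fitted curve and its
#' threshold, not a posterior.
#'
#' @param session an `am_session` (should have passed [filter_sessions()]).
#' @return object of class `psychometric_fit`: `par` (location, scale, guess,
#'   lapse), `hit_table`, `fa_rate`, `dprime` function of depth, `threshold_db`,
#'   `threshold_flag` ("ok", "ceiling" = below lowest tested depth,
#'   "undefined"), `converged`, `session_id`, plus `rate_hz`, `animal_id`,
#'   `group` copied from the session.
#' @export
fit_psychometric <- function(session) {
  ht <- session_hit_table(session)
  if (nrow(ht) < 3)
    stop("psychometric fit needs at least 3 distinct Go depths, got ",
         nrow(ht))
  nogo <- session$trials[session$trials$type == "nogo", ]
  n_nogo <- nrow(nogo); n_fa <- sum(nogo$outcome == "fa")
  fa_rate <- if (n_nogo > 0) n_fa / n_nogo else 0
  span <- diff(range(ht$depth_db))
  start <- c(mu = stats::weighted.mean(ht$depth_db, ht$n_go),
             sigma = max(span / 4, 0.5),
             guess = max(fa_rate, 0.02), lapse = 0.02)
  lower <- c(min(ht$depth_db) - 3 * span, 0.1, 1e-6, 1e-6)
  upper <- c(max(ht$depth_db) + 3 * span, 10 * span, 0.5, 0.5)
  pscale <- c(max(span / 4, 1), 1, 0.1, 0.1)
  opt <- optim(start, psych_negll, ht = ht, n_nogo = n_nogo, n_fa = n_fa,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500, parscale = pscale))
  if (opt$convergence != 0) {
    # restart from the returned point with a softened line search
    start2 <- pmin(pmax(opt$par * c(1, 1.05, 1, 1) + c(0.1, 0, 0, 0), lower),
                   upper)
    opt2 <- optim(start2, psych_negll, ht = ht, n_nogo = n_nogo, n_fa = n_fa,
                  method = "L-BFGS-B", lower = lower, upper = upper,
                  control = list(maxit = 1000, factr = 1e9,
                                 parscale = pscale))
    if (opt2$value <= opt$value) opt <- opt2
  }
  if (opt$convergence != 0)
    warning("psychometric fit did not converge (code ", opt$convergence,
            "): ", opt$message)
  par <- setNames(opt$par, c("location", "scale", "guess", "lapse"))
  dp <- function(depth_db)
    compute_dprime(psych_truth_p(depth_db, par[1], par[2], par[3], par[4]),
                   fa_rate)
  fit <- structure(list(par = par, hit_table = ht, fa_rate = fa_rate,
                        dprime = dp, converged = opt$convergence == 0,
                        negll = opt$value,
                        session_id = session$session_id,
                        animal_id = session$animal_id, group = session$group,
                        rate_hz = session$rate_hz),
                   class = "psychometric_fit")
  thr <- extract_threshold(fit)
  fit$threshold_db <- thr$threshold_db
  fit$threshold_flag <- thr$flag
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit (%s, %g Hz): location %.2f dB, scale %.2f, guess %.3f, lapse %.3f\n",
    x$animal_id, x$rate_hz, x$par[1], x$par[2], x$par[3], x$par[4]))
  cat(sprintf("  threshold (d'=1): %s  [%s]\n",
              if (is.na(x$threshold_db)) "undefined"
              else sprintf("%.2f dB re 100%%", x$threshold_db),
              x$threshold_flag))
  invisible(x)
}

#' Detection threshold at d' = 1 from a fitted psychometric function
#'
#' Solves `dprime(depth) = 1` on the fitted curve over the tested depth
#' range. If the fitted d-prime exceeds 1 everywhere the threshold is flagged
#' `"ceiling"` (below the lowest tested depth) and reported as the lowest
#' tested depth; if it never reaches 1 the threshold is `NA` with flag
#' `"undefined"`.
#'
#' @param fit a `psychometric_fit`.
#' @return list with `threshold_db` and `flag` ("ok"/"ceiling"/"undefined").
#' @export
extract_threshold <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  rng <- range(fit$hit_table$depth_db)
  f <- function(x) fit$dprime(x) - 1
  lo <- f(rng[1]); hi <- f(rng[2])
  if (lo > 0 && hi > 0)
    return(list(threshold_db = rng[1], flag = "ceiling"))
  if (lo < 0 && hi < 0)
    return(list(threshold_db = NA_real_, flag = "undefined"))
  root <- uniroot(f, lower = rng[1], upper = rng[2], tol = 1e-6)$root
  list(threshold_db = root, flag = "ok")
}

#' Lapse rate of a session
#'
#' Proportion of misses among Go trials at the easiest (highest) depth
#' presented, a proxy for task engagement.
#'
#' @param session an `am_session`.
#' @return proportion in \[0, 1\].
#' @export
lapse_rate <- function(session) {
  ht <- session_hit_table(session)
  if (nrow(ht) == 0) stop("session has no Go trials")
  easiest <- ht[which.max(ht$depth_db), ]
  if (easiest$n_go == 0) stop("no trials at the easiest depth")
  1 - easiest$hit_rate
}

#' Fit the temporal modulation transfer function (TMTF)
#'
#' Least-squares fit of the exponential `y(m) = A * exp(b * m)` to detection
#' thresholds `y` (dB re 100%) across modulation rates `m` (Hz). `A` is the
#' TMTF gain (its y-intercept, overall detection efficiency) and `b` its
#' slope (how fast thresholds deteriorate with rate). Used for behavioral and
#' for EFR-derived thresholds alike.
#'
#' @param rates_hz modulation rates m (>= 2 values).
#' @param thresholds_db thresholds y at those rates.
#' @return object of class `tmtf_fit`: `A`, `b`, `fitted`, `residuals`,
#'   `rates_hz`, `thresholds_db`.
#' @export
fit_tmtf <- function(rates_hz, thresholds_db) {
  ok <- complete.cases(rates_hz, thresholds_db)
  rates_hz <- rates_hz[ok]; thresholds_db <- thresholds_db[ok]
  if (length(unique(rates_hz)) < 2)
    stop("TMTF fit needs thresholds at >= 2 distinct rates")
  if (any(thresholds_db == 0) ||
      length(unique(sign(thresholds_db))) != 1) {
    # mixed/zero signs: no log-linear start; crude two-point start
    A0 <- thresholds_db[which.min(rates_hz)]; b0 <- 0
  } else {
    lf <- lm(log(abs(thresholds_db)) ~ rates_hz)
    A0 <- sign(thresholds_db[1]) * exp(coef(lf)[1]); b0 <- coef(lf)[2]
  }
  est <- c(A = unname(A0), b = unname(b0))
  fit <- tryCatch({
    nl <- nls(thresholds_db ~ A * exp(b * rates_hz),
              start = list(A = est[["A"]], b = est[["b"]]),
              control = list(maxiter = 200, warnOnly = TRUE),
              algorithm = "port")
    coef(nl)
  }, error = function(e) est)
  A <- unname(fit[["A"]]); b <- unname(fit[["b"]])
  fitted <- A * exp(b * rates_hz)
  structure(list(A = A, b = b, fitted = fitted,
                 residuals = thresholds_db - fitted,
                 rates_hz = rates_hz, thresholds_db = thresholds_db),
            class = "tmtf_fit")
}

#' @export
print.tmtf_fit <- function(x, ...) {
  cat(sprintf("TMTF fit over %d rates: gain A = %.3f dB, slope b = %.5f /Hz\n",
              length(x$rates_hz), x$A, x$b))
  invisible(x)
}
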