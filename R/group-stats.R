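#' Hierarchical bootstrap test of a group difference
#'
#' Accounts for unequal unit counts per animal: on each iteration, up to
#' `per_animal` values are sampled without replacement from every animal
#' (animals with fewer values contribute all of them; this is logged), the
#' values are averaged within each hearing-status group, and the group
#' difference (first group minus second) is recorded. The empirical
#' two-tailed confidence interval at `ci_level` (98.75% as printed) is taken
#' from the bootstrap distribution; the difference is significant at p < 0.05
#' when zero falls outside it.
#'
#' @param values numeric vector of the per-unit metric.
#' @param animal factor/vector of animal ids aligned with `values`.
#' @param group factor/vector of group labels (exactly two levels).
#' @param n_boot bootstrap iterations (10,000 with real data).
#' @param per_animal values sampled per animal per iteration (default 30).
#' @param ci_level two-tailed CI level (default 0.9875).
#' @param seed RNG seed.
#' @param keep_distribution keep the full bootstrap distribution.
#' @return object of class `group_comparison`: `mean_diff`, `ci` (low/high),
#'   `significant`, `groups`, `group_means`, `n_boot`, `per_animal`,
#'   `small_animals` (ids with fewer than `per_animal` values), `seed`, and
#'   optionally `distribution`.
#' @export
bootstrap_group_diff <- function(values, animal, group, n_boot = 10000,
                                 per_animal = 30, ci_level = 0.9875,
                                 seed = 1L, keep_distribution = FALSE) {
  ok <- is.finite(values)
  values <- values[ok]; animal <- animal[ok]; group <- group[ok]
  glev <- sort(unique(as.character(group)))
  if (length(glev) != 2) stop("need exactly two groups, got ",
                              paste(glev, collapse = ", "))
  by_animal <- split(values, as.character(animal))
  animal_group <- vapply(split(as.character(group), as.character(animal)),
                         function(g) g[1], character(1))
  if (!all(glev %in% animal_group))
    stop("a group has zero animals with data")
  small <- names(by_animal)[lengths(by_animal) < per_animal]
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      means <- vapply(glev, function(g) {
        ids <- names(animal_group)[animal_group == g]
        mean(unlist(lapply(ids, function(a) {
          v <- by_animal[[a]]
          if (length(v) <= per_animal) v else sample(v, per_animal)
        }), use.names = FALSE))
      }, numeric(1))
      means[1] - means[2]
    }, numeric(1))
  })
  alpha <- 1 - ci_level
  ci <- unname(quantile(diffs, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(list(mean_diff = mean(diffs), ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 groups = glev,
                 group_means = vapply(glev, function(g)
                   mean(values[group == g]), numeric(1)),
                 n_boot = n_boot, per_animal = per_animal,
                 ci_level = ci_level, small_animals = small,
                 seed = as.integer(seed),
                 distribution = if (keep_distribution) diffs else NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Bootstrap group difference (%s - %s): %.3f, %.2f%% CI [%.3f, %.3f], %s\n",
    x$groups[1], x$groups[2], x$mean_diff, 100 * x$ci_level, x$ci[1], x$ci[2],
    if (x$significant) "significant at p < 0.05" else "not significant"))
  if (length(x$small_animals))
    cat("  animals using all values (<", x$per_animal, "):",
        paste(x$small_animals, collapse = ", "), "\n")
  invisible(x)
}

#' Holm-Bonferroni step-down multiple-comparison correction
#'
#' Sorts the p-values ascending and rejects `p_(i)` while
#' `p_(i) < alpha / (m - i + 1)`, stopping at the first failure.
#'
#' @param p_values p-values in \[0, 1\].
#' @param alpha family-wise error rate (default 0.05).
#' @return logical rejection flags in the original order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || any(is.na(p_values)))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[o[i]] < alpha / (m - i + 1)) reject[o[i]] <- TRUE
    else break
  }
  reject
}

#' Convert comparison results to JSON records
#'
#' @param comparisons named list of `group_comparison` objects.
#' @param path output file.
#' @param include_distribution include the full bootstrap draws.
#' @export
write_comparisons_json <- function(comparisons, path,
                                   include_distribution = FALSE) {
  recs <- lapply(comparisons, function(x) {
    r <- x[c("mean_diff", "ci", "significant", "groups", "group_means",
             "n_boot", "per_animal", "ci_level", "small_animals", "seed")]
    if (include_distribution) r$distribution <- x$distribution
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
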