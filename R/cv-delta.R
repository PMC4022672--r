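#' Fit the global CV-shift estimator to a grouped expression dataset
#'
#' The package's central fit. For every probe set the CV of the replicate
#' intensities is computed in each group and contrasted as
#' `dlog_cv = log10(CV_KO) - log10(CV_WT)`; the arithmetic mean of `dlog_cv`
#' across probe sets estimates the log of the geometric-mean CV fold-change
#' (knockout over wild-type), tested against zero with a one-sample
#' two-tailed t-test whose p-value is computed in log space
#' ([one_sample_test_logp()]). Probes whose mean expression in either group
#' falls below the dataset-wide median are filtered out by default
#' ([median_filter_mask()]).
#'
#' Alongside the primary result two robustness variants are always computed:
#' the arithmetic-difference statistic (`dcv = CV_KO - CV_WT`) and the
#' unfiltered analysis, in all combinations. A seeded percentile bootstrap of
#' mean - median ([mean_median_ci()]) provides the outlier-vs-global-shift
#' diagnostic: a mean displaced from a near-zero median indicates a few
#' extreme probes, while mean and median moving together indicate a broad
#' shift in variability across the transcriptome.
#'
#' @param x A grouped [expression_dataset()].
#' @param statistic Primary statistic: `"dlog_cv"` (default) or `"dcv"`.
#' @param filter Apply the median-expression filter? Default `TRUE`.
#' @param threshold_method Filter threshold convention, see
#'   [median_filter_mask()].
#' @param n_boot Bootstrap resamples for the mean-minus-median confidence
#'   interval (default 1000; 0 skips the bootstrap).
#' @param seed Seed for the bootstrap (the fit itself is deterministic).
#' @return An object of class `"cvdelta"` with components `summary` (one-row
#'   data.frame, see [summarize_dataset()]), `variants` (the four
#'   statistic-by-filter combinations), `stats`, `deltas`, `threshold`,
#'   `diagnostics` (the bootstrap record, or `NULL`), `source`, `call`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_probes = 2000, f_cv = 1.5, seed = 3))
#' fit <- cv_delta(sim$dataset, seed = 3)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
cv_delta <- function(x, statistic = c("dlog_cv", "dcv"), filter = TRUE,
                     threshold_method = c("grand_mean", "pooled_means"),
                     n_boot = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  threshold_method <- match.arg(threshold_method)
  stats <- probe_group_stats(x)
  mask <- median_filter_mask(stats, method = threshold_method)
  deltas <- compute_deltas(stats, mask)
  variants <- do.call(rbind, lapply(c("dlog_cv", "dcv"), function(st)
    rbind(summarize_dataset(deltas, use_filter = TRUE, statistic = st),
          summarize_dataset(deltas, use_filter = FALSE, statistic = st))))
  main <- variants[variants$statistic == statistic &
                     variants$filtered == filter, , drop = FALSE]
  rownames(main) <- NULL
  diag <- NULL
  if (n_boot > 0) {
    v <- deltas[[statistic]]
    sel <- is.finite(v) & (if (filter) deltas$pass_filter else TRUE)
    diag <- mean_median_ci(v[sel], n_boot = n_boot, seed = seed)
  }
  structure(
    list(summary = main, variants = variants, stats = stats, deltas = deltas,
         threshold = mask$threshold, mask = mask$mask, diagnostics = diag,
         statistic = statistic, filtered = filter,
         n_wt = sum(x$group == "WT"), n_ko = sum(x$group == "KO"),
         source = x$source, call = match.call()),
    class = "cvdelta"
  )
}

#' @export
print.cvdelta <- function(x, ...) {
  s <- x$summary
  cat("Global CV-shift fit (", s$statistic, ", ",
      if (s$filtered) "median-filtered" else "all probes", ")\n", sep = "")
  cat("  source:", x$source, "\n")
  cat(sprintf("  probes: %d analyzed of %d (threshold %.4g; WT n=%d, KO n=%d)\n",
              s$n_analyzed, s$n_total, x$threshold, x$n_wt, x$n_ko))
  cat(sprintf("  mean %s = %.4f +/- %.4f (SEM), median = %.4f\n",
              s$statistic, s$mean, s$sem, s$median))
  if (s$statistic == "dlog_cv")
    cat(sprintf("  CV fold-change (KO/WT) = %.3f\n", s$fold_change))
  cat(sprintf("  t = %.2f, pp = %.2f (p %s)\n", s$t_stat, s$pp,
              if (s$p > 0) sprintf("= %.3g", s$p) else "underflows; pp is exact"))
  if (!is.null(x$diagnostics)) {
    ci <- x$diagnostics$ci
    cat(sprintf("  mean - median 95%% CI: [%.4f, %.4f]%s\n", ci[1], ci[2],
                if (x$diagnostics$spans_zero) " (spans zero: no outlier signature)"
                else " (excludes zero: mean tugged away from median)"))
  }
  invisible(x)
}

#' @export
summary.cvdelta <- function(object, ...) {
  structure(list(fit = object), class = "summary.cvdelta")
}

#' @export
print.summary.cvdelta <- function(x, ...) {
  print(x$fit)
  cat("\nRobustness variants:\n")
  v <- x$fit$variants
  v$mean <- round(v$mean, 4); v$sem <- round(v$sem, 4)
  v$median <- round(v$median, 4); v$t_stat <- round(v$t_stat, 2)
  v$pp <- round(v$pp, 2); v$fold_change <- round(v$fold_change, 3)
  v$mean_dlog_mean <- round(v$mean_dlog_mean, 4)
  print(v[, c("statistic", "filtered", "n_analyzed", "mean", "sem", "median",
              "t_stat", "pp", "fold_change")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.cvdelta <- function(object, ...) {
  s <- object$summary
  c(mean = s$mean, sem = s$sem, median = s$median, t = s$t_stat,
    pp = s$pp, fold_change = s$fold_change)
}

#' Confidence intervals for a CV-shift fit
#'
#' `parm = "mean"` gives the Student-t interval for the mean of the primary
#' statistic; `parm = "mean_minus_median"` returns the stored bootstrap
#' percentile interval for mean - median (95% only, computed at fit time).
#'
#' @param object A [cv_delta()] fit.
#' @param parm `"mean"` or `"mean_minus_median"`.
#' @param level Confidence level (for `"mean"`).
#' @param ... Unused.
#' @return A 1x2 matrix of interval endpoints.
#' @export
confint.cvdelta <- function(object, parm = "mean", level = 0.95, ...) {
  parm <- match.arg(parm, c("mean", "mean_minus_median"))
  s <- object$summary
  if (parm == "mean") {
    half <- qt(1 - (1 - level) / 2, df = s$n_analyzed - 1) * s$sem
    ci <- c(s$mean - half, s$mean + half)
  } else {
    if (is.null(object$diagnostics))
      stop("fit was run with n_boot = 0; no bootstrap interval available")
    if (level != 0.95)
      stop("the bootstrap interval is computed at the 95% level only")
    ci <- object$diagnostics$ci
  }
  matrix(ci, nrow = 1,
         dimnames = list(parm, sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                          1 - (1 - level) / 2))))
}

#' Plot the distribution of the per-probe delta statistic
#'
#' Histogram of the analyzed per-probe values with a moment-fitted normal
#' curve superimposed; the solid vertical line marks the median, the dashed
#' line zero. When the global shift is genuine (not outlier-driven) the
#' median tracks the centre of the normal curve rather than zero.
#'
#' @param x A [cv_delta()] fit (run with `n_boot > 0`).
#' @param ... Passed to [plot.mm_diagnostics()].
#' @return `x`, invisibly.
#' @export
plot.cvdelta <- function(x, ...) {
  if (is.null(x$diagnostics))
    stop("fit was run with n_boot = 0; refit with n_boot > 0 to plot")
  plot(x$diagnostics, xlab = x$statistic, ...)
  invisible(x)
}
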