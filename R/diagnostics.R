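#' Pearson correlations between log-scale summary statistics
#'
#' The five scatter-panel correlations that characterize a two-group
#' expression dataset: KO-vs-WT agreement of log mean, log SD and log CV, and
#' the within-WT mean-variance relationships (log SD vs log mean, which is
#' tightly positive when noise scales with expression, and log CV vs log
#' mean, which is negative in the presence of an expression-independent
#' noise floor).
#'
#' @param stats A [probe_group_stats()] table containing both groups.
#' @param mask Optional filter mask from [median_filter_mask()]; when given,
#'   correlations are computed over passing probes only.
#' @return A data.frame with columns `panel`, `pearson_r`, `n` (probes with
#'   finite values in both coordinates).
#' @export
panel_correlations <- function(stats, mask = NULL) {
  w <- stats_wide(stats)
  if (!is.null(mask)) {
    keep <- mask$mask[w$probe_id]
    w <- w[!is.na(keep) & keep, , drop = FALSE]
  }
  lg <- function(v) ifelse(v > 0, log10(v), NA_real_)
  panels <- list(
    "meanKO~meanWT" = cbind(lg(w$mean_wt), lg(w$mean_ko)),
    "sdKO~sdWT"     = cbind(lg(w$sd_wt), lg(w$sd_ko)),
    "cvKO~cvWT"     = cbind(lg(w$cv_wt), lg(w$cv_ko)),
    "sdWT~meanWT"   = cbind(lg(w$mean_wt), lg(w$sd_wt)),
    "cvWT~meanWT"   = cbind(lg(w$mean_wt), lg(w$cv_wt))
  )
  rows <- lapply(names(panels), function(nm) {
    xy <- panels[[nm]]
    ok <- is.finite(xy[, 1]) & is.finite(xy[, 2])
    if (sum(ok) < 3L)
      stop("panel ", nm, ": fewer than 3 usable probes")
    data.frame(panel = nm, pearson_r = cor(xy[ok, 1], xy[ok, 2]),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Distribution diagnostics: histogram, normal overlay, mean-minus-median CI
#'
#' Characterizes the distribution of per-probe delta values to distinguish an
#' outlier-driven shift (median near zero, mean tugged away by a few extreme
#' probes) from a broad global shift (median concurring with the mean). The
#' mean - median difference is interval-estimated by a seeded percentile
#' bootstrap (resampling probes with replacement); the normal overlay is
#' fitted by moments, so its centre is the sample mean.
#'
#' @param values Numeric vector of per-probe deltas (non-finite entries
#'   dropped); at least 10 required.
#' @param n_boot Bootstrap resamples (default 1000; below 100 a warning).
#' @param seed Optional seed making the bootstrap bit-reproducible.
#' @return An object of class `"mm_diagnostics"`: `mean`, `median`,
#'   `normal_mu`, `normal_sigma`, `ci` (2.5%/97.5% percentile interval for
#'   mean - median), `spans_zero`, `histogram` (breaks/counts/mids/density,
#'   Freedman-Diaconis bins capped at 200), `n`, `n_boot`, `seed`.
#' @export
mean_median_ci <- function(values, n_boot = 1000, seed = NULL) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 10L) stop("need at least 10 finite values, got ", n)
  if (n_boot < 100L) warning("n_boot < 100 gives an unstable interval")
  m <- mean(v)
  md <- median(v)
  if (max(v) == min(v)) {
    boot <- rep(0, n_boot)
  } else {
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      r <- v[sample.int(n, n, replace = TRUE)]
      mean(r) - median(r)
    }, numeric(1)))
  }
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  bins <- max(1L, min(200L, if (max(v) > min(v)) nclass.FD(v) else 1L))
  h <- hist(v, breaks = bins, plot = FALSE)
  structure(
    list(mean = m, median = md, normal_mu = m, normal_sigma = sd(v),
         ci = ci, spans_zero = ci[1] <= 0 && ci[2] >= 0,
         histogram = h[c("breaks", "counts", "mids", "density")],
         n = n, n_boot = n_boot, seed = seed),
    class = "mm_diagnostics"
  )
}

#' @export
print.mm_diagnostics <- function(x, ...) {
  cat(sprintf("Distribution diagnostics over %d values:\n", x$n))
  cat(sprintf("  mean = %.4f, median = %.4f, sd = %.4f\n",
              x$mean, x$median, x$normal_sigma))
  cat(sprintf("  mean - median 95%% bootstrap CI: [%.4f, %.4f] -> %s\n",
              x$ci[1], x$ci[2],
              if (x$spans_zero) "spans zero (no outlier signature)"
              else "excludes zero (outlier-displaced mean)"))
  invisible(x)
}

#' @export
plot.mm_diagnostics <- function(x, xlab = "delta", main = NULL, ...) {
  h <- x$histogram
  plot(h$mids, h$density, type = "h", lwd = 3, col = "grey70",
       xlab = xlab, ylab = "density",
       main = if (is.null(main)) "Per-probe delta distribution" else main, ...)
  if (x$normal_sigma > 0) {
    xs <- seq(min(h$breaks), max(h$breaks), length.out = 200)
    lines(xs, dnorm(xs, x$normal_mu, x$normal_sigma), lwd = 2)
  }
  abline(v = x$median, lwd = 2)
  abline(v = 0, lty = 2)
  legend("topright", bty = "n",
         legend = c("normal fit (moments)", "median", "zero"),
         lty = c(1, 1, 2), lwd = c(2, 2, 1))
  invisible(x)
}

#' Cross-dataset correlation of expression shift vs variability shift
#'
#' Across a collection of datasets, correlates the per-dataset mean
#' expression shift (mean over probes of `log10 mean_KO - log10 mean_WT`)
#' with the mean variability shift (mean `dlog_cv`). A broad transcriptional
#' induction or repression would, through the CV-vs-expression relationship,
#' predict a negative association; its absence argues that variability
#' differences are not explained by global expression changes.
#'
#' @param x A data.frame with columns `mean_dlog_mean` and `mean_dlog_cv`
#'   (one row per dataset), or a `"cvdelta_collection"` from
#'   [analyze_collection()].
#' @return A list: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`.
#' @export
cross_dataset_correlation <- function(x) {
  if (inherits(x, "cvdelta_collection")) x <- x$table[!x$table$failed, ]
  if (!all(c("mean_dlog_mean", "mean_dlog_cv") %in% names(x)))
    stop("need columns mean_dlog_mean and mean_dlog_cv")
  ok <- is.finite(x$mean_dlog_mean) & is.finite(x$mean_dlog_cv)
  if (sum(ok) < 3L) stop("need at least 3 datasets, got ", sum(ok))
  a <- x$mean_dlog_mean[ok]
  b <- x$mean_dlog_cv[ok]
  pe <- cor.test(a, b, method = "pearson")
  sp <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = sum(ok))
}

#' @importFrom stats dnorm setNames
#' @importFrom graphics lines
NULL
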