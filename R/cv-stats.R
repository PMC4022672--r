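#' Per-probe, per-group mean, SD and CV
#'
#' Computes, for every probe set and each group, the mean, sample standard
#' deviation (denominator n - 1) and coefficient of variation (CV = SD/mean)
#' of the replicate intensities. Probes with any missing value in either
#' group are excluded up front with a message, so that every retained SD is
#' estimated from the full complement of replicates. Probes with a
#' nonpositive mean get `cv = NA` (undefined).
#'
#' @param x A grouped [expression_dataset()] with at least 2 replicates per
#'   group.
#' @return A data.frame with columns `probe_id`, `group`, `n`, `mean`, `sd`,
#'   `cv` (long format, WT rows then KO rows, probe order preserved). The
#'   number of probes dropped for missing values is attached as attribute
#'   `n_excluded_missing`.
#' @export
probe_group_stats <- function(x) {
  stopifnot(inherits(x, "expression_dataset"))
  if (!is_grouped(x)) stop("dataset is ungrouped; assign_groups() first")
  wt <- group_values(x, "WT")
  ko <- group_values(x, "KO")
  if (ncol(wt) < 2L || ncol(ko) < 2L)
    stop("need at least 2 replicates per group to estimate an SD (WT n=",
         ncol(wt), ", KO n=", ncol(ko), ")")
  complete <- complete.cases(wt) & complete.cases(ko)
  n_dropped <- sum(!complete)
  if (n_dropped)
    message("probe_group_stats: excluding ", n_dropped,
            " probe(s) with missing values")
  wt <- wt[complete, , drop = FALSE]
  ko <- ko[complete, , drop = FALSE]
  probe_ids <- rownames(x$values)[complete]
  one_group <- function(v, label) {
    m <- rowMeans(v)
    s <- row_sd(v)
    data.frame(probe_id = probe_ids, group = label, n = ncol(v),
               mean = m, sd = s,
               cv = ifelse(m > 0, s / m, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(one_group(wt, "WT"), one_group(ko, "KO"))
  attr(out, "n_excluded_missing") <- n_dropped
  out
}

# Wide (one row per probe) view of a probe_group_stats table.
stats_wide <- function(stats) {
  wt <- stats[stats$group == "WT", ]
  ko <- stats[stats$group == "KO", ]
  if (!nrow(wt) || !nrow(ko)) stop("stats table must contain both groups")
  ko <- ko[match(wt$probe_id, ko$probe_id), ]
  if (anyNA(ko$probe_id)) stop("stats table has unmatched probes across groups")
  data.frame(probe_id = wt$probe_id,
             n_wt = wt$n, n_ko = ko$n,
             mean_wt = wt$mean, mean_ko = ko$mean,
             sd_wt = wt$sd, sd_ko = ko$sd,
             cv_wt = wt$cv, cv_ko = ko$cv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-expression filter
#'
#' Marks the probe sets retained by the expression filter: a probe passes iff
#' its mean expression in *both* groups is at or above the dataset-wide
#' threshold. Rationale: a tissue expresses only about half or fewer of the
#' genes its array probes, so probes below the median expression mostly
#' report unexpressed genes and contribute only noise.
#'
#' Two threshold conventions are offered. The default, `"grand_mean"`, takes
#' the median over probes of the per-probe grand mean (the mean across all
#' samples of both groups). `"pooled_means"` takes the median of the pooled
#' per-group means (two values per probe). Probes exactly at the threshold
#' pass — only strictly sub-threshold expression is filtered.
#'
#' @param stats A [probe_group_stats()] table containing both groups.
#' @param method Threshold convention, see above.
#' @return A list: `mask` (named logical vector over probes, `TRUE` = pass)
#'   and `threshold` (the intensity cutoff used).
#' @export
median_filter_mask <- function(stats, method = c("grand_mean", "pooled_means")) {
  method <- match.arg(method)
  w <- stats_wide(stats)
  if (!nrow(w)) stop("empty stats table")
  threshold <- switch(method,
    grand_mean = {
      grand <- (w$n_wt * w$mean_wt + w$n_ko * w$mean_ko) / (w$n_wt + w$n_ko)
      median(grand)
    },
    pooled_means = median(c(w$mean_wt, w$mean_ko))
  )
  mask <- w$mean_wt >= threshold & w$mean_ko >= threshold
  names(mask) <- w$probe_id
  list(mask = mask, threshold = threshold)
}

#' Per-probe KO-vs-WT deltas
#'
#' For each probe set computes the three contrasts of interest:
#' `dlog_cv = log10(CV_KO) - log10(CV_WT)` (the primary statistic; its mean
#' across probes is the log of the geometric-mean CV fold-change),
#' `dcv = CV_KO - CV_WT` (the arithmetic robustness variant), and
#' `dlog_mean = log10(mean_KO) - log10(mean_WT)` (the expression-shift
#' analogue). Probes with an undefined CV (nonpositive mean) or a zero CV in
#' either group are excluded from *both* CV variants — so the log and
#' arithmetic analyses run on identical probe sets — with the reason
#' recorded.
#'
#' @param stats A [probe_group_stats()] table containing both groups.
#' @param mask Optional filter mask from [median_filter_mask()]; when `NULL`
#'   every probe is marked as passing.
#' @return A data.frame with columns `probe_id`, `dlog_cv`, `dcv`,
#'   `dlog_mean`, `pass_filter`, `excluded_reason` (`NA` when usable).
#'   Exclusion counts are attached as attribute `exclusions`.
#' @export
compute_deltas <- function(stats, mask = NULL) {
  w <- stats_wide(stats)
  reason <- rep(NA_character_, nrow(w))
  undef <- is.na(w$cv_wt) | is.na(w$cv_ko)
  zero <- !undef & (w$cv_wt == 0 | w$cv_ko == 0)
  reason[undef] <- "nonpositive mean"
  reason[zero] <- "zero CV"
  usable <- is.na(reason)
  dlog_cv <- dcv <- rep(NA_real_, nrow(w))
  dlog_cv[usable] <- log10(w$cv_ko[usable]) - log10(w$cv_wt[usable])
  dcv[usable] <- w$cv_ko[usable] - w$cv_wt[usable]
  dlog_mean <- ifelse(w$mean_wt > 0 & w$mean_ko > 0,
                      log10(w$mean_ko) - log10(w$mean_wt), NA_real_)
  pass <- if (is.null(mask)) rep(TRUE, nrow(w)) else {
    m <- mask$mask[w$probe_id]
    ifelse(is.na(m), FALSE, m)
  }
  out <- data.frame(probe_id = w$probe_id, dlog_cv = dlog_cv, dcv = dcv,
                    dlog_mean = dlog_mean, pass_filter = pass,
                    excluded_reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  excl <- table(reason[!usable])
  attr(out, "exclusions") <- setNames(as.integer(excl), names(excl))
  n_excl <- sum(!usable)
  if (n_excl)
    message("compute_deltas: excluding ", n_excl, " probe(s): ",
            paste(sprintf("%s (%d)", names(excl), excl), collapse = ", "))
  out
}

#' One-sample two-tailed t-test with log-space p-value
#'
#' Tests whether the mean of a vector of per-probe delta statistics differs
#' from zero: `t = mean / (sd / sqrt(n))`, df = n - 1. With tens of
#' thousands of probes the p-value routinely falls far below the smallest
#' representable double (p < 1e-300), so the two-tailed p is computed on the
#' log scale via the log of the Student-t survival function and reported as
#' `pp = -log10(p)`, which stays finite and exact arbitrarily deep into the
#' tail. The linear-scale `p` is also returned (0 when it underflows).
#'
#' @param values Numeric vector; non-finite entries are dropped; at least 2
#'   finite values required.
#' @return A list: `t_stat`, `df`, `p`, `pp`, `n`. A constant nonzero vector
#'   has sd 0, giving an infinite `t` and `pp = Inf` with a warning.
#' @examples
#' one_sample_test_logp(c(0.1, 0.2, 0.3, 0.4, 0.5))
#' @export
one_sample_test_logp <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 2L) stop("need at least 2 finite values, got ", n)
  m <- mean(v)
  s <- sd(v)
  df <- n - 1L
  if (s == 0) {
    if (m == 0) return(list(t_stat = 0, df = df, p = 1, pp = 0, n = n))
    warning("all values identical and nonzero: zero SD, p-value degenerate")
    return(list(t_stat = sign(m) * Inf, df = df, p = 0, pp = Inf, n = n))
  }
  t_stat <- m / (s / sqrt(n))
  log_p <- log(2) + pt(abs(t_stat), df, lower.tail = FALSE, log.p = TRUE)
  pp <- -log_p / log(10)
  list(t_stat = t_stat, df = df, p = exp(log_p), pp = pp, n = n)
}

#' Summarize a dataset's global variability shift
#'
#' Aggregates a per-probe delta table into the dataset-level result: the mean
#' of the chosen statistic across analyzed probes (for `dlog_cv`, the log10
#' of the geometric-mean CV fold-change), its SEM and median, the one-sample
#' t-test of mean = 0 with log-space significance `pp = -log10(p)`, and the
#' CV fold-change `10^mean` (for `dlog_cv`). Analyzed probes are those with a
#' finite statistic that pass the expression filter (when `use_filter`).
#'
#' @param deltas A [compute_deltas()] table.
#' @param use_filter Restrict to probes passing the median-expression filter?
#' @param statistic `"dlog_cv"` (default) or `"dcv"`.
#' @return One-row data.frame: `statistic`, `filtered`, `n_total`,
#'   `n_analyzed`, `mean`, `sem`, `median`, `t_stat`, `p`, `pp`,
#'   `fold_change` (`NA` for `dcv`), `mean_dlog_mean`.
#' @export
summarize_dataset <- function(deltas, use_filter = TRUE,
                              statistic = c("dlog_cv", "dcv")) {
  statistic <- match.arg(statistic)
  if (!nrow(deltas)) stop("empty delta table")
  v <- deltas[[statistic]]
  sel <- is.finite(v) & (if (use_filter) deltas$pass_filter else TRUE)
  v <- v[sel]
  n <- length(v)
  if (!n) stop("no probes left after filtering")
  test <- one_sample_test_logp(v)
  m <- mean(v)
  dlm <- deltas$dlog_mean[sel]
  data.frame(
    statistic = statistic, filtered = use_filter,
    n_total = nrow(deltas), n_analyzed = n,
    mean = m, sem = sd(v) / sqrt(n), median = median(v),
    t_stat = test$t_stat, p = test$p, pp = test$pp,
    fold_change = if (statistic == "dlog_cv") 10^m else NA_real_,
    mean_dlog_mean = mean(dlm[is.finite(dlm)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
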