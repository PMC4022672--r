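test_that("per-probe group statistics match hand computation", {
  ds <- make_dataset_rows(list(
    list(wt = c(5, 5, 5, 5), ko = c(1, 2, 3, 4)),
    list(wt = c(2, 4, 6, 8), ko = c(10, 10, 10, 10))
  ))
  st <- probe_group_stats(ds)
  p1_wt <- st[st$probe_id == "p001" & st$group == "WT", ]
  expect_equal(p1_wt$mean, 5)
  expect_equal(p1_wt$sd, 0)
  expect_equal(p1_wt$cv, 0)
  p1_ko <- st[st$probe_id == "p001" & st$group == "KO", ]
  expect_equal(p1_ko$mean, 2.5)
  expect_equal(p1_ko$sd, 1.2909944, tolerance = 1e-7)   # n-1 denominator
  expect_equal(p1_ko$cv, 0.5163978, tolerance = 1e-7)
  # cv * mean = sd wherever mean > 0
  pos <- st$mean > 0
  expect_equal(st$cv[pos] * st$mean[pos], st$sd[pos])
})

test_that("a nonpositive mean leaves the CV undefined", {
  ds <- make_dataset_rows(list(
    list(wt = c(-1, 1, -1, 1), ko = c(1, 2, 3, 4)),
    list(wt = c(1, 2, 3, 4), ko = c(1, 2, 3, 4))
  ))
  st <- probe_group_stats(ds)
  expect_true(is.na(st$cv[st$probe_id == "p001" & st$group == "WT"]))
  d <- suppressMessages(compute_deltas(st))
  expect_equal(d$excluded_reason[d$probe_id == "p001"], "nonpositive mean")
  expect_true(is.na(d$dlog_cv[d$probe_id == "p001"]))
  expect_true(is.na(d$dcv[d$probe_id == "p001"]))
})

test_that("probes with missing replicate values are excluded with a count", {
  wt <- matrix(1:16, 4) + 0.5
  ko <- matrix(17:32, 4) + 0.5
  wt[2, 3] <- NA
  ds <- make_dataset(wt, ko)
  expect_message(st <- probe_group_stats(ds), "1 probe")
  expect_equal(length(unique(st$probe_id)), 3L)
  expect_false("p002" %in% st$probe_id)
})

test_that("fewer than 2 replicates in a group is an error", {
  ds <- make_dataset(matrix(1:4, 4), matrix(5:20, 4))
  expect_error(probe_group_stats(ds), "at least 2 replicates")
})

test_that("median filter threshold and mask follow the grand-mean rule", {
  # equal group means 1,2,3,4 -> grand means 1,2,3,4 -> threshold 2.5
  rows <- lapply(c(1, 2, 3, 4), function(m)
    list(wt = rep(m, 4) + c(-0.1, 0.1, -0.1, 0.1),
         ko = rep(m, 4) + c(0.1, -0.1, 0.1, -0.1)))
  st <- probe_group_stats(make_dataset_rows(rows))
  mk <- median_filter_mask(st)
  expect_equal(mk$threshold, 2.5)
  expect_equal(unname(mk$mask), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("probes exactly at the threshold pass; all-tied data all pass", {
  rows <- replicate(5, list(wt = c(3, 3, 3, 3), ko = c(3, 3, 3, 3)),
                    simplify = FALSE)
  st <- probe_group_stats(make_dataset_rows(rows))
  mk <- median_filter_mask(st)
  expect_equal(mk$threshold, 3)
  expect_true(all(mk$mask))
})

test_that("filter fails a probe when either group mean is sub-threshold", {
  # probe 1: WT well above, KO below; probes 2-3 set the threshold
  rows <- list(
    list(wt = rep(10, 4), ko = rep(1, 4)),
    list(wt = rep(5, 4), ko = rep(5, 4)),
    list(wt = rep(6, 4), ko = rep(6, 4))
  )
  st <- probe_group_stats(make_dataset_rows(rows))
  mk <- median_filter_mask(st)
  expect_equal(mk$threshold, 5.5)
  expect_false(mk$mask[["p001"]])
})

test_that("deltas evaluate the log and arithmetic contrasts correctly", {
  wt <- matrix(rnorm(40, 50, 5), 10)
  ko <- wt
  ds <- make_dataset(wt, ko)
  d <- compute_deltas(probe_group_stats(ds))
  expect_equal(d$dlog_cv, rep(0, 10))
  expect_equal(d$dcv, rep(0, 10))
  expect_equal(d$dlog_mean, rep(0, 10))

  # engineered CVs: WT 0.2, KO 0.4 at equal means
  base <- c(-1, -1, 1, 1)
  rows <- list(list(wt = 10 + base * 0.2 * 10 * sqrt(3) / 2,
                    ko = 10 + base * 0.4 * 10 * sqrt(3) / 2))
  st <- probe_group_stats(make_dataset_rows(rows))
  expect_equal(st$cv, c(0.2, 0.4), tolerance = 1e-12)
  d2 <- compute_deltas(st)
  expect_equal(d2$dlog_cv, log10(2), tolerance = 1e-12)
  expect_equal(d2$dcv, 0.2, tolerance = 1e-12)
})

test_that("a zero CV in either group excludes the probe with a reason", {
  rows <- list(
    list(wt = c(1, 2, 3, 4), ko = c(5, 5, 5, 5)),
    list(wt = c(1, 2, 3, 4), ko = c(1, 2, 3, 4))
  )
  st <- probe_group_stats(make_dataset_rows(rows))
  d <- suppressMessages(compute_deltas(st))
  expect_equal(d$excluded_reason[1], "zero CV")
  expect_true(is.na(d$dlog_cv[1]))
  expect_true(is.na(d$dcv[1]))  # excluded from both variants
  expect_equal(attr(d, "exclusions")[["zero CV"]], 1L)
})

test_that("one-sample log-space test matches the textbook t computation", {
  z <- one_sample_test_logp(rep(0, 20))
  expect_equal(z$t_stat, 0)
  expect_equal(z$pp, 0)
  expect_equal(z$p, 1)

  # frozen from an independent evaluation of t = mean/(sd/sqrt(n)), df = 4
  r <- one_sample_test_logp(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(r$t_stat, 4.2426407, tolerance = 1e-7)
  expect_equal(r$p, 0.0132356, tolerance = 1e-6)
  expect_equal(r$pp, 1.8782557, tolerance = 1e-6)

  expect_error(one_sample_test_logp(c(1, NA, Inf)), "at least 2")
  expect_warning(r0 <- one_sample_test_logp(rep(0.3, 5)), "zero SD")
  expect_true(is.infinite(r0$pp))
})

test_that("pp maps the standard significance landmarks correctly", {
  # pp = -log10(p): p 0.05 -> 1.30, 0.01 -> 2, 0.001 -> 3
  for (p_target in c(0.05, 0.01, 0.001)) {
    df <- 30
    t_target <- qt(1 - p_target / 2, df)
    # a 31-value vector engineered to produce exactly t_target
    v <- scale(rnorm(31))[, 1]          # mean 0, sd 1
    v <- v + t_target / sqrt(31)        # mean shifts t to t_target
    r <- one_sample_test_logp(v)
    expect_equal(r$pp, -log10(p_target), tolerance = 1e-10)
  }
})

test_that("log-space pp agrees with the direct p-value and survives underflow", {
  set.seed(31)
  for (shift in c(0.05, 0.2, 0.5)) {
    v <- rnorm(500, shift, 1)
    r <- one_sample_test_logp(v)
    p_direct <- 2 * pt(abs(r$t_stat), r$df, lower.tail = FALSE)
    if (p_direct > 1e-300)
      expect_equal(r$pp, -log10(p_direct), tolerance = 1e-6)
  }
  # far beyond double-precision underflow: p ~ 10^-700 territory
  v <- rnorm(5000, 1, 1)
  r <- one_sample_test_logp(v)
  expect_true(is.finite(r$pp))
  expect_gt(r$pp, 300)
  expect_equal(r$p, 0)  # linear-scale p honestly underflows
})

test_that("summary converts mean dlog_cv to the CV fold-change", {
  # fold change = 10^mean exactly, matching the printed extreme conversions
  expect_equal(round(10^-0.174, 2), 0.67)
  ds <- make_dataset(matrix(rnorm(40, 50, 5), 10),
                     matrix(rnorm(40, 50, 10), 10))
  d <- compute_deltas(probe_group_stats(ds))
  s <- summarize_dataset(d, use_filter = FALSE)
  expect_equal(s$fold_change, 10^s$mean)
  expect_equal(sign(s$t_stat), sign(s$mean))
  expect_gte(s$pp, 0)
  s2 <- summarize_dataset(d, use_filter = FALSE, statistic = "dcv")
  expect_true(is.na(s2$fold_change))
})

test_that("summaries agree with the brute-force oracle on toy tables", {
  set.seed(17)
  for (rep_i in 1:5) {
    mu <- runif(10, 10, 200)
    wt <- matrix(mu, 10, 4) * matrix(runif(40, 0.8, 1.2), 10)
    ko <- matrix(mu, 10, 4) * matrix(runif(40, 0.8, 1.2), 10)
    ds <- make_dataset(wt, ko)
    for (filter in c(TRUE, FALSE)) for (statistic in c("dlog_cv", "dcv")) {
      st <- probe_group_stats(ds)
      d <- compute_deltas(st, median_filter_mask(st))
      got <- summarize_dataset(d, use_filter = filter, statistic = statistic)
      want <- oracle_summary(wt, ko, filter = filter, statistic = statistic)
      expect_equal(got$n_analyzed, want$n_analyzed)
      expect_equal(got$mean, want$mean, tolerance = 1e-10)
      expect_equal(got$sem, want$sem, tolerance = 1e-10)
      expect_equal(got$median, want$median, tolerance = 1e-10)
      expect_equal(got$t_stat, want$t_stat, tolerance = 1e-10)
      expect_equal(got$pp, want$pp, tolerance = 1e-6)
    }
  }
})

test_that("swapping group labels negates the contrasts and keeps pp", {
  set.seed(23)
  wt <- matrix(runif(80, 10, 200), 20)
  ko <- matrix(runif(80, 10, 200), 20)
  fit <- cv_delta(make_dataset(wt, ko), n_boot = 0)
  swapped <- cv_delta(make_dataset(ko, wt), n_boot = 0)
  expect_equal(swapped$deltas$dlog_cv, -fit$deltas$dlog_cv)
  expect_equal(swapped$deltas$dcv, -fit$deltas$dcv)
  expect_equal(swapped$deltas$dlog_mean, -fit$deltas$dlog_mean)
  expect_equal(swapped$summary$mean, -fit$summary$mean)
  expect_equal(swapped$summary$t_stat, -fit$summary$t_stat)
  expect_equal(swapped$summary$pp, fit$summary$pp)
  expect_equal(swapped$deltas$pass_filter, fit$deltas$pass_filter)
})

test_that("the analysis is invariant to a global intensity rescaling", {
  set.seed(29)
  wt <- matrix(runif(80, 10, 200), 20)
  ko <- matrix(runif(80, 10, 200), 20)
  fit <- cv_delta(make_dataset(wt, ko), n_boot = 0)
  scaled <- cv_delta(make_dataset(wt * 37.5, ko * 37.5), n_boot = 0)
  expect_equal(scaled$deltas$dlog_cv, fit$deltas$dlog_cv, tolerance = 1e-12)
  expect_equal(scaled$deltas$pass_filter, fit$deltas$pass_filter)
  expect_equal(scaled$threshold, fit$threshold * 37.5, tolerance = 1e-12)
  expect_equal(scaled$summary$mean, fit$summary$mean, tolerance = 1e-12)
})

test_that("degenerate summaries error cleanly", {
  expect_error(summarize_dataset(data.frame()), "empty")
  d <- data.frame(probe_id = "p1", dlog_cv = NA_real_, dcv = NA_real_,
                  dlog_mean = NA_real_, pass_filter = TRUE,
                  excluded_reason = "zero CV")
  expect_error(summarize_dataset(d), "no probes")
})
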