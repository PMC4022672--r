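#' Simulation configuration for synthetic expression matrices
#'
#' Parameters of the generative model behind [simulate_dataset()]. Each probe
#' set g has a true expression level mu_g drawn log-normally,
#' `log10(mu_g) ~ Normal(mean_log_mu, mean_log_sigma)`. A wild-type replicate
#' measurement is
#'
#' `value = mu_g * (1 + e_m) + e_a`,  `e_m ~ N(0, cv_mult)`, `e_a ~ N(0, sigma_add)`
#'
#' i.e. multiplicative noise proportional to expression plus an additive
#' noise floor independent of expression. This two-parameter model yields the
#' two mean-variance signatures of real arrays: SD rising essentially
#' linearly with mean expression, and CV falling with mean expression
#' (`CV(mu) ~ sqrt(cv_mult^2 + sigma_add^2/mu^2)`, strictly decreasing).
#'
#' A knockout replicate is
#' `mu_g * 10^delta_mean_log * (1 + e_m') + e_a'` with both noise components
#' scaled by a per-probe factor f_g: `e_m' ~ N(0, f_g*cv_mult)`,
#' `e_a' ~ N(0, f_g*sigma_add)`. For most probes `f_g = f_cv`, the global
#' KO/WT variability fold-change; a random `outlier_fraction` of probes get
#' `f_g = f_cv * outlier_factor`. Scaling both components means the sampling
#' distribution of the KO sample CV is (denominator noise aside) f_g times
#' the WT one, so the expected per-probe delta log10 CV is `log10(f_g)` --
#' the generator's truth is recoverable exactly.
#'
#' @param n_probes Number of probe sets (default 45000, the size of a
#'   full-genome mouse array).
#' @param n_wt,n_ko Biological replicates per group (default 4).
#' @param mean_log_mu,mean_log_sigma Mean and SD of `log10(mu_g)` (default
#'   2 and 0.8: levels centred at 100 intensity units over ~4 decades).
#' @param cv_mult Multiplicative noise coefficient (default 0.1, i.e. 10% CV
#'   at high expression).
#' @param sigma_add Additive noise-floor SD in intensity units (default 2).
#' @param f_cv Global KO/WT CV fold-change; 1 is the null (default 1).
#' @param delta_mean_log Global KO expression shift in log10 units (default 0).
#' @param outlier_fraction Fraction of probes receiving an extra KO CV
#'   multiplier (default 0).
#' @param outlier_factor That multiplier (default 1).
#' @param intensity_floor Values below this positive floor are clipped to it,
#'   keeping matrices nonnegative (default 1e-3).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   matrix.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_probes = 45000, n_wt = 4, n_ko = 4,
                       mean_log_mu = 2, mean_log_sigma = 0.8,
                       cv_mult = 0.1, sigma_add = 2,
                       f_cv = 1, delta_mean_log = 0,
                       outlier_fraction = 0, outlier_factor = 1,
                       intensity_floor = 1e-3, seed = 1L) {
  stopifnot(
    n_probes >= 1, n_wt >= 1, n_ko >= 1,
    mean_log_sigma >= 0, cv_mult >= 0, sigma_add >= 0,
    f_cv > 0, outlier_fraction >= 0, outlier_fraction < 1,
    outlier_factor > 0, intensity_floor > 0,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  structure(
    list(n_probes = as.integer(n_probes), n_wt = as.integer(n_wt),
         n_ko = as.integer(n_ko), mean_log_mu = mean_log_mu,
         mean_log_sigma = mean_log_sigma, cv_mult = cv_mult,
         sigma_add = sigma_add, f_cv = f_cv,
         delta_mean_log = delta_mean_log,
         outlier_fraction = outlier_fraction,
         outlier_factor = outlier_factor,
         intensity_floor = intensity_floor, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d probes, WT n=%d, KO n=%d, seed %d\n",
    x$n_probes, x$n_wt, x$n_ko, x$seed))
  cat(sprintf("  levels: log10(mu) ~ N(%g, %g)\n", x$mean_log_mu, x$mean_log_sigma))
  cat(sprintf("  noise: cv_mult=%g, sigma_add=%g, floor=%g\n",
              x$cv_mult, x$sigma_add, x$intensity_floor))
  cat(sprintf("  KO: f_cv=%g, delta_mean_log=%g, outliers %g%% x%g\n",
              x$f_cv, x$delta_mean_log, 100 * x$outlier_fraction,
              x$outlier_factor))
  invisible(x)
}

#' Simulate an expression dataset with known variability ground truth
#'
#' Draws a probe-by-sample matrix from the model described in [sim_config()]
#' and returns it together with a truth record (per-probe true level `mu`,
#' variability factor `f_g`, outlier flag). Values falling below the
#' intensity floor are clipped to it; a clip rate above 1% triggers a
#' warning (the parameters imply a non-negligible mass of negative
#' intensities) and above 20% an error.
#'
#' @param config A [sim_config()]. Alternatively pass [sim_config()]
#'   arguments through `...`.
#' @param ... Arguments forwarded to [sim_config()] when `config` is missing.
#' @return An object of class `"sim_result"`: a list with `dataset` (a
#'   grouped [expression_dataset()]), `truth` (data.frame `probe_id`, `mu`,
#'   `f_g`, `outlier`), `config`, and `clip_rate`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_probes = 500, seed = 7))
#' fit <- cv_delta(sim$dataset, n_boot = 200, seed = 7)
#' coef(fit)
#' @export
simulate_dataset <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  res <- with_seed(cfg$seed, {
    n <- cfg$n_probes
    mu <- 10^rnorm(n, cfg$mean_log_mu, cfg$mean_log_sigma)
    f_g <- rep(cfg$f_cv, n)
    outlier <- rep(FALSE, n)
    n_out <- round(cfg$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      f_g[idx] <- cfg$f_cv * cfg$outlier_factor
      outlier[idx] <- TRUE
    }
    wt <- matrix(mu, n, cfg$n_wt) *
      (1 + matrix(rnorm(n * cfg$n_wt), n) * cfg$cv_mult) +
      matrix(rnorm(n * cfg$n_wt), n) * cfg$sigma_add
    # f_g recycles down rows of the n x n_ko matrices (column-major), scaling
    # both noise components of every KO replicate of probe g by f_g
    ko <- matrix(mu * 10^cfg$delta_mean_log, n, cfg$n_ko) *
      (1 + matrix(rnorm(n * cfg$n_ko), n) * (cfg$cv_mult * f_g)) +
      matrix(rnorm(n * cfg$n_ko), n) * (cfg$sigma_add * f_g)
    list(mu = mu, f_g = f_g, outlier = outlier, wt = wt, ko = ko)
  })
  n_cells <- length(res$wt) + length(res$ko)
  n_clip <- sum(res$wt < cfg$intensity_floor) + sum(res$ko < cfg$intensity_floor)
  clip_rate <- n_clip / n_cells
  if (clip_rate > 0.20)
    stop(sprintf(
      "simulation parameters imply predominantly negative intensities: %.1f%% of values below the floor",
      100 * clip_rate))
  if (clip_rate > 0.01)
    warning(sprintf("%.1f%% of simulated values clipped to the intensity floor",
                    100 * clip_rate))
  res$wt[res$wt < cfg$intensity_floor] <- cfg$intensity_floor
  res$ko[res$ko < cfg$intensity_floor] <- cfg$intensity_floor

  probe_ids <- sprintf("%07d_at", 1400000L + seq_len(cfg$n_probes))
  wt_ids <- sprintf("WT_%02d", seq_len(cfg$n_wt))
  ko_ids <- sprintf("KO_%02d", seq_len(cfg$n_ko))
  values <- cbind(res$wt, res$ko)
  dimnames(values) <- list(probe_ids, c(wt_ids, ko_ids))
  group <- setNames(rep(c("WT", "KO"), c(cfg$n_wt, cfg$n_ko)),
                    c(wt_ids, ko_ids))
  dataset <- expression_dataset(values, group = group,
                                source = sprintf("synthetic:%d", cfg$seed))
  truth <- data.frame(probe_id = probe_ids, mu = res$mu, f_g = res$f_g,
                      outlier = res$outlier, stringsAsFactors = FALSE)
  structure(list(dataset = dataset, truth = truth, config = cfg,
                 clip_rate = clip_rate),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated", x$config$n_probes, "probe sets; clip rate",
      sprintf("%.3f%%", 100 * x$clip_rate), "\n")
  print(x$dataset)
  invisible(x)
}

#' Write a simulated dataset and its truth record to TSV files
#'
#' The matrix is written in the dialect [read_expression_tsv()] reads; the
#' truth record goes to a sidecar file `<path>.truth.tsv`.
#'
#' @param x A `"sim_result"` from [simulate_dataset()].
#' @param path Output path for the matrix TSV.
#' @return `path`, invisibly.
#' @export
write_sim_result <- function(x, path) {
  stopifnot(inherits(x, "sim_result"))
  write_expression_tsv(x$dataset, path)
  write.table(x$truth, paste0(path, ".truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
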