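#' Run the full analysis on a single dataset
#'
#' Convenience wrapper covering the whole per-dataset workflow: read the
#' input (GEO Series Matrix or plain TSV, auto-detected), assign groups,
#' apply the validity screens (failing fast with the report's reasons), fit
#' [cv_delta()], and optionally write the per-probe delta table and one-row
#' summary as TSV files.
#'
#' @param input An [expression_dataset()], or a path to a Series Matrix /
#'   TSV file.
#' @param groups Named character vector (sample id -> `"WT"`/`"KO"`), or a
#'   path to a YAML/JSON mapping ([read_group_mapping()]). Omit if `input`
#'   is already grouped.
#' @param statistic,filter,threshold_method,n_boot,seed Passed to
#'   [cv_delta()].
#' @param max_negative_fraction,min_replicates Passed to
#'   [validate_dataset()].
#' @param out_dir If non-`NULL`, `deltas.tsv` and `summary.tsv` are written
#'   there (created if needed).
#' @return The `"cvdelta"` fit, with the validation report attached as
#'   attribute `"validation"`.
#' @export
analyze_dataset <- function(input, groups = NULL,
                            statistic = c("dlog_cv", "dcv"), filter = TRUE,
                            threshold_method = c("grand_mean", "pooled_means"),
                            n_boot = 1000, seed = NULL,
                            max_negative_fraction = 0, min_replicates = 4,
                            out_dir = NULL) {
  dataset <- if (inherits(input, "expression_dataset")) input else {
    if (!is.character(input) || !file.exists(input))
      stop("input file not found: ", input)
    if (is_series_matrix(input)) read_series_matrix(input)
    else read_expression_tsv(input)
  }
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1L && file.exists(groups))
      groups <- read_group_mapping(groups)
    dataset <- assign_groups(dataset, groups)
  }
  report <- validate_dataset(dataset,
                             max_negative_fraction = max_negative_fraction,
                             min_replicates = min_replicates)
  if (!report$passed)
    stop("dataset failed validation: ", paste(report$reasons, collapse = "; "))
  fit <- cv_delta(dataset, statistic = statistic, filter = filter,
                  threshold_method = threshold_method, n_boot = n_boot,
                  seed = seed)
  attr(fit, "validation") <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(fit$deltas, file.path(out_dir, "deltas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(collection_row(fit, label = basename(out_dir)),
                file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  fit
}

is_series_matrix <- function(path) {
  head <- readLines(path, n = 200L, warn = FALSE)
  any(grepl("^!series_matrix_table_begin", head, ignore.case = TRUE)) ||
    any(startsWith(head, "!Series_"))
}

collection_row <- function(fit, label, littermate = FALSE) {
  s <- fit$summary
  ci <- if (is.null(fit$diagnostics)) c(NA_real_, NA_real_) else fit$diagnostics$ci
  data.frame(
    dataset = label, littermate = littermate,
    n_total = s$n_total, n_analyzed = s$n_analyzed,
    mean_dlog_cv = s$mean, sem = s$sem, fold_change = s$fold_change,
    t_stat = s$t_stat, pp = s$pp, median_dlog_cv = s$median,
    ci_low = ci[1], ci_high = ci[2], mean_dlog_mean = s$mean_dlog_mean,
    statistic = s$statistic, filtered = s$filtered,
    failed = FALSE, error = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

failed_row <- function(label, littermate, msg) {
  data.frame(
    dataset = label, littermate = littermate,
    n_total = NA_integer_, n_analyzed = NA_integer_,
    mean_dlog_cv = NA_real_, sem = NA_real_, fold_change = NA_real_,
    t_stat = NA_real_, pp = NA_real_, median_dlog_cv = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, mean_dlog_mean = NA_real_,
    statistic = NA_character_, filtered = NA,
    failed = TRUE, error = msg,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Analyze a collection of datasets
#'
#' Runs [analyze_dataset()] over a list of dataset configurations, collecting
#' one summary row per dataset ordered by increasing mean `dlog_cv` (the
#' convention for multi-dataset displays). A dataset that fails validation or
#' errors is recorded as a failed row; the others proceed. Bootstrap seeds
#' are derived per dataset from `master_seed` plus the dataset index, so a
#' collection is reproducible while its datasets stay independent.
#'
#' Summary counts report how the collection splits between decreased and
#' increased variability and how many datasets clear the standard
#' significance landmarks `pp` > 1.301 (p < 0.05), 3, 7, 10 and 100.
#'
#' @param configs A list; each element is either an already grouped
#'   [expression_dataset()] (or `"sim_result"`), or a list with fields
#'   `input` (dataset or path), optional `groups`, optional `label`,
#'   optional `littermate` flag.
#' @param master_seed Integer; dataset i bootstraps with seed
#'   `master_seed + i`.
#' @param littermates_only Restrict the result to littermate-flagged
#'   datasets (robustness check against husbandry artifacts).
#' @param out_file If non-`NULL`, the combined table is written there as TSV.
#' @param ... Passed to [analyze_dataset()] (`statistic`, `filter`,
#'   `n_boot`, ...).
#' @return An object of class `"cvdelta_collection"`: `table` (sorted
#'   ascending by `mean_dlog_cv`, failed rows last), `counts` (named vector:
#'   `n_datasets`, `n_failed`, `n_negative`, `n_positive`, and
#'   `n_pp_gt_<threshold>`), `pp_thresholds`, `master_seed`.
#' @export
analyze_collection <- function(configs, master_seed = 1,
                               littermates_only = FALSE, out_file = NULL,
                               ...) {
  if (!length(configs)) stop("need at least 1 dataset config")
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    if (inherits(cf, "sim_result")) cf <- list(input = cf$dataset)
    if (inherits(cf, "expression_dataset")) cf <- list(input = cf)
    label <- cf$label
    if (is.null(label))
      label <- if (is.character(cf$input)) basename(cf$input)
               else sprintf("dataset_%02d", i)
    littermate <- isTRUE(cf$littermate)
    rows[[i]] <- tryCatch(
      collection_row(
        analyze_dataset(cf$input, groups = cf$groups,
                        seed = master_seed + i, ...),
        label = label, littermate = littermate),
      error = function(e) failed_row(label, littermate, conditionMessage(e))
    )
  }
  tab <- do.call(rbind, rows)
  if (littermates_only) tab <- tab[tab$littermate, , drop = FALSE]
  ok <- !tab$failed
  tab <- rbind(tab[ok, , drop = FALSE][order(tab$mean_dlog_cv[ok]), ,
                                       drop = FALSE],
               tab[!ok, , drop = FALSE])
  rownames(tab) <- NULL
  pp_thresholds <- c(1.301, 3, 7, 10, 100)
  counts <- c(
    n_datasets = nrow(tab), n_failed = sum(tab$failed),
    n_negative = sum(tab$mean_dlog_cv < 0, na.rm = TRUE),
    n_positive = sum(tab$mean_dlog_cv > 0, na.rm = TRUE),
    setNames(vapply(pp_thresholds,
                    function(th) sum(tab$pp > th, na.rm = TRUE), integer(1)),
             sprintf("n_pp_gt_%g", pp_thresholds))
  )
  if (!is.null(out_file))
    write.table(tab, out_file, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(table = tab, counts = counts,
                 pp_thresholds = pp_thresholds, master_seed = master_seed),
            class = "cvdelta_collection")
}

#' @export
print.cvdelta_collection <- function(x, ...) {
  cat("CV-shift collection:", x$counts[["n_datasets"]], "datasets (",
      x$counts[["n_failed"]], "failed )\n")
  cat(sprintf("  variability decreased in %d, increased in %d\n",
              x$counts[["n_negative"]], x$counts[["n_positive"]]))
  for (th in x$pp_thresholds)
    cat(sprintf("  pp > %-6g (p < %.3g): %d datasets\n", th, 10^-th,
                x$counts[[sprintf("n_pp_gt_%g", th)]]))
  tab <- x$table
  for (col in c("mean_dlog_cv", "sem", "fold_change", "median_dlog_cv"))
    tab[[col]] <- round(tab[[col]], 4)
  tab$pp <- round(tab$pp, 2)
  print(tab[, c("dataset", "n_analyzed", "mean_dlog_cv", "sem",
                "fold_change", "pp", "median_dlog_cv", "failed")],
        row.names = FALSE)
  invisible(x)
}
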