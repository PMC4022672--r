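#' Construct an expression dataset
#'
#' The package's basic container: a probe-by-sample matrix of nonnegative
#' intensities with optional wild-type/knockout group labels. Probe and
#' sample identifiers are carried as the matrix dimnames and must be unique.
#'
#' @param values Numeric matrix, rows = probe sets, columns = samples, with
#'   rownames (probe identifiers) and colnames (sample identifiers).
#' @param group Optional named character vector mapping sample id to
#'   `"WT"` or `"KO"`. `NULL` leaves the dataset ungrouped (as when freshly
#'   read from a GEO Series Matrix file).
#' @param source Free-text provenance, e.g. a file path or `"synthetic:<seed>"`.
#' @param metadata Optional named list of extra provenance (e.g. the
#'   `!Sample_title` lines of a Series Matrix file) kept for manual group
#'   assignment.
#' @return An object of class `"expression_dataset"`.
#' @seealso [assign_groups()], [validate_dataset()], [cv_delta()]
#' @export
expression_dataset <- function(values, group = NULL, source = "unknown",
                               metadata = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("`values` must have rownames (probe ids) and colnames (sample ids)")
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicated probe id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  if (!is.null(group)) {
    group <- validate_group_map(group, sample_ids)
    group <- group[sample_ids[sample_ids %in% names(group)]]
  }
  structure(
    list(values = values, group = group, source = source, metadata = metadata),
    class = "expression_dataset"
  )
}

validate_group_map <- function(group, sample_ids) {
  if (is.null(names(group)) || any(names(group) == ""))
    stop("group mapping must be a named vector (names = sample ids)")
  group <- vapply(group, as.character, character(1))
  bad <- setdiff(unique(group), c("WT", "KO"))
  if (length(bad))
    stop("group labels must be \"WT\" or \"KO\"; found: ",
         paste(bad, collapse = ", "))
  unknown <- setdiff(names(group), sample_ids)
  if (length(unknown))
    stop("group mapping references unknown sample id(s): ",
         paste(unknown, collapse = ", "))
  group
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset:", nrow(x$values), "probe sets x",
      ncol(x$values), "samples\n")
  cat("  source:", x$source, "\n")
  if (is.null(x$group)) {
    cat("  ungrouped (use assign_groups() to label WT/KO samples)\n")
  } else {
    cat(sprintf("  groups: WT n=%d, KO n=%d\n",
                sum(x$group == "WT"), sum(x$group == "KO")))
  }
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  missing values:", n_na, "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Is the dataset grouped?
#' @param x An [expression_dataset()].
#' @return Logical scalar.
#' @export
is_grouped <- function(x) {
  stopifnot(inherits(x, "expression_dataset"))
  !is.null(x$group)
}

# Values restricted to one group, samples in dataset column order.
group_values <- function(x, group) {
  stopifnot(is_grouped(x))
  ids <- names(x$group)[x$group == group]
  x$values[, ids, drop = FALSE]
}

#' Assign WT/KO group labels to samples
#'
#' Attaches an explicit sample-to-group mapping. Samples present in the
#' dataset but absent from the mapping are dropped with a message: GEO series
#' often bundle extra conditions (heterozygotes, treatments) beyond the
#' knockout/wild-type comparison. Group labels are never inferred from sample
#' titles; free-text GEO annotation is too unreliable for silent inference.
#'
#' @param x An [expression_dataset()].
#' @param mapping Named character vector, `sample_id = "WT"` or `"KO"`.
#' @return A grouped `expression_dataset` containing only the mapped samples.
#' @export
assign_groups <- function(x, mapping) {
  stopifnot(inherits(x, "expression_dataset"))
  sample_ids <- colnames(x$values)
  mapping <- validate_group_map(mapping, sample_ids)
  keep <- sample_ids[sample_ids %in% names(mapping)]
  dropped <- setdiff(sample_ids, keep)
  if (length(dropped))
    message("assign_groups: dropping ", length(dropped),
            " sample(s) absent from the mapping: ",
            paste(dropped, collapse = ", "))
  for (g in c("WT", "KO"))
    if (!any(mapping[keep] == g))
      stop("group ", g, " would be empty after assignment")
  expression_dataset(x$values[, keep, drop = FALSE], group = mapping[keep],
                     source = x$source, metadata = x$metadata)
}

#' Apply the dataset-validity screens
#'
#' Two screens decide whether a dataset is usable: (i) the matrix must be
#' essentially free of negative intensities (negative processed values signal
#' an incompatible preprocessing; the default tolerance is zero), and (ii)
#' each group must have at least `min_replicates` biological replicates so
#' that per-probe SD and CV are estimated with usable precision.
#'
#' The check is a pure predicate: the dataset is never modified.
#'
#' @param x A grouped [expression_dataset()].
#' @param max_negative_fraction Maximum tolerated fraction of negative matrix
#'   cells (over all cells). Default 0.
#' @param min_replicates Minimum replicates per group. Default 4.
#' @return An object of class `"validation_report"`: fields `n_probes`,
#'   `n_samples_per_group`, `negative_fraction`, `passed`, `reasons`.
#' @export
validate_dataset <- function(x, max_negative_fraction = 0, min_replicates = 4) {
  stopifnot(inherits(x, "expression_dataset"))
  if (!is_grouped(x))
    stop("dataset is ungrouped; assign_groups() first")
  n_per_group <- c(WT = sum(x$group == "WT"), KO = sum(x$group == "KO"))
  neg_frac <- sum(x$values < 0, na.rm = TRUE) / length(x$values)
  reasons <- character(0)
  if (neg_frac > max_negative_fraction)
    reasons <- c(reasons, sprintf(
      "negative values: %.1f%% of cells are negative (max allowed %.1f%%)",
      100 * neg_frac, 100 * max_negative_fraction))
  if (any(n_per_group < min_replicates))
    reasons <- c(reasons, sprintf(
      "replicates: group sizes WT=%d, KO=%d below minimum %d",
      n_per_group[["WT"]], n_per_group[["KO"]], min_replicates))
  structure(
    list(n_probes = nrow(x$values), n_samples_per_group = n_per_group,
         negative_fraction = neg_frac, passed = length(reasons) == 0L,
         reasons = reasons),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Dataset validation:", if (x$passed) "PASSED" else "FAILED", "\n")
  cat(sprintf("  %d probe sets; WT n=%d, KO n=%d; %.2f%% negative cells\n",
              x$n_probes, x$n_samples_per_group[["WT"]],
              x$n_samples_per_group[["KO"]], 100 * x$negative_fraction))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}
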