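#' Read a GEO Series Matrix file
#'
#' Parses the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a Series Matrix export: first header row = sample accessions,
#' first column = probe-set identifiers. Cells may be quoted or unquoted;
#' `"null"`, `"NA"` and empty cells become missing values (`NA`), never zero.
#' `!Sample_title` and `!Sample_characteristics_ch1` metadata lines are
#' retained in the result's `metadata` so groups can be assigned by reading
#' the series annotation; the dataset is returned ungrouped.
#'
#' @param path Path to a Series Matrix text file (uncompressed).
#' @return An ungrouped [expression_dataset()].
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("malformed Series Matrix file: no complete ",
         "!series_matrix_table_begin/!series_matrix_table_end block in ",
         path,
         if (length(begin)) paste0(" (begin at line ", begin[1], ")") else
           " (begin marker missing)")
  meta_keys <- c("!Sample_title", "!Sample_geo_accession",
                 "!Sample_characteristics_ch1")
  metadata <- list()
  for (k in meta_keys) {
    hits <- lines[startsWith(lines, k)]
    if (length(hits))
      metadata[[sub("^!", "", k)]] <-
        unquote_cells(strsplit(hits[1], "\t", fixed = TRUE)[[1]][-1])
  }

  table_lines <- lines[(begin + 1L):(end - 1L)]
  cells <- strsplit(table_lines, "\t", fixed = TRUE)
  header <- unquote_cells(cells[[1]])
  sample_ids <- header[-1]
  if (!length(sample_ids))
    stop("malformed Series Matrix table: header row at line ", begin + 1L,
         " has no sample columns")
  body <- cells[-1]
  probe_ids <- vapply(body, function(r) unquote_cells(r[1]), character(1))
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicated probe id(s) in ", path, ": ", paste(dup, collapse = ", "))
  values <- matrix(NA_real_, length(probe_ids), length(sample_ids),
                   dimnames = list(probe_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- unquote_cells(body[[i]][-1])
    if (length(row) != length(sample_ids))
      stop("malformed Series Matrix table: row for probe ", probe_ids[i],
           " (line ", begin + 1L + i, ") has ", length(row),
           " value cells, expected ", length(sample_ids))
    values[i, ] <- parse_numeric_cells(row)
  }
  expression_dataset(values, source = path, metadata = metadata)
}

unquote_cells <- function(x) gsub('^"|"$', "", x)

parse_numeric_cells <- function(x) {
  x[x %in% c("", "null", "NULL", "NA", "na")] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read a plain probe-by-sample TSV expression matrix
#'
#' Expects a header row (first column name arbitrary, remaining columns =
#' sample ids) and one row per probe set, first cell the probe identifier.
#'
#' @param path Path to a tab-separated file.
#' @return An ungrouped [expression_dataset()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", "null", ""))
  if (ncol(df) < 2L) stop("expected a probe-id column plus sample columns in ", path)
  probe_ids <- df[[1]]
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicated probe id(s) in ", path, ": ", paste(dup, collapse = ", "))
  values <- vapply(df[-1], function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(probe_ids, names(df)[-1]))
  expression_dataset(values, source = path)
}

#' Write an expression dataset as TSV
#'
#' Inverse of [read_expression_tsv()]; values are written with 17 significant
#' digits so that a read-back reproduces every double bit-exactly.
#'
#' @param x An [expression_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_dataset"))
  v <- x$values
  txt <- matrix(sprintf("%.17g", v), nrow(v))
  txt[is.na(v)] <- "NA"
  header <- paste(c("probe_id", colnames(v)), collapse = "\t")
  rows <- paste(rownames(v), apply(txt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample-to-group mapping from a YAML or JSON config
#'
#' The config is a flat mapping keyed by sample accession, values `WT`/`KO`:
#' ```yaml
#' GSM570001: WT
#' GSM570002: KO
#' ```
#'
#' @param path Path to a YAML (or JSON) file.
#' @return Named character vector suitable for [assign_groups()].
#' @export
read_group_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read group-mapping configs")
  raw <- yaml::read_yaml(path)
  if (!length(raw) || is.null(names(raw)))
    stop("group-mapping config must be a mapping of sample id to WT/KO")
  vapply(raw, as.character, character(1))
}
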