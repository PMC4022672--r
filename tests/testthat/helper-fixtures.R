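# Build a grouped dataset directly from WT/KO replicate matrices.
make_dataset <- function(wt, ko, probe_ids = NULL) {
  n <- nrow(wt)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%03d", seq_len(n))
  values <- cbind(wt, ko)
  wt_ids <- sprintf("W%d", seq_len(ncol(wt)))
  ko_ids <- sprintf("K%d", seq_len(ncol(ko)))
  dimnames(values) <- list(probe_ids, c(wt_ids, ko_ids))
  expression_dataset(values,
                     group = setNames(rep(c("WT", "KO"),
                                          c(ncol(wt), ncol(ko))),
                                      c(wt_ids, ko_ids)),
                     source = "fixture")
}

# A dataset where every probe's replicates are an explicit small vector.
# rows: list of list(wt = c(...), ko = c(...))
make_dataset_rows <- function(rows, probe_ids = NULL) {
  wt <- do.call(rbind, lapply(rows, `[[`, "wt"))
  ko <- do.call(rbind, lapply(rows, `[[`, "ko"))
  make_dataset(wt, ko, probe_ids)
}

# Hand-written GEO Series Matrix fixture.
write_series_matrix_fixture <- function(path,
                                        probe_ids = c("a_at", "b_at", "c_at"),
                                        sample_ids = c("GSM1", "GSM2"),
                                        values = NULL,
                                        extra_rows = character(0)) {
  if (is.null(values))
    values <- matrix(seq_len(length(probe_ids) * length(sample_ids)),
                     nrow = length(probe_ids))
  fmt <- function(v) ifelse(is.na(v), "null", format(v))
  body <- vapply(seq_along(probe_ids), function(i)
    paste(c(sprintf('"%s"', probe_ids[i]), fmt(values[i, ])),
          collapse = "\t"), character(1))
  lines <- c(
    "!Series_title\t\"fixture series\"",
    paste(c("!Sample_title", sprintf('"sample %s"', sample_ids)),
          collapse = "\t"),
    paste(c("!Sample_geo_accession", sprintf('"%s"', sample_ids)),
          collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c('"ID_REF"', sprintf('"%s"', sample_ids)), collapse = "\t"),
    body,
    extra_rows,
    "!series_matrix_table_end"
  )
  writeLines(lines, path)
  path
}

# Independent brute-force recomputation of the dataset summary from raw
# replicate matrices: explicit formulas, no reuse of package internals.
oracle_summary <- function(wt, ko, filter = TRUE, statistic = "dlog_cv") {
  n <- nrow(wt)
  mean_of <- function(x) sum(x) / length(x)
  sd_of <- function(x) {
    m <- mean_of(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  mw <- mk <- sw <- sk <- numeric(n)
  for (i in seq_len(n)) {
    mw[i] <- mean_of(wt[i, ]); sw[i] <- sd_of(wt[i, ])
    mk[i] <- mean_of(ko[i, ]); sk[i] <- sd_of(ko[i, ])
  }
  cvw <- ifelse(mw > 0, sw / mw, NA)
  cvk <- ifelse(mk > 0, sk / mk, NA)
  grand <- (rowSums(wt) + rowSums(ko)) / (ncol(wt) + ncol(ko))
  thr <- median(grand)
  pass <- mw >= thr & mk >= thr
  usable <- !is.na(cvw) & !is.na(cvk) & cvw > 0 & cvk > 0
  val <- if (statistic == "dlog_cv") log10(cvk) - log10(cvw) else cvk - cvw
  sel <- usable & (if (filter) pass else TRUE)
  v <- val[sel]
  m <- mean_of(v); s <- sd_of(v)
  t_stat <- m / (s / sqrt(length(v)))
  p <- 2 * pt(abs(t_stat), length(v) - 1, lower.tail = FALSE)
  list(threshold = thr, n_analyzed = length(v), mean = m,
       sem = s / sqrt(length(v)), median = median(v), t_stat = t_stat,
       p = p, pp = -log10(p),
       fold_change = if (statistic == "dlog_cv") 10^m else NA)
}
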