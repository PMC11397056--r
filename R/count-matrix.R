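#' Construct a count matrix
#'
#' A `count_matrix` is an integer feature-by-sample matrix with unique,
#' ordered feature and sample identifiers. It is the raw unit handed to
#' every downstream stage (filtering, normalization, differential
#' abundance, co-expression).
#'
#' @param counts Numeric matrix of non-negative integers (features in rows).
#' @param feature_ids,sample_ids Optional character vectors; defaults taken
#'   from `dimnames(counts)`.
#' @return An integer matrix of class `count_matrix` with `dimnames` set.
#' @export
count_matrix <- function(counts, feature_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("count_matrix requires feature and sample identifiers")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(feature_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts must be finite and non-missing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(feature_ids, sample_ids)
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples, %s total counts\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a feature-by-sample count table
#'
#' Parses a tab-separated count table whose first column holds feature
#' identifiers and remaining columns hold per-sample integer counts.
#' Leading lines starting with `#` are ignored. The featureCounts dialect
#' (annotation columns `Chr`, `Start`, `End`, `Strand`, `Length` after the
#' id column) is detected from the header and those columns are dropped.
#'
#' @param path Path to a TSV file.
#' @return A [count_matrix].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop("no header row in ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncol_expect <- length(header)
  body <- cells[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expect)) {
    bad <- which(widths != ncol_expect)[1L]
    stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                 line_no[bad + 1L], path, widths[bad], ncol_expect))
  }
  fc_meta <- c("Chr", "Start", "End", "Strand", "Length")
  meta_cols <- which(header %in% fc_meta)
  sample_cols <- setdiff(seq_along(header)[-1L], meta_cols)
  if (length(sample_cols) == 0L) stop("no sample columns in ", path)
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop(sprintf("duplicate feature id '%s' at line %d of %s",
                 dup, line_no[which(ids == dup)[2L] + 1L], path))
  }
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(sample_cols))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][sample_cols]))
    if (anyNA(vals) || any(!is.finite(vals)))
      stop(sprintf("non-numeric count at line %d of %s", line_no[i + 1L], path))
    if (any(vals < 0))
      stop(sprintf("negative count at line %d of %s", line_no[i + 1L], path))
    if (any(vals != round(vals)))
      stop(sprintf("non-integer count at line %d of %s", line_no[i + 1L], path))
    mat[i, ] <- vals
  }
  count_matrix(mat, feature_ids = ids, sample_ids = header[sample_cols])
}

#' Write a count matrix as plain TSV
#'
#' First column `feature_id`, one column per sample; the format read back
#' by [read_counts()].
#'
#' @param cm A [count_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm), unclass(cm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `group`, `tissue`. One row per
#' (sample, tissue) membership: the same animal identifier may appear for
#' several tissues.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with character columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  df[need]
}

#' @rdname read_sample_sheet
#' @param samples Sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
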