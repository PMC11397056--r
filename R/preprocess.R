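#' Drop features with low total counts
#'
#' Retains exactly the features whose count total, summed across all
#' samples in the matrix (all groups pooled), is strictly greater than
#' `min_total`. The default of 50 reproduces the usual "> 50 reads across
#' all samples" rule for annotated small RNAs. Feature order is preserved
#' and the operation is idempotent.
#'
#' @param cm A [count_matrix].
#' @param min_total Strict lower bound on the per-feature total (default 50).
#' @return A [count_matrix] with the retained features.
#' @export
filter_low_counts <- function(cm, min_total = 50) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- rowSums(cm)
  keep <- totals > min_total
  count_matrix(unclass(cm)[keep, , drop = FALSE],
               feature_ids = rownames(cm)[keep],
               sample_ids = colnames(cm))
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample TMM scaling factors. For each sample against the
#' reference, M (log2 ratio of library-size-scaled counts) and A (average
#' log2 abundance) are formed over features with positive counts in both
#' samples; features in the upper/lower `trim_m` tail of M and `trim_a`
#' tail of A are discarded; the factor is 2 to the precision-weighted mean
#' of the remaining M values, with inverse approximate binomial variances
#' as weights. Factors are rescaled to geometric mean 1. The reference is
#' the sample whose 75th-percentile-to-library-size ratio is closest to
#' the mean of that ratio across samples.
#'
#' @param cm A [count_matrix] with at least two samples.
#' @param trim_m Fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A values trimmed from each tail (default 0.05).
#' @param reference Optional sample id to force as reference.
#' @return An object of class `norm_factors`: list with `library_sizes`,
#'   `tmm_factors` (named, geometric mean 1) and `reference_sample`.
#' @export
tmm_factors <- function(cm, trim_m = 0.30, trim_a = 0.05, reference = NULL) {
  stopifnot(inherits(cm, "count_matrix"), ncol(cm) >= 2L)
  x <- unclass(cm)
  storage.mode(x) <- "double"
  lib <- colSums(x)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  if (is.null(reference)) {
    f75 <- apply(x, 2L, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(reference, colnames(x))
    if (is.na(ref)) stop("reference sample not found: ", reference)
  }
  yr <- x[, ref]
  nr <- lib[ref]
  f <- vapply(seq_len(ncol(x)), function(s) {
    ys <- x[, s]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) {
      log_msg("sample ", colnames(x)[s],
              " shares no positive features with the reference; factor set to 1",
              level = "WARN")
      return(1)
    }
    ys <- ys[ok]; yk <- yr[ok]
    ns <- lib[s]
    m <- log2((ys / ns) / (yk / nr))
    a <- 0.5 * log2((ys / ns) * (yk / nr))
    w <- (ns - ys) / (ns * ys) + (nr - yk) / (nr * yk)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep) || sum(w[keep]) == 0) return(1)
    fac <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
    if (!is.finite(fac) || fac <= 0) 1 else fac
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  structure(list(library_sizes = lib, tmm_factors = f,
                 reference_sample = colnames(x)[ref]),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:", x$reference_sample, ")\n")
  print(round(x$tmm_factors, 4))
  invisible(x)
}

#' Counts per million on effective library sizes
#'
#' CPM of a count is `count / (library_size * tmm_factor) * 1e6`: the
#' effective library size is the column total rescaled by the sample's TMM
#' factor. With all factors equal to 1 each CPM column sums to 1e6.
#'
#' @param cm A [count_matrix].
#' @param nf A `norm_factors` object from [tmm_factors()], or `NULL` for
#'   unit factors (plain CPM).
#' @return A numeric matrix of class `expression_matrix` (untransformed CPM).
#' @export
cpm <- function(cm, nf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- unclass(cm)
  storage.mode(x) <- "double"
  lib <- colSums(x)
  fac <- rep(1, ncol(x))
  if (!is.null(nf)) {
    stopifnot(inherits(nf, "norm_factors"))
    if (!identical(names(nf$tmm_factors), colnames(x)))
      stop("normalization factors do not match the samples of the matrix")
    fac <- nf$tmm_factors
    lib <- nf$library_sizes
  }
  eff <- lib * fac
  if (any(eff <= 0)) stop("zero effective library size")
  out <- sweep(x, 2L, eff, "/") * 1e6
  class(out) <- c("expression_matrix", class(out))
  out
}

#' Inverse-hyperbolic-sine transform of a CPM matrix
#'
#' Applies `log(x + sqrt(x^2 + 1))` elementwise — the inverse hyperbolic
#' sine, a variance-stabilizing transform that behaves like `log(2x)` for
#' large x but is defined (and zero) at zero. The log base defaults to the
#' natural log, which makes the formula exactly `asinh`; base 2 or 10 can
#' be selected, which rescales values by a constant.
#'
#' @param em Numeric matrix of non-negative values (CPM).
#' @param base Log base (default `exp(1)`).
#' @return A matrix of class `expression_matrix` with transformed values.
#' @export
asinh_transform <- function(em, base = exp(1)) {
  x <- unclass(em)
  if (any(x < 0)) stop("asinh_transform is defined here only for values >= 0")
  out <- asinh(x) / log(base)
  if (!inherits(out, "expression_matrix"))
    class(out) <- c("expression_matrix", class(out))
  out
}

#' Abundance share of the top k features
#'
#' Fraction of the grand total contributed by the `k` features with the
#' largest per-feature totals; ties in totals are broken by feature id so
#' the result is deterministic.
#'
#' @param cm A [count_matrix] with positive grand total.
#' @param k Number of top features (at least 1). If `k` exceeds the number
#'   of features, all features are used (share 1) with a warning.
#' @return The share as a fraction in (0, 1].
#' @export
top_k_share <- function(cm, k) {
  stopifnot(inherits(cm, "count_matrix"), k >= 1)
  totals <- rowSums(cm)
  grand <- sum(totals)
  if (grand <= 0) stop("grand total must be positive")
  if (k > length(totals)) {
    log_msg("k = ", k, " exceeds the ", length(totals),
            " features; using all of them", level = "WARN")
    k <- length(totals)
  }
  ord <- order(-totals, rownames(cm))
  sum(totals[ord[seq_len(k)]]) / grand
}

#' Write an expression matrix as TSV
#'
#' @param em An `expression_matrix`.
#' @param path Output path.
#' @param digits Significant digits for numeric output (default 6).
#' @export
write_expression <- function(em, path, digits = 6) {
  df <- data.frame(feature_id = rownames(em),
                   signif(unclass(em), digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
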