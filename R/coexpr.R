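#' Pearson correlation with analytic p-value
#'
#' Sample Pearson r with the usual two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Perfect correlation gives a p floored at machine epsilon; an input with
#' zero variance yields `r = NA`, `p = 1` (the pair is not testable).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(list(r = NA_real_, p = 1, n = n))
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(list(r = r, p = .Machine$double.eps, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = max(p, .Machine$double.eps), n = n)
}

# Vectorized cross-correlation of rows: returns list(r, p) matrices
# (rows of a x rows of b), given matched columns.
cross_cor_p <- function(a, b) {
  n <- ncol(a)
  za <- row_standardize(a)
  zb <- row_standardize(b)
  r <- tcrossprod(za, zb) / (n - 1)
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p <- pmax(p, .Machine$double.eps)
  list(r = r, p = p)
}

row_standardize <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  (m - mu) / s
}

#' All miRNA-by-gene correlations within a stratum
#'
#' Computes the Pearson correlation and analytic p-value for every
#' (miRNA, gene) pair between two transformed expression matrices sharing
#' the same samples. Zero-variance features cannot be correlated and are
#' excluded up front (the count is logged). Matches
#' [pearson_with_p()] pair by pair.
#'
#' @param mirna_em,mrna_em `expression_matrix` objects with identical
#'   sample sets (matched by sample id; order may differ).
#' @return data.frame of class `coexpr_table`: `mirna`, `gene`, `n`, `r`,
#'   `p` (one row per pair, miRNA-major order).
#' @export
all_pairs <- function(mirna_em, mrna_em) {
  a <- unclass(mirna_em); b <- unclass(mrna_em)
  if (!setequal(colnames(a), colnames(b))) {
    only_a <- setdiff(colnames(a), colnames(b))
    only_b <- setdiff(colnames(b), colnames(a))
    stop("sample sets differ; unmatched: ",
         paste(c(only_a, only_b), collapse = ", "))
  }
  b <- b[, colnames(a), drop = FALSE]
  n <- ncol(a)
  if (n < 3L) stop("need at least 3 shared samples")
  va <- apply(a, 1L, stats::var) > 0
  vb <- apply(b, 1L, stats::var) > 0
  if (any(!va) || any(!vb))
    log_msg("excluding ", sum(!va), " miRNA and ", sum(!vb),
            " gene zero-variance features from correlation")
  a <- a[va, , drop = FALSE]; b <- b[vb, , drop = FALSE]
  cp <- cross_cor_p(a, b)
  out <- data.frame(
    mirna = rep(rownames(a), each = nrow(b)),
    gene = rep(rownames(b), times = nrow(a)),
    n = n,
    r = as.vector(t(cp$r)),
    p = as.vector(t(cp$p)),
    stringsAsFactors = FALSE)
  class(out) <- c("coexpr_table", class(out))
  out
}

#' Permutation-based empirical FDR for co-expression p-values
#'
#' Estimates, for each observed p-value threshold t, the expected number
#' of null pairs reaching p <= t by repeatedly permuting the sample
#' columns of the mRNA matrix relative to the miRNA matrix (the pairing
#' is broken; each matrix's internal correlation structure is preserved)
#' and recomputing all pair p-values. eFDR(t) is the mean null count at t
#' divided by the observed count at t, capped at 1, pooled over all pairs
#' (a per-pair null cannot resolve thresholds of order 1e-5 at feasible
#' randomization counts). Each pair receives the eFDR at its own p;
#' monotonicity in p is then enforced by a cumulative minimum from the
#' largest p downward. Ties count inclusively (p <= t), which is
#' conservative.
#'
#' @param table `coexpr_table` from [all_pairs()] on the same matrices.
#' @param mirna_em,mrna_em The matrices the table was computed from.
#' @param n_rand Number of randomizations (default 10000; the study-scale
#'   value — scale down for tests).
#' @param seed Integer seed for the permutation stream.
#' @param permute Which matrix's columns to shuffle: `"mrna"` (default)
#'   or `"mirna"`.
#' @return The table with an `efdr` column added, plus attribute
#'   `permutation_null` (list: `n_rand`, `seed`).
#' @export
empirical_fdr <- function(table, mirna_em, mrna_em, n_rand = 10000,
                          seed = NULL, permute = c("mrna", "mirna")) {
  stopifnot(inherits(table, "coexpr_table"))
  if (n_rand < 1) stop("n_rand must be at least 1")
  permute <- match.arg(permute)
  a <- unclass(mirna_em); b <- unclass(mrna_em)
  b <- b[, colnames(a), drop = FALSE]
  va <- apply(a, 1L, stats::var) > 0
  vb <- apply(b, 1L, stats::var) > 0
  a <- a[va, , drop = FALSE]; b <- b[vb, , drop = FALSE]
  n <- ncol(a)
  thr <- sort(unique(table$p))
  obs_sorted <- sort(table$p)
  n_obs_le <- findInterval(thr, obs_sorted)          # observed pairs at <= t
  null_tot <- numeric(length(thr))
  run_perms <- function() {
    for (i in seq_len(n_rand)) {
      perm <- sample.int(n)
      cp <- if (permute == "mrna") cross_cor_p(a, b[, perm, drop = FALSE])
            else cross_cor_p(a[, perm, drop = FALSE], b)
      null_tot <<- null_tot + findInterval(thr, sort(as.vector(cp$p)))
    }
  }
  if (is.null(seed)) run_perms() else with_seed(seed, run_perms())
  efdr_thr <- pmin(1, (null_tot / n_rand) / n_obs_le)
  # monotone non-decreasing in p: cumulative min from the largest p down
  efdr_thr <- rev(cummin(rev(efdr_thr)))
  table$efdr <- efdr_thr[match(table$p, thr)]
  attr(table, "permutation_null") <- list(n_rand = n_rand, seed = seed)
  table
}

#' Flag significant co-expression pairs
#'
#' `significant` is `efdr < efdr_threshold`, strictly; the default
#' threshold 4e-5 corresponds to the nominal p < 1e-5 operating point
#' used at study scale.
#'
#' @param table `coexpr_table` with the `efdr` column filled.
#' @param efdr_threshold Strict upper bound on eFDR (default 0.00004).
#' @return The table with a logical `significant` column.
#' @export
infer_significant <- function(table, efdr_threshold = 0.00004) {
  stopifnot(inherits(table, "coexpr_table"))
  if (nrow(table) > 0 && is.null(table$efdr))
    stop("efdr column not filled; run empirical_fdr() first")
  table$significant <- if (nrow(table)) table$efdr < efdr_threshold else logical(0)
  table
}

#' Co-expression analysis for one (group, tissue) stratum
#'
#' Runs the per-stratum recipe end to end: subset both count matrices to
#' the stratum's samples, TMM-normalize, CPM, asinh-transform, all-pairs
#' correlation, empirical FDR, significance flags. Strata never share
#' samples, matching a per-group, per-tissue normalization design.
#'
#' @param mirna_cm,mrna_cm Filtered [count_matrix] objects (miRNA, mRNA).
#' @param samples Sample sheet data.frame.
#' @param group,tissue Stratum selectors; miRNA samples are taken from
#'   `mirna_tissue` (default `"ULF-EV"`) in the same group.
#' @param mirna_tissue Tissue label of the miRNA matrix samples.
#' @param n_rand,seed,efdr_threshold Passed through to [empirical_fdr()]
#'   and [infer_significant()].
#' @return A `coexpr_table` with `efdr` and `significant` filled.
#' @export
coexpression_stratum <- function(mirna_cm, mrna_cm, samples, group, tissue,
                                 mirna_tissue = "ULF-EV", n_rand = 10000,
                                 seed = NULL, efdr_threshold = 0.00004) {
  mi_ids <- samples$sample_id[samples$group == group &
                                samples$tissue == mirna_tissue]
  mr_ids <- samples$sample_id[samples$group == group &
                                samples$tissue == tissue]
  ids <- intersect(intersect(mi_ids, colnames(mirna_cm)),
                   intersect(mr_ids, colnames(mrna_cm)))
  if (length(ids) < 3L)
    stop("stratum ", group, "/", tissue, " has fewer than 3 matched samples")
  sub_em <- function(cm) {
    s <- count_matrix(unclass(cm)[, ids, drop = FALSE],
                      feature_ids = rownames(cm), sample_ids = ids)
    asinh_transform(cpm(s, tmm_factors(s)))
  }
  mi <- sub_em(mirna_cm)
  mr <- sub_em(mrna_cm)
  tab <- all_pairs(mi, mr)
  tab <- empirical_fdr(tab, mi, mr, n_rand = n_rand, seed = seed)
  infer_significant(tab, efdr_threshold)
}
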