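#' Hypergeometric category enrichment
#'
#' Over-representation test of a gene set of interest against an
#' expressed-gene background. For each category with at least one
#' background gene, the upper-tail hypergeometric probability
#' P(X >= k) for X ~ Hypergeom(N, K, n) is computed, where N is the
#' background size, K the background genes in the category, n the
#' interest-set size and k the interest genes in the category. Genes
#' absent from the annotation contribute to N but to no category.
#' Family-wise error is controlled by Holm's step-down method.
#'
#' @param interest Character vector of genes of interest; must be a
#'   subset of `background`.
#' @param background Character vector of expressed genes (the universe).
#' @param ann data.frame with columns `gene`, `category_id` and
#'   optionally `category_name`.
#' @param fwer_threshold Significance bound on the Holm-adjusted value,
#'   inclusive (default 0.01).
#' @return data.frame with `category_id`, `category_name`, `k`, `K`,
#'   `n`, `N`, `p`, `fwer`, `significant`, sorted by `fwer` then `p`.
#' @export
hypergeom_enrich <- function(interest, background, ann,
                             fwer_threshold = 0.01) {
  interest <- unique(as.character(interest))
  background <- unique(as.character(background))
  stray <- setdiff(interest, background)
  if (length(stray))
    stop("interest genes missing from the background: ",
         paste(stray, collapse = ", "))
  miss <- setdiff(c("gene", "category_id"), names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (length(interest) == 0L)
    return(data.frame(category_id = character(0), category_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fwer = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  ann <- unique(ann[ann$gene %in% background,
                    intersect(c("gene", "category_id", "category_name"),
                              names(ann))])
  if (is.null(ann$category_name)) ann$category_name <- ann$category_id
  n <- length(interest)
  N <- length(background)
  sp <- split(ann$gene, ann$category_id)
  cats <- names(sp)
  K <- vapply(sp, length, integer(1L))
  k <- vapply(sp, function(g) sum(interest %in% g), integer(1L))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fwer <- holm_adjust(p)
  nm <- ann$category_name[match(cats, ann$category_id)]
  out <- data.frame(category_id = cats, category_name = nm,
                    k = k, K = K, n = n, N = N, p = p, fwer = fwer,
                    significant = fwer <= fwer_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$fwer, out$p, out$category_id), , drop = FALSE]
}

#' Holm step-down adjusted p-values
#'
#' Family-wise error rate adjustment: the i-th smallest p is multiplied
#' by (m - i + 1), a running maximum enforces monotonicity, values are
#' capped at 1 and returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` are an error.
#' @return Adjusted values, same length and order as `p`.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  adj[order(o)]
}
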