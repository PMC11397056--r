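# Independent oracles, coded from the definitions and kept separate from
# the package's own code paths. Tests compare package output against these.

options(evmirnet.quiet = TRUE)

# --- multiple testing: literal definitions ------------------------------

# BH step-up: adjusted p_(k) = min_{j >= k} min(1, m * p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    best <- Inf
    for (j in k:m) best <- min(best, m * ps[j] / j)
    adj[k] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Holm step-down: adjusted p_(k) = max_{j <= k} min(1, (m - j + 1) * p_(j))
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    worst <- -Inf
    for (j in 1:k) worst <- max(worst, (m - j + 1) * ps[j])
    adj[k] <- min(1, worst)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- Pearson r and p from the definitional formulas ---------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p)
}

# --- TMM: brute-force trim-and-weight recipe ----------------------------

# Literal re-implementation using explicit sorting rather than ranks.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- sapply(seq_len(ncol(counts)), function(s)
    unname(quantile(counts[, s], 0.75)) / lib[s])
  ref <- which.min(abs(f75 - mean(f75)))
  facs <- sapply(seq_len(ncol(counts)), function(s) {
    ok <- counts[, s] > 0 & counts[, ref] > 0
    ys <- counts[ok, s]; yr <- counts[ok, ref]
    m <- log2((ys / lib[s]) / (yr / lib[ref]))
    a <- 0.5 * log2((ys / lib[s]) * (yr / lib[ref]))
    w <- (lib[s] - ys) / (lib[s] * ys) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  })
  facs / exp(mean(log(facs)))
}

# --- conditional NB exact test: direct enumeration ----------------------

oracle_exact_p <- function(ta, tb, na, nb, phi) {
  tt <- ta + tb
  mu <- tt / (na + nb)
  a <- 0:tt
  pr <- dnbinom(a, size = na / phi, mu = na * mu) *
    dnbinom(tt - a, size = nb / phi, mu = nb * mu)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[ta + 1] * (1 + 1e-10)])
}

# --- NB likelihood-ratio test oracle (free optimization) ----------------

oracle_nb_lrt_p <- function(y, x, off, phi) {
  nll_full <- function(b) -sum(dnbinom(y, size = 1 / phi,
                                       mu = exp(off + b[1] + b[2] * x),
                                       log = TRUE))
  nll_null <- function(b0) -sum(dnbinom(y, size = 1 / phi,
                                        mu = exp(off + b0), log = TRUE))
  f <- optim(c(log(mean(y / exp(off)) + 0.01), 0), nll_full)
  n0 <- optimize(nll_null, c(-30, 30))
  stat <- max(0, 2 * (n0$objective - f$value))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# --- latent-factor pair model: independent simulation -------------------

# Loading solved numerically from the model's correlation expression
# (different route from the package's closed form).
oracle_pair_lambda <- function(rho, mu1, mu2, phi) {
  v1 <- 1 / mu1 + phi; v2 <- 1 / mu2 + phi
  f <- function(l) l^2 / sqrt((l^2 + v1) * (l^2 + v2)) - abs(rho)
  uniroot(f, c(1e-6, 50))$root
}

# Realized asinh-CPM correlation of one planted pair at large n.
oracle_pair_realized_r <- function(rho, mu1, mu2, phi, n = 20000) {
  l <- oracle_pair_lambda(rho, mu1, mu2, phi)
  z <- rnorm(n)
  y1 <- rnbinom(n, size = 1 / phi, mu = mu1 * exp(l * z))
  y2 <- rnbinom(n, size = 1 / phi, mu = mu2 * exp(sign(rho) * l * z))
  cor(asinh(y1), asinh(y2))
}

# --- small fixture builders ---------------------------------------------

toy_counts <- function(mat, features = NULL, samples = NULL) {
  features <- features %||% sprintf("f%d", seq_len(nrow(mat)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(mat)))
  count_matrix(mat, features, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_group_sheet <- function(cm, na, nb, groups = c("A", "B")) {
  data.frame(sample_id = colnames(cm),
             group = rep(groups, c(na, nb)),
             tissue = "ULF-EV", stringsAsFactors = FALSE)
}
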