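test_that("read_counts parses plain and featureCounts dialects identically", {
  mat <- matrix(c(5L, 0L, 12L, 7L, 3L, 9L), nrow = 3,
                dimnames = list(c("bta-mir-1", "bta-mir-2", "bta-mir-3"),
                                c("s1", "s2")))
  plain <- tempfile(fileext = ".tsv")
  writeLines(c("# produced by a counting tool",
               "feature_id\ts1\ts2",
               paste(rownames(mat), mat[, 1], mat[, 2], sep = "\t")), plain)
  fc <- tempfile(fileext = ".tsv")
  writeLines(c("# Program:featureCounts",
               "Geneid\tChr\tStart\tEnd\tStrand\tLength\ts1\ts2",
               paste(rownames(mat), "1", "10", "90", "+", "81",
                     mat[, 1], mat[, 2], sep = "\t")), fc)
  a <- read_counts(plain)
  b <- read_counts(fc)
  expect_identical(unclass(a), unclass(b))
  expect_identical(unname(unclass(a)), unname(mat))
  expect_identical(rownames(a), rownames(mat))
})

test_that("read_counts rejects malformed input with line numbers", {
  bad <- tempfile()
  writeLines(c("feature_id\ts1", "f1\t3", "f1\t4"), bad)
  expect_error(read_counts(bad), "duplicate feature id")
  writeLines(c("feature_id\ts1", "f1\t3\t9"), bad)
  expect_error(read_counts(bad), "ragged row at line 2")
  writeLines(c("feature_id\ts1", "f1\t-2"), bad)
  expect_error(read_counts(bad), "negative count at line 2")
  writeLines(c("feature_id\ts1", "f1\t2.5"), bad)
  expect_error(read_counts(bad), "non-integer count at line 2")
})

test_that("count TSV round-trips losslessly", {
  cm <- toy_counts(matrix(rpois(12, 20), 4))
  path <- tempfile()
  write_counts(cm, path)
  expect_identical(unclass(read_counts(path)), unclass(cm))
})

test_that("filter_low_counts applies the strict >50 rule and is idempotent", {
  cm <- toy_counts(rbind(c(26, 25),    # total 51: kept
                         c(25, 25),    # total 50: dropped
                         c(0, 0),      # dropped
                         c(20, 40)),   # kept
                   features = c("keep51", "drop50", "zero", "keep60"))
  f <- filter_low_counts(cm)
  expect_identical(rownames(f), c("keep51", "keep60"))
  expect_identical(unclass(filter_low_counts(f)), unclass(f))
  # counts [20,20,20] total 60: retained
  cm3 <- toy_counts(matrix(c(20L, 20L, 20L), 1))
  expect_identical(nrow(filter_low_counts(cm3)), 1L)
  # all-zero matrix: empty result allowed
  expect_identical(nrow(filter_low_counts(toy_counts(matrix(0L, 3, 2)))), 0L)
})

test_that("tmm_factors is 1 for identical or purely rescaled columns", {
  x <- rpois(500, 50) + 1L
  same <- toy_counts(cbind(x, x))
  expect_equal(unname(tmm_factors(same)$tmm_factors), c(1, 1))
  doubled <- toy_counts(cbind(x, 2L * x))
  expect_equal(unname(tmm_factors(doubled)$tmm_factors), c(1, 1),
               tolerance = 1e-12)
})

test_that("tmm_factors matches the brute-force trim-and-weight oracle", {
  set.seed(402)
  base <- rpois(1100, 100) + 1L
  a <- rpois(1100, base)
  b <- rpois(1100, base)
  b[1:100] <- rpois(100, base[1:100] * 10)  # asymmetric composition
  c_ <- rpois(1100, base)
  cm <- toy_counts(cbind(a, b, c_))
  got <- tmm_factors(cm)$tmm_factors
  want <- oracle_tmm(cbind(a, b, c_))
  expect_equal(unname(got), unname(want), tolerance = 1e-8)
  expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
})

test_that("tmm_factors recovers unit factors under library-size shifts", {
  set.seed(77)
  mu <- rexp(2000, 1 / 100)
  counts <- sapply(c(0.5, 1, 2, 4), function(s) rpois(2000, mu * s))
  # composition-neutral: Poisson noise only, expect factors ~1
  f <- tmm_factors(toy_counts(counts))$tmm_factors
  expect_true(all(abs(f - 1) < 0.02))
  # exact multiples: factors 1 to numerical precision
  f2 <- tmm_factors(toy_counts(cbind(mu2 <- rpois(500, 200) + 1L,
                                     3L * mu2, 7L * mu2)))$tmm_factors
  expect_true(all(abs(f2 - 1) < 1e-6))
})

test_that("tmm_factors agrees with the reference edgeR implementation", {
  set.seed(5)
  mu <- rpois(1200, 80) + 1L
  x <- cbind(a = rpois(1200, mu),
             b = rpois(1200, mu * rep(c(8, 1), c(150, 1050))),
             c = rpois(1200, 2 * mu), d = rpois(1200, mu))
  mine <- tmm_factors(count_matrix(x, sprintf("f%d", 1:1200),
                                   colnames(x)))$tmm_factors
  theirs <- edgeR::calcNormFactors(x, method = "TMM")
  expect_equal(unname(mine), unname(theirs), tolerance = 0.01)
})

test_that("cpm evaluates the stated formula and columns sum to 1e6", {
  cm <- toy_counts(matrix(c(4L, 0L, 1999996L, 0L, 10L, 999990L), ncol = 2))
  plain <- cpm(cm)
  expect_equal(plain[1, 1], 2.0)   # 4 / 2e6 * 1e6
  expect_equal(plain[2, 1], 0.0)
  expect_equal(unname(colSums(plain)), c(1e6, 1e6))
  # explicit factor: count 10, library 1e6, factor 2 -> 5
  nf <- structure(list(library_sizes = c(s1 = 2e6, s2 = 1e6),
                       tmm_factors = c(s1 = 1, s2 = 2),
                       reference_sample = "s1"), class = "norm_factors")
  expect_equal(cpm(cm, nf)[2, 2], 10 / (1e6 * 2) * 1e6)
})

test_that("asinh_transform matches the closed form and inverts with sinh", {
  expect_identical(asinh_transform(matrix(0))[1, 1], 0)
  expect_equal(asinh_transform(matrix(1))[1, 1], log(1 + sqrt(2)),
               tolerance = 1e-10)
  expect_equal(asinh_transform(matrix(1e6))[1, 1], log(2e6),
               tolerance = 1e-6)
  x <- matrix(runif(100, 0, 1e5), 10)
  y <- asinh_transform(x)
  expect_true(all(diff(asinh_transform(matrix(sort(runif(50, 0, 100)), 1))[1, ]) >= 0))
  expect_equal(sinh(unclass(y)), unclass(x), tolerance = 1e-9)
  expect_error(asinh_transform(matrix(-1)), ">= 0")
  # configurable base rescales by a constant
  expect_equal(asinh_transform(matrix(3), base = 2)[1, 1],
               asinh(3) / log(2))
})

test_that("top_k_share sums the k largest totals deterministically", {
  cm <- toy_counts(matrix(c(90L, 5L, 5L), 3))
  expect_equal(top_k_share(cm, 1), 0.9)
  expect_equal(top_k_share(toy_counts(matrix(7L, 1, 3)), 1), 1.0)
  uniform <- toy_counts(matrix(10L, 100, 2))
  expect_equal(top_k_share(uniform, 40), 0.40)
  # k beyond the feature count: all features, share 1
  expect_equal(top_k_share(cm, 10), 1.0)
})
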