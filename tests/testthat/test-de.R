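make_nb_dataset <- function(n_feat, na, nb, phi, lfc_idx = integer(0),
                            lfc = 0, mean_range = c(50, 500)) {
  mu <- runif(n_feat, mean_range[1], mean_range[2])
  shift <- rep(1, n_feat)
  shift[lfc_idx] <- 2^lfc
  counts <- cbind(
    matrix(rnbinom(n_feat * na, size = 1 / phi, mu = mu * shift), n_feat),
    matrix(rnbinom(n_feat * nb, size = 1 / phi, mu = mu), n_feat))
  toy_counts(counts)
}

test_that("estimate_dispersions tracks the simulation truth", {
  set.seed(11)
  groups <- rep(c("A", "B"), each = 20)
  # Poisson data: phi ~ 0
  pois <- toy_counts(matrix(rpois(400 * 40, 100), 400))
  dp <- estimate_dispersions(pois, groups)
  expect_lt(median(dp$phi), 0.05)
  # NB with phi = 0.4: median raw estimate within 25%
  nb <- toy_counts(matrix(rnbinom(400 * 40, size = 1 / 0.4, mu = 100), 400))
  dn <- estimate_dispersions(nb, groups, shrink_weight = 0)
  expect_lt(abs(median(dn$phi) - 0.4) / 0.4, 0.25)
  # constant (all-zero) feature gets the common dispersion
  z <- unclass(nb); z[1, ] <- 0L
  dz <- estimate_dispersions(toy_counts(z), groups)
  expect_equal(unname(dz$phi[1]), dz$common)
})

test_that("test_exact degenerate cases give p = 1", {
  cm <- toy_counts(rbind(c(5L, 5L, 5L, 5L, 5L, 5L),  # symmetric
                         c(0L, 0L, 0L, 0L, 0L, 0L))) # all zero
  groups <- rep(c("A", "B"), each = 3)
  disp <- structure(list(phi = c(0.1, 0.1), common = 0.1,
                         shrink_weight = 0.3),
                    class = "dispersion_estimates")
  p <- test_exact(cm, groups, NULL, disp)
  expect_equal(unname(p[2]), 1)
  expect_gt(unname(p[1]), 0.99)
})

test_that("test_exact equals exhaustive conditional enumeration", {
  # library sizes equal so pseudo-totals are the raw group totals
  cases <- list(c(ta = 2, tb = 20), c(ta = 10, tb = 10), c(ta = 0, tb = 7),
                c(ta = 35, tb = 4))
  for (cs in cases) {
    # split the totals over 3 + 3 samples; equal per-sample totals keep
    # the common-library rescaling a no-op up to rounding
    split3 <- function(t) {q <- t %/% 3; c(q, q, t - 2 * q)}
    row_f <- c(split3(cs[["ta"]]), split3(cs[["tb"]]))
    cm2 <- toy_counts(rbind(row_f, 1000 - row_f),  # pad to equal libraries
                      features = c("f", "pad"))
    disp <- structure(list(phi = c(0.1, 0.1), common = 0.1,
                           shrink_weight = 0),
                      class = "dispersion_estimates")
    p <- test_exact(cm2, rep(c("A", "B"), each = 3), NULL, disp)
    expect_equal(unname(p["f"]),
                 oracle_exact_p(cs[["ta"]], cs[["tb"]], 3, 3, 0.1),
                 tolerance = 1e-10)
  }
})

test_that("test_wald finds no effect under equal means and recovers signs", {
  set.seed(21)
  eq <- make_nb_dataset(50, 6, 6, 0.1)
  groups <- rep(c("A", "B"), c(6, 6))
  disp <- estimate_dispersions(eq, groups)
  w <- test_wald(eq, groups, NULL, disp)
  expect_gt(median(w$p_wald), 0.2)
  expect_true(all(w$converged))
  # planted |log2fc| = 2 on a fifth of features, n = 7 vs 5: among the
  # planted ones the estimated sign matches the truth >= 95% of the time
  up <- 1:20; dn_ <- 21:40
  mu <- runif(200, 50, 500)
  shift <- rep(1, 200); shift[up] <- 4; shift[dn_] <- 1 / 4
  pl <- toy_counts(cbind(
    matrix(rnbinom(200 * 7, size = 10, mu = mu * shift), 200),
    matrix(rnbinom(200 * 5, size = 10, mu = mu), 200)))
  g2 <- rep(c("A", "B"), c(7, 5))
  w2 <- test_wald(pl, g2, NULL, estimate_dispersions(pl, g2))
  expect_gte(mean(c(w2$log2fc[up] > 0, w2$log2fc[dn_] < 0)), 0.95)
})

test_that("Wald p agrees with a likelihood-ratio oracle within an order", {
  set.seed(31)
  cm <- make_nb_dataset(30, 7, 5, 0.1, lfc_idx = 1:30, lfc = 2)
  groups <- rep(c("A", "B"), c(7, 5))
  disp <- estimate_dispersions(cm, groups)
  w <- test_wald(cm, groups, NULL, disp)
  off <- log(colSums(cm))
  x <- as.numeric(groups == "A")
  ok <- 0
  for (g in 1:30) {
    plrt <- oracle_nb_lrt_p(as.double(cm[g, ]), x, off, disp$phi[g])
    pw <- max(w$p_wald[g], 1e-300)
    plrt <- max(plrt, 1e-300)
    if (abs(log10(pw) - log10(plrt)) <= 1) ok <- ok + 1
  }
  expect_gte(ok / 30, 0.9)
})

test_that("bh_fdr equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("consensus_calls applies the strict both-tests conjunction", {
  feats <- c("a", "b", "c")
  wald <- data.frame(feature_id = feats, log2fc = c(2, -1, 1),
                     p_wald = c(0.2, 0.04 * 2 / 3, 0.01 / 3),
                     converged = TRUE, stringsAsFactors = FALSE)
  # choose exact p so BH-adjusted values hit the documented cases
  exact <- c(a = 0.01 / 3, b = 0.01 * 2 / 3, c = 0.05)
  res <- consensus_calls(exact, wald, alpha = 0.05)
  # a: fdr pair (0.01, 0.20) -> not DE despite one tiny fdr
  expect_false(res$consensus_de[1])
  # b: (0.01, 0.04) -> DE, direction follows log2fc
  expect_true(res$consensus_de[2])
  expect_identical(res$direction[2], -1)
  # c: fdr_exact == 0.05 exactly -> strict inequality fails
  expect_equal(res$fdr_exact[3], 0.05)
  expect_false(res$consensus_de[3])
  expect_true(all(res$fdr_exact >= res$p_exact - 1e-15))
  expect_error(consensus_calls(c(x = 0.1), wald), "aligned")
})

test_that("null simulation: consensus calls are rarer than single-test calls", {
  set.seed(55)
  fp_cons <- 0; fp_single <- 0
  for (rep in 1:3) {
    cm <- make_nb_dataset(300, 7, 5, 0.15)
    sheet <- two_group_sheet(cm, 7, 5)
    res <- de_contrast(cm, sheet, c("A", "B"))
    fp_cons <- fp_cons + sum(res$consensus_de)
    fp_single <- fp_single + min(sum(res$fdr_exact < 0.05),
                                 sum(res$fdr_wald < 0.05))
  }
  expect_lte(fp_cons, fp_single)
  expect_lte(fp_cons / (3 * 300), 0.02)  # nominal FDR control on the null
})
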