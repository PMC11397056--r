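db_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene\tregion", rows), path)
  path
}

test_that("load_target_db deduplicates, validates regions, round-trips", {
  p <- db_file(c("bta-miR-17-5p\tNPC2\t3UTR",
                 "bta-miR-17-5p\tNPC2\t3UTR",
                 "bta-miR-18a-5p\tCREG1\tCDS"))
  db <- load_target_db(p)
  expect_identical(nrow(db), 2L)
  expect_error(load_target_db(db_file("bta-miR-17-5p\tNPC2\tintron")),
               "region")
  bad <- tempfile(); writeLines("mirna\tgene\nx\ty", bad)
  expect_error(load_target_db(bad), "missing columns")
  out <- tempfile()
  write_target_db(db, out)
  expect_identical(as.data.frame(load_target_db(out)), as.data.frame(db))
})

test_that("name maps validate uniqueness and the heuristic derives arms", {
  expect_error(name_map(c("a", "b"), c("m-5p", "m-5p")),
               "more than one precursor")
  nm <- suppressMessages(default_name_map(c("bta-mir-17", "bta-mir-7-3",
                                            "MIR18A", "bta-mir-181b-2")))
  expect_setequal(nm$mature[nm$precursor == "bta-mir-17"],
                  c("bta-miR-17-5p", "bta-miR-17-3p"))
  # locus index dropped: mature of the second mir-7 locus is miR-7
  expect_true("bta-miR-7-5p" %in% nm$mature[nm$precursor == "bta-mir-7-3"])
  expect_true("bta-miR-18a-5p" %in% nm$mature[nm$precursor == "MIR18A"])
  expect_true("bta-miR-181b-5p" %in%
                nm$mature[nm$precursor == "bta-mir-181b-2"])
})

sig_row <- function(mirna, gene, r) {
  structure(data.frame(mirna = mirna, gene = gene, n = 10, r = r,
                       p = 1e-8, efdr = 0, significant = TRUE,
                       stringsAsFactors = FALSE),
            class = c("coexpr_table", "data.frame"))
}

test_that("supported_pairs keeps only negative, database-backed pairs", {
  db <- target_db(data.frame(mirna = "bta-miR-17-5p", gene = "NPC2",
                             region = "3UTR"))
  nm <- suppressMessages(default_name_map("bta-mir-17"))
  expect_identical(nrow(supported_pairs(sig_row("bta-mir-17", "NPC2", -0.9),
                                        db, nm)), 1L)
  expect_identical(nrow(supported_pairs(sig_row("bta-mir-17", "NPC2", 0.9),
                                        db, nm)), 0L)
  expect_identical(nrow(supported_pairs(sig_row("bta-mir-17", "OTHER", -0.9),
                                        db, nm)), 0L)
  # positive pairs allowed when the negativity requirement is lifted
  expect_identical(nrow(supported_pairs(sig_row("bta-mir-17", "NPC2", 0.9),
                                        db, nm, require_negative = FALSE)),
                   1L)
  # non-significant rows never pass
  tab <- sig_row("bta-mir-17", "NPC2", -0.9); tab$significant <- FALSE
  expect_identical(nrow(supported_pairs(tab, db, nm)), 0L)
})

test_that("decoy target rows never remove a supported pair", {
  set.seed(17)
  tab <- sig_row("bta-mir-17", "NPC2", -0.9)
  nm <- suppressMessages(default_name_map("bta-mir-17"))
  db1 <- target_db(data.frame(mirna = "bta-miR-17-5p", gene = "NPC2",
                              region = "3UTR"))
  decoys <- data.frame(mirna = sprintf("bta-miR-%d-5p", 100:199),
                       gene = sprintf("G%d", 100:199), region = "CDS")
  db2 <- target_db(rbind(as.data.frame(db1), decoys))
  s1 <- supported_pairs(tab, db1, nm)
  s2 <- supported_pairs(tab, db2, nm)
  expect_identical(s1$gene, s2$gene)
})

test_that("de_target_overlap intersects targets with down-regulated genes", {
  db <- target_db(data.frame(
    mirna = c("bta-miR-17-5p", "bta-miR-17-5p", "bta-miR-18a-3p"),
    gene = c("G1", "G2", "G2"), region = "3UTR"))
  nm <- suppressMessages(default_name_map(c("bta-mir-17", "MIR18A")))
  ov <- de_target_overlap(c("bta-mir-17", "MIR18A"), c("G2", "G3"), db, nm)
  expect_identical(ov$gene, "G2")
  expect_identical(ov$n_mirnas, 2L)
  expect_identical(nrow(de_target_overlap(character(0), c("G1"), db, nm)), 0L)
})

test_that("target coverage of recovered planted pairs approaches the config", {
  # coverage c = 0.6 of planted negative pairs appear in the table, so the
  # supported fraction among all planted pairs should match c exactly here
  ds <- generate_dataset(synthetic_config(
    n_samples_per_group = c(AI = 10), n_mirna = 50, n_mrna = 50, n_de = 0,
    n_pairs = 20, pair_rho = -0.9, target_db_coverage = 0.6,
    decoy_targets = 100, mrna_tissues = "EET",
    no_conceptus_groups = character(0), feature_log_sd = 1, seed = 29))
  pp <- ds$truth$planted_pairs
  tab <- structure(data.frame(mirna = pp$mirna, gene = pp$gene, n = 10,
                              r = -0.9, p = 1e-9, efdr = 0,
                              significant = TRUE, stringsAsFactors = FALSE),
                   class = c("coexpr_table", "data.frame"))
  sp <- supported_pairs(tab, ds$targets, ds$nmap)
  expect_identical(nrow(sp), as.integer(round(0.6 * 20)))
})
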