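#' Configuration for the synthetic dataset generator
#'
#' Captures the stated world the generator emulates: negative-binomial
#' counts with heterogeneous library sizes, a minority of miRNAs
#' differentially abundant between groups, a minority of (miRNA, gene)
#' pairs sharing a latent per-animal factor that induces correlation of
#' configurable sign and magnitude on the transformed-CPM scale, and a
#' predicted-target table covering a configurable fraction of the planted
#' negative pairs.
#'
#' Defaults mirror the study design the generator stands in for: groups
#' AI (n = 7), IVP-ET (n = 7), NCP (n = 5); 263 annotated miRNAs. The
#' group listed first carries all planted differential abundance; the
#' group listed last is treated as the baseline for truth labels. Groups
#' named in `no_conceptus_groups` contribute no conceptus-derived (EET)
#' mRNA samples.
#'
#' @param n_samples_per_group Named integer vector, group -> sample count.
#' @param n_mirna,n_mrna Feature counts for the two matrices.
#' @param baseline_mean Median expected count at library size 1e6.
#' @param feature_log_sd Log-normal spread (sd of natural log) of
#'   per-feature baseline means; 2 gives the strong dominance of a few
#'   species typical of small-RNA libraries.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2).
#' @param libsize_log_sd Log-normal sd of library sizes around 1e6.
#' @param n_de Number of planted differentially abundant miRNAs.
#' @param de_log2fc Absolute planted log2 fold change (signs alternate).
#' @param n_pairs Number of planted co-expressed (miRNA, gene) pairs.
#' @param pair_rho Target latent correlation on the asinh-CPM scale,
#'   in (-1, 1); the sign is the sign of the planted correlation.
#' @param target_db_coverage Fraction of planted negative pairs included
#'   in the synthetic target table.
#' @param decoy_targets Number of random non-planted target rows.
#' @param pair_tissue mRNA tissue that hosts the planted pairs.
#' @param mrna_tissues Tissues to generate mRNA matrices for.
#' @param no_conceptus_groups Groups lacking conceptus tissue (no EET).
#' @param n_categories Number of annotation categories.
#' @param seed Master seed; all streams derive from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples_per_group = c(AI = 7, `IVP-ET` = 7,
                                                     NCP = 5),
                             n_mirna = 263, n_mrna = 500,
                             baseline_mean = 200, feature_log_sd = 2,
                             dispersion = 0.2, libsize_log_sd = 0.4,
                             n_de = 20, de_log2fc = 2,
                             n_pairs = 25, pair_rho = -0.8,
                             target_db_coverage = 0.6, decoy_targets = 200,
                             pair_tissue = "EET",
                             mrna_tissues = c("EET", "CAR", "ICAR"),
                             no_conceptus_groups = "NCP",
                             n_categories = 25, seed = 1) {
  cfg <- list(n_samples_per_group = n_samples_per_group, n_mirna = n_mirna,
              n_mrna = n_mrna, baseline_mean = baseline_mean,
              feature_log_sd = feature_log_sd, dispersion = dispersion,
              libsize_log_sd = libsize_log_sd, n_de = n_de,
              de_log2fc = de_log2fc, n_pairs = n_pairs, pair_rho = pair_rho,
              target_db_coverage = target_db_coverage,
              decoy_targets = decoy_targets, pair_tissue = pair_tissue,
              mrna_tissues = mrna_tissues,
              no_conceptus_groups = no_conceptus_groups,
              n_categories = n_categories, seed = seed)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, why) stop("invalid config field '", field, "': ",
                                    why, call. = FALSE)
  g <- cfg$n_samples_per_group
  if (is.null(names(g)) || any(names(g) == ""))
    fail("n_samples_per_group", "groups must be named")
  if (any(g < 2)) fail("n_samples_per_group",
                       "each group needs at least 2 samples")
  for (f in c("n_mirna", "n_mrna", "n_de", "n_pairs", "decoy_targets",
              "n_categories"))
    if (cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      fail(f, "must be a non-negative integer")
  if (cfg$baseline_mean <= 0) fail("baseline_mean", "must be positive")
  if (cfg$dispersion <= 0) fail("dispersion", "must be positive")
  if (cfg$libsize_log_sd < 0) fail("libsize_log_sd", "must be non-negative")
  if (cfg$feature_log_sd < 0) fail("feature_log_sd", "must be non-negative")
  if (abs(cfg$pair_rho) >= 1) fail("pair_rho", "must lie strictly in (-1, 1)")
  if (cfg$target_db_coverage < 0 || cfg$target_db_coverage > 1)
    fail("target_db_coverage", "must lie in [0, 1]")
  if (cfg$n_de > cfg$n_mirna) fail("n_de", "cannot exceed n_mirna")
  if (cfg$n_pairs > 0 && cfg$n_mrna == 0)
    fail("n_pairs", "needs n_mrna > 0")
  if (cfg$n_pairs > min(cfg$n_mirna, max(cfg$n_mrna, 1)))
    fail("n_pairs",
         "cannot exceed min(n_mirna, n_mrna): pairs use disjoint features")
  if (cfg$n_pairs > 0 && !(cfg$pair_tissue %in% cfg$mrna_tissues))
    fail("pair_tissue", "must be one of mrna_tissues")
  invisible(cfg)
}

# Latent-factor loading for a planted pair, by the delta method: the
# asinh-CPM value of an NB count with log-mean shifted by lambda * Z is
# approximately lambda * Z + noise with Var(noise) ~ 1/mu + phi, so the
# pair correlation is lambda^2 / sqrt((lambda^2 + v1)(lambda^2 + v2)).
# Solving for lambda^2 gives a quadratic.
lambda_for_rho <- function(rho, mu1, mu2, phi) {
  r2 <- rho^2
  if (r2 == 0) return(0)
  v1 <- 1 / mu1 + phi
  v2 <- 1 / mu2 + phi
  a <- 1 - r2
  b <- -r2 * (v1 + v2)
  cc <- -r2 * v1 * v2
  u <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  sqrt(u)
}

#' Generate a synthetic multi-tissue dataset with known ground truth
#'
#' Draws a miRNA count matrix (uterine-fluid EV samples, all groups), one
#' mRNA count matrix per tissue (the EET matrix omits groups named in
#' `no_conceptus_groups`, which have no conceptus to sample), a sample
#' sheet, a predicted-target table and a category annotation, together
#' with the ground truth of all planted effects.
#'
#' Counts are NB(mu, phi) with
#' `log mu = log(base mean) + DE shift + lambda * Z + log(N_s / 1e6)`:
#' the DE shift (`sign * de_log2fc` in log2) applies to planted miRNAs in
#' the first group only; Z is a standard-normal latent factor per planted
#' pair and animal, shared between the pair's miRNA (loading +lambda) and
#' gene (loading `sign(pair_rho) * lambda`), with lambda calibrated by a
#' delta-method moment match so the realized asinh-CPM correlation
#' approaches `pair_rho`. Each output matrix draws from its own RNG
#' stream derived from the master seed, so adding tissues never perturbs
#' existing matrices; identical config gives bit-identical output.
#'
#' @param config A [synthetic_config].
#' @return list of class `ev_dataset`: `mirna` ([count_matrix]), `mrna`
#'   (named list of [count_matrix] per tissue), `samples` (sample sheet),
#'   `targets` ([target_db]), `annotation`, `nmap` ([name_map]) and
#'   `truth` (list: `de_features`, `planted_pairs`,
#'   `true_libsize_factors`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  cfg <- config
  groups <- names(cfg$n_samples_per_group)
  animals <- unlist(lapply(groups, function(g)
    sprintf("%s_%d", g, seq_len(cfg$n_samples_per_group[[g]]))))
  animal_group <- rep(groups, times = unlist(cfg$n_samples_per_group))
  n_anim <- length(animals)

  mirna_ids <- sprintf("bta-mir-%03d", seq_len(cfg$n_mirna))
  gene_ids <- if (cfg$n_mrna > 0) sprintf("GENE%04d", seq_len(cfg$n_mrna))
              else character(0)

  base_mu <- with_seed(substream_seed(cfg$seed, "features"), {
    list(mirna = stats::rlnorm(cfg$n_mirna, log(cfg$baseline_mean),
                               cfg$feature_log_sd),
         mrna = stats::rlnorm(cfg$n_mrna, log(cfg$baseline_mean),
                              cfg$feature_log_sd))
  })

  truth <- with_seed(substream_seed(cfg$seed, "truth"), {
    de_idx <- if (cfg$n_de > 0) sort(sample.int(cfg$n_mirna, cfg$n_de))
              else integer(0)
    de_sign <- if (cfg$n_de > 0) rep_len(c(1, -1), cfg$n_de) else integer(0)
    pool <- setdiff(seq_len(cfg$n_mirna), de_idx)
    if (length(pool) < cfg$n_pairs) pool <- seq_len(cfg$n_mirna)
    pair_mi <- if (cfg$n_pairs > 0) sort(sample(pool, cfg$n_pairs))
               else integer(0)
    pair_ge <- if (cfg$n_pairs > 0) sort(sample.int(cfg$n_mrna, cfg$n_pairs))
               else integer(0)
    list(de_idx = de_idx, de_sign = de_sign,
         pair_mi = pair_mi, pair_ge = pair_ge)
  })

  lambda <- if (cfg$n_pairs > 0)
    vapply(seq_len(cfg$n_pairs), function(i)
      lambda_for_rho(cfg$pair_rho, base_mu$mirna[truth$pair_mi[i]],
                     base_mu$mrna[truth$pair_ge[i]], cfg$dispersion),
      numeric(1L))
  else numeric(0)
  gene_loading_sign <- sign(cfg$pair_rho)

  z <- if (cfg$n_pairs > 0)
    with_seed(substream_seed(cfg$seed, "latent"),
              matrix(stats::rnorm(cfg$n_pairs * n_anim), cfg$n_pairs, n_anim,
                     dimnames = list(NULL, animals)))
  else matrix(0, 0, n_anim, dimnames = list(NULL, animals))

  draw_matrix <- function(label, feature_ids, mu_base, anim_idx,
                          log_shift_fun) {
    ids <- animals[anim_idx]
    with_seed(substream_seed(cfg$seed, label), {
      libsizes <- stats::rlnorm(length(ids), log(1e6), cfg$libsize_log_sd)
      mu <- outer(mu_base, libsizes / 1e6)
      mu <- mu * exp(log_shift_fun(anim_idx))
      counts <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$dispersion,
                                      mu = mu),
                       nrow = length(feature_ids))
      list(cm = count_matrix(counts, feature_ids, ids),
           libsizes = stats::setNames(libsizes, ids))
    })
  }

  # miRNA matrix: DE shift in the first group + latent loadings
  first_group <- groups[1L]
  mirna_shift <- function(anim_idx) {
    sh <- matrix(0, cfg$n_mirna, length(anim_idx))
    in_a <- animal_group[anim_idx] == first_group
    if (cfg$n_de > 0 && any(in_a))
      sh[truth$de_idx, in_a] <- sh[truth$de_idx, in_a] +
        truth$de_sign * cfg$de_log2fc * log(2)
    if (cfg$n_pairs > 0)
      sh[truth$pair_mi, ] <- sh[truth$pair_mi, ] +
        lambda * z[, anim_idx, drop = FALSE]
    sh
  }
  mi <- draw_matrix("matrix:mirna", mirna_ids, base_mu$mirna,
                    seq_len(n_anim), mirna_shift)

  mrna <- list()
  mrna_lib <- list()
  for (tis in if (cfg$n_mrna > 0) cfg$mrna_tissues else character(0)) {
    anim_idx <- if (tis == "EET")
      which(!(animal_group %in% cfg$no_conceptus_groups))
    else seq_len(n_anim)
    shift_fun <- function(ai) {
      sh <- matrix(0, cfg$n_mrna, length(ai))
      if (cfg$n_pairs > 0 && tis == cfg$pair_tissue)
        sh[truth$pair_ge, ] <- sh[truth$pair_ge, ] +
          gene_loading_sign * lambda * z[, ai, drop = FALSE]
      sh
    }
    m <- draw_matrix(paste0("matrix:mrna:", tis), gene_ids, base_mu$mrna,
                     anim_idx, shift_fun)
    mrna[[tis]] <- m$cm
    mrna_lib[[tis]] <- m$libsizes
  }

  samples <- rbind(
    data.frame(sample_id = animals, group = animal_group, tissue = "ULF-EV",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(mrna), function(tis)
      data.frame(sample_id = colnames(mrna[[tis]]),
                 group = animal_group[match(colnames(mrna[[tis]]), animals)],
                 tissue = tis, stringsAsFactors = FALSE))))

  nmap <- suppressMessages(default_name_map(mirna_ids))

  targets <- with_seed(substream_seed(cfg$seed, "targets"), {
    rows <- list()
    planted_mi <- mirna_ids[truth$pair_mi]
    planted_ge <- gene_ids[truth$pair_ge]
    neg <- which(rep(cfg$pair_rho, cfg$n_pairs) < 0)
    n_cover <- round(cfg$target_db_coverage * length(neg))
    covered <- if (n_cover > 0) sort(sample(neg, n_cover)) else integer(0)
    if (length(covered))
      rows$planted <- data.frame(
        mirna = primary_mature(planted_mi[covered], nmap),
        gene = planted_ge[covered],
        region = sample(c("3UTR", "5UTR", "CDS"), length(covered),
                        replace = TRUE, prob = c(0.6, 0.1, 0.3)),
        stringsAsFactors = FALSE)
    if (cfg$decoy_targets > 0 && cfg$n_mrna > 0) {
      di <- sample.int(cfg$n_mirna, cfg$decoy_targets, replace = TRUE)
      dg <- sample.int(cfg$n_mrna, cfg$decoy_targets, replace = TRUE)
      keep <- !(paste(di, dg) %in% paste(truth$pair_mi, truth$pair_ge))
      arm <- sample(c("-5p", "-3p"), sum(keep), replace = TRUE)
      rows$decoy <- data.frame(
        mirna = paste0(sub("-(5p|3p)$", "",
                           primary_mature(mirna_ids[di[keep]], nmap)), arm),
        gene = gene_ids[dg[keep]],
        region = sample(c("3UTR", "5UTR", "CDS"), sum(keep), replace = TRUE,
                        prob = c(0.6, 0.1, 0.3)),
        stringsAsFactors = FALSE)
    }
    if (length(rows)) target_db(do.call(rbind, rows))
    else target_db(data.frame(mirna = character(0), gene = character(0),
                              region = character(0)))
  })

  annotation <- if (cfg$n_mrna > 0 && cfg$n_categories > 0)
    with_seed(substream_seed(cfg$seed, "annotation"), {
      cats <- sprintf("CAT%02d", seq_len(cfg$n_categories))
      per_gene <- sample(1:3, cfg$n_mrna, replace = TRUE)
      data.frame(
        gene = rep(gene_ids, per_gene),
        category_id = unlist(lapply(per_gene, function(k)
          sample(cats, k))),
        stringsAsFactors = FALSE)
    })
  else data.frame(gene = character(0), category_id = character(0),
                  stringsAsFactors = FALSE)
  annotation$category_name <- sub("^CAT", "process ", annotation$category_id)
  annotation <- unique(annotation)

  baseline_group <- groups[length(groups)]
  de_features <- data.frame(
    feature = mirna_ids[truth$de_idx],
    contrast = if (cfg$n_de > 0)
      rep(paste(first_group, baseline_group, sep = ":"), cfg$n_de)
    else character(0),
    sign = truth$de_sign,
    stringsAsFactors = FALSE)
  planted_pairs <- data.frame(
    mirna = mirna_ids[truth$pair_mi],
    gene = gene_ids[truth$pair_ge],
    true_rho = rep(cfg$pair_rho, cfg$n_pairs),
    tissue = rep(cfg$pair_tissue, cfg$n_pairs),
    stringsAsFactors = FALSE)

  structure(list(
    mirna = mi$cm, mrna = mrna, samples = samples, targets = targets,
    annotation = annotation, nmap = nmap,
    truth = list(de_features = de_features, planted_pairs = planted_pairs,
                 true_libsize_factors = c(list(mirna = mi$libsizes / 1e6),
                                          lapply(mrna_lib, function(l)
                                            l / 1e6))),
    config = cfg), class = "ev_dataset")
}

# First (-5p) mature arm of each precursor.
primary_mature <- function(precursors, nmap) {
  vapply(precursors, function(p) nmap$mature[nmap$precursor == p][1L],
         character(1L), USE.NAMES = FALSE)
}

#' @export
print.ev_dataset <- function(x, ...) {
  cat(sprintf("ev_dataset: %d miRNAs x %d samples; mRNA tissues: %s\n",
              nrow(x$mirna), ncol(x$mirna),
              if (length(x$mrna)) paste(names(x$mrna), collapse = ", ")
              else "(none)"))
  cat(sprintf("  planted: %d DE miRNAs, %d co-expressed pairs, %d target rows\n",
              nrow(x$truth$de_features), nrow(x$truth$planted_pairs),
              nrow(x$targets)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the plain-text formats consumed by the readers: per-matrix count
#' TSVs, a sample sheet CSV, target and annotation TSVs, a name-map TSV
#' and the ground truth as JSON. Round-trips losslessly through
#' [read_counts()] and friends.
#'
#' @param ds An `ev_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ev_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(mirna = file.path(dir, "mirna_counts.tsv"))
  write_counts(ds$mirna, paths[["mirna"]])
  for (tis in names(ds$mrna)) {
    p <- file.path(dir, sprintf("mrna_%s_counts.tsv", tis))
    write_counts(ds$mrna[[tis]], p)
    paths[[paste0("mrna_", tis)]] <- p
  }
  paths[["samples"]] <- file.path(dir, "sample_sheet.csv")
  write_sample_sheet(ds$samples, paths[["samples"]])
  paths[["targets"]] <- file.path(dir, "targets.tsv")
  write_target_db(ds$targets, paths[["targets"]])
  paths[["annotation"]] <- file.path(dir, "annotation.tsv")
  utils::write.table(ds$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["name_map"]] <- file.path(dir, "name_map.tsv")
  utils::write.table(as.data.frame(ds$nmap), paths[["name_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths[["truth"]] <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, paths[["truth"]], digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the files.
#' @return list with the same components as `generate_dataset()` output
#'   (without `config`); `truth` is `NULL` when no truth file is present.
#' @export
read_dataset <- function(dir) {
  mirna <- read_counts(file.path(dir, "mirna_counts.tsv"))
  mrna_files <- list.files(dir, "^mrna_.*_counts\\.tsv$")
  mrna <- list()
  for (f in mrna_files) {
    tis <- sub("^mrna_(.*)_counts\\.tsv$", "\\1", f)
    mrna[[tis]] <- read_counts(file.path(dir, f))
  }
  samples <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  tp <- file.path(dir, "targets.tsv")
  targets <- if (file.exists(tp)) load_target_db(tp) else NULL
  ap <- file.path(dir, "annotation.tsv")
  annotation <- if (file.exists(ap))
    utils::read.delim(ap, stringsAsFactors = FALSE) else NULL
  np <- file.path(dir, "name_map.tsv")
  nmap <- if (file.exists(np)) read_name_map(np) else NULL
  jp <- file.path(dir, "truth.json")
  truth <- if (file.exists(jp)) jsonlite::read_json(jp, simplifyVector = TRUE)
           else NULL
  structure(list(mirna = mirna, mrna = mrna, samples = samples,
                 targets = targets, annotation = annotation, nmap = nmap,
                 truth = truth), class = "ev_dataset")
}
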