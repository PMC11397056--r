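#' Build a pipeline run configuration
#'
#' Collects paths, contrasts, strata and thresholds for [run_all()].
#' Either `simulate` holds a [synthetic_config] (the dataset is generated
#' under `<outdir>/data`), or `paths` points at existing files. Every
#' threshold defaults to its study-scale operating value; all randomness
#' flows from the single master `seed`.
#'
#' @param paths list with entries `mirna_counts`, `mrna_counts` (named
#'   character vector, tissue -> path), `sample_sheet`, and optionally
#'   `target_db`, `name_map`, `annotation`. Ignored when `simulate` is
#'   given.
#' @param simulate Optional [synthetic_config] (or argument list for it).
#' @param contrasts list of 2-vectors `c(A, B)`; A is the log2fc
#'   numerator.
#' @param strata list of 2-vectors `c(group, tissue)` for co-expression.
#' @param overlap_contrast Contrast whose up-regulated miRNAs / tissue
#'   down-regulated genes feed the target-overlap stage.
#' @param min_total,alpha,efdr_threshold,fwer_threshold,n_rand Stage
#'   thresholds (defaults 50, 0.05, 4e-5, 0.01, 10000).
#' @param seed Master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(paths = NULL, simulate = NULL,
                       contrasts = list(c("AI", "NCP"), c("AI", "IVP-ET")),
                       strata = list(c("AI", "EET"), c("IVP-ET", "EET"),
                                     c("AI", "CAR"), c("IVP-ET", "CAR"),
                                     c("AI", "ICAR"), c("IVP-ET", "ICAR")),
                       overlap_contrast = c("AI", "IVP-ET"),
                       min_total = 50, alpha = 0.05,
                       efdr_threshold = 0.00004, fwer_threshold = 0.01,
                       n_rand = 10000, seed = 1) {
  if (is.null(paths) && is.null(simulate))
    stop("either 'paths' or 'simulate' must be provided")
  if (min_total < 0) stop("invalid threshold: min_total must be >= 0")
  for (th in c("alpha", "efdr_threshold", "fwer_threshold")) {
    v <- get(th)
    if (v <= 0 || v > 1) stop("invalid threshold: ", th,
                              " must lie in (0, 1]")
  }
  if (n_rand < 1) stop("invalid threshold: n_rand must be >= 1")
  structure(list(paths = paths, simulate = simulate, contrasts = contrasts,
                 strata = strata, overlap_contrast = overlap_contrast,
                 min_total = min_total, alpha = alpha,
                 efdr_threshold = efdr_threshold,
                 fwer_threshold = fwer_threshold, n_rand = n_rand,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration file
#'
#' Flat key/value text format with `[section]` headers, `key = value`
#' lines, and `#` comments. Sections: `[run]` (seed, outdir-independent
#' thresholds), `[paths]` (`mirna_counts`, `mrna_<TISSUE>`,
#' `sample_sheet`, `target_db`, `name_map`, `annotation`), `[simulate]`
#' (any [synthetic_config] scalar argument), `[contrasts]` and
#' `[strata]` (repeated `contrast = A:B` / `stratum = GROUP:TISSUE`
#' lines).
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("cannot parse config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[section]] <- c(kv[[section]], stats::setNames(list(val), key))
  }
  num_or <- function(sec, key, default) {
    v <- kv[[sec]][[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  split2 <- function(x) strsplit(x, ":", fixed = TRUE)[[1L]]
  contrasts <- lapply(unname(unlist(kv[["contrasts"]])), split2)
  strata <- lapply(unname(unlist(kv[["strata"]])), split2)
  paths <- NULL
  if (!is.null(kv[["paths"]])) {
    p <- kv[["paths"]]
    mrna_keys <- grep("^mrna_", names(p), value = TRUE)
    paths <- list(
      mirna_counts = p[["mirna_counts"]],
      mrna_counts = stats::setNames(unlist(p[mrna_keys]),
                                    sub("^mrna_", "", mrna_keys)),
      sample_sheet = p[["sample_sheet"]], target_db = p[["target_db"]],
      name_map = p[["name_map"]], annotation = p[["annotation"]])
  }
  simulate <- NULL
  if (!is.null(kv[["simulate"]])) {
    simulate <- lapply(kv[["simulate"]], function(v) {
      n <- suppressWarnings(as.numeric(v))
      if (is.na(n)) v else n
    })
  }
  ov <- kv[["run"]][["overlap_contrast"]]
  run_config(
    paths = paths, simulate = simulate,
    contrasts = if (length(contrasts)) contrasts
                else list(c("AI", "NCP"), c("AI", "IVP-ET")),
    strata = if (length(strata)) strata
             else list(c("AI", "EET"), c("IVP-ET", "EET")),
    overlap_contrast = if (is.null(ov)) c("AI", "IVP-ET") else split2(ov),
    min_total = num_or("run", "min_total", 50),
    alpha = num_or("run", "alpha", 0.05),
    efdr_threshold = num_or("run", "efdr_threshold", 0.00004),
    fwer_threshold = num_or("run", "fwer_threshold", 0.01),
    n_rand = num_or("run", "n_rand", 10000),
    seed = num_or("run", "seed", 1))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> differential abundance
#' per contrast -> co-expression per stratum -> target integration ->
#' enrichment, writing one TSV per stage output plus a machine-readable
#' `summary.json` under `outdir`. Identical config and seed give an
#' identical summary. Any stage failure aborts with the stage name.
#'
#' @param config A `run_config` (or path to a config file).
#' @param outdir Output directory.
#' @return The run summary list, invisibly; written to
#'   `file.path(outdir, "summary.json")`.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- load or simulate -------------------------------------------------
  ds <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (!inherits(sim, "synthetic_config")) {
        sim$seed <- sim$seed %||% config$seed
        sim <- do.call(synthetic_config, sim)
      }
      d <- generate_dataset(sim)
      write_dataset(d, file.path(outdir, "data"))
      d
    } else {
      p <- config$paths
      mrna <- list()
      for (tis in names(p$mrna_counts))
        mrna[[tis]] <- read_counts(p$mrna_counts[[tis]])
      list(mirna = read_counts(p$mirna_counts), mrna = mrna,
           samples = read_sample_sheet(p$sample_sheet),
           targets = if (!is.null(p$target_db)) load_target_db(p$target_db),
           annotation = if (!is.null(p$annotation))
             utils::read.delim(p$annotation, stringsAsFactors = FALSE),
           nmap = if (!is.null(p$name_map)) read_name_map(p$name_map))
    }
  })
  samples <- ds$samples
  known_groups <- unique(samples$group)
  for (ct in c(config$contrasts, list(config$overlap_contrast))) {
    bad <- setdiff(ct, known_groups)
    if (length(bad)) stop("pipeline stage 'validate' failed: unknown group ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }

  # ---- preprocess -------------------------------------------------------
  filt <- stage("preprocess", {
    mi <- filter_low_counts(ds$mirna, config$min_total)
    mr <- lapply(ds$mrna, filter_low_counts, min_total = config$min_total)
    write_counts(mi, file.path(outdir, "mirna_filtered.tsv"))
    list(mirna = mi, mrna = mr)
  })

  # ---- differential abundance ------------------------------------------
  de_res <- stage("de", {
    out <- list()
    for (ct in config$contrasts) {
      key <- paste(ct, collapse = ":")
      res <- de_contrast(filt$mirna, samples[samples$tissue == "ULF-EV", ],
                         ct, alpha = config$alpha)
      utils::write.table(res, file.path(outdir,
                                        sprintf("de_%s_vs_%s.tsv", ct[1L],
                                                ct[2L])),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[key]] <- res
    }
    out
  })

  # ---- co-expression per stratum ---------------------------------------
  coex <- stage("coexpress", {
    out <- list()
    for (st in config$strata) {
      g <- st[1L]; tis <- st[2L]
      key <- paste(g, tis, sep = "_")
      if (is.null(filt$mrna[[tis]])) {
        log_msg("no mRNA matrix for tissue ", tis, "; skipping stratum ",
                key, level = "WARN")
        next
      }
      n_in <- sum(samples$group == g & samples$tissue == tis)
      if (n_in < 3L) {
        log_msg("stratum ", key, " has ", n_in,
                " samples; skipping", level = "WARN")
        next
      }
      tab <- coexpression_stratum(
        filt$mirna, filt$mrna[[tis]], samples, g, tis,
        n_rand = config$n_rand,
        seed = substream_seed(config$seed, paste0("coexpr:", key)),
        efdr_threshold = config$efdr_threshold)
      utils::write.table(tab, file.path(outdir,
                                        sprintf("coexpr_%s.tsv", key)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[key]] <- tab
    }
    out
  })

  # ---- target integration ----------------------------------------------
  nmap <- ds$nmap %||%
    suppressMessages(default_name_map(rownames(filt$mirna)))
  supported <- stage("integrate", {
    out <- list()
    if (!is.null(ds$targets)) {
      for (key in names(coex)) {
        sp <- supported_pairs(coex[[key]], ds$targets, nmap)
        utils::write.table(sp, file.path(outdir,
                                         sprintf("supported_pairs_%s.tsv",
                                                 key)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[key]] <- sp
      }
    }
    out
  })

  overlap <- stage("integrate-de", {
    out <- list()
    if (!is.null(ds$targets)) {
      oc <- config$overlap_contrast
      key <- paste(oc, collapse = ":")
      de_mi <- de_res[[key]] %||%
        de_contrast(filt$mirna, samples[samples$tissue == "ULF-EV", ], oc,
                    alpha = config$alpha)
      up <- de_mi$feature_id[de_mi$consensus_de & de_mi$direction > 0]
      for (tis in names(filt$mrna)) {
        have <- vapply(oc, function(g)
          sum(samples$group == g & samples$tissue == tis) >= 2, logical(1L))
        if (!all(have)) next
        de_mr <- de_contrast(filt$mrna[[tis]],
                             samples[samples$tissue == tis, ], oc,
                             alpha = config$alpha)
        down <- de_mr$feature_id[de_mr$consensus_de & de_mr$direction < 0]
        ov <- de_target_overlap(up, down, ds$targets, nmap)
        utils::write.table(ov, file.path(outdir,
                                         sprintf("de_target_overlap_%s.tsv",
                                                 tis)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[tis]] <- list(overlap = ov, down = down, up = up)
      }
    }
    out
  })

  # ---- enrichment -------------------------------------------------------
  enrich <- stage("enrich", {
    out <- list()
    if (!is.null(ds$annotation) && nrow(ds$annotation)) {
      for (tis in names(overlap)) {
        interest <- overlap[[tis]]$overlap$gene
        background <- rownames(filt$mrna[[tis]])
        interest <- intersect(interest, background)
        er <- hypergeom_enrich(interest, background, ds$annotation,
                               config$fwer_threshold)
        utils::write.table(er, file.path(outdir,
                                         sprintf("enrichment_%s.tsv", tis)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[tis]] <- er
      }
    }
    out
  })

  # ---- summary ----------------------------------------------------------
  summary <- list(
    seed = config$seed,
    parameters = list(min_total = config$min_total, alpha = config$alpha,
                      efdr_threshold = config$efdr_threshold,
                      fwer_threshold = config$fwer_threshold,
                      n_rand = config$n_rand),
    n_mirna_after_filter = nrow(filt$mirna),
    n_mrna_after_filter = lapply(filt$mrna, nrow),
    de_counts = lapply(de_res, function(r) sum(r$consensus_de)),
    significant_pairs = lapply(coex, function(t) sum(t$significant)),
    supported_pairs = lapply(supported, nrow),
    target_overlap_genes = lapply(overlap, function(o) nrow(o$overlap)),
    enriched_categories = lapply(enrich, function(e) sum(e$significant)))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
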