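#' Predicted miRNA target table
#'
#' Constructs a target database from records of (mature miRNA, gene,
#' region). Regions are restricted to the closed vocabulary `3UTR`,
#' `5UTR`, `CDS` (binding-site location); exact duplicate records are
#' removed; matching elsewhere is case-insensitive, so names are
#' normalized to a canonical case here (miRNA lower-cased except the
#' conventional `miR` token, genes upper-cased).
#'
#' @param records data.frame with columns `mirna`, `gene`, `region`.
#' @return data.frame of class `target_db`.
#' @export
target_db <- function(records) {
  need <- c("mirna", "gene", "region")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("target table missing columns: ",
                         paste(miss, collapse = ", "))
  db <- records[need]
  db$region <- toupper(db$region)
  bad <- setdiff(unique(db$region), c("3UTR", "5UTR", "CDS"))
  if (length(bad)) stop("unknown region label(s): ",
                        paste(bad, collapse = ", "))
  db$mirna <- canonical_mirna(db$mirna)
  db$gene <- toupper(db$gene)
  db <- unique(db)
  rownames(db) <- NULL
  class(db) <- c("target_db", class(db))
  db
}

canonical_mirna <- function(x) {
  out <- tolower(x)
  sub("-mir-", "-miR-", out, fixed = TRUE)
}

#' Read a predicted-target TSV
#'
#' @param path TSV with header columns `mirna`, `gene`, `region`.
#' @return A [target_db].
#' @export
load_target_db <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  target_db(df)
}

#' @rdname load_target_db
#' @param db A `target_db`.
#' @export
write_target_db <- function(db, path) {
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Precursor-to-mature miRNA name map
#'
#' Two-column table mapping each annotated precursor (hairpin locus, e.g.
#' `bta-mir-17`) to its processed mature arms (e.g. `bta-miR-17-5p`).
#' Every mature name must map back to exactly one precursor.
#'
#' @param precursor,mature Character vectors of equal length.
#' @return data.frame of class `name_map`.
#' @export
name_map <- function(precursor, mature) {
  stopifnot(length(precursor) == length(mature))
  nm <- unique(data.frame(precursor = as.character(precursor),
                          mature = canonical_mirna(mature),
                          stringsAsFactors = FALSE))
  dup <- nm$mature[duplicated(nm$mature)]
  if (length(dup)) stop("mature name(s) mapped to more than one precursor: ",
                        paste(unique(dup), collapse = ", "))
  class(nm) <- c("name_map", class(nm))
  nm
}

#' @rdname name_map
#' @param path TSV with columns `precursor`, `mature`.
#' @export
read_name_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("precursor", "mature"), names(df))
  if (length(miss)) stop("name map missing columns: ",
                         paste(miss, collapse = ", "))
  name_map(df$precursor, df$mature)
}

#' Heuristic precursor-to-mature mapping
#'
#' Fallback used when no curated map is supplied: each precursor gets
#' `-5p` and `-3p` arms built from its canonical stem. Gene-style tokens
#' (`MIR18A`) are normalized to the `miR-18a` style, and a trailing locus
#' index (`mir-7-3`, `mir-129-2`) is dropped, since mature names carry
#' the family stem only. Heuristic use is always logged; curated maps
#' should be preferred.
#'
#' @param precursors Character vector of precursor names.
#' @return A [name_map].
#' @export
default_name_map <- function(precursors) {
  precursors <- unique(as.character(precursors))
  log_msg("no curated name map supplied; deriving mature names ",
          "heuristically for ", length(precursors), " precursors",
          level = "WARN")
  stem <- vapply(precursors, precursor_stem, character(1L))
  name_map(precursor = rep(precursors, each = 2L),
           mature = paste0("bta-miR-", rep(stem, each = 2L),
                           c("-5p", "-3p")))
}

precursor_stem <- function(p) {
  s <- p
  s <- sub("^bta-", "", s, ignore.case = TRUE)
  s <- sub("^mir-?", "", s, ignore.case = TRUE)
  s <- sub("^let-?", "let-", s, ignore.case = TRUE)
  s <- tolower(s)
  # MIR18A -> 18a already handled by lowercasing; insert dash variants not needed
  # drop a trailing locus index: 7-3 -> 7, 181b-2 -> 181b
  s <- sub("^([0-9]+[a-z]*)-[0-9]+$", "\\1", s)
  s
}

#' Target-supported inverted co-expression pairs
#'
#' Restricts a significant co-expression table to the rows whose pair is
#' backed by the predicted-target database: the row must be significant,
#' have negative correlation (when `require_negative`), and some mature
#' form of the row's precursor miRNA must be a predicted regulator of the
#' row's gene. Rows whose precursor is absent from the name map are
#' skipped with a logged warning.
#'
#' @param coexpr `coexpr_table` with `significant` filled.
#' @param db A [target_db].
#' @param nmap A [name_map]; built heuristically when `NULL`.
#' @param require_negative Keep only r < 0 rows (default `TRUE`; miRNAs
#'   predominantly degrade their targets, so regulatory pairs should be
#'   inverted).
#' @return The supported subset of `coexpr` (same columns).
#' @export
supported_pairs <- function(coexpr, db, nmap = NULL, require_negative = TRUE) {
  stopifnot(inherits(db, "target_db"))
  if (nrow(coexpr) > 0 && is.null(coexpr$significant))
    stop("co-expression table has no significance flags")
  if (is.null(nmap)) nmap <- default_name_map(unique(coexpr$mirna))
  cand <- coexpr[coexpr$significant &
                   (!require_negative | coexpr$r < 0), , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  missing_prec <- setdiff(unique(cand$mirna), nmap$precursor)
  if (length(missing_prec))
    log_msg("precursor(s) absent from the name map, rows skipped: ",
            paste(missing_prec, collapse = ", "), level = "WARN")
  key <- paste(db$mirna, db$gene, sep = "\r")
  hit <- vapply(seq_len(nrow(cand)), function(i) {
    mats <- nmap$mature[nmap$precursor == cand$mirna[i]]
    if (length(mats) == 0L) return(FALSE)
    any(paste(mats, toupper(cand$gene[i]), sep = "\r") %in% key)
  }, logical(1L))
  out <- cand[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of DE-miRNA targets with down-regulated genes
#'
#' Given the miRNAs more abundant in one condition and the genes with
#' lower abundance in a tissue, returns the down-regulated genes that are
#' predicted targets of at least one mature form of those miRNAs,
#' together with the supporting mature names.
#'
#' @param de_up_mirnas Character vector of precursor names (may be empty).
#' @param down_genes Character vector of gene symbols (may be empty).
#' @param db A [target_db].
#' @param nmap A [name_map]; heuristic fallback when `NULL`.
#' @return data.frame `gene`, `mirnas` (comma-separated mature names),
#'   `n_mirnas`, ordered by gene for determinism.
#' @export
de_target_overlap <- function(de_up_mirnas, down_genes, db, nmap = NULL) {
  stopifnot(inherits(db, "target_db"))
  if (length(de_up_mirnas) == 0L || length(down_genes) == 0L)
    return(data.frame(gene = character(0), mirnas = character(0),
                      n_mirnas = integer(0), stringsAsFactors = FALSE))
  if (is.null(nmap)) nmap <- default_name_map(de_up_mirnas)
  mats <- nmap$mature[nmap$precursor %in% de_up_mirnas]
  down <- toupper(down_genes)
  sub <- db[db$mirna %in% mats & db$gene %in% down, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(gene = character(0), mirnas = character(0),
                      n_mirnas = integer(0), stringsAsFactors = FALSE))
  sp <- split(sub$mirna, sub$gene)
  genes <- sort(names(sp))
  data.frame(gene = genes,
             mirnas = vapply(sp[genes], function(m)
               paste(sort(unique(m)), collapse = ","), character(1L)),
             n_mirnas = vapply(sp[genes], function(m)
               length(unique(m)), integer(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
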