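# Tabular IO: taxonomy lineages, trait tables, ranking TSVs, per-COG member
# listings. Taxonomy is supplied as a flat lineage TSV (one row per organism,
# seven rank columns) rather than by parsing NCBI taxonomy dumps.

#' Load a taxonomy lineage table
#'
#' @param path TSV with columns `organism_id` plus the seven ranks
#'   `superkingdom, phylum, class, order, family, genus, species`. Cells may
#'   be empty except `species`; empty cells become `NA` (rank absent).
#' @return data.frame, one row per organism.
#' @export
load_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("organism_id", TAXONOMIC_RANKS)
  if (!all(need %in% names(tab))) {
    stop_parse(sprintf("taxonomy table must have columns: %s",
                       paste(need, collapse = ", ")))
  }
  if (anyDuplicated(tab$organism_id)) {
    stop_parse(sprintf("duplicate organism_id in taxonomy table: %s",
                       tab$organism_id[duplicated(tab$organism_id)][1]))
  }
  for (rk in TAXONOMIC_RANKS) {
    tab[[rk]][!nzchar(trimws(tab[[rk]]))] <- NA_character_
  }
  if (anyNA(tab$species)) {
    stop_parse("taxonomy rows with missing species cell")
  }
  tab[, need]
}

#' Load an oxygen-requirement / growth-temperature trait table
#'
#' @param path TSV with columns `organism_id`, `oxygen_class`
#'   (aerobe/anaerobe/facultative/unknown; anything else is mapped to
#'   `unknown` with a warning) and `ogt` in degrees Celsius (may be blank).
#' @return data.frame with columns `organism_id`, `oxygen_class`,
#'   `ogt_celsius`.
#' @export
load_traits <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("organism_id", "oxygen_class", "ogt") %in% names(tab))) {
    stop_parse("trait table must have columns organism_id, oxygen_class, ogt")
  }
  oxy <- tolower(trimws(tab$oxygen_class))
  bad <- !(oxy %in% OXYGEN_CLASSES)
  if (any(bad)) {
    warning(sprintf("unrecognized oxygen class value(s) mapped to 'unknown': %s",
                    paste(unique(tab$oxygen_class[bad]), collapse = ", ")),
            call. = FALSE)
    oxy[bad] <- "unknown"
  }
  ogt_raw <- trimws(tab$ogt)
  ogt <- rep(NA_real_, length(ogt_raw))
  has <- nzchar(ogt_raw)
  parsed <- suppressWarnings(as.numeric(ogt_raw[has]))
  if (anyNA(parsed)) {
    stop_parse(sprintf("non-numeric OGT value(s): %s",
                       paste(ogt_raw[has][is.na(parsed)], collapse = ", ")))
  }
  if (any(parsed < 0 | parsed > 130)) {
    stop_parse("OGT outside plausible range [0, 130] degrees C")
  }
  ogt[has] <- parsed
  data.frame(organism_id = tab$organism_id, oxygen_class = oxy,
             ogt_celsius = ogt, stringsAsFactors = FALSE)
}

#' Write a ranking table as TSV
#'
#' Mirrors the tool's downloadable result table: a consecutive rank number,
#' the COG (or batch-group) label, the score columns and the functional
#' description. When the ranking was computed with normalization, the
#' selected/total feature counts and the normalized score are included as
#' well. Scores are rendered with 4 decimal places.
#'
#' @param rows A ranking data.frame from [score_cogs()] or [score_batch()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(rows, path) {
  normalized <- !is.null(attr(rows, "normalization")) &&
    attr(rows, "normalization") != "none"
  out <- data.frame(rank = seq_len(nrow(rows)), stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) out <- data.frame(rank = integer(0))
  out$group <- rows$group_label
  if (any(!is.na(rows$subgroup))) out$subgroup <- rows$subgroup
  if (normalized) {
    out$n_selected_features <- rows$selected_feature_count
    out$n_total_features <- rows$total_feature_count
  }
  out$apsf <- fmt_score(rows$apsf)
  if (normalized) out$score <- fmt_score(rows$score)
  out$description <- rows$description
  if (nrow(rows) == 0L) out <- out[0, , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write ranking TSV '%s'", path))
  invisible(path)
}

#' Write the member listing of one COG
#'
#' One row per sequence considered for a COG's score: superkingdom (domain),
#' protein GI, gene GI, COG id and source-organism name.
#'
#' @param ds A [cog_dataset()].
#' @param cog_id COG to list.
#' @param path Output TSV path.
#' @param selection Optional organism [cog_selection] restriction.
#' @return `path`, invisibly.
#' @export
write_member_listing_tsv <- function(ds, cog_id, path, selection = NULL) {
  idx <- scope_sequences(ds, selection, cog_id)
  s <- ds$sequences[idx, , drop = FALSE]
  o <- ds$organisms[match(s$organism_id, ds$organisms$organism_id), ]
  out <- data.frame(
    domain = ifelse(is.na(o$superkingdom), "", o$superkingdom),
    protein_gi = s$protein_gi,
    gene_gi = s$gene_gi,
    cog = s$cog_id,
    organism = o$display_name,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
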