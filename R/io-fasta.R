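# FASTA fallback loader: one protein FASTA (and optionally one CDS FASTA)
# per COG, plus an organism manifest. Lets the tool run on plain per-COG
# sequence bundles when no XML database is at hand.

fasta_ext_regex <- "\\.(fa|faa|fna|fasta)$"

parse_fasta_headers <- function(headers, file) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop_parse(sprintf(
      "FASTA header '%s' in '%s' does not match 'organism_id|protein_gi|gene_gi'",
      headers[which(bad)[1]], file))
  }
  m <- do.call(rbind, parts)
  data.frame(organism_id = m[, 1], protein_gi = m[, 2], gene_gi = m[, 3],
             stringsAsFactors = FALSE)
}

#' Load a per-COG FASTA bundle
#'
#' Expects one protein FASTA per COG in `protein_dir` (file base name = COG
#' id) with headers `organism_id|protein_gi|gene_gi`, optionally a matching
#' CDS FASTA per COG in `cds_dir`, and a tab-separated organism manifest with
#' columns `organism_id`, `display_name`. Protein records without a CDS
#' partner are kept protein-only with a warning. The resulting dataset has
#' the same semantics as one read by [parse_nucocog_xml()].
#'
#' @param protein_dir Directory of protein FASTA files.
#' @param cds_dir Directory of CDS FASTA files (may be missing files).
#' @param manifest Path to the organism manifest TSV.
#' @param descriptions Optional TSV (`cog_id`, `description`) of COG
#'   annotations; COGs absent from it get an empty description.
#' @param source Dataset flavour tag.
#' @return A [cog_dataset()].
#' @export
parse_fasta_bundle <- function(protein_dir, cds_dir = NULL, manifest,
                               descriptions = NULL,
                               source = c("cog", "arcog", "combined")) {
  source <- match.arg(source)
  if (!dir.exists(protein_dir)) stop_io(sprintf("no such directory: %s", protein_dir))
  prot_files <- sort(list.files(protein_dir, pattern = fasta_ext_regex,
                                full.names = TRUE))
  if (length(prot_files) == 0L) stop_parse("no FASTA files in protein_dir")

  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("organism_id", "display_name") %in% names(man))) {
    stop_parse("manifest must have columns organism_id, display_name")
  }
  organisms <- data.frame(organism_id = as.character(man$organism_id),
                          display_name = as.character(man$display_name),
                          stringsAsFactors = FALSE)

  desc_map <- character(0)
  if (!is.null(descriptions)) {
    dd <- utils::read.delim(descriptions, stringsAsFactors = FALSE)
    desc_map <- stats::setNames(as.character(dd$description),
                                as.character(dd$cog_id))
  }

  seq_list <- vector("list", length(prot_files))
  cog_ids <- sub(fasta_ext_regex, "", basename(prot_files))
  for (k in seq_along(prot_files)) {
    cid <- cog_ids[k]
    aa_set <- Biostrings::readAAStringSet(prot_files[k])
    hd <- parse_fasta_headers(names(aa_set), prot_files[k])
    recs <- cbind(hd,
                  data.frame(cog_id = cid,
                             aa_seq = toupper(as.character(aa_set)),
                             nt_seq = "",
                             stringsAsFactors = FALSE))
    if (!is.null(cds_dir)) {
      cds_file <- list.files(cds_dir, pattern = paste0("^", cid, fasta_ext_regex),
                             full.names = TRUE)
      if (length(cds_file) >= 1L) {
        nt_set <- Biostrings::readDNAStringSet(cds_file[1])
        nhd <- parse_fasta_headers(names(nt_set), cds_file[1])
        key <- paste(recs$organism_id, recs$protein_gi, sep = "\r")
        nkey <- paste(nhd$organism_id, nhd$protein_gi, sep = "\r")
        idx <- match(key, nkey)
        hit <- !is.na(idx)
        recs$nt_seq[hit] <- gsub("U", "T",
                                 toupper(as.character(nt_set))[idx[hit]],
                                 fixed = TRUE)
      }
    }
    n_unpaired <- sum(!nzchar(recs$nt_seq))
    if (n_unpaired > 0L) {
      warning(sprintf("%s: %d protein record(s) lack a CDS partner; kept protein-only",
                      cid, n_unpaired), call. = FALSE)
    }
    seq_list[[k]] <- recs
  }
  sequences <- do.call(rbind, seq_list)
  cogs <- data.frame(
    cog_id = cog_ids,
    description = ifelse(cog_ids %in% names(desc_map), desc_map[cog_ids], ""),
    stringsAsFactors = FALSE
  )
  cog_dataset(source, organisms, cogs,
              sequences[, c("organism_id", "cog_id", "protein_gi", "gene_gi",
                            "aa_seq", "nt_seq")])
}

#' Export sequences of a COG or selection as FASTA
#'
#' Headers use the bundle grammar `organism_id|protein_gi|gene_gi`; record
#' order follows the dataset, so exports are deterministic.
#'
#' @param ds A [cog_dataset()].
#' @param path Output FASTA path.
#' @param cog_ids Optional COG restriction.
#' @param selection Optional organism [cog_selection].
#' @param type `"protein"` or `"cds"`. CDS export skips protein-only records.
#' @return Number of records written, invisibly.
#' @export
export_fasta <- function(ds, path, cog_ids = NULL, selection = NULL,
                         type = c("protein", "cds")) {
  type <- match.arg(type)
  idx <- scope_sequences(ds, selection, cog_ids)
  s <- ds$sequences[idx, , drop = FALSE]
  if (type == "cds") s <- s[nzchar(s$nt_seq), , drop = FALSE]
  if (nrow(s) == 0L) stop_undefined("no sequences in scope to export")
  hdr <- paste(s$organism_id, s$protein_gi, s$gene_gi, sep = "|")
  set <- if (type == "protein") {
    Biostrings::AAStringSet(stats::setNames(s$aa_seq, hdr))
  } else {
    Biostrings::DNAStringSet(stats::setNames(s$nt_seq, hdr))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(nrow(s))
}
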