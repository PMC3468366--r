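#' In-memory ortholog-group dataset
#'
#' A `cog_dataset` holds everything one composition query needs: the organism
#' table (with optional taxonomic lineage and trait columns), the COG
#' catalogue, and one row per ortholog member pairing an amino-acid sequence
#' with its coding nucleotide sequence. Feature counts are attached lazily by
#' [precompute_counts()].
#'
#' @param source Dataset flavour: classic COGs, archaeal arCOGs, or a
#'   combined set. Informational only; it does not change any computation.
#' @param organisms data.frame with columns `organism_id`, `display_name`,
#'   optionally the seven lineage ranks, `oxygen_class` and `ogt_celsius`.
#' @param cogs data.frame with columns `cog_id`, `description`.
#' @param sequences data.frame with columns `organism_id`, `cog_id`,
#'   `protein_gi`, `gene_gi`, `aa_seq`, `nt_seq` (empty string for
#'   protein-only records).
#'
#' @return An object of class `cog_dataset`.
#' @export
cog_dataset <- function(source = c("cog", "arcog", "combined"),
                        organisms, cogs, sequences) {
  source <- match.arg(source)
  organisms <- as.data.frame(organisms, stringsAsFactors = FALSE)
  cogs <- as.data.frame(cogs, stringsAsFactors = FALSE)
  sequences <- as.data.frame(sequences, stringsAsFactors = FALSE)

  for (rk in TAXONOMIC_RANKS) {
    if (is.null(organisms[[rk]])) organisms[[rk]] <- NA_character_
  }
  if (is.null(organisms$oxygen_class)) organisms$oxygen_class <- NA_character_
  if (is.null(organisms$ogt_celsius)) organisms$ogt_celsius <- NA_real_
  if (is.null(sequences$nt_seq)) sequences$nt_seq <- ""
  sequences$nt_seq[is.na(sequences$nt_seq)] <- ""

  ds <- structure(
    list(source = source,
         organisms = organisms,
         cogs = cogs,
         sequences = sequences,
         counts = NULL,
         has_taxonomy = any(!is.na(organisms$species)),
         has_traits = any(!is.na(organisms$oxygen_class))),
    class = "cog_dataset"
  )
  validate_cog_dataset(ds)
}

#' Validate a `cog_dataset`'s structural invariants
#'
#' Checks referential integrity (every sequence resolves to a known organism
#' and catalogued COG, no duplicate (organism, protein GI) pairs), sequence
#' alphabets, and the non-empty-protein / CDS-length rules.
#'
#' @param ds A `cog_dataset`.
#' @return `ds`, invisibly usable, after passing all checks.
#' @export
validate_cog_dataset <- function(ds) {
  org <- ds$organisms
  seqs <- ds$sequences
  if (anyDuplicated(org$organism_id)) {
    stop_integrity("duplicate organism_id in organism table")
  }
  if (anyDuplicated(ds$cogs$cog_id)) {
    stop_integrity("duplicate cog_id in COG catalogue")
  }
  if (nrow(seqs) == 0L) {
    stop_parse("dataset contains no sequence records")
  }
  bad_org <- !(seqs$organism_id %in% org$organism_id)
  if (any(bad_org)) {
    stop_integrity(sprintf(
      "sequence(s) reference unknown organism(s); offending protein GI(s): %s",
      paste(utils::head(seqs$protein_gi[bad_org], 10L), collapse = ", ")))
  }
  bad_cog <- !(seqs$cog_id %in% ds$cogs$cog_id)
  if (any(bad_cog)) {
    stop_integrity(sprintf(
      "sequence(s) reference uncatalogued COG(s): %s",
      paste(unique(utils::head(seqs$cog_id[bad_cog], 10L)), collapse = ", ")))
  }
  key <- paste(seqs$organism_id, seqs$protein_gi, sep = "\r")
  if (anyDuplicated(key)) {
    stop_integrity(sprintf(
      "duplicate (organism_id, protein_gi) pair(s): %s",
      paste(utils::head(key[duplicated(key)], 5L), collapse = ", ")))
  }
  if (any(!nzchar(seqs$aa_seq))) {
    stop_integrity("empty amino-acid sequence(s) present")
  }
  short_nt <- nzchar(seqs$nt_seq) & nchar(seqs$nt_seq) < 3L
  if (any(short_nt)) {
    stop_integrity("non-empty CDS shorter than one codon")
  }
  for (i in seq_len(nrow(seqs))) {
    check_alphabet(seqs$aa_seq[i], "[^ACDEFGHIKLMNPQRSTVWYX*]", "amino-acid")
    if (nzchar(seqs$nt_seq[i])) {
      check_alphabet(seqs$nt_seq[i], "[^ACGTN]", "nucleotide")
    }
  }
  ds
}

#' @export
print.cog_dataset <- function(x, ...) {
  cat(sprintf("<cog_dataset> source=%s: %d organisms, %d COGs, %d sequences\n",
              x$source, nrow(x$organisms), nrow(x$cogs), nrow(x$sequences)))
  cat(sprintf("  paired CDS: %d/%d; taxonomy: %s; traits: %s; counts cached: %s\n",
              sum(nzchar(x$sequences$nt_seq)), nrow(x$sequences),
              if (x$has_taxonomy) "yes" else "no",
              if (x$has_traits) "yes" else "no",
              if (is.null(x$counts)) "no" else "yes"))
  invisible(x)
}

#' @export
#' @method summary cog_dataset
summary.cog_dataset <- function(object, ...) {
  seqs <- object$sequences
  cat(sprintf("cog_dataset (%s)\n", object$source))
  cat(sprintf("  organisms : %d\n", nrow(object$organisms)))
  cat(sprintf("  COGs      : %d\n", nrow(object$cogs)))
  cat(sprintf("  sequences : %d (%d with CDS)\n",
              nrow(seqs), sum(nzchar(seqs$nt_seq))))
  cat(sprintf("  residues  : %d; nucleotides: %.0f\n",
              sum(nchar(seqs$aa_seq)), sum(nchar(seqs$nt_seq))))
  invisible(object)
}

#' Attach a taxonomy lineage table to a dataset
#'
#' @param ds A `cog_dataset`.
#' @param taxonomy data.frame from [load_taxonomy()].
#' @return The dataset with lineage columns filled for matching organisms.
#' @export
attach_taxonomy <- function(ds, taxonomy) {
  stopifnot(inherits(ds, "cog_dataset"))
  idx <- match(ds$organisms$organism_id, taxonomy$organism_id)
  if (all(is.na(idx))) {
    warning("taxonomy table matches no organism in the dataset")
  }
  for (rk in TAXONOMIC_RANKS) {
    ds$organisms[[rk]] <- ifelse(is.na(idx), ds$organisms[[rk]],
                                 taxonomy[[rk]][idx])
  }
  ds$has_taxonomy <- any(!is.na(ds$organisms$species))
  ds
}

#' Attach an oxygen-requirement / growth-temperature trait table
#'
#' @param ds A `cog_dataset`.
#' @param traits data.frame from [load_traits()].
#' @return The dataset with `oxygen_class` and `ogt_celsius` filled.
#' @export
attach_traits <- function(ds, traits) {
  stopifnot(inherits(ds, "cog_dataset"))
  idx <- match(ds$organisms$organism_id, traits$organism_id)
  ds$organisms$oxygen_class <- ifelse(is.na(idx), ds$organisms$oxygen_class,
                                      traits$oxygen_class[idx])
  ds$organisms$ogt_celsius <- ifelse(is.na(idx), ds$organisms$ogt_celsius,
                                     traits$ogt_celsius[idx])
  ds$has_traits <- any(!is.na(ds$organisms$oxygen_class))
  ds
}

# Row indices of dataset$sequences matching an organism selection and/or an
# explicit COG scope. NULL means "no restriction".
scope_sequences <- function(ds, selection = NULL, cog_ids = NULL) {
  keep <- rep(TRUE, nrow(ds$sequences))
  if (!is.null(selection)) {
    ids <- if (inherits(selection, "cog_selection")) selection$organism_ids else selection
    keep <- keep & (ds$sequences$organism_id %in% ids)
  }
  if (!is.null(cog_ids)) {
    unknown <- setdiff(cog_ids, ds$cogs$cog_id)
    if (length(unknown)) {
      stop_usage(sprintf("unknown COG id(s): %s", paste(unknown, collapse = ", ")))
    }
    keep <- keep & (ds$sequences$cog_id %in% cog_ids)
  }
  which(keep)
}
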