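# Per-sequence feature counting: the pre-computed quantities the scoring
# engine sums. Ambiguity policy: X (protein) and N (DNA) contribute neither
# to counts nor to totals; codons are read as consecutive frame-0 triplets,
# a trailing incomplete triplet is dropped, and triplets containing N are
# excluded. Stop codons are counted in codon_counts, but sense-only totals
# are carried alongside because codon-frequency queries default to a
# sense-codon denominator.

#' Count amino acids in one protein sequence
#'
#' @param aa_seq Uppercase sequence over the 20 standard one-letter codes
#'   plus `X` (ambiguous) and `*` (stop). `X`/`*` are excluded from counts
#'   and total.
#' @return list with `counts` (named integer vector over the 20 codes) and
#'   `total`.
#' @export
count_amino_acids <- function(aa_seq) {
  check_alphabet(aa_seq, "[^ACDEFGHIKLMNPQRSTVWYX*]", "amino-acid")
  m <- Biostrings::letterFrequency(Biostrings::AAStringSet(aa_seq),
                                   letters = AA_CODES)
  counts <- stats::setNames(as.integer(m[1, ]), AA_CODES)
  list(counts = counts, total = sum(counts))
}

#' Count nucleotides in one sequence
#'
#' @param nt_seq Uppercase sequence over `A,C,G,T,N`; `N` is excluded from
#'   counts and total. May be empty.
#' @return list with `counts` (named over A,C,G,T) and `total`.
#' @export
count_nucleotides <- function(nt_seq) {
  if (nzchar(nt_seq)) check_alphabet(nt_seq, "[^ACGTN]", "nucleotide")
  m <- Biostrings::letterFrequency(Biostrings::DNAStringSet(nt_seq),
                                   letters = NT_CODES)
  counts <- stats::setNames(as.integer(m[1, ]), NT_CODES)
  list(counts = counts, total = sum(counts))
}

#' Count codons in one CDS
#'
#' Reads frame-0, non-overlapping triplets from position 1. A trailing
#' incomplete triplet is dropped; triplets containing `N` are excluded from
#' counts and total. Stop codons are included in `counts`/`total`;
#' `total_sense` excludes them.
#'
#' @param nt_seq Uppercase CDS over `A,C,G,T,N`.
#' @return list with `counts` (named over the 64 triplets), `total` and
#'   `total_sense`.
#' @export
count_codons <- function(nt_seq) {
  if (nzchar(nt_seq)) check_alphabet(nt_seq, "[^ACGTN]", "nucleotide")
  m <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(nt_seq),
                                            width = 3, step = 3)
  counts <- stats::setNames(as.integer(m[1, ]), colnames(m))
  list(counts = counts, total = sum(counts),
       total_sense = sum(counts[SENSE_CODONS]))
}

#' Genomic GC percentage from nucleotide counts
#'
#' @param nt_counts Named counts over `A,C,G,T` (a vector, or the list
#'   returned by [count_nucleotides()]).
#' @return `100 * (G + C) / (A + C + G + T)`.
#' @export
gc_fraction <- function(nt_counts) {
  if (is.list(nt_counts)) nt_counts <- nt_counts$counts
  total <- sum(nt_counts[NT_CODES])
  if (is.na(total) || total == 0) {
    stop_undefined("GC content undefined: no unambiguous nucleotides")
  }
  100 * sum(nt_counts[c("G", "C")]) / total
}

# Matrix-form counting over a whole sequence table; one Biostrings pass per
# feature type. Row order matches dataset$sequences.
feature_count_matrices <- function(sequences) {
  for (i in seq_len(nrow(sequences))) {
    check_alphabet(sequences$aa_seq[i], "[^ACDEFGHIKLMNPQRSTVWYX*]", "amino-acid")
    if (nzchar(sequences$nt_seq[i])) {
      check_alphabet(sequences$nt_seq[i], "[^ACGTN]", "nucleotide")
    }
  }
  aa <- Biostrings::letterFrequency(Biostrings::AAStringSet(sequences$aa_seq),
                                    letters = AA_CODES)
  nt <- Biostrings::letterFrequency(Biostrings::DNAStringSet(sequences$nt_seq),
                                    letters = NT_CODES)
  codon <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences$nt_seq), width = 3, step = 3)
  storage.mode(aa) <- "double"
  storage.mode(nt) <- "double"
  storage.mode(codon) <- "double"
  list(
    aa = aa, aa_total = rowSums(aa),
    nt = nt, nt_total = rowSums(nt),
    codon = codon,
    codon_total = rowSums(codon),
    codon_total_sense = rowSums(codon[, SENSE_CODONS, drop = FALSE]),
    has_cds = nzchar(sequences$nt_seq)
  )
}

#' Pre-compute and cache per-sequence feature counts
#'
#' Mirrors the pre-calculated count tables of the original database: all
#' scoring operations sum these cached counts instead of re-reading the
#' sequences.
#'
#' @param ds A [cog_dataset()].
#' @return The dataset with `$counts` filled.
#' @export
precompute_counts <- function(ds) {
  stopifnot(inherits(ds, "cog_dataset"))
  if (is.null(ds$counts)) ds$counts <- feature_count_matrices(ds$sequences)
  ds
}

get_counts <- function(ds) {
  if (is.null(ds$counts)) feature_count_matrices(ds$sequences) else ds$counts
}

#' Write / read the feature-count cache as a TSV sidecar
#'
#' One row per sequence keyed by (organism_id, protein_gi), mirroring the
#' original tool's pre-calculated database tables.
#'
#' @param ds A [cog_dataset()] (counts are computed if absent).
#' @param path Sidecar TSV path.
#' @return `path` invisibly for the writer; for the reader, the dataset with
#'   `$counts` restored (after key verification).
#' @export
write_counts_tsv <- function(ds, path) {
  ds <- precompute_counts(ds)
  cn <- ds$counts
  tab <- data.frame(organism_id = ds$sequences$organism_id,
                    protein_gi = ds$sequences$protein_gi,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(cn$aa), aa_total = cn$aa_total,
               as.data.frame(cn$nt), nt_total = cn$nt_total,
               as.data.frame(cn$codon), codon_total = cn$codon_total)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(ds, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  key_file <- paste(tab$organism_id, tab$protein_gi, sep = "\r")
  key_ds <- paste(ds$sequences$organism_id, ds$sequences$protein_gi, sep = "\r")
  idx <- match(key_ds, key_file)
  if (anyNA(idx)) stop_integrity("count sidecar does not cover all sequences")
  tab <- tab[idx, , drop = FALSE]
  rownames(tab) <- NULL
  aa <- as.matrix(tab[, AA_CODES])
  # A,C,G,T columns appear twice (nucleotides and as codon names do not
  # clash, but aa names C/G/T/A do); nucleotide columns are suffixed by
  # read.delim's duplicate-name handling, recover them positionally.
  nt_cols <- which(names(tab) %in% c("A.1", "C.1", "G.1", "T.1"))
  nt <- as.matrix(tab[, nt_cols])
  colnames(nt) <- sub("\\.1$", "", colnames(nt))
  nt <- nt[, NT_CODES, drop = FALSE]
  codon <- as.matrix(tab[, CODONS])
  ds$counts <- list(aa = aa, aa_total = unname(rowSums(aa)),
                    nt = nt, nt_total = unname(rowSums(nt)),
                    codon = codon, codon_total = unname(rowSums(codon)),
                    codon_total_sense = unname(rowSums(codon[, SENSE_CODONS, drop = FALSE])),
                    has_cds = nzchar(ds$sequences$nt_seq))
  ds
}

#' Check that each CDS translates to its protein sequence
#'
#' Translates every paired CDS with the standard genetic code and compares to
#' the stored protein, ignoring a terminal stop codon. Ambiguous codons
#' (containing `N`) and ambiguous residues (`X`) are not counted as
#' mismatches. Mismatches produce warnings, never errors: real ortholog data
#' contains exceptions.
#'
#' @param ds A [cog_dataset()], or a single-row sequence record data.frame.
#' @param warn Emit a warning when mismatches are found.
#' @return data.frame with one row per sequence: `organism_id`, `protein_gi`,
#'   `status` (consistent / mismatch / skipped), `n_mismatch`,
#'   `first_mismatch` (position or NA).
#' @export
verify_cds_consistency <- function(ds, warn = TRUE) {
  seqs <- if (inherits(ds, "cog_dataset")) ds$sequences else ds
  gc_table <- Biostrings::GENETIC_CODE
  res <- data.frame(organism_id = seqs$organism_id,
                    protein_gi = seqs$protein_gi,
                    status = "skipped", n_mismatch = 0L,
                    first_mismatch = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(seqs))) {
    nt <- seqs$nt_seq[i]
    if (!nzchar(nt)) next
    n_cod <- nchar(nt) %/% 3L
    starts <- 3L * (seq_len(n_cod) - 1L) + 1L
    codons <- substring(nt, starts, starts + 2L)
    trans <- unname(gc_table[codons])          # NA for N-containing codons
    # drop one terminal stop, if present
    if (n_cod > 0L && !is.na(trans[n_cod]) && trans[n_cod] == "*") {
      trans <- trans[-n_cod]
    }
    aa <- strsplit(seqs$aa_seq[i], "")[[1]]
    L <- min(length(trans), length(aa))
    mism <- logical(max(length(trans), length(aa)))
    if (L > 0L) {
      t0 <- trans[seq_len(L)]; a0 <- aa[seq_len(L)]
      mism[seq_len(L)] <- !is.na(t0) & a0 != "X" & t0 != a0
    }
    if (length(trans) != length(aa)) {
      mism[(L + 1L):length(mism)] <- TRUE
    }
    n_bad <- sum(mism)
    res$status[i] <- if (n_bad == 0L) "consistent" else "mismatch"
    res$n_mismatch[i] <- n_bad
    if (n_bad > 0L) res$first_mismatch[i] <- which(mism)[1]
  }
  n_mismatch <- sum(res$status == "mismatch")
  if (warn && n_mismatch > 0L) {
    warning(sprintf("%d record(s) with CDS/protein translation mismatches",
                    n_mismatch), call. = FALSE)
  }
  res
}
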