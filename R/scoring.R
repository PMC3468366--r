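# The scoring engine. The central quantity is the APSF — the average
# percentage of the selected sequence features in a scope of sequences —
# computed by POOLING: summing the pre-computed per-sequence feature counts
# and dividing by the summed feature-type totals (length-weighted), not by
# averaging per-sequence percentages. Normalized frequency scores divide a
# scope's APSF by a reference APSF taken over the whole database or over all
# sequences of the selected organisms.

validate_features <- function(feature_type, features, include_stops) {
  features <- toupper(features)
  valid <- switch(feature_type,
                  amino_acid = AA_CODES,
                  nucleotide = NT_CODES,
                  codon = CODONS)
  bad <- setdiff(features, valid)
  if (length(bad)) {
    stop_usage(sprintf("invalid %s feature(s): %s", feature_type,
                       paste(bad, collapse = ", ")))
  }
  if (length(features) == 0L) stop_usage("empty feature set")
  if (feature_type == "codon" && !include_stops &&
      any(features %in% STOP_CODONS)) {
    stop_usage(paste("stop codons are excluded from the default sense-codon",
                     "denominator; pass include_stops = TRUE to query them"))
  }
  unique(features)
}

# Per-sequence numerator/denominator vectors for a feature set.
feature_vectors <- function(counts, feature_type, features, include_stops) {
  switch(feature_type,
    amino_acid = list(sel = rowSums(counts$aa[, features, drop = FALSE]),
                      tot = counts$aa_total,
                      usable = rep(TRUE, length(counts$aa_total))),
    nucleotide = list(sel = rowSums(counts$nt[, features, drop = FALSE]),
                      tot = counts$nt_total,
                      usable = counts$has_cds),
    codon = list(sel = rowSums(counts$codon[, features, drop = FALSE]),
                 tot = if (include_stops) counts$codon_total else counts$codon_total_sense,
                 usable = counts$has_cds)
  )
}

#' Average percentage of selected sequence features (APSF)
#'
#' Pools pre-computed feature counts over a scope of sequences:
#' `100 * sum(selected feature counts) / sum(feature-type totals)`. Records
#' lacking the needed sequence kind (protein-only records in nucleotide or
#' codon queries) are skipped and tallied.
#'
#' @param ds A [cog_dataset()].
#' @param scope Integer row indices into `ds$sequences` (`NULL` = all).
#' @param feature_type `"amino_acid"`, `"nucleotide"` or `"codon"`.
#' @param features Non-empty set of feature symbols of that type.
#' @param include_stops For codon queries: use all-triplet totals instead of
#'   the default sense-codon denominator.
#' @param mean_of_sequences Sensitivity alternative: average the
#'   per-sequence percentages instead of pooling.
#' @return list with `selected_feature_count`, `total_feature_count`,
#'   `apsf` (percentage), `n_sequences` (used), `n_skipped`.
#' @export
apsf <- function(ds, scope = NULL, feature_type = c("amino_acid", "nucleotide", "codon"),
                 features, include_stops = FALSE, mean_of_sequences = FALSE) {
  feature_type <- match.arg(feature_type)
  features <- validate_features(feature_type, features, include_stops)
  counts <- get_counts(ds)
  if (is.null(scope)) scope <- seq_len(nrow(ds$sequences))
  fv <- feature_vectors(counts, feature_type, features, include_stops)
  usable <- scope[fv$usable[scope] & fv$tot[scope] > 0]
  n_skipped <- length(scope) - length(usable)
  if (length(usable) == 0L) {
    stop_undefined(sprintf(
      "no usable sequences in scope for feature type '%s' (%d skipped)",
      feature_type, n_skipped), n_skipped = n_skipped)
  }
  sel <- sum(fv$sel[usable])
  tot <- sum(fv$tot[usable])
  pct <- if (mean_of_sequences) {
    mean(100 * fv$sel[usable] / fv$tot[usable])
  } else {
    100 * sel / tot
  }
  list(selected_feature_count = sel, total_feature_count = tot, apsf = pct,
       n_sequences = length(usable), n_skipped = n_skipped)
}

#' Reference APSF for normalization
#'
#' Mode `"whole_database"` pools over every sequence in the dataset (all
#' COGs, all organisms); mode `"selected_organisms"` pools over all sequences
#' of the selected organisms across all COGs.
#'
#' @inheritParams apsf
#' @param normalization `"whole_database"` or `"selected_organisms"`.
#' @param selection Organism [cog_selection] (required for mode
#'   `"selected_organisms"`).
#' @return The reference APSF percentage.
#' @export
reference_apsf <- function(ds, feature_type, features,
                           normalization = c("whole_database", "selected_organisms"),
                           selection = NULL, include_stops = FALSE,
                           mean_of_sequences = FALSE) {
  normalization <- match.arg(normalization)
  scope <- if (normalization == "whole_database") {
    NULL
  } else {
    if (is.null(selection)) stop_usage("mode 'selected_organisms' needs a selection")
    scope_sequences(ds, selection)
  }
  apsf(ds, scope, feature_type, features, include_stops, mean_of_sequences)$apsf
}

# Subgroup label per sequence at a taxonomic rank (NA when the organism
# lacks the rank).
sequence_subgroups <- function(ds, rank) {
  if (!(rank %in% TAXONOMIC_RANKS)) {
    stop_usage(sprintf("unsupported subgroup rank '%s'", rank))
  }
  if (!ds$has_taxonomy) stop_usage("subgrouping requires an attached taxonomy")
  vals <- ds$organisms[[rank]]
  vals[match(ds$sequences$organism_id, ds$organisms$organism_id)]
}

# Shared grouped-scoring kernel for score_cogs and score_batch: `groups` is a
# factor-like label per dataset sequence row (NA = out of scope).
score_groups <- function(ds, group_label, subgroup, feature_type, features,
                         normalization, selection, include_stops,
                         mean_of_sequences, descriptions) {
  counts <- get_counts(ds)
  fv <- feature_vectors(counts, feature_type, features, include_stops)
  in_scope <- !is.na(group_label)
  key <- interaction(group_label, subgroup, drop = TRUE, sep = "\r")
  usable <- in_scope & fv$usable & fv$tot > 0

  all_keys <- levels(key)
  rows <- data.frame(key = all_keys, stringsAsFactors = FALSE)
  split_keys <- strsplit(all_keys, "\r", fixed = TRUE)
  rows$group_label <- vapply(split_keys, `[`, character(1), 1)
  rows$subgroup <- vapply(split_keys, `[`, character(1), 2)
  rows$subgroup[rows$subgroup == "\a"] <- NA_character_

  agg <- function(x, w) {
    out <- stats::setNames(rep(0, length(all_keys)), all_keys)
    if (any(w)) {
      s <- rowsum(x[w], as.character(key[w]))
      out[rownames(s)] <- s[, 1]
    }
    out
  }
  rows$selected_feature_count <- agg(fv$sel, usable)[rows$key]
  rows$total_feature_count <- agg(fv$tot, usable)[rows$key]
  rows$n_sequences <- agg(rep(1, length(fv$sel)), usable)[rows$key]
  rows$n_skipped <- agg(rep(1, length(fv$sel)), in_scope & !(fv$usable & fv$tot > 0))[rows$key]

  n_omitted <- sum(rows$n_sequences == 0)
  rows <- rows[rows$n_sequences > 0, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop_undefined("no group has usable sequences in scope")
  }
  if (mean_of_sequences) {
    pct <- 100 * fv$sel / fv$tot
    m <- agg(ifelse(usable, pct, 0), usable)[rows$key]
    rows$apsf <- m / rows$n_sequences
  } else {
    rows$apsf <- 100 * rows$selected_feature_count / rows$total_feature_count
  }

  if (normalization == "none") {
    rows$score <- rows$apsf
    ref <- NA_real_
  } else {
    ref <- reference_apsf(ds, feature_type, features, normalization,
                          selection, include_stops, mean_of_sequences)
    if (ref == 0) {
      stop_undefined("reference APSF is zero; normalized scores undefined")
    }
    rows$score <- rows$apsf / ref
  }
  rows$description <- descriptions[rows$group_label]
  rows$description[is.na(rows$description)] <- ""

  rows <- rows[order(-rows$score, rows$group_label, rows$subgroup,
                     na.last = TRUE, method = "radix"), , drop = FALSE]
  rows$key <- NULL
  rownames(rows) <- NULL
  rows <- rows[, c("group_label", "subgroup", "n_sequences", "n_skipped",
                   "selected_feature_count", "total_feature_count",
                   "apsf", "score", "description")]
  attr(rows, "normalization") <- normalization
  attr(rows, "feature_type") <- feature_type
  attr(rows, "features") <- features
  attr(rows, "reference_apsf") <- ref
  attr(rows, "n_groups_omitted") <- n_omitted
  class(rows) <- c("cog_scores", "data.frame")
  rows
}

#' Score every COG for a feature set
#'
#' Computes one ranking row per COG (or per COG x taxon subgroup): the pooled
#' APSF of the feature set over the COG's sequences from the selected
#' organisms, optionally divided by a reference APSF. Rows are sorted by
#' score descending, ties broken by COG id ascending. COGs with no usable
#' sequence in scope are omitted and tallied in the `n_groups_omitted`
#' attribute.
#'
#' @inheritParams apsf
#' @param selection Organism [cog_selection] (`NULL` = all organisms).
#' @param normalization `"none"`, `"whole_database"` or
#'   `"selected_organisms"`.
#' @param subgroup_rank Optional taxonomic rank; one row per taxon occurring
#'   in the selection at that rank, per COG.
#' @param cog_scope Optional explicit COG id list (`NULL` = all COGs).
#' @return A `cog_scores` data.frame (see [score_batch()] for columns).
#' @export
score_cogs <- function(ds, feature_type = c("amino_acid", "nucleotide", "codon"),
                       features, selection = NULL,
                       normalization = c("none", "whole_database", "selected_organisms"),
                       subgroup_rank = NULL, cog_scope = NULL,
                       include_stops = FALSE, mean_of_sequences = FALSE) {
  feature_type <- match.arg(feature_type)
  normalization <- match.arg(normalization)
  features <- validate_features(feature_type, features, include_stops)
  idx <- scope_sequences(ds, selection, cog_scope)
  group <- rep(NA_character_, nrow(ds$sequences))
  group[idx] <- ds$sequences$cog_id[idx]
  subgroup <- rep("\a", nrow(ds$sequences))
  if (!is.null(subgroup_rank)) {
    sg <- sequence_subgroups(ds, subgroup_rank)
    subgroup <- sg
    group[is.na(sg)] <- NA_character_   # organisms lacking the rank drop out
  }
  descriptions <- stats::setNames(ds$cogs$description, ds$cogs$cog_id)
  score_groups(ds, group, subgroup, feature_type, features, normalization,
               selection, include_stops, mean_of_sequences, descriptions)
}

#' @export
print.cog_scores <- function(x, n = 10L, ...) {
  cat(sprintf("<cog_scores> %d row(s); features {%s} (%s); normalization: %s",
              nrow(x), paste(attr(x, "features"), collapse = ","),
              attr(x, "feature_type"), attr(x, "normalization")))
  if (!is.na(attr(x, "reference_apsf"))) {
    cat(sprintf("; reference APSF %.4f%%", attr(x, "reference_apsf")))
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more row(s)\n", nrow(x) - n))
  invisible(x)
}

#' Parse a batch query text
#'
#' Grammar, one query per line: `NAME : FEATURES : COG_LIST` with features
#' comma-separated and COG ids comma- or whitespace-separated. Blank lines
#' and `#` comments are ignored. One score per line is calculated downstream.
#'
#' @param text Character vector of lines (or one string with embedded
#'   newlines).
#' @param ds Optional [cog_dataset()]; when given, COG ids are checked
#'   against its catalogue.
#' @return list of groups, each `list(name, features, cog_ids)`.
#' @export
parse_batch <- function(text, ds = NULL) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  groups <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(sub("#.*$", "", lines[ln]))
    if (!nzchar(raw)) next
    parts <- trimws(strsplit(raw, ":", fixed = TRUE)[[1]])
    if (length(parts) != 3L || !all(nzchar(parts))) {
      stop_parse(sprintf("malformed batch line %d: '%s'", ln, lines[ln]))
    }
    features <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    features <- features[nzchar(features)]
    cog_ids <- strsplit(parts[3], "[,[:space:]]+")[[1]]
    cog_ids <- cog_ids[nzchar(cog_ids)]
    if (length(features) == 0L || length(cog_ids) == 0L) {
      stop_parse(sprintf("malformed batch line %d: '%s'", ln, lines[ln]))
    }
    if (!is.null(ds)) {
      unknown <- setdiff(cog_ids, ds$cogs$cog_id)
      if (length(unknown)) {
        stop_usage(sprintf("batch line %d: unknown COG id(s): %s",
                           ln, paste(unknown, collapse = ", ")))
      }
    }
    groups[[length(groups) + 1L]] <-
      list(name = parts[1], features = features, cog_ids = cog_ids)
  }
  groups
}

#' Score user-defined groups of COGs
#'
#' For each batch group, pools the APSF over all sequences of all listed
#' COGs (within the selection, per subgroup when requested), then normalizes
#' like [score_cogs()]. Cumulative group scores are how pathway-level bias
#' (e.g. the cognate-bias analysis) is measured.
#'
#' @inheritParams score_cogs
#' @param groups Parsed batch groups from [parse_batch()].
#' @return A `cog_scores` data.frame, one row per group (x subgroup); groups
#'   with an empty scope are omitted with a warning.
#' @export
score_batch <- function(ds, groups, feature_type = c("amino_acid", "nucleotide", "codon"),
                        selection = NULL,
                        normalization = c("none", "whole_database", "selected_organisms"),
                        subgroup_rank = NULL, include_stops = FALSE,
                        mean_of_sequences = FALSE) {
  feature_type <- match.arg(feature_type)
  normalization <- match.arg(normalization)
  if (length(groups) == 0L) stop_usage("no batch groups to score")
  subgroup_all <- rep("\a", nrow(ds$sequences))
  if (!is.null(subgroup_rank)) subgroup_all <- sequence_subgroups(ds, subgroup_rank)

  out <- list()
  for (g in groups) {
    features <- validate_features(feature_type, g$features, include_stops)
    idx <- scope_sequences(ds, selection, g$cog_ids)
    group <- rep(NA_character_, nrow(ds$sequences))
    group[idx] <- g$name
    subgroup <- subgroup_all
    if (!is.null(subgroup_rank)) group[is.na(subgroup)] <- NA_character_
    rows <- tryCatch(
      score_groups(ds, group, subgroup, feature_type, features, normalization,
                   selection, include_stops, mean_of_sequences,
                   stats::setNames(sprintf("features {%s} over %d COG(s)",
                                           paste(features, collapse = ","),
                                           length(g$cog_ids)),
                                   g$name)),
      cogbias_undefined_error = function(e) {
        warning(sprintf("batch group '%s' has no usable sequences in scope; omitted",
                        g$name), call. = FALSE)
        NULL
      })
    if (!is.null(rows)) out[[length(out) + 1L]] <- rows
  }
  if (length(out) == 0L) stop_undefined("every batch group had an empty scope")
  res <- do.call(rbind, lapply(out, as.data.frame))
  res <- res[order(-res$score, res$group_label, res$subgroup,
                   na.last = TRUE, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "normalization") <- normalization
  attr(res, "feature_type") <- feature_type
  attr(res, "n_groups_omitted") <- length(groups) - length(out)
  class(res) <- c("cog_scores", "data.frame")
  res
}
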