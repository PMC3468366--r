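# The four composition analyses shipped as recipes on top of the scoring
# engine: positively-charged-residue ranking, cognate-bias batch scoring,
# the (E+K)/(Q+H)-vs-OGT and AGR-codon-vs-OGT regressions, and the GC-by-
# oxygen-class comparison.

#' Rank COGs by positively charged residues
#'
#' Convenience recipe: K/R/H amino-acid frequency per COG, normalized against
#' all sequences in the database. In real ortholog data the top of this
#' ranking is dominated by ribosomal proteins, whose arginine/lysine-rich
#' tails contact the rRNA backbone.
#'
#' @param ds A [cog_dataset()].
#' @param selection Optional organism [cog_selection].
#' @return A `cog_scores` ranking.
#' @export
rank_positive_residues <- function(ds, selection = NULL) {
  score_cogs(ds, "amino_acid", c("K", "R", "H"), selection = selection,
             normalization = "whole_database")
}

#' Load a cognate map (amino acid -> biosynthesis COGs)
#'
#' @param path TSV with columns `amino_acid` and `cog_ids` (comma-separated
#'   COG ids of the amino acid's biosynthetic enzymes).
#' @return Named list: one character vector of COG ids per amino acid.
#' @export
load_cognate_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "cog_ids") %in% names(tab))) {
    stop_parse("cognate map must have columns amino_acid, cog_ids")
  }
  aa <- toupper(trimws(tab$amino_acid))
  bad <- setdiff(aa, AA_CODES)
  if (length(bad)) {
    stop_parse(sprintf("cognate map has invalid amino acid(s): %s",
                       paste(bad, collapse = ", ")))
  }
  stats::setNames(lapply(strsplit(tab$cog_ids, "[,[:space:]]+"),
                         function(x) x[nzchar(x)]), aa)
}

#' Cognate-bias analysis
#'
#' For each amino acid x in the cognate map, scores the batch group
#' (features = {x}, COGs = x's biosynthetic-enzyme COGs) per taxon subgroup,
#' normalized against the whole database by default. Scores below 1 indicate
#' that the amino acid is underrepresented in the enzymes of its own
#' biosynthesis (the cognate bias hypothesis).
#'
#' @param ds A [cog_dataset()].
#' @param cognate_map Named list (amino acid -> COG ids), e.g. from
#'   [load_cognate_map()].
#' @param normalization Reference mode, default `"whole_database"`.
#' @param subgroup_rank Taxonomic rank for subgrouping, default `"species"`.
#' @param selection Optional organism [cog_selection].
#' @return data.frame with columns `subgroup` (taxon), `amino_acid`, `score`,
#'   `apsf`, `n_sequences`; cells with no sequences are absent.
#' @export
cognate_bias <- function(ds, cognate_map,
                         normalization = "whole_database",
                         subgroup_rank = "species", selection = NULL) {
  if (length(cognate_map) == 0L) stop_usage("empty cognate map")
  groups <- lapply(names(cognate_map), function(a) {
    list(name = a, features = a, cog_ids = cognate_map[[a]])
  })
  rows <- score_batch(ds, groups, "amino_acid", selection = selection,
                      normalization = normalization,
                      subgroup_rank = subgroup_rank)
  out <- data.frame(subgroup = rows$subgroup, amino_acid = rows$group_label,
                    score = rows$score, apsf = rows$apsf,
                    n_sequences = rows$n_sequences, stringsAsFactors = FALSE)
  out[order(out$amino_acid, out$subgroup, method = "radix"), , drop = FALSE]
}

#' Thermophily ratio (E+K)/(Q+H) of one proteome
#'
#' Pooled over all of the organism's protein sequences: the count of
#' glutamate plus lysine residues divided by the count of glutamine plus
#' histidine. The ratio rises with optimum growth temperature.
#'
#' @param ds A [cog_dataset()].
#' @param organism_id One organism id, or `NULL` for a named vector over all
#'   organisms (`NA` where undefined).
#' @return Ratio (dimensionless), or named vector.
#' @export
ekqh_ratio <- function(ds, organism_id = NULL) {
  counts <- get_counts(ds)
  one <- function(oid) {
    idx <- which(ds$sequences$organism_id == oid)
    if (length(idx) == 0L) {
      stop_undefined(sprintf("organism '%s' has no protein sequences", oid))
    }
    num <- sum(counts$aa[idx, c("E", "K")])
    den <- sum(counts$aa[idx, c("Q", "H")])
    if (den == 0) {
      stop_undefined(sprintf("(E+K)/(Q+H) undefined for '%s': Q+H count is zero", oid))
    }
    num / den
  }
  if (!is.null(organism_id)) return(one(organism_id))
  vapply(stats::setNames(ds$organisms$organism_id, ds$organisms$organism_id),
         function(oid) tryCatch(one(oid), cogbias_undefined_error = function(e) NA_real_),
         numeric(1))
}

#' AGR fraction of arginine codons in one genome
#'
#' Percentage of AGR codons (AGA + AGG; R = purine) among all six arginine
#' codons, pooled over the organism's CDS codon counts. Thermophiles
#' preferentially use AGR codons.
#'
#' @param ds A [cog_dataset()].
#' @param organism_id One organism id, or `NULL` for a named vector over all
#'   organisms (`NA` where undefined).
#' @return Percentage in `[0, 100]`, or named vector.
#' @export
agr_fraction <- function(ds, organism_id = NULL) {
  counts <- get_counts(ds)
  one <- function(oid) {
    idx <- which(ds$sequences$organism_id == oid)
    if (length(idx) == 0L) {
      stop_undefined(sprintf("organism '%s' has no sequences", oid))
    }
    agr <- sum(counts$codon[idx, AGR_CODONS])
    all_arg <- sum(counts$codon[idx, ARG_CODONS])
    if (all_arg == 0) {
      stop_undefined(sprintf("no arginine codons for '%s'", oid))
    }
    100 * agr / all_arg
  }
  if (!is.null(organism_id)) return(one(organism_id))
  vapply(stats::setNames(ds$organisms$organism_id, ds$organisms$organism_id),
         function(oid) tryCatch(one(oid), cogbias_undefined_error = function(e) NA_real_),
         numeric(1))
}

#' Regress a per-organism quantity on optimum growth temperature
#'
#' Ordinary least squares of `value ~ OGT` (slope in value units per degree
#' Celsius) plus the Pearson correlation of the pairs. Organisms missing
#' either quantity are dropped and reported.
#'
#' @param values Named numeric vector (organism -> value).
#' @param ogts Named numeric vector (organism -> OGT in degrees Celsius).
#' @param min_n Minimum number of complete pairs (default 3; the internal
#'   kernel is exact already at 2 points).
#' @return An `ogt_regression` object: `slope`, `intercept`, `r`, `n`,
#'   `slope_se`, `dropped` (ids), `zero_variance` flag, and the underlying
#'   `lm` fit.
#' @export
ogt_regression <- function(values, ogts, min_n = 3L) {
  org <- union(names(values), names(ogts))
  v <- values[org]; t <- ogts[org]
  ok <- !is.na(v) & !is.na(t)
  dropped <- org[!ok]
  v <- as.numeric(v[ok]); t <- as.numeric(t[ok])
  if (sum(ok) < min_n) {
    stop_undefined(sprintf("only %d complete (value, OGT) pairs; need >= %d",
                           sum(ok), min_n))
  }
  if (stats::var(t) == 0) stop_undefined("OGT has zero variance; slope undefined")
  zero_var <- stats::var(v) == 0
  if (zero_var) {
    res <- structure(list(slope = 0, intercept = v[1], r = NA_real_,
                          n = length(v), slope_se = 0, dropped = dropped,
                          zero_variance = TRUE, fit = NULL),
                     class = "ogt_regression")
    return(res)
  }
  fit <- stats::lm(v ~ t)
  # summary.lm warns on exactly collinear input; exact fits are legitimate here
  co <- suppressWarnings(summary(fit)$coefficients)
  structure(list(slope = unname(co["t", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r = stats::cor(t, v),
                 n = length(v),
                 slope_se = unname(co["t", "Std. Error"]),
                 dropped = dropped, zero_variance = FALSE, fit = fit),
            class = "ogt_regression")
}

#' @export
print.ogt_regression <- function(x, ...) {
  cat(sprintf("OGT regression: slope %.4g per degree C (SE %.3g), intercept %.4g, r = %s, n = %d\n",
              x$slope, x$slope_se, x$intercept,
              if (is.na(x$r)) "undefined (zero variance)" else sprintf("%.3f", x$r),
              x$n))
  if (length(x$dropped)) {
    cat(sprintf("  dropped (missing value or OGT): %s\n",
                paste(x$dropped, collapse = ", ")))
  }
  invisible(x)
}

#' @export
#' @method plot ogt_regression
plot.ogt_regression <- function(x, xlab = "OGT (degrees C)", ylab = "value", ...) {
  if (is.null(x$fit)) stop_undefined("zero-variance fit; nothing to plot")
  t <- x$fit$model$t; v <- x$fit$model$v
  graphics::plot(t, v, xlab = xlab, ylab = ylab, pch = 19, ...)
  graphics::abline(x$fit, col = "red3")
  invisible(x)
}

#' Pooled GC content of two trait-defined organism patterns
#'
#' Selects organisms by two trait patterns (default the pre-defined
#' "Aerobia" and "Anaerobia") and pools the GC percentage over all CDS of
#' each selection. Pooling matches the scoring engine; a per-organism mean is
#' available as a sensitivity alternative.
#'
#' @param ds A [cog_dataset()] with traits attached.
#' @param pattern_a,pattern_b Trait patterns for [select_by_trait()].
#' @param per_organism_mean Average per-organism GC values instead of pooling.
#' @param ogt_min Passed through for `"thermophile"` patterns.
#' @return list with `gc_a`, `gc_b` (percent), `n_a`, `n_b` (organisms),
#'   `pattern_a`, `pattern_b`.
#' @export
gc_by_trait <- function(ds, pattern_a = "aerobia", pattern_b = "anaerobia",
                        per_organism_mean = FALSE, ogt_min = NULL) {
  counts <- get_counts(ds)
  one <- function(pattern) {
    sel <- select_by_trait(ds, pattern, ogt_min = ogt_min)
    if (length(sel$organism_ids) == 0L) {
      stop_undefined(sprintf("trait pattern '%s' selects no organism", pattern))
    }
    idx <- scope_sequences(ds, sel)
    idx <- idx[counts$nt_total[idx] > 0]
    if (length(idx) == 0L) {
      stop_undefined(sprintf("selection '%s' has no CDS", pattern))
    }
    gc <- if (per_organism_mean) {
      per_org <- vapply(split(idx, ds$sequences$organism_id[idx]), function(ii) {
        100 * sum(counts$nt[ii, c("G", "C")]) / sum(counts$nt_total[ii])
      }, numeric(1))
      mean(per_org)
    } else {
      100 * sum(counts$nt[idx, c("G", "C")]) / sum(counts$nt_total[idx])
    }
    list(gc = gc, n = length(sel$organism_ids))
  }
  a <- one(pattern_a); b <- one(pattern_b)
  list(gc_a = a$gc, gc_b = b$gc, n_a = a$n, n_b = b$n,
       pattern_a = pattern_a, pattern_b = pattern_b)
}
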