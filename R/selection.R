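# Organism selections: by explicit list, taxon subtree, trait pattern, or
# COG membership, combinable into supersets (union, the default) or
# intersections (the logical-AND reading).

new_selection <- function(ids, provenance) {
  structure(list(organism_ids = sort(unique(ids)),
                 provenance = provenance),
            class = "cog_selection")
}

#' @export
print.cog_selection <- function(x, ...) {
  cat(sprintf("<cog_selection> %d organism(s) [%s]\n",
              length(x$organism_ids), paste(x$provenance, collapse = "; ")))
  invisible(x)
}

#' Select organisms manually by id
#'
#' @param ds A [cog_dataset()].
#' @param ids Character vector of organism ids.
#' @return A `cog_selection`.
#' @export
select_ids <- function(ds, ids) {
  unknown <- setdiff(ids, ds$organisms$organism_id)
  if (length(unknown)) {
    stop_usage(sprintf("unknown organism id(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  new_selection(ids, sprintf("ids:%d listed", length(unique(ids))))
}

#' Select organisms by taxon at a given rank
#'
#' Matches the lineage value at `rank` against `taxon`, case-insensitively
#' and exactly. Organisms lacking that rank never match.
#'
#' @param ds A [cog_dataset()] with taxonomy attached.
#' @param rank One of the seven supported ranks (superkingdom ... species).
#' @param taxon Taxon name to match.
#' @return A `cog_selection` (possibly empty, with a warning).
#' @export
select_by_taxon <- function(ds, rank, taxon) {
  if (!(rank %in% TAXONOMIC_RANKS)) {
    stop_usage(sprintf("unsupported rank '%s' (use one of: %s)",
                       rank, paste(TAXONOMIC_RANKS, collapse = ", ")))
  }
  if (!ds$has_taxonomy) stop_usage("no taxonomy attached to the dataset")
  vals <- ds$organisms[[rank]]
  hit <- !is.na(vals) & tolower(vals) == tolower(taxon)
  if (!any(hit)) {
    warning(sprintf("no organism matches %s = '%s'", rank, taxon), call. = FALSE)
  }
  new_selection(ds$organisms$organism_id[hit],
                sprintf("taxon:%s=%s", rank, taxon))
}

#' Select organisms by trait pattern
#'
#' Pre-defined patterns: `"aerobia"` (oxygen class aerobe), `"anaerobia"`
#' (anaerobe) — facultative and unknown organisms belong to neither — and
#' `"thermophile"`, organisms with optimum growth temperature at or above
#' `ogt_min` degrees Celsius.
#'
#' @param ds A [cog_dataset()] with traits attached.
#' @param pattern `"aerobia"`, `"anaerobia"` or `"thermophile"`.
#' @param ogt_min Required OGT threshold for `"thermophile"`.
#' @return A `cog_selection`.
#' @export
select_by_trait <- function(ds, pattern = c("aerobia", "anaerobia", "thermophile"),
                            ogt_min = NULL) {
  pattern <- match.arg(pattern)
  if (!ds$has_traits) stop_usage("no trait table attached to the dataset")
  org <- ds$organisms
  if (pattern == "thermophile") {
    if (is.null(ogt_min)) stop_usage("pattern 'thermophile' requires ogt_min")
    if (all(is.na(org$ogt_celsius))) {
      stop_usage("trait table carries no OGT values")
    }
    hit <- !is.na(org$ogt_celsius) & org$ogt_celsius >= ogt_min
    prov <- sprintf("trait:ogt>=%g", ogt_min)
  } else {
    want <- if (pattern == "aerobia") "aerobe" else "anaerobe"
    hit <- !is.na(org$oxygen_class) & org$oxygen_class == want
    prov <- sprintf("trait:%s", pattern)
  }
  new_selection(org$organism_id[hit], prov)
}

#' Select organisms occurring in a COG
#'
#' @param ds A [cog_dataset()].
#' @param cog_id COG of interest.
#' @return A `cog_selection` of all organisms with at least one member
#'   sequence in that COG.
#' @export
select_by_cog <- function(ds, cog_id) {
  if (!(cog_id %in% ds$cogs$cog_id)) {
    stop_usage(sprintf("unknown COG id: %s", cog_id))
  }
  ids <- unique(ds$sequences$organism_id[ds$sequences$cog_id == cog_id])
  new_selection(ids, sprintf("cog:%s", cog_id))
}

#' Combine consecutive selections
#'
#' Consecutive selection criteria form a superset of organisms by default
#' (set union); `method = "intersect"` gives the logical-AND combination
#' instead.
#'
#' @param ... `cog_selection` objects (or one list of them).
#' @param method `"union"` (default) or `"intersect"`.
#' @return A `cog_selection` with concatenated provenance.
#' @export
combine_selections <- function(..., method = c("union", "intersect")) {
  method <- match.arg(method)
  sels <- list(...)
  if (length(sels) == 1L && !inherits(sels[[1]], "cog_selection")) {
    sels <- sels[[1]]
  }
  if (length(sels) == 0L) stop_usage("combine_selections needs >= 1 selection")
  stopifnot(all(vapply(sels, inherits, logical(1), "cog_selection")))
  ids <- lapply(sels, `[[`, "organism_ids")
  out <- if (method == "union") Reduce(union, ids) else Reduce(intersect, ids)
  new_selection(out, unlist(lapply(sels, `[[`, "provenance")))
}

#' All organisms of a dataset as a selection
#'
#' @param ds A [cog_dataset()].
#' @return A `cog_selection` covering every organism.
#' @export
select_all <- function(ds) {
  new_selection(ds$organisms$organism_id, "all organisms")
}
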