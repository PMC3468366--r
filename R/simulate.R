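# Synthetic NUCOCOG-dialect datasets with controllable composition
# structure: per-COG amino-acid enrichments, per-organism GC and AGR codon
# targets, and an OGT model linking growth temperature to AGR usage. CDS are
# produced by back-translation with synonymous-codon sampling probabilities
# solved in closed form (see vignette), so every generated record translates
# exactly back to its protein.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Specify a synthetic dataset
#'
#' @param n_organisms,n_cogs,seq_len_codons Dataset dimensions; one sequence
#'   per (organism, COG), `seq_len_codons` residues each (>= 10).
#' @param background_aa_freqs Length-20 named frequency vector (normalized if
#'   slightly off).
#' @param enriched list of `list(cog_ids=, features=, factor=)`: in the named
#'   COGs the listed amino acids are drawn at `factor` times their background
#'   frequency (the remaining mass is redistributed proportionally over the
#'   other residues), so `factor` is the realized relative enrichment.
#' @param per_organism_gc Target GC fraction(s) in `[0,1]`: one number or a
#'   vector of length `n_organisms`.
#' @param per_organism_agr Target AGR fraction(s) among arginine codons, same
#'   shape. Mutually exclusive with `ogt_model`.
#' @param ogt_model Optional `list(slope, intercept, sigma, ogt_range)`:
#'   organisms get OGT ~ U(ogt_range) degrees C and an AGR-fraction target
#'   `slope * OGT + intercept + N(0, sigma)`, clamped to `[0.05, 0.95]`.
#' @param oxygen_classes Optional per-organism oxygen classes; default
#'   alternates aerobe/anaerobe.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `bias_spec` object.
#' @export
bias_spec <- function(n_organisms = 20L, n_cogs = 100L, seq_len_codons = 300L,
                      background_aa_freqs = BACKGROUND_AA_FREQS,
                      enriched = list(),
                      per_organism_gc = 0.5,
                      per_organism_agr = NULL,
                      ogt_model = NULL,
                      oxygen_classes = NULL,
                      seed = 1L) {
  if (seq_len_codons < 10L) stop_usage("seq_len_codons must be >= 10")
  if (n_organisms < 1L || n_cogs < 1L) stop_usage("need >= 1 organism and COG")
  f <- background_aa_freqs[AA_CODES]
  if (anyNA(f) || any(f < 0)) {
    stop_usage("background_aa_freqs must be a named non-negative vector over the 20 residues")
  }
  f <- f / sum(f)
  for (e in enriched) {
    if (!all(c("cog_ids", "features", "factor") %in% names(e))) {
      stop_usage("each enrichment needs cog_ids, features, factor")
    }
    if (e$factor <= 0) stop_usage("enrichment factor must be > 0")
    if (!all(e$features %in% AA_CODES)) {
      stop_usage("enrichment features must be amino-acid codes")
    }
    if (sum(e$factor * f[e$features]) >= 1) {
      stop_usage("enrichment factor pushes feature mass to >= 1")
    }
  }
  if (!is.null(per_organism_agr) && !is.null(ogt_model)) {
    stop_usage("give either per_organism_agr or ogt_model, not both")
  }
  recycle <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L) x <- rep(x, n_organisms)
    if (length(x) != n_organisms) {
      stop_usage(sprintf("%s must have length 1 or n_organisms", what))
    }
    x
  }
  gc <- recycle(per_organism_gc, "per_organism_gc")
  if (any(gc < 0 | gc > 1)) stop_usage("per_organism_gc must be in [0,1]")
  agr <- recycle(per_organism_agr, "per_organism_agr")
  if (!is.null(agr) && any(agr < 0 | agr > 1)) {
    stop_usage("per_organism_agr must be in [0,1]")
  }
  if (!is.null(ogt_model)) {
    ogt_model$ogt_range <- ogt_model$ogt_range %||% c(20, 45)
    if (!all(c("slope", "intercept", "sigma") %in% names(ogt_model))) {
      stop_usage("ogt_model needs slope, intercept, sigma")
    }
  }
  oxy <- recycle(oxygen_classes, "oxygen_classes") %||%
    rep_len(c("aerobe", "anaerobe"), n_organisms)
  if (!all(oxy %in% OXYGEN_CLASSES)) stop_usage("invalid oxygen class")
  structure(list(n_organisms = as.integer(n_organisms),
                 n_cogs = as.integer(n_cogs),
                 seq_len_codons = as.integer(seq_len_codons),
                 background_aa_freqs = f,
                 enriched = enriched,
                 per_organism_gc = gc,
                 per_organism_agr = agr,
                 ogt_model = ogt_model,
                 oxygen_classes = oxy,
                 seed = as.integer(seed)),
            class = "bias_spec")
}

# Synonymous codons per amino acid with their lowest- and highest-GC members
# (alphabetical tie-break for determinism).
synonym_table <- function() {
  code <- Biostrings::GENETIC_CODE
  lapply(stats::setNames(AA_CODES, AA_CODES), function(a) {
    cods <- sort(names(code)[code == a])
    gc <- CODON_GC[cods]
    list(codons = cods,
         min = cods[which.min(gc)], max = cods[which.max(gc)],
         gc_min = min(gc), gc_max = max(gc))
  })
}

# Expected per-codon GC at mixing weight lambda (0 = all lowest-GC synonyms,
# 1 = all highest-GC), for a given mean amino-acid composition and an AGR
# target for arginine. Affine in lambda, so the target solves in closed form.
solve_lambda <- function(mean_aa, gc_target, agr_target, L, syn) {
  e0 <- e1 <- 0
  for (a in AA_CODES) {
    if (a == "R") {
      e0 <- e0 + mean_aa[a] * (agr_target * CODON_GC["AGA"] +
                               (1 - agr_target) * CODON_GC["CGT"])
      e1 <- e1 + mean_aa[a] * (agr_target * CODON_GC["AGG"] +
                               (1 - agr_target) * CODON_GC["CGC"])
    } else {
      e0 <- e0 + mean_aa[a] * syn[[a]]$gc_min
      e1 <- e1 + mean_aa[a] * syn[[a]]$gc_max
    }
  }
  # one TAA stop codon (GC 0) is appended per sequence
  needed <- gc_target * (L + 1) / L
  lambda <- (needed - e0) / (e1 - e0)
  list(lambda = lambda, feasible = lambda >= -1e-9 & lambda <= 1 + 1e-9)
}

codon_sampler <- function(lambda, agr_target, syn) {
  lambda <- clamp(lambda, 0, 1)
  out <- lapply(syn, function(s) {
    if (s$min == s$max) {
      list(codons = s$min, probs = 1)
    } else {
      list(codons = c(s$min, s$max), probs = c(1 - lambda, lambda))
    }
  })
  out$R <- list(codons = c("AGA", "AGG", "CGT", "CGC"),
                probs = c(agr_target * (1 - lambda), agr_target * lambda,
                          (1 - agr_target) * (1 - lambda),
                          (1 - agr_target) * lambda))
  out
}

#' Generate a synthetic ortholog dataset
#'
#' Proteins are drawn residue-by-residue from the (per-COG enriched)
#' background composition; CDS are back-translated with synonymous-codon
#' probabilities solved per organism to meet its GC and AGR targets, plus a
#' terminal TAA stop codon. Taxonomy (one species per organism) and trait
#' tables are attached. Fully deterministic given the spec's seed.
#'
#' @param spec A [bias_spec()].
#' @return list with `dataset` (a [cog_dataset()] with taxonomy and traits
#'   attached) and `ground_truth` (list of `organisms` and `enrichments`
#'   data.frames echoing the generating parameters).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "bias_spec"))
  set.seed(spec$seed)
  n <- spec$n_organisms
  m <- spec$n_cogs
  L <- spec$seq_len_codons
  org_ids <- sprintf("org%03d", seq_len(n))
  cog_ids <- sprintf("COG%04d", seq_len(m))

  # organism-level draws first, in id order
  if (!is.null(spec$ogt_model)) {
    om <- spec$ogt_model
    ogt <- stats::runif(n, om$ogt_range[1], om$ogt_range[2])
    agr <- clamp(om$slope * ogt + om$intercept + stats::rnorm(n, 0, om$sigma),
                 0.05, 0.95)
  } else {
    ogt <- rep(NA_real_, n)
    agr <- spec$per_organism_agr %||% rep(0.5, n)
  }

  # per-COG residue composition
  freqs <- matrix(rep(spec$background_aa_freqs, each = m), nrow = m,
                  dimnames = list(cog_ids, AA_CODES))
  for (e in spec$enriched) {
    unknown <- setdiff(e$cog_ids, cog_ids)
    if (length(unknown)) {
      stop_usage(sprintf("enrichment names COGs outside the catalogue: %s",
                         paste(unknown, collapse = ", ")))
    }
    for (cid in e$cog_ids) {
      f <- spec$background_aa_freqs
      new_f <- f
      new_f[e$features] <- e$factor * f[e$features]
      rest <- setdiff(AA_CODES, e$features)
      new_f[rest] <- f[rest] * (1 - sum(new_f[e$features])) / (1 - sum(f[e$features]))
      freqs[cid, ] <- new_f
    }
  }
  mean_aa <- colMeans(freqs)

  syn <- synonym_table()
  lambda <- numeric(n)
  for (i in seq_len(n)) {
    sol <- solve_lambda(mean_aa, spec$per_organism_gc[i], agr[i], L, syn)
    if (!sol$feasible) {
      stop_usage(sprintf(
        "GC target %.3f with AGR target %.3f infeasible for organism %s",
        spec$per_organism_gc[i], agr[i], org_ids[i]))
    }
    lambda[i] <- clamp(sol$lambda, 0, 1)
  }

  seq_rows <- vector("list", n * m)
  counter <- 0L
  for (i in seq_len(n)) {
    sampler <- codon_sampler(lambda[i], agr[i], syn)
    for (k in seq_len(m)) {
      aa <- sample(AA_CODES, L, replace = TRUE, prob = freqs[k, ])
      codons <- character(L)
      for (a in unique(aa)) {
        idx <- which(aa == a)
        s <- sampler[[a]]
        codons[idx] <- if (length(s$codons) == 1L) s$codons else {
          s$codons[sample.int(length(s$codons), length(idx), replace = TRUE,
                              prob = s$probs)]
        }
      }
      counter <- counter + 1L
      seq_rows[[counter]] <- data.frame(
        organism_id = org_ids[i], cog_id = cog_ids[k],
        protein_gi = sprintf("p%06d", counter),
        gene_gi = sprintf("g%06d", counter),
        aa_seq = paste(aa, collapse = ""),
        nt_seq = paste0(paste(codons, collapse = ""), "TAA"),
        stringsAsFactors = FALSE)
    }
  }
  sequences <- do.call(rbind, seq_rows)

  organisms <- data.frame(
    organism_id = org_ids,
    display_name = sprintf("Synthorg %03d", seq_len(n)),
    superkingdom = ifelse(seq_len(n) <= ceiling(n / 2), "Bacteria", "Archaea"),
    phylum = sprintf("Phylum%d", ((seq_len(n) - 1L) %% 4L) + 1L),
    class = sprintf("Class%d", ((seq_len(n) - 1L) %% 4L) + 1L),
    order = sprintf("Order%d", ((seq_len(n) - 1L) %% 4L) + 1L),
    family = sprintf("Family%d", ((seq_len(n) - 1L) %% 4L) + 1L),
    genus = sprintf("Genus%03d", seq_len(n)),
    species = sprintf("Synthorg species %03d", seq_len(n)),
    oxygen_class = spec$oxygen_classes,
    ogt_celsius = ogt,
    stringsAsFactors = FALSE
  )
  cogs <- data.frame(cog_id = cog_ids,
                     description = sprintf("synthetic ortholog group %d", seq_len(m)),
                     stringsAsFactors = FALSE)
  ds <- cog_dataset("cog", organisms, cogs, sequences)
  ds$has_taxonomy <- TRUE
  ds$has_traits <- TRUE

  enr <- if (length(spec$enriched)) {
    do.call(rbind, lapply(spec$enriched, function(e) {
      data.frame(cog_id = e$cog_ids,
                 features = paste(e$features, collapse = ","),
                 factor = e$factor, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cog_id = character(0), features = character(0),
               factor = numeric(0))
  }
  gt_org <- data.frame(organism_id = org_ids,
                       oxygen_class = spec$oxygen_classes,
                       ogt_celsius = ogt,
                       gc_target = spec$per_organism_gc,
                       agr_target = agr,
                       lambda = lambda, stringsAsFactors = FALSE)
  list(dataset = ds,
       ground_truth = list(organisms = gt_org, enrichments = enr,
                           spec = spec))
}

#' Write a fixture bundle to disk
#'
#' Emits the dataset XML, the taxonomy and trait TSVs and the generator's
#' ground-truth table; re-running with the same spec/seed produces
#' byte-identical files.
#'
#' @param ds A [cog_dataset()] (typically from [generate_dataset()]).
#' @param ground_truth The matching ground-truth list (or `NULL`).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_bundle <- function(ds, ground_truth, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop_io(sprintf("cannot write to directory '%s'", dir))
  }
  paths <- c(xml = file.path(dir, "dataset.xml"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             traits = file.path(dir, "traits.tsv"))
  write_nucocog_xml(ds, paths["xml"])
  tax <- ds$organisms[, c("organism_id", TAXONOMIC_RANKS)]
  tax[is.na(tax)] <- ""
  utils::write.table(tax, paths["taxonomy"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  traits <- data.frame(organism_id = ds$organisms$organism_id,
                       oxygen_class = ifelse(is.na(ds$organisms$oxygen_class),
                                             "unknown", ds$organisms$oxygen_class),
                       ogt = ifelse(is.na(ds$organisms$ogt_celsius), "",
                                    format(ds$organisms$ogt_celsius, digits = 10,
                                           trim = TRUE)),
                       stringsAsFactors = FALSE)
  utils::write.table(traits, paths["traits"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ground_truth)) {
    paths["ground_truth"] <- file.path(dir, "ground_truth.tsv")
    gt <- ground_truth$organisms
    utils::write.table(format(gt, digits = 10, trim = TRUE),
                       paths["ground_truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}
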