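---
title: "Mining composition bias in ortholog groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining composition bias in ortholog groups: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogbias)
```

## The quantity being computed

Clusters of orthologous groups (COGs) tie sequences from many microbial
genomes to a shared cellular function, so systematic deviations of sequence
composition within a COG — or within a user-defined group of COGs such as a
biosynthetic pathway — carry biological signal. The engine's central
quantity is the **APSF**, the average percentage of the selected sequence
features in a scope of sequences. For a feature set $F$ (amino acids,
nucleotides, or codons) and a scope $S$:

$$\mathrm{APSF}(S, F) \;=\; 100 \cdot
\frac{\sum_{s \in S} \sum_{f \in F} c_f(s)}{\sum_{s \in S} T(s)}$$

where $c_f(s)$ is the pre-computed count of feature $f$ in sequence $s$ and
$T(s)$ the usable total of $s$ for that feature type. This is a **pooled
(length-weighted) percentage**: counts are summed over the scope before
dividing, so long sequences weigh more. The alternative — the mean of
per-sequence percentages — is exposed as `mean_of_sequences = TRUE` for
sensitivity checks but is never the default, because summing stored counts
and lengths is what defines the score.

The **frequency score** divides a scope's APSF by a reference APSF:

* `whole_database`: the APSF over every sequence of the dataset;
* `selected_organisms`: the APSF over all sequences of the selected
  organisms, across all COGs.

Two exact identities follow and are enforced by tests: with the full
organism selection both modes coincide, and the pooled all-COG group scores
exactly 1 under either mode. A reference APSF of 0 raises an error rather
than producing infinities; it is reachable only on degenerate data.

### Ambiguity and denominator policy

* Protein residues `X` and `*` contribute neither to counts nor to totals.
* Bases `N` are excluded from nucleotide counts and totals.
* Codons are read as consecutive frame-0 triplets from position 1 of the
  stored CDS (no reading-frame search); a trailing incomplete triplet is
  dropped and any `N`-containing triplet is excluded.
* Codon queries use **sense codons** as the denominator by default; stop
  codons are stored in the counts but excluded from both numerator and
  denominator. `include_stops = TRUE` restores all-triplet totals. The
  default reflects that codon-usage questions (e.g. arginine AGR usage)
  concern coding choice among synonyms; the flag makes the choice explicit
  because it changes percentages.
* Records lacking the needed sequence kind (protein-only records in
  nucleotide/codon queries) are skipped and tallied per query (`n_skipped`);
  a scope with no usable record raises an undefined-score error instead of
  returning a number.

Whether the original count tables included ambiguous characters in their
stored lengths is not documented anywhere we could check; the
exclude-from-both policy is the one we consider defensible and it is applied
uniformly.

## Selections and subgrouping

Organism selections are built by explicit id list, by lineage value at one
of seven ranks (superkingdom … species; case-insensitive exact match), by
trait pattern (`aerobia` = aerobes, `anaerobia` = anaerobes — facultative
and unknown organisms belong to neither, so they cannot silently tilt a
GC comparison — and `thermophile` with an OGT threshold), or by occurrence
in a COG. Consecutive criteria combine by **set union** by default: the
combined selection is the superset of the individual ones. Because a
logical-AND reading of "consecutive selections" is also plausible,
`method = "intersect"` provides it; the two readings genuinely conflict, so
both are exposed and the default is the superset.

With `subgroup_rank` set, one score is computed per taxon occurring in the
selection at that rank, per COG (or batch group). Organisms lacking the rank
drop out of subgrouped queries and are tallied.

Rankings sort by score descending with ties broken by group label ascending.
The tie-break is a repository convention chosen for deterministic output;
repeated runs of every non-simulation code path are byte-identical, which
the test suite checks at the file level.

## Batch queries

Group queries use one line per group: `NAME : FEATURES : COG_LIST`
(features comma-separated, COGs comma- or whitespace-separated, `#`
comments ignored). The group's APSF pools over *all* sequences of all its
COGs — a cumulative score, which is what makes pathway-level questions
(underrepresentation of an amino acid across the enzymes of its own
biosynthesis) expressible. The grammar itself is an artifact definition:
only its existence and "one score per line" semantics are fixed by the
tool's heritage, not its syntax.

## File formats

The XML dialect is likewise an artifact definition, documented here because
the original database download never published a schema:

```
<dataset source="cog|arcog|combined">
  <organism id="..." name="..."/>
  <cog id="COG0001" desc="...">
    <seq org="..." protein_gi="..." gene_gi="...">
      <aa>MKT...</aa>
      <nt>ATGAAA...</nt>      <!-- optional -->
    </seq>
  </cog>
</dataset>
```

Unknown attributes are ignored on read. Sequences are uppercased and `U` is
normalized to `T` on load; protein-only records are legal throughout (they
are skipped, with a count, by nucleotide and codon queries). Taxonomy is a
flat lineage TSV (one row per organism, seven rank columns, species
mandatory) rather than parsed NCBI dump files — converting `nodes.dmp` /
`names.dmp` is deliberately out of scope. Ranking TSVs render scores with 4
decimal places (full precision is kept in memory); when normalization is
active they also carry the selected and total feature counts.

## The synthetic-data generator

`bias_spec()` / `generate_dataset()` produce datasets in which the truth is
known, so recovery can be asserted:

* **Proteins** are drawn i.i.d. from a background residue composition
  (default: an average microbial proteome composition,
  `BACKGROUND_AA_FREQS`). A per-COG enrichment `(cog_ids, features,
  factor)` pins the enriched residues at `factor ×` background and
  redistributes the remaining mass proportionally over the other residues —
  so `factor` *is* the realized relative enrichment, which is the ground
  truth the recovery tests assert against.
* **CDS** are back-translations. Each organism draws every synonymous codon
  from a two-point mixture between its lowest-GC and highest-GC synonym,
  with one mixing weight $\lambda$ per organism. The expected per-codon GC
  is affine in $\lambda$, so the organism's GC target (including the
  appended TAA stop codon) solves in closed form; an unreachable target is
  reported as infeasible with the organism named. Arginine is handled
  specially: the AGR share (AGA+AGG among all six arginine codons) is set
  directly to the organism's AGR target, with the same $\lambda$ mixing
  inside the AGR and CGN groups. Realized GC and AGR therefore match their
  targets up to multinomial sampling noise — the tests bound this at 3
  binomial standard deviations of the generated lengths.
* **OGT model**: optionally, organisms receive an optimum growth temperature
  drawn uniformly from a range (default 20–45 °C) and an AGR-fraction target
  `slope · OGT + intercept + N(0, σ)`, clamped to [0.05, 0.95]. The default
  study condition used by the acceptance checks is slope 0.02 per °C,
  intercept −0.20, σ = 0.10: on the 0–1 AGR-fraction scale this yields a
  clearly detectable but noisy correlation at n = 40 organisms, the regime
  the regression recipe is meant for. (A slope of 0.02 *percentage points*
  per °C over an archaeal temperature span would be invisible next to the
  binomial sampling noise of desk-scale sequence sets; the fraction scale is
  the one on which a generator target is meaningful.)
* **Taxonomy and traits**: each organism is its own species and genus;
  superkingdom splits the set in half (Bacteria/Archaea) and coarser ranks
  cycle so that every rank has non-trivial groups; oxygen classes alternate
  aerobe/anaerobe unless specified.
* **Determinism**: one RNG stream seeded once, draws ordered organism-major
  then COG-major; the same spec yields byte-identical fixture bundles.

What the generator does **not** emulate: phylogenetic correlation between
organisms, length variation between sequences, indels/paralogs, genuine
codon-usage tables (each organism uses at most two synonyms per amino acid
plus the four-codon arginine mix), or X/N ambiguity. Passing recovery tests
therefore show the engine measures what was planted — they do not show that
real ortholog data contains such signals, and the published magnitudes of
the GC and temperature relationships can only be reproduced with the real
database downloads and curated trait tables.

## Recipes

* `rank_positive_residues()`: K/R/H APSF per COG against the whole-database
  reference — in real data the top of this ranking is dominated by ribosomal
  proteins.
* `cognate_bias()`: per species and amino acid, the batch score of
  (amino acid, its biosynthesis COGs), whole-database reference by default;
  scores below 1 indicate cognate underrepresentation. The amino-acid-to-COG
  map is user configuration; the shipped
  `inst/extdata/cognate_map_synthetic.tsv` is an illustrative example, not a
  curated pathway assignment (no complete published assignment exists to
  copy).
* `ekqh_ratio()` / `agr_fraction()`: per-organism pooled thermophily
  markers — the (E+K)/(Q+H) residue ratio and the AGR percentage among
  arginine codons. Both equal the corresponding `apsf()` count arithmetic
  exactly (a two-path consistency test).
* `ogt_regression()`: ordinary least squares of a per-organism value on OGT
  (slope in value units per °C) plus the Pearson correlation; organisms
  missing either quantity are dropped and reported; constant values are
  reported as a zero-variance case (slope 0, r undefined) rather than an
  error.
* `gc_by_trait()`: pooled GC percentage over all CDS of two trait-pattern
  selections (default Aerobia vs Anaerobia). Pooling matches the scoring
  engine; a single number per pattern is also consistent with a mean of
  per-organism GC values, which `per_organism_mean = TRUE` provides — the
  pooled default is a documented choice, not a published fact.

## Problem sizes

The recovery checks run on sizes chosen to make their statistical margins
comfortable at a fixed seed while staying desk-scale: 20 organisms × 100
COGs × 300 codons for enrichment recovery (a 1.5× K/R/H enrichment in 5
COGs separates from background by >10 standard deviations), 25 × 150 × 400
codons for the cognate-depletion bands, 40 organisms × 30 COGs × 200 codons
for the regression, and 20 × 50 × 200 codons for the GC comparison. These
are the package's own study conditions; the generator accepts anything.

## Known limitations

* Only the standard genetic code; no alternative codes, no ORF search.
* Seven fixed taxonomic ranks; no free-text or fuzzy taxon matching.
* No significance testing of score differences — the engine reports
  rankings and scores, not p-values.
* The combined-database deduplication of real downloads is the data
  producer's concern; the loader only enforces uniqueness of
  (organism, protein GI).
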