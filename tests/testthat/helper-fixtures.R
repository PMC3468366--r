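# Shared fixtures and independent brute-force oracles. The oracles count by
# concatenating raw strings with strsplit/substring, deliberately avoiding
# the package's counting path.

toy_file <- function(f) {
  system.file("extdata", f, package = "cogbias", mustWork = TRUE)
}

load_toy <- function() {
  ds <- parse_nucocog_xml(toy_file("toy.xml"))
  ds <- attach_taxonomy(ds, load_taxonomy(toy_file("taxonomy.tsv")))
  ds <- attach_traits(ds, load_traits(toy_file("traits.tsv")))
  precompute_counts(ds)
}

# Build a cog_dataset directly from a named list of amino-acid sequences
# (and optional CDS), one organism per sequence unless org is given.
make_aa_dataset <- function(aa, nt = NULL, org = NULL, cog = NULL) {
  n <- length(aa)
  org <- org %||% sprintf("org%02d", seq_len(n))
  cog <- cog %||% rep("COG0001", n)
  orgs <- unique(org)
  organisms <- data.frame(organism_id = orgs,
                          display_name = paste("Organism", orgs),
                          species = paste("Species", orgs),
                          stringsAsFactors = FALSE)
  cogs <- data.frame(cog_id = unique(cog), description = "", stringsAsFactors = FALSE)
  sequences <- data.frame(organism_id = org, cog_id = cog,
                          protein_gi = sprintf("p%03d", seq_len(n)),
                          gene_gi = sprintf("g%03d", seq_len(n)),
                          aa_seq = aa,
                          nt_seq = if (is.null(nt)) "" else nt,
                          stringsAsFactors = FALSE)
  precompute_counts(cog_dataset("cog", organisms, cogs, sequences))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
STOPS <- c("TAA", "TAG", "TGA")

# Brute-force oracle: pooled percentage of `features` over concatenated
# sequences, counting characters (or frame-0 triplets) by hand.
oracle_apsf <- function(strings, features, type = c("amino_acid", "nucleotide", "codon"),
                        include_stops = FALSE) {
  type <- match.arg(type)
  if (type %in% c("nucleotide", "codon")) strings <- strings[nzchar(strings)]
  if (type == "codon") {
    toks <- unlist(lapply(strings, function(s) {
      n <- nchar(s) %/% 3L
      if (n == 0L) return(character(0))
      st <- 3L * (seq_len(n) - 1L) + 1L
      substring(s, st, st + 2L)
    }))
    toks <- toks[!grepl("N", toks, fixed = TRUE)]
    if (!include_stops) toks <- toks[!(toks %in% STOPS)]
  } else {
    toks <- unlist(strsplit(strings, ""))
    drop <- if (type == "amino_acid") c("X", "*") else "N"
    toks <- toks[!(toks %in% drop)]
  }
  list(selected = sum(toks %in% features), total = length(toks),
       apsf = 100 * sum(toks %in% features) / length(toks))
}

# Small deterministic generated dataset reused by several test files.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_dataset(bias_spec(
        n_organisms = 6, n_cogs = 8, seq_len_codons = 40,
        enriched = list(list(cog_ids = "COG0001", features = "K", factor = 2)),
        seed = 424242))
      cache <<- list(ds = precompute_counts(gen$dataset), gt = gen$ground_truth)
    }
    cache
  }
})
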