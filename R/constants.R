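# Feature alphabets and shared lookup tables.

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

NT_CODES <- c("A", "C", "G", "T")

CODONS <- sort(as.vector(outer(outer(NT_CODES, NT_CODES, paste0),
                               NT_CODES, paste0)))

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

# Arginine codons: AGR = AGA/AGG (R = purine), CGN = the four CG* codons.
AGR_CODONS <- c("AGA", "AGG")
CGN_CODONS <- c("CGA", "CGC", "CGG", "CGT")
ARG_CODONS <- c(CGN_CODONS, AGR_CODONS)

TAXONOMIC_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")

OXYGEN_CLASSES <- c("aerobe", "anaerobe", "facultative", "unknown")

# G+C letters per codon, used by the back-translating generator.
CODON_GC <- vapply(CODONS, function(x) {
  sum(strsplit(x, "")[[1]] %in% c("G", "C"))
}, integer(1)) / 3

#' Default background amino-acid composition
#'
#' Average microbial proteome composition (fractions over the 20 standard
#' residues, summing to 1), used as the synthetic generator's default
#' background.
#'
#' @format Named numeric vector of length 20.
#' @export
BACKGROUND_AA_FREQS <- c(
  A = 0.0825, C = 0.0138, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)
BACKGROUND_AA_FREQS <- BACKGROUND_AA_FREQS / sum(BACKGROUND_AA_FREQS)
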