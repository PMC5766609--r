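AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Highest-usage human codon per amino acid; the default single
## trimer-block codon before optimization. Overridable everywhere.
HUMAN_PREFERRED_CODON <- c(
  A = "GCC", R = "AGG", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG")

#' Genetic-code helpers
#'
#' `codon_to_aa()` translates codons via the standard genetic code;
#' `synonymous_codons()` lists all codons for a residue (no stop codons);
#' `preferred_codon()` returns the default (highest human usage) codon.
#'
#' @param codon DNA triplet(s).
#' @return For `codon_to_aa()`, 1-letter residue codes (`"*"` for stop).
#' @export
codon_to_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' @rdname codon_to_aa
#' @param residue 1-letter amino acid code(s).
#' @export
synonymous_codons <- function(residue) {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc == toupper(residue)])
}

#' @rdname codon_to_aa
#' @export
preferred_codon <- function(residue) {
  unname(HUMAN_PREFERRED_CODON[toupper(residue)])
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
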