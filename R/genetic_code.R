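# Genetic-code constants shared across the package. All codons are handled in
# the RNA alphabet (ACGU) internally; DNA input is normalized on entry.

rna_bases <- c("A", "C", "G", "U")

# 1-letter -> 3-letter amino-acid codes for the 20 standard residues.
aa_three_letter <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)

# Standard genetic code keyed by RNA codon, derived once from Biostrings.
genetic_code_rna <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  gc
})

stop_codons <- names(genetic_code_rna)[genetic_code_rna == "*"]

#' The 61 sense codons
#'
#' All sense codons of the standard genetic code, in the RNA alphabet and
#' lexicographic order.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  sort(names(genetic_code_rna)[genetic_code_rna != "*"])
}

# 3-letter amino acid for each sense codon.
codon_amino_acid <- function(codons) {
  aa1 <- genetic_code_rna[codons]
  unname(aa_three_letter[aa1])
}

# Reverse complement in the RNA alphabet; anticodon (5'->3') of the
# Watson-Crick decoder of a codon is revcomp(codon).
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Normalize a nucleotide string to uppercase RNA.
normalize_rna <- function(x) chartr("Tt", "UU", toupper(x))

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
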