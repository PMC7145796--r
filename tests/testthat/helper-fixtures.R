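# Shared toy fixtures, built in code.

code1 <- genetic_code(1L)
code12 <- genetic_code(12L)

# A small usage table with hand-chosen counts. Ala family: GCT 60, GCC 30,
# GCA 10, GCG 0 (smoothed). Gly family: uniform 25 each. Other families are
# left at zero counts and smooth to uniform.
toy_counts <- c(GCT = 60, GCC = 30, GCA = 10,
                GGA = 25, GGC = 25, GGG = 25, GGT = 25,
                ATG = 10, TGG = 10, AAA = 9, AAG = 1)
toy_table <- codon_usage_table(toy_counts, code = code1, source = "file")

toy_table12 <- codon_usage_table(toy_counts, code = code12, source = "file")

# Uniform table: every codon counted once -> all syn fractions equal, all
# adaptiveness weights 1.
uniform_table <- codon_usage_table(
  stats::setNames(rep(1, 64), all_codons()), code = code1, source = "file")

codons_of <- function(dna) {
  s <- if (inherits(dna, "coding_sequence")) dna$nucleotides else dna
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

random_protein <- function(n, seed) {
  set.seed(seed)
  protein_sequence(paste0("p", seed),
                   paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                  "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                                  "W", "Y"), n, replace = TRUE), collapse = ""))
}
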