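make_cfg <- function(strategy, table = toy_table, ...) {
  optimization_config(strategy, usage_table = table, ...)
}

test_that("max-CAI optimization picks the most frequent codon, ties alphabetical", {
  cfg <- make_cfg("max_cai")
  v <- optimize_max_cai(protein_sequence("p", "MA"), cfg)
  expect_identical(v$dna$nucleotides, "ATGGCT")   # GCT is the Ala maximum
  # tie: two codons share the family maximum -> alphabetically first wins
  tie_tab <- codon_usage_table(c(GCT = 50, GCC = 50), code = code1)
  vt <- optimize_max_cai(protein_sequence("p", "A"), make_cfg("max_cai", tie_tab))
  expect_identical(vt$dna$nucleotides, "GCC")
  # CAI of a max-CAI variant is 1
  prot <- random_protein(40, seed = 2)
  vmax <- optimize_max_cai(prot, cfg)
  expect_equal(compute_cai(vmax, toy_table), 1)
})

test_that("max-CAI output attains the exhaustive-search optimum on short proteins", {
  # brute force: enumerate every synonymous coding of proteins up to 5
  # residues and compare the best CAI with the optimizer's
  cfg <- make_cfg("max_cai", toy_table12)
  w <- relative_adaptiveness(toy_table12)
  fam <- codon_families(code12)
  for (seed in 1:5) {
    prot <- random_protein(4, seed = seed)
    aas <- strsplit(prot$residues, "")[[1]]
    choices <- lapply(aas, function(aa) setdiff(fam[[aa]], "CTG"))
    grid <- expand.grid(choices, stringsAsFactors = FALSE)
    best <- max(apply(grid, 1, function(cs) {
      keep <- !aas %in% c("M", "W")
      if (!any(keep)) return(1)
      exp(mean(log(w[unlist(cs)[keep]])))
    }))
    v <- optimize_max_cai(prot, cfg)
    expect_equal(compute_cai(v, toy_table12), best, tolerance = 1e-12)
  }
})

test_that("all strategies translate back to the input protein, forbidden-free", {
  spec <- synthetic_spec(seed = 3, n_proteins = 2, protein_length = 60,
                         gene_set_size = 20, gene_length = 100)
  ref <- generate_reference_set(spec)
  for (p in ref$proteins) {
    for (strat in c("threshold_random", "guided_random", "max_cai")) {
      cfg <- optimization_config(strat, ref$table, seed = 11)
      v <- switch(strat,
                  threshold_random = optimize_threshold_random(p, cfg),
                  guided_random = optimize_guided_random(p, cfg),
                  max_cai = optimize_max_cai(p, cfg))
      expect_identical(translate_cds(v$dna)$residues, p$residues,
                       info = strat)
      expect_false(any(codons_of(v$dna) == "CTG"), info = strat)
    }
  }
})

test_that("random strategies are deterministic under a fixed seed", {
  prot <- random_protein(50, seed = 4)
  cfg <- make_cfg("guided_random", seed = 99)
  v1 <- optimize_guided_random(prot, cfg)
  v2 <- optimize_guided_random(prot, cfg)
  expect_identical(v1$dna$nucleotides, v2$dna$nucleotides)
  cfg2 <- make_cfg("threshold_random", seed = 99)
  t1 <- optimize_threshold_random(prot, cfg2)
  t2 <- optimize_threshold_random(prot, cfg2)
  expect_identical(t1$dna$nucleotides, t2$dna$nucleotides)
  # different seed -> (almost surely) different draw
  v3 <- optimize_guided_random(prot, make_cfg("guided_random", seed = 100))
  expect_false(identical(v1$dna$nucleotides, v3$dna$nucleotides))
})

test_that("thresholding removes rare codons; single survivor is forced", {
  tab <- codon_usage_table(c(GCT = 95, GCC = 5), code = code1)
  cfg <- make_cfg("threshold_random", tab, frequency_threshold = 0.10, seed = 1,
                  max_direct_repeat = 10000L)
  v <- optimize_threshold_random(protein_sequence("p", strrep("A", 30)), cfg)
  expect_identical(v$dna$nucleotides, strrep("GCT", 30))
})

test_that("threshold-random sampling matches its renormalized target (chi-square)", {
  # Lys family: AAA 0.9, AAG 0.1 in toy_table, threshold 0.15 removes AAG
  # Gly family: uniform 0.25 each, all survive
  cfg <- make_cfg("threshold_random", frequency_threshold = 0.15, seed = 3,
                  max_direct_repeat = 100000L, max_homopolymer = 100000L,
                  gc_bounds = c(0, 1))
  prot <- protein_sequence("p", strrep("G", 1e4))
  v <- optimize_threshold_random(prot, cfg)
  codons <- codons_of(v$dna$nucleotides)
  obs <- table(factor(codons, levels = codon_families(code1)$G))
  expect_gt(stats::chisq.test(obs, p = rep(0.25, 4))$p.value, 0.01)
})

test_that("guided-random sampling follows synonymous fractions", {
  cfg <- make_cfg("guided_random", seed = 3)
  prot <- protein_sequence("p", strrep("A", 1e4))
  v <- optimize_guided_random(prot, cfg)
  codons <- codons_of(v$dna$nucleotides)
  expect_equal(sum(codons == "GCG"), 0)   # zero-fraction codon never drawn
  obs <- table(factor(codons, levels = c("GCT", "GCC", "GCA")))
  expect_gt(stats::chisq.test(obs, p = c(0.6, 0.3, 0.1))$p.value, 0.01)
})

test_that("threshold 0 equals guided-random in distribution", {
  cfg_t <- make_cfg("threshold_random", frequency_threshold = 0, seed = 5,
                    gc_bounds = c(0, 1), max_homopolymer = 100000L,
                    max_direct_repeat = 100000L)
  cfg_g <- make_cfg("guided_random", seed = 6)
  prot <- protein_sequence("p", strrep("A", 5e3))
  ct <- table(factor(codons_of(optimize_threshold_random(prot, cfg_t)$dna$nucleotides),
                     levels = c("GCT", "GCC", "GCA")))
  cg <- table(factor(codons_of(optimize_guided_random(prot, cfg_g)$dna$nucleotides),
                     levels = c("GCT", "GCC", "GCA")))
  expect_gt(stats::chisq.test(rbind(ct, cg))$p.value, 0.01)
})

test_that("scaffold transfer copies identical codons and re-encodes substitutions", {
  cfg <- make_cfg("scaffold_transfer", toy_table)
  scaffold <- coding_sequence("scaf", "ATGGCAGGTAAA", code1)  # M A G K
  # identity: target equals the scaffold protein
  same <- transfer_mutations(scaffold, protein_sequence("t", "MAGK"), cfg)
  expect_identical(same$dna$nucleotides, scaffold$nucleotides)
  # one substitution (A2 -> G): exactly one codon differs
  sub <- transfer_mutations(scaffold, protein_sequence("t", "MGGK"), cfg)
  d <- codons_of(sub$dna$nucleotides) != codons_of(scaffold$nucleotides)
  expect_identical(sum(d), 1L)
  expect_identical(translate_cds(sub$dna)$residues, "MGGK")
  # substituted residue gets the most frequent codon; Gly is uniform in
  # toy_table so the tie-break picks the fewest-nt-change codon from GCA: GGA
  expect_identical(codons_of(sub$dna$nucleotides)[2], "GGA")
  # indel -> error
  expect_error(transfer_mutations(scaffold, protein_sequence("t", "MAGKV"), cfg),
               "lengths differ")
})

test_that("constraint repair removes forbidden codons and homopolymers", {
  # forbidden CTG under table 12 is resampled away, protein preserved
  tab <- toy_table12
  cfg <- optimization_config("threshold_random", tab, seed = 8)
  dna <- coding_sequence("x", "ATGCTGCTGAAA", code12)   # M S S K
  res <- enforce_constraints(dna, cfg)
  expect_false(any(codons_of(res$dna$nucleotides) == "CTG"))
  expect_identical(translate_cds(res$dna)$residues,
                   translate_cds(dna)$residues)
  expect_gt(nrow(res$repair_log), 0)
  expect_identical(nrow(res$unresolved), 0L)
  # a 12-nt A homopolymer (4x AAA = Lys) is broken up where synonyms allow
  dna2 <- coding_sequence("y", paste0("ATG", strrep("AAA", 4), "GGT"), code1)
  cfg2 <- optimization_config("threshold_random", toy_table, seed = 9,
                              max_homopolymer = 8L)
  res2 <- enforce_constraints(dna2, cfg2)
  runs <- rle(strsplit(res2$dna$nucleotides, "")[[1]])
  expect_lte(max(runs$lengths), 8L)
  expect_identical(translate_cds(res2$dna)$residues,
                   translate_cds(dna2)$residues)
})

test_that("unsatisfiable forbidden codons raise an error", {
  cfg <- optimization_config("max_cai", toy_table, forbidden_codons = "TGG")
  expect_error(optimize_max_cai(protein_sequence("p", "MW"), cfg),
               "no allowed codon")
})
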