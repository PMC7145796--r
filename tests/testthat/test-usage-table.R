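test_that("usage table invariants hold on hand-built and uniform tables", {
  for (tab in list(toy_table, uniform_table, toy_table12)) {
    fam <- codon_families(tab$code)
    for (aa in names(fam)) {
      fr <- tab$syn_fraction[fam[[aa]]]
      expect_equal(sum(fr), 1, tolerance = 1e-9)
      expect_equal(max(tab$adaptiveness_w[fam[[aa]]]), 1, tolerance = 1e-12)
      expect_true(all(tab$adaptiveness_w[fam[[aa]]] > 0))
    }
    expect_equal(sum(tab$per_thousand), 1000, tolerance = 1e-6)
    # stop codons excluded from family normalization
    stops <- names(which(tab$code$codon_to_aa == "*"))
    expect_true(all(is.na(tab$syn_fraction[stops])))
  }
})

test_that("tabulate_usage counts codons and derives fractions by hand", {
  tab <- tabulate_usage(c(g1 = "ATGGCT", g2 = "ATGGCC"), code1)
  expect_equal(unname(tab$counts[c("ATG", "GCT", "GCC")]), c(2, 1, 1))
  expect_equal(unname(tab$syn_fraction[c("GCT", "GCC")]), c(0.5, 0.5))
  expect_identical(tab$source, "gene-set")
  expect_identical(tab$genes, c("g1", "g2"))
  expect_error(tabulate_usage(list()), "empty gene set")
})

test_that("tabulation is permutation-invariant and additive", {
  g <- c(a = "ATGGCTAAAGGT", b = "ATGGCCAAAGGA", c = "ATGTTTGGG")
  t1 <- tabulate_usage(g, code1)
  t2 <- tabulate_usage(g[c(3, 1, 2)], code1)
  expect_equal(t1$counts, t2$counts)
  t_ab <- tabulate_usage(g[1:2], code1)
  t_c <- tabulate_usage(g[3], code1)
  expect_equal(t1$counts, t_ab$counts + t_c$counts)
})

test_that("relative adaptiveness divides by the family maximum", {
  # Ala fractions 0.6 / 0.3 / 0.1 / 0 (GCG unobserved)
  tab <- codon_usage_table(c(GCT = 60, GCC = 30, GCA = 10), code = code1)
  expect_equal(unname(tab$syn_fraction[c("GCT", "GCC", "GCA", "GCG")]),
               c(0.6, 0.3, 0.1, 0))
  w <- relative_adaptiveness(tab)
  expect_equal(unname(w["GCT"]), 1)
  expect_equal(unname(w["GCC"]), 0.5)
  expect_equal(unname(w["GCA"]), 10 / 60)
  expect_equal(unname(w["GCG"]), 0.5 / 60)
  # most frequent codon of any family always has w = 1
  fam <- codon_families(code1)
  for (aa in c("L", "G", "K")) {
    expect_equal(max(w[fam[[aa]]]), 1)
  }
  # uniform table: every w = 1
  expect_true(all(relative_adaptiveness(uniform_table) == 1, na.rm = TRUE))
})

test_that("usage tables round-trip exactly through CountCodon-style text", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_codon_usage(toy_table, path)
  back <- read_codon_usage(path, code1)
  expect_equal(back$counts, toy_table$counts)
  expect_equal(back$syn_fraction, toy_table$syn_fraction)
})

test_that("the parser accepts multi-column layouts and RNA codons", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("UUU 10 0.0  UUC 30 0.0  CUG 5 0.0",
               "GCU 7 0.0"), path)
  tab <- read_codon_usage(path, code1)
  expect_equal(unname(tab$counts[c("TTT", "TTC", "CTG", "GCT")]),
               c(10, 30, 5, 7))
  writeLines("ATG ten 0.0", path)
  expect_error(read_codon_usage(path, code1), "non-numeric")
})

test_that("tabulation of iid draws is statistically consistent with the source", {
  # draw 2e4 codons iid from toy_table fractions and tabulate them back; the
  # recovered per-family counts must be chi-square-consistent with the source
  # fractions (the sampling itself is the oracle)
  set.seed(7)
  fam <- codon_families(code1)
  aas <- sample(names(fam), 2e4, replace = TRUE)
  codons <- vapply(aas, function(aa) {
    m <- fam[[aa]]
    if (length(m) == 1L) m else sample(m, 1L, prob = toy_table$syn_fraction[m])
  }, character(1))
  genes <- split(codons, rep(1:20, each = 1e3))
  genes <- vapply(genes, paste, character(1), collapse = "")
  tab <- tabulate_usage(stats::setNames(genes, paste0("g", 1:20)), code1)
  for (aa in c("A", "G", "K", "L")) {
    m <- fam[[aa]]
    keep <- toy_table$syn_fraction[m] > 0
    p <- stats::chisq.test(tab$counts[m][keep],
                           p = toy_table$syn_fraction[m][keep])$p.value
    expect_gt(p, 0.001)
  }
  # zero-fraction codons are never drawn
  expect_equal(unname(tab$counts["GCG"]), 0)
})

test_that("FASTA round-trips preserve sequences and ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  prots <- list(protein_sequence("pA", strrep("MKV", 30)),
                protein_sequence("pB", "MGGS"))
  write_fasta(prots, path)
  back <- read_protein_fasta(path)
  expect_identical(back[[1]]$residues, prots[[1]]$residues)
  expect_identical(back[[2]]$id, "pB")
  cds <- list(coding_sequence("c1", "ATGGCTAAA", code12))
  write_fasta(cds, path)
  expect_identical(read_cds_fasta(path, code12)[[1]]$nucleotides, "ATGGCTAAA")
})
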