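#' Synthetic study specification
#'
#' Parameters for the synthetic-data generator, which emulates every input
#' the pipeline needs: a codon usage table with realistic skew, a gene set
#' whose tabulation recovers that table, protein sequences, and replicate
#' brightness measurements with wild-type autofluorescence and a log-linear
#' dependence of brightness on the 5'-region folding score.
#'
#' The brightness model is `log10(B) = beta0 + beta1 * mfe_5prime` plus
#' Normal replicate noise of sd `sigma` (log10 scale); the measured raw
#' value adds an autofluorescence draw, so autofluorescence subtraction is
#' the exact inverse of the generative model. `beta1 > 0` encodes the
#' premise that less 5' mRNA structure (folding score closer to 0) is
#' beneficial for expression. The default intercept places a typical
#' 250-nt-region score (about -220 with the default pair weights) near
#' 10^4 arbitrary units, a realistic flow-cytometry mean-fluorescence
#' scale.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of synthetic proteins (default 5, as in a
#'   typical panel of codon variants per fluorescent protein).
#' @param protein_length Residues per protein (default 239, the length of
#'   a GFP-family fluorescent protein).
#' @param table_concentration Dirichlet concentration per synonymous
#'   family; small values give skewed usage (default 0.5).
#' @param gene_set_size,gene_length Number of genes and codons per gene in
#'   the tabulation gene set (defaults 200 x 500 = 1e5 codons).
#' @param table_id Genetic code for all synthetic sequences (default 12).
#' @param beta0 Baseline log10 brightness (intercept, a.u.).
#' @param beta1 Effect of `mfe_5prime` on log10 brightness per score unit
#'   (default 0.05, positive).
#' @param sigma Replicate sd on the log10 scale (default 0.02).
#' @param autofluorescence_mean,autofluorescence_sd Wild-type
#'   autofluorescence distribution (a.u.), truncated at 0.
#' @param n_replicates Biological replicates per strain (default 3).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_proteins = 5L, protein_length = 239L,
                           table_concentration = 0.5,
                           gene_set_size = 200L, gene_length = 500L,
                           table_id = 12L,
                           beta0 = 15, beta1 = 0.05, sigma = 0.02,
                           autofluorescence_mean = 100,
                           autofluorescence_sd = 10,
                           n_replicates = 3L) {
  if (n_proteins < 1L || protein_length < 1L ||
      gene_set_size < 1L || gene_length < 1L) {
    stop("degenerate spec: sizes must be positive")
  }
  stopifnot(sigma >= 0, n_replicates >= 2L, table_concentration > 0)
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length),
         table_concentration = table_concentration,
         gene_set_size = as.integer(gene_set_size),
         gene_length = as.integer(gene_length),
         table_id = as.integer(table_id),
         beta0 = beta0, beta1 = beta1, sigma = sigma,
         autofluorescence_mean = autofluorescence_mean,
         autofluorescence_sd = autofluorescence_sd,
         n_replicates = as.integer(n_replicates)),
    class = "synthetic_spec"
  )
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Generate a synthetic reference set
#'
#' Draws a skewed codon usage table (per-family Dirichlet fractions), a
#' gene set whose codons realize those fractions, and a panel of random
#' protein sequences. Gene residues are drawn uniformly; the codons
#' encoding each residue are then allocated within the synonymous family by
#' stratified proportional allocation (largest-remainder rounding, random
#' placement among that family's positions), so [tabulate_usage()] on the
#' gene set recovers the source synonymous fractions to within integer
#' rounding rather than multinomial noise. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [codon_usage_table()]), `genes` (list of
#'   [coding_sequence()]), `proteins` (list of [protein_sequence()]).
#' @export
generate_reference_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code(spec$table_id)
  fam <- codon_families(code)
  with_seed(spec$seed, {
    counts <- stats::setNames(numeric(0), character(0))
    for (aa in names(fam)) {
      members <- sort(fam[[aa]])
      frac <- rdirichlet1(length(members), spec$table_concentration)
      # counts proportional to drawn fractions; scale large enough that
      # rounding barely perturbs them
      counts[members] <- round(frac * 6e4)
    }
    table <- codon_usage_table(counts, code = code, source = "gene-set",
                               genes = sprintf("syn%03d", seq_len(spec$gene_set_size)))
    aas_pool <- AMINO_ACIDS
    n_total <- spec$gene_set_size * spec$gene_length
    all_aas <- sample(aas_pool, n_total, replace = TRUE)
    all_codons_vec <- character(n_total)
    for (aa in names(fam)) {
      idx <- which(all_aas == aa)
      if (length(idx) == 0L) next
      members <- fam[[aa]]
      frac <- table$syn_fraction[members]
      # largest-remainder allocation of codon counts to the family's positions
      raw <- frac * length(idx)
      base <- floor(raw)
      short <- length(idx) - sum(base)
      if (short > 0L) {
        o <- order(raw - base, decreasing = TRUE)
        base[o[seq_len(short)]] <- base[o[seq_len(short)]] + 1L
      }
      pool <- rep(members, times = base)
      all_codons_vec[idx] <- if (length(pool) > 1L) sample(pool) else pool
    }
    genes <- lapply(seq_len(spec$gene_set_size), function(i) {
      from <- (i - 1L) * spec$gene_length + 1L
      codons <- all_codons_vec[from:(from + spec$gene_length - 1L)]
      coding_sequence(sprintf("syn%03d", i),
                      paste(c(codons, "TAA"), collapse = ""), code = code)
    })
    proteins <- lapply(seq_len(spec$n_proteins), function(i) {
      res <- c("M", sample(aas_pool, spec$protein_length - 1L, replace = TRUE))
      protein_sequence(sprintf("prot%02d", i), paste(res, collapse = ""))
    })
    list(table = table, genes = genes, proteins = proteins)
  })
}

#' Simulate replicate brightness measurements
#'
#' Generates FACS-style replicate mean-fluorescence records for a set of
#' coding variants from their diagnostics: per replicate,
#' `raw = 10^(beta0 + beta1 * mfe_5prime + N(0, sigma)) + autofluorescence`,
#' with the autofluorescence draw truncated at 0. Wild-type records are
#' pure autofluorescence draws, one set per channel. Each fluorescent
#' protein (the variant's protein id) gets its own channel, matching
#' per-panel normalization downstream.
#'
#' @param variants List of `coding_variant` objects.
#' @param reports Output of [diagnose_variants()] for the same variants
#'   (matched by variant id).
#' @param spec A [synthetic_spec()]; its `seed` drives the draws.
#' @return List with `records` and `wildtype` data frames in the layout
#'   [correct_and_summarize()] expects.
#' @export
simulate_brightness <- function(variants, reports, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (inherits(variants, "coding_variant")) variants <- list(variants)
  ids <- vapply(variants, function(v) paste0(v$protein_id, "|", v$strategy_label),
                character(1))
  if (!all(ids %in% reports$variant)) {
    stop("reports missing variant(s): ",
         paste(setdiff(ids, reports$variant), collapse = ", "))
  }
  mfe5 <- reports$mfe_5prime[match(ids, reports$variant)]
  fps <- vapply(variants, function(v) v$protein_id, character(1))
  strategies <- vapply(variants, function(v) v$strategy_label, character(1))
  nrep <- spec$n_replicates
  draw_af <- function(n) {
    pmax(stats::rnorm(n, spec$autofluorescence_mean, spec$autofluorescence_sd), 0)
  }
  with_seed(spec$seed, {
    rows <- lapply(seq_along(variants), function(i) {
      log10b <- spec$beta0 + spec$beta1 * mfe5[i] +
        stats::rnorm(nrep, 0, spec$sigma)
      data.frame(strain = ids[i], fp = fps[i], strategy = strategies[i],
                 replicate = seq_len(nrep), channel = fps[i],
                 raw_mean = 10^log10b + draw_af(nrep),
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
    wt <- do.call(rbind, lapply(unique(fps), function(ch) {
      data.frame(strain = "wildtype", fp = "none", strategy = "none",
                 replicate = seq_len(nrep), channel = ch,
                 raw_mean = draw_af(nrep), stringsAsFactors = FALSE)
    }))
    list(records = records, wildtype = wt)
  })
}
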