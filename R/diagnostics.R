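#' Diagnostics configuration
#'
#' Parameters for the per-variant sequence diagnostics: the synonymous
#' fraction below which a codon counts as rare, the minimum number of
#' consecutive rare codons that makes a run, and the length of the 5' region
#' folded separately.
#'
#' The rare-codon threshold operates on the within-family synonymous
#' fraction. The minimum run length defaults to 2 consecutive rare codons;
#' 3 is a common alternative and both are reachable via `min_run_length`.
#'
#' @param rare_threshold Synonymous fraction below which a codon is rare
#'   (default 0.15).
#' @param min_run_length Minimum consecutive rare codons in a reported run
#'   (default 2).
#' @param five_prime_length Length (nt) of the 5' region folded separately
#'   (default 250).
#' @return An object of class `diagnostics_config`.
#' @export
diagnostics_config <- function(rare_threshold = 0.15, min_run_length = 2L,
                               five_prime_length = 250L) {
  if (rare_threshold <= 0 || rare_threshold >= 1) {
    stop("rare_threshold must be in (0, 1)")
  }
  if (min_run_length < 1L) stop("min_run_length must be >= 1")
  structure(
    list(rare_threshold = rare_threshold,
         min_run_length = as.integer(min_run_length),
         five_prime_length = as.integer(five_prime_length)),
    class = "diagnostics_config"
  )
}

# Codons of a CDS with the trailing stop (if any) removed.
coding_codons <- function(dna) {
  codons <- split_codons(dna$nucleotides)
  aas <- dna$code$codon_to_aa[codons]
  if (aas[length(aas)] == "*") codons <- codons[-length(codons)]
  codons
}

#' Codon adaptation index
#'
#' The geometric mean of the relative adaptiveness weights of a coding
#' sequence's codons, with 1 the theoretical maximum (every codon its
#' family's most frequent). Stop codons and single-codon families
#' (methionine and tryptophan under both supported codes) are excluded, per
#' the standard CAI definition: their weight is identically 1 and their
#' inclusion only dilutes the index.
#'
#' @param dna A [coding_sequence()] (or `coding_variant`).
#' @param table A [codon_usage_table()].
#' @return CAI in (0, 1].
#' @examples
#' tab <- tabulate_usage(c(g = "ATGGCTGCTGCC"), genetic_code(1))
#' compute_cai(coding_sequence("v", "ATGGCT"), tab)  # 1: GCT is the family max
#' @export
compute_cai <- function(dna, table) {
  if (inherits(dna, "coding_variant")) dna <- dna$dna
  stopifnot(inherits(dna, "coding_sequence"),
            inherits(table, "codon_usage_table"))
  codons <- coding_codons(dna)
  fam <- codon_families(table$code)
  single <- unlist(fam[lengths(fam) == 1L], use.names = FALSE)
  codons <- codons[!codons %in% single]
  if (length(codons) == 0L) {
    stop("no codons left after excluding stops and single-codon families")
  }
  w <- relative_adaptiveness(table)[codons]
  exp(mean(log(w)))
}

#' GC content
#'
#' @param dna A [coding_sequence()], `coding_variant`, or DNA string.
#' @return Percent G+C, in \\[0, 100].
#' @export
gc_content <- function(dna) {
  if (inherits(dna, "coding_variant")) dna <- dna$dna
  s <- if (inherits(dna, "coding_sequence")) dna$nucleotides else toupper(dna)
  if (nchar(s) == 0L) stop("empty sequence")
  nts <- strsplit(s, "")[[1]]
  100 * sum(nts %in% c("G", "C")) / length(nts)
}

#' Rare-codon runs
#'
#' Finds maximal stretches of consecutive codons whose synonymous fraction
#' falls below `cfg$rare_threshold`, keeping stretches of at least
#' `cfg$min_run_length` codons. Runs are a proxy for ribosome slow-down
#' sites. A run of length 5 counts once; runs never overlap. The trailing
#' stop codon is ignored.
#'
#' @param dna A [coding_sequence()] or `coding_variant`.
#' @param table A [codon_usage_table()].
#' @param cfg A [diagnostics_config()].
#' @return List with `runs` (two-column matrix of 1-based inclusive codon
#'   positions `start`, `end`, sorted) and `count`.
#' @export
rare_codon_runs <- function(dna, table, cfg = diagnostics_config()) {
  if (inherits(dna, "coding_variant")) dna <- dna$dna
  stopifnot(inherits(dna, "coding_sequence"),
            inherits(table, "codon_usage_table"),
            inherits(cfg, "diagnostics_config"))
  codons <- coding_codons(dna)
  frac <- table$syn_fraction[codons]
  rare <- !is.na(frac) & frac < cfg$rare_threshold
  r <- rle(rare)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$min_run_length
  runs <- cbind(start = starts[keep], end = ends[keep])
  list(runs = runs, count = nrow(runs))
}

#' Per-position codon frequency profile
#'
#' The synonymous fraction of each codon along the coding sequence (1-based
#' codon positions; trailing stop excluded), as produced by codon-plot
#' style tools for spotting rare-codon clusters.
#'
#' @inheritParams rare_codon_runs
#' @return Numeric vector, one synonymous fraction per codon.
#' @export
codon_frequency_profile <- function(dna, table) {
  if (inherits(dna, "coding_variant")) dna <- dna$dna
  stopifnot(inherits(dna, "coding_sequence"),
            inherits(table, "codon_usage_table"))
  codons <- coding_codons(dna)
  unname(table$syn_fraction[codons])
}

#' Full diagnostics for a set of variants
#'
#' Computes, per variant: CAI, GC percent, rare-codon run count, and the
#' folding score of the full coding region and of its first
#' `cfg$five_prime_length` nucleotides.
#'
#' @param variants List of `coding_variant` or [coding_sequence()] objects.
#' @param table A [codon_usage_table()].
#' @param cfg A [diagnostics_config()].
#' @param fold_cfg A [fold_config()].
#' @return A data.frame with one row per variant: `variant`, `strategy`,
#'   `cai`, `gc_percent`, `rare_run_count`, `mfe_full`, `mfe_5prime`.
#' @export
diagnose_variants <- function(variants, table, cfg = diagnostics_config(),
                              fold_cfg = fold_config()) {
  if (inherits(variants, c("coding_variant", "coding_sequence"))) {
    variants <- list(variants)
  }
  rows <- lapply(variants, function(v) {
    dna <- if (inherits(v, "coding_variant")) v$dna else v
    id <- if (inherits(v, "coding_variant")) {
      paste0(v$protein_id, "|", v$strategy_label)
    } else dna$id
    strategy <- if (inherits(v, "coding_variant")) v$strategy_label else NA_character_
    seqnt <- dna$nucleotides
    five <- substr(seqnt, 1L, min(nchar(seqnt), cfg$five_prime_length))
    data.frame(
      variant = id, strategy = strategy,
      cai = compute_cai(dna, table),
      gc_percent = gc_content(dna),
      rare_run_count = rare_codon_runs(dna, table, cfg)$count,
      mfe_full = fold_mfe(seqnt, fold_cfg)$score,
      mfe_5prime = fold_mfe(five, fold_cfg)$score,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
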