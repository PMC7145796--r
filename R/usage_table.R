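#' Codon usage tables
#'
#' A codon usage table holds, for all 64 codons: raw counts, occurrences per
#' 1000 codons, the within-family synonymous fraction, and the relative
#' adaptiveness weight w (synonymous fraction divided by the family maximum)
#' used by the codon adaptation index. Stop codons carry counts and
#' per-thousand values but are excluded from family normalization
#' (`syn_fraction` and `adaptiveness_w` are `NA` for stops).
#'
#' Synonymous fractions are raw within-family shares: a zero-count codon has
#' fraction 0 (and is never drawn by the sampling strategies). For the
#' adaptiveness weights, zero counts are first replaced by a pseudo-count of
#' 0.5 (the usual CAI convention) so every weight is strictly positive and
#' geometric means are defined. A family with no counts at all falls back to
#' uniform fractions.
#'
#' @param counts Named non-negative integer vector; names are codons. Codons
#'   absent from the vector are taken as zero.
#' @param code A [genetic_code()].
#' @param source Character descriptor of provenance, e.g. `"entire-genome"`,
#'   `"gene-set"` or `"file"`.
#' @param genes Optional character vector of gene identifiers (recorded when
#'   `source = "gene-set"`).
#' @return An object of class `codon_usage_table` with fields `code`,
#'   `counts`, `per_thousand`, `syn_fraction`, `adaptiveness_w`, `source`,
#'   `genes`.
#' @export
codon_usage_table <- function(counts, code = genetic_code(1L),
                              source = "file", genes = NULL) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- all_codons()
  full <- stats::setNames(numeric(64), codons)
  if (length(counts) > 0) {
    if (is.null(names(counts))) stop("counts must be a named vector")
    nm <- toupper(names(counts))
    bad <- setdiff(nm, codons)
    if (length(bad) > 0) stop("unknown codon(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0)) stop("negative codon count")
    full[nm] <- full[nm] + as.numeric(counts)
  }
  total <- sum(full)
  per_thousand <- if (total > 0) 1000 * full / total else full
  fam <- codon_families(code)
  syn_fraction <- stats::setNames(rep(NA_real_, 64), codons)
  adaptiveness_w <- syn_fraction
  for (aa in names(fam)) {
    members <- fam[[aa]]
    cts <- full[members]
    syn_fraction[members] <- if (sum(cts) > 0) cts / sum(cts) else {
      rep(1 / length(members), length(members))
    }
    smoothed <- ifelse(cts == 0, 0.5, cts)   # pseudo-count so w > 0
    adaptiveness_w[members] <- smoothed / max(smoothed)
  }
  structure(
    list(code = code, counts = full, per_thousand = per_thousand,
         syn_fraction = syn_fraction, adaptiveness_w = adaptiveness_w,
         source = source, genes = genes),
    class = "codon_usage_table"
  )
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %s, %d codons counted (table %d)\n",
              x$source, sum(x$counts), x$code$table_id))
  invisible(x)
}

#' Tabulate codon usage from a gene set
#'
#' Count codon occurrences over a set of coding sequences and derive
#' per-thousand frequencies, synonymous fractions and relative adaptiveness
#' weights, in the manner of the CountCodon tabulation used to build custom
#' usage tables from highly expressed genes. A trailing stop codon of each
#' gene is counted (it contributes to `counts` and `per_thousand` but never
#' to family normalization).
#'
#' @param genes A list of [coding_sequence()] objects, or a named character
#'   vector of DNA strings.
#' @param code A [genetic_code()] (required when `genes` are plain strings;
#'   otherwise taken from the first gene).
#' @return A [codon_usage_table()] with `source = "gene-set"`.
#' @examples
#' tab <- tabulate_usage(c(g1 = "ATGGCT", g2 = "ATGGCC"), genetic_code(1))
#' tab$counts[c("ATG", "GCT", "GCC")]  # 2 1 1
#' @export
tabulate_usage <- function(genes, code = NULL) {
  if (is.character(genes)) {
    if (is.null(code)) stop("code is required for plain-string genes")
    ids <- if (is.null(names(genes))) paste0("gene", seq_along(genes)) else names(genes)
    genes <- mapply(coding_sequence, ids, genes,
                    MoreArgs = list(code = code), SIMPLIFY = FALSE)
  }
  if (length(genes) == 0L) stop("empty gene set")
  stopifnot(all(vapply(genes, inherits, logical(1), "coding_sequence")))
  if (is.null(code)) code <- genes[[1]]$code
  counts <- table(unlist(lapply(genes, function(g) split_codons(g$nucleotides))))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  codon_usage_table(counts, code = code, source = "gene-set",
                    genes = unname(vapply(genes, function(g) g$id, character(1))))
}

#' Relative adaptiveness weights
#'
#' Per-codon relative adaptiveness: the within-family synonymous fraction
#' divided by the family maximum, so the most frequent codon of each family
#' has weight 1. Zero-count codons have been smoothed at table construction,
#' so every weight is strictly positive. Stop codons are `NA`.
#'
#' @param table A [codon_usage_table()].
#' @return Named numeric vector over all 64 codons.
#' @export
relative_adaptiveness <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  w <- table$adaptiveness_w
  if (any(!is.na(w) & w <= 0)) stop("internal error: non-positive weight")
  w
}

#' Read a CountCodon/Kazusa-style usage table
#'
#' Parses whitespace-separated `CODON count per1000` triples; the triples may
#' be laid out several per line (the multi-column Kazusa layout) or one per
#' line. RNA codons (U) are accepted and converted to DNA (T). The per-1000
#' column is ignored on input (it is recomputed from counts).
#'
#' @param path File path.
#' @param code A [genetic_code()].
#' @return A [codon_usage_table()] with `source = "file"`.
#' @export
read_codon_usage <- function(path, code = genetic_code(1L)) {
  tokens <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(tokens) %% 3L != 0L) {
    stop("malformed usage table: token count not a multiple of 3")
  }
  m <- matrix(tokens, ncol = 3L, byrow = TRUE)
  codons <- chartr("Uu", "Tt", toupper(m[, 1]))
  counts <- suppressWarnings(as.numeric(m[, 2]))
  if (any(is.na(counts))) stop("malformed usage table: non-numeric count")
  if (anyDuplicated(codons)) stop("duplicate codon in usage table")
  codon_usage_table(stats::setNames(counts, codons), code = code,
                    source = "file")
}

#' Write a usage table as CountCodon-style text
#'
#' One codon per line, alphabetical order, columns `codon count per1000`.
#' Counts round-trip exactly through [read_codon_usage()].
#'
#' @param table A [codon_usage_table()].
#' @param path Output file path.
#' @export
write_codon_usage <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  codons <- all_codons()
  lines <- sprintf("%s %s %.6f", codons,
                   format(table$counts[codons], scientific = FALSE, trim = TRUE),
                   table$per_thousand[codons])
  writeLines(lines, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return List of [protein_sequence()] objects.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  mapply(protein_sequence, ids, as.character(set), SIMPLIFY = FALSE)
}

#' Read coding sequences from FASTA
#' @param path FASTA file.
#' @param code A [genetic_code()].
#' @return List of [coding_sequence()] objects.
#' @export
read_cds_fasta <- function(path, code = genetic_code(1L)) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  mapply(coding_sequence, ids, as.character(set),
         MoreArgs = list(code = code), SIMPLIFY = FALSE)
}

#' Write protein or coding sequences to FASTA (60-column wrap)
#' @param seqs List of [protein_sequence()] or [coding_sequence()] objects
#'   (or coding variants, whose DNA is written).
#' @param path Output file path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, c("protein_sequence", "coding_sequence", "coding_variant"))) {
    seqs <- list(seqs)
  }
  strings <- vapply(seqs, function(s) {
    if (inherits(s, "coding_variant")) s <- s$dna
    if (inherits(s, "protein_sequence")) s$residues else s$nucleotides
  }, character(1))
  ids <- vapply(seqs, function(s) {
    if (inherits(s, "coding_variant")) paste0(s$protein_id, "|", s$strategy_label)
    else s$id
  }, character(1))
  if (inherits(seqs[[1]], "protein_sequence")) {
    set <- Biostrings::AAStringSet(strings)
  } else {
    set <- Biostrings::DNAStringSet(strings)
  }
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
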