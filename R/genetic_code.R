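#' Genetic codes
#'
#' Construct a genetic code: a mapping of all 64 DNA triplets to one-letter
#' amino acids (`"*"` marks stop). Two codes are supported: the standard
#' nuclear code (table 1) and the alternative yeast nuclear code (table 12)
#' used by *Candida albicans* and other CTG-clade yeasts, in which CTG is
#' decoded as serine rather than leucine.
#'
#' @param table_id Integer, 1 (standard) or 12 (alternative yeast nuclear).
#' @return An object of class `genetic_code`: a list with `name`, `table_id`
#'   and `codon_to_aa` (a named character vector over all 64 codons).
#' @examples
#' code <- genetic_code(12)
#' code$codon_to_aa[["CTG"]]  # "S"
#' @export
genetic_code <- function(table_id = 1L) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 12L)) {
    stop("unsupported genetic code table: ", table_id)
  }
  map <- Biostrings::GENETIC_CODE
  map <- stats::setNames(as.character(map), names(map))
  name <- "standard"
  if (table_id == 12L) {
    map[["CTG"]] <- "S"
    name <- "alternative yeast nuclear"
  }
  map <- map[order(names(map))]
  structure(
    list(name = name, table_id = table_id, codon_to_aa = map),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> %s (table %d)\n", x$name, x$table_id))
  invisible(x)
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synonymous codon families
#'
#' Group the 64 codons of a genetic code by encoded amino acid. Stop codons
#' are excluded.
#'
#' @param code A [genetic_code()].
#' @return Named list: amino acid -> character vector of codons
#'   (alphabetical order).
#' @export
codon_families <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  key <- as.character(code$table_id)
  cached <- .family_cache[[key]]
  if (!is.null(cached)) return(cached)
  map <- code$codon_to_aa
  map <- map[map != "*"]
  fam <- split(names(map), map)
  .family_cache[[key]] <- fam
  fam
}

# the two supported codes are immutable, so their families can be cached
.family_cache <- new.env(parent = emptyenv())

#' All 64 codons, alphabetically
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sort(codons)
}

split_codons <- function(nucleotides) {
  n <- nchar(nucleotides)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, " nt) is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  starts <- seq(1L, n, by = 3L)
  substring(nucleotides, starts, starts + 2L)
}

check_dna_alphabet <- function(nucleotides) {
  if (grepl("[^ACGT]", nucleotides)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", nucleotides), "")[[1]])
    stop("invalid DNA character(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Protein sequence
#'
#' @param id Identifier.
#' @param residues One-letter amino-acid string (20 standard residues).
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues) {
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), AMINO_ACIDS)
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  structure(list(id = as.character(id), residues = residues),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Coding DNA sequence
#'
#' A validated coding sequence: A/C/G/T alphabet, length divisible by 3 and
#' no internal stop codon under its genetic code. A trailing stop codon is
#' allowed and preserved.
#'
#' @param id Identifier.
#' @param nucleotides DNA string.
#' @param code A [genetic_code()].
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(id, nucleotides, code = genetic_code(1L)) {
  stopifnot(inherits(code, "genetic_code"))
  nucleotides <- toupper(nucleotides)
  check_dna_alphabet(nucleotides)
  codons <- split_codons(nucleotides)
  if (length(codons) == 0L) stop("empty coding sequence")
  aas <- code$codon_to_aa[codons]
  internal <- aas[-length(aas)]
  if (any(internal == "*")) {
    stop("internal stop codon at codon position ",
         which(internal == "*")[1])
  }
  structure(
    list(id = as.character(id), nucleotides = nucleotides, code = code),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s (%d nt, table %d)\n",
              x$id, nchar(x$nucleotides), x$code$table_id))
  invisible(x)
}

#' Translate a coding sequence
#'
#' Translate codon by codon under the sequence's (or an overriding) genetic
#' code. A single trailing stop codon is dropped and flagged via the
#' `"stop_trimmed"` attribute; an internal stop is an error.
#'
#' @param cds A [coding_sequence()] or a plain DNA string.
#' @param code Optional [genetic_code()] overriding `cds$code`.
#' @return A [protein_sequence()] with attribute `stop_trimmed` (logical).
#' @examples
#' p <- translate_cds(coding_sequence("x", "ATGCTG", genetic_code(12)))
#' p$residues  # "MS"
#' @export
translate_cds <- function(cds, code = NULL) {
  if (is.character(cds)) {
    cds <- coding_sequence("seq", cds,
                           code = if (is.null(code)) genetic_code(1L) else code)
  }
  stopifnot(inherits(cds, "coding_sequence"))
  if (is.null(code)) code <- cds$code
  codons <- split_codons(cds$nucleotides)
  aas <- unname(code$codon_to_aa[codons])
  stop_trimmed <- FALSE
  if (aas[length(aas)] == "*") {
    aas <- aas[-length(aas)]
    stop_trimmed <- TRUE
  }
  if (any(aas == "*")) {
    stop("internal stop codon at codon position ", which(aas == "*")[1])
  }
  if (length(aas) == 0L) stop("sequence is a bare stop codon")
  out <- protein_sequence(cds$id, paste(aas, collapse = ""))
  attr(out, "stop_trimmed") <- stop_trimmed
  out
}
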