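#' Folding configuration
#'
#' Settings for the secondary-structure folding score. The built-in engine
#' (`"builtin_dp"`) is a weighted base-pair-maximization dynamic program:
#' it maximizes the total pair score over pseudoknot-free structures with a
#' minimum hairpin loop, and reports the negated optimum as a pseudo-energy
#' (more structure = more negative). It is intended for ranking variants by
#' propensity to fold, not for thermodynamic energies; the engine contract
#' (nucleotide string in, score plus dot-bracket out) lets a thermodynamic
#' engine such as RNAfold be plugged in (`engine = "rnafold"`, which shells
#' out to the ViennaRNA `RNAfold` binary when present) without changing
#' callers.
#'
#' @param engine `"builtin_dp"` (default) or `"rnafold"`.
#' @param pair_scores Named vector of pair weights, default
#'   `c(GC = 3, AU = 2, GU = 1)`.
#' @param min_loop Minimum unpaired nucleotides in a hairpin loop
#'   (default 3).
#' @return An object of class `fold_config`.
#' @export
fold_config <- function(engine = c("builtin_dp", "rnafold"),
                        pair_scores = c(GC = 3, AU = 2, GU = 1),
                        min_loop = 3L) {
  engine <- match.arg(engine)
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_scores)),
            all(pair_scores > 0), min_loop >= 0L)
  structure(
    list(engine = engine, pair_scores = pair_scores,
         min_loop = as.integer(min_loop)),
    class = "fold_config"
  )
}

as_rna_string <- function(x) {
  if (inherits(x, "coding_variant")) x <- x$dna
  if (inherits(x, "coding_sequence")) x <- x$nucleotides
  x <- chartr("Tt", "Uu", toupper(x))
  if (grepl("[^ACGU]", x)) {
    stop("invalid nucleotide character in folding input")
  }
  x
}

#' Minimum-free-energy folding score
#'
#' Folds a nucleotide sequence (DNA input is converted to RNA on entry) and
#' returns the folding score and one optimal structure in dot-bracket
#' notation. With the built-in engine the score is the negated maximum
#' total pair score (GC/AU/GU weighted, pseudoknot-free, minimum hairpin
#' loop respected); traceback ties are broken by pairing the leftmost
#' position with its smallest admissible partner, so output is
#' deterministic.
#'
#' @param rna Nucleotide string, [coding_sequence()] or `coding_variant`.
#' @param cfg A [fold_config()].
#' @return List with `score` (<= 0), `structure` (dot-bracket string of the
#'   same length) and `engine`.
#' @examples
#' fold_mfe("GGGAAACCC")  # score -9, "(((...)))"
#' @export
fold_mfe <- function(rna, cfg = fold_config()) {
  stopifnot(inherits(cfg, "fold_config"))
  s <- as_rna_string(rna)
  if (nchar(s) == 0L) stop("empty sequence")
  if (cfg$engine == "rnafold") {
    return(fold_rnafold(s))
  }
  res <- nussinov_fold(s, cfg$pair_scores[["GC"]], cfg$pair_scores[["AU"]],
                       cfg$pair_scores[["GU"]], cfg$min_loop)
  list(score = -res$score, structure = res$structure, engine = "builtin_dp")
}

# External engine: ViennaRNA's RNAfold, when the binary is on PATH.
fold_rnafold <- function(s) {
  bin <- Sys.which("RNAfold")
  if (bin == "") stop("RNAfold binary not found on PATH")
  out <- system2(bin, args = "--noPS", input = s, stdout = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) stop("unparseable RNAfold output: ", line)
  list(score = as.numeric(m[3]), structure = m[2], engine = "rnafold")
}

#' Exhaustive folding oracle
#'
#' Enumerates every pseudoknot-free pair set of a short sequence (<= 14 nt)
#' and returns the best-scoring one. Exists to verify [fold_mfe()]'s
#' dynamic program on small inputs; it shares no code with it beyond the
#' pair-score table.
#'
#' @inheritParams fold_mfe
#' @return List with `score`, `structure`, `engine = "brute_force"`.
#' @export
brute_force_fold <- function(rna, cfg = fold_config()) {
  stopifnot(inherits(cfg, "fold_config"))
  s <- as_rna_string(rna)
  n <- nchar(s)
  if (n > 14L) stop("brute-force oracle limited to 14 nt")
  if (n == 0L) {
    return(list(score = 0, structure = "", engine = "brute_force"))
  }
  nts <- strsplit(s, "")[[1]]
  pair_ok <- function(a, b) {
    paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  }
  pair_val <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) return(cfg$pair_scores[["GC"]])
    if (key %in% c("AU", "UA")) return(cfg$pair_scores[["AU"]])
    cfg$pair_scores[["GU"]]
  }
  # all pseudoknot-free pair sets over positions i..j, each a k x 2 matrix
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    out <- lapply(enum(i + 1L, j), identity)       # i unpaired
    for (k in seq.int(i + cfg$min_loop + 1L, j)) {
      if (k > j) break
      if (!pair_ok(nts[i], nts[k])) next
      inner <- enum(i + 1L, k - 1L)
      outer_ <- enum(k + 1L, j)
      for (a in inner) for (b in outer_) {
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
      }
    }
    out
  }
  sets <- if (n >= cfg$min_loop + 2L) enum(1L, n) else list(matrix(integer(0), ncol = 2))
  scores <- vapply(sets, function(ps) {
    if (nrow(ps) == 0L) return(0)
    sum(vapply(seq_len(nrow(ps)),
               function(r) pair_val(nts[ps[r, 1]], nts[ps[r, 2]]), numeric(1)))
  }, numeric(1))
  best <- sets[[which.max(scores)]]
  db <- rep(".", n)
  if (nrow(best) > 0L) {
    db[best[, 1]] <- "("
    db[best[, 2]] <- ")"
  }
  list(score = -max(scores), structure = paste(db, collapse = ""),
       engine = "brute_force")
}
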