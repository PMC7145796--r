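#' @useDynLib codonopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Optimization configuration
#'
#' Bundles a usage table with the knobs shared by the optimization
#' strategies: the synonymous-fraction threshold below which codons are
#' eliminated (threshold-random strategy), the forbidden-codon set, the RNG
#' seed, and the sequence-complexity limits used by constraint repair.
#'
#' All frequency thresholds operate on the within-family synonymous
#' fraction, not the per-1000 genome frequency. Under the alternative yeast
#' nuclear code (table 12) CTG is forbidden by default for every residue:
#' even though it decodes predominantly as serine, the residual leucine
#' mistranslation makes it ambiguous for heterologous constructs. Pass
#' `forbidden_codons = character(0)` to allow it.
#'
#' @param strategy One of `"threshold_random"`, `"guided_random"`,
#'   `"max_cai"`, `"scaffold_transfer"`.
#' @param usage_table A [codon_usage_table()].
#' @param frequency_threshold Synonymous-fraction threshold (default 0.10):
#'   codons below it are removed before sampling in the threshold-random
#'   strategy.
#' @param forbidden_codons Codons never emitted. Default: `"CTG"` when the
#'   table's code is table 12, otherwise none.
#' @param seed Integer RNG seed (required by the random strategies).
#' @param max_homopolymer Longest tolerated single-nucleotide run (nt).
#' @param max_direct_repeat Shortest repeated substring flagged (nt).
#' @param gc_window,gc_bounds Sliding-window width (nt) and GC-fraction
#'   bounds used by complexity repair.
#' @param max_repair_iterations Resampling passes before giving up.
#' @return An object of class `optimization_config`.
#' @export
optimization_config <- function(strategy = c("threshold_random", "guided_random",
                                             "max_cai", "scaffold_transfer"),
                                usage_table,
                                frequency_threshold = 0.10,
                                forbidden_codons = NULL,
                                seed = NULL,
                                max_homopolymer = 8L,
                                max_direct_repeat = 12L,
                                gc_window = 50L,
                                gc_bounds = c(0.30, 0.70),
                                max_repair_iterations = 100L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(usage_table, "codon_usage_table"))
  if (frequency_threshold < 0 || frequency_threshold >= 1) {
    stop("frequency_threshold must be in [0, 1)")
  }
  if (is.null(forbidden_codons)) {
    forbidden_codons <- if (usage_table$code$table_id == 12L) "CTG" else character(0)
  }
  forbidden_codons <- toupper(forbidden_codons)
  bad <- setdiff(forbidden_codons, all_codons())
  if (length(bad) > 0) stop("unknown forbidden codon(s): ", paste(bad, collapse = ", "))
  structure(
    list(strategy = strategy, usage_table = usage_table,
         frequency_threshold = frequency_threshold,
         forbidden_codons = forbidden_codons, seed = seed,
         max_homopolymer = as.integer(max_homopolymer),
         max_direct_repeat = as.integer(max_direct_repeat),
         gc_window = as.integer(gc_window), gc_bounds = gc_bounds,
         max_repair_iterations = as.integer(max_repair_iterations)),
    class = "optimization_config"
  )
}

# Allowed codons (family minus forbidden) with their synonymous fractions,
# for one residue. Errors if the residue loses every codon.
allowed_codons <- function(aa, cfg) {
  fam <- codon_families(cfg$usage_table$code)
  if (!aa %in% names(fam)) stop("unknown residue: ", aa)
  codons <- setdiff(fam[[aa]], cfg$forbidden_codons)
  if (length(codons) == 0L) {
    stop("residue ", aa, " has no allowed codon after removing forbidden set")
  }
  stats::setNames(cfg$usage_table$syn_fraction[codons], codons)
}

new_coding_variant <- function(protein, codons, cfg, label, repair_log = NULL) {
  dna <- coding_sequence(protein$id, paste(codons, collapse = ""),
                         code = cfg$usage_table$code)
  structure(
    list(protein_id = protein$id, dna = dna, strategy_label = label,
         seed = cfg$seed,
         repair_log = if (is.null(repair_log)) {
           data.frame(iteration = integer(0), codon_index = integer(0),
                      reason = character(0), old = character(0),
                      new = character(0))
         } else repair_log),
    class = "coding_variant"
  )
}

#' @export
print.coding_variant <- function(x, ...) {
  cat(sprintf("<coding_variant> %s [%s] %d nt, %d repair(s)\n",
              x$protein_id, x$strategy_label, nchar(x$dna$nucleotides),
              nrow(x$repair_log)))
  invisible(x)
}

#' Bulk maximal-CAI optimization
#'
#' Encodes every residue with its most frequent allowed codon (ATGme-style
#' bulk optimization), yielding the sequence with the highest possible codon
#' adaptation index. Ties on synonymous fraction are broken alphabetically.
#'
#' @param protein A [protein_sequence()].
#' @param cfg An [optimization_config()] with `strategy = "max_cai"`.
#' @return A `coding_variant`.
#' @export
optimize_max_cai <- function(protein, cfg) {
  stopifnot(inherits(protein, "protein_sequence"),
            inherits(cfg, "optimization_config"))
  if (cfg$strategy != "max_cai") stop("cfg$strategy must be 'max_cai'")
  aas <- strsplit(protein$residues, "")[[1]]
  pick <- vapply(unique(aas), function(aa) {
    fr <- allowed_codons(aa, cfg)
    fr <- fr[order(names(fr))]            # alphabetical tie-break
    names(fr)[which.max(fr)]
  }, character(1))
  new_coding_variant(protein, unname(pick[aas]), cfg, "ATGme")
}

# Draw one codon per residue with the given per-residue weight function.
# Draws are grouped by residue (still fully seed-deterministic).
sample_codons <- function(aas, cfg, weight_fn) {
  out <- character(length(aas))
  for (aa in unique(aas)) {
    fr <- allowed_codons(aa, cfg)
    w <- weight_fn(fr)
    if (all(w <= 0)) {
      stop("residue ", aa, " has no codon left after thresholding")
    }
    idx <- which(aas == aa)
    out[idx] <- if (length(w) == 1L) names(w) else {
      sample(names(w), length(idx), replace = TRUE, prob = w / sum(w))
    }
  }
  out
}

#' Threshold-random optimization
#'
#' IDT-style optimization: codons whose synonymous fraction falls below
#' `cfg$frequency_threshold` are eliminated from each family, the remaining
#' fractions renormalized, and a codon drawn independently per residue
#' proportionally to the renormalized fractions. A complexity-repair pass
#' ([enforce_constraints()]) then removes homopolymers, direct repeats and
#' GC-extreme windows by synonymous resampling.
#'
#' @inheritParams optimize_max_cai
#' @return A `coding_variant` with a repair log.
#' @export
optimize_threshold_random <- function(protein, cfg) {
  stopifnot(inherits(protein, "protein_sequence"),
            inherits(cfg, "optimization_config"))
  if (cfg$strategy != "threshold_random") {
    stop("cfg$strategy must be 'threshold_random'")
  }
  if (is.null(cfg$seed)) stop("threshold_random requires a seed")
  thr <- cfg$frequency_threshold
  aas <- strsplit(protein$residues, "")[[1]]
  with_seed(cfg$seed, {
    codons <- sample_codons(aas, cfg, function(fr) ifelse(fr < thr, 0, fr))
    rep <- repair_codons(codons, cfg)
  })
  new_coding_variant(protein, rep$codons, cfg, "IDT", repair_log = rep$log)
}

#' Guided-random (Monte Carlo) optimization
#'
#' OPTIMIZER-style optimization: a codon is drawn independently for each
#' residue with probability proportional to its synonymous fraction in the
#' supplied usage table, with no frequency threshold. The "entire-genome"
#' and "highly-expressed-gene" flavours differ only in the usage table
#' carried by `cfg`.
#'
#' @inheritParams optimize_max_cai
#' @param label Strategy label recorded on the variant (default
#'   `"OPT Entire"`; use `"OPT High"` for a highly-expressed-gene table).
#' @return A `coding_variant`.
#' @export
optimize_guided_random <- function(protein, cfg, label = "OPT Entire") {
  stopifnot(inherits(protein, "protein_sequence"),
            inherits(cfg, "optimization_config"))
  if (cfg$strategy != "guided_random") stop("cfg$strategy must be 'guided_random'")
  if (is.null(cfg$seed)) stop("guided_random requires a seed")
  aas <- strsplit(protein$residues, "")[[1]]
  codons <- with_seed(cfg$seed, sample_codons(aas, cfg, identity))
  new_coding_variant(protein, codons, cfg, label)
}

#' Transfer a scaffold's codon choices onto a related protein
#'
#' For proteins closely related to an already well-expressed scaffold
#' (e.g. deriving mTurquoise2 or YemVenus codon sequences from a GFP
#' scaffold), copies the scaffold codon verbatim wherever the residues
#' agree, and at substituted residues uses the most frequent allowed codon
#' of the new residue (ties: fewest nucleotide changes from the scaffold
#' codon, then alphabetical). Only substitutions are supported; the target
#' must have the scaffold's length.
#'
#' @param scaffold A `coding_variant` or [coding_sequence()] whose codons
#'   are transferred.
#' @param target A [protein_sequence()] of the same length as the
#'   scaffold's protein.
#' @param cfg An [optimization_config()] with `strategy = "scaffold_transfer"`.
#' @return A `coding_variant` labelled `"gamma-scaffold"`.
#' @export
transfer_mutations <- function(scaffold, target, cfg) {
  stopifnot(inherits(target, "protein_sequence"),
            inherits(cfg, "optimization_config"))
  if (cfg$strategy != "scaffold_transfer") {
    stop("cfg$strategy must be 'scaffold_transfer'")
  }
  if (inherits(scaffold, "coding_variant")) scaffold <- scaffold$dna
  stopifnot(inherits(scaffold, "coding_sequence"))
  scaffold_prot <- translate_cds(scaffold, code = cfg$usage_table$code)
  s_aas <- strsplit(scaffold_prot$residues, "")[[1]]
  t_aas <- strsplit(target$residues, "")[[1]]
  if (length(s_aas) != length(t_aas)) {
    stop("scaffold and target lengths differ (", length(s_aas), " vs ",
         length(t_aas), "): indels are unsupported")
  }
  s_codons <- split_codons(scaffold$nucleotides)[seq_along(s_aas)]
  codons <- character(length(t_aas))
  for (i in seq_along(t_aas)) {
    if (t_aas[i] == s_aas[i] && !s_codons[i] %in% cfg$forbidden_codons) {
      codons[i] <- s_codons[i]
    } else {
      fr <- allowed_codons(t_aas[i], cfg)
      cand <- names(fr)[fr == max(fr)]
      if (length(cand) > 1L) {
        nt_diff <- vapply(cand, function(cd) {
          sum(strsplit(cd, "")[[1]] != strsplit(s_codons[i], "")[[1]])
        }, numeric(1))
        cand <- cand[nt_diff == min(nt_diff)]
        cand <- sort(cand)
      }
      codons[i] <- cand[1]
    }
  }
  new_coding_variant(target, codons, cfg, "gamma-scaffold")
}

# ---- complexity scanning and repair ------------------------------------

# Codon indices (1-based) covered by nucleotide interval [from, to].
nt_to_codon_idx <- function(from, to) {
  unique(seq.int((from - 1L) %/% 3L + 1L, (to - 1L) %/% 3L + 1L))
}

# Scan a codon vector for complexity violations; returns a data.frame of
# (codon_index, reason), empty when clean.
scan_violations <- function(codons, cfg) {
  seqstr <- paste(codons, collapse = "")
  n <- nchar(seqstr)
  nts <- strsplit(seqstr, "")[[1]]
  idx <- integer(0); reason <- character(0)
  hit <- function(i, why) {
    idx <<- c(idx, i); reason <<- c(reason, rep(why, length(i)))
  }
  if (length(cfg$forbidden_codons) > 0) {
    i <- which(codons %in% cfg$forbidden_codons)
    if (length(i) > 0) hit(i, "forbidden_codon")
  }
  r <- rle(nts)
  if (any(r$lengths > cfg$max_homopolymer)) {
    ends <- cumsum(r$lengths)
    for (k in which(r$lengths > cfg$max_homopolymer)) {
      hit(nt_to_codon_idx(ends[k] - r$lengths[k] + 1L, ends[k]), "homopolymer")
    }
  }
  L <- cfg$max_direct_repeat
  if (n >= 2L * L) {
    starts <- seq_len(n - L + 1L)
    subs <- substring(seqstr, starts, starts + L - 1L)
    dup <- which(duplicated(subs))
    # ignore overlapping self-matches (homopolymer-like), handled above
    for (s in dup) {
      first <- match(subs[s], subs)
      if (s - first >= L) hit(nt_to_codon_idx(s, s + L - 1L), "direct_repeat")
    }
  }
  W <- cfg$gc_window
  if (n >= W) {
    gc <- cumsum(nts %in% c("G", "C"))
    win <- (gc[W:n] - c(0, gc)[seq_len(n - W + 1L)]) / W
    bad <- which(win < cfg$gc_bounds[1] | win > cfg$gc_bounds[2])
    for (s in bad) hit(nt_to_codon_idx(s, s + W - 1L), "gc_window")
  }
  unique(data.frame(codon_index = idx, reason = reason,
                    stringsAsFactors = FALSE))
}

# Iterative synonymous resampling of violating positions. Consumes the
# current RNG stream (callers wrap in with_seed). Returns codons + log +
# unresolved violations.
repair_codons <- function(codons, cfg) {
  code <- cfg$usage_table$code
  aas <- unname(code$codon_to_aa[codons])
  log <- data.frame(iteration = integer(0), codon_index = integer(0),
                    reason = character(0), old = character(0),
                    new = character(0), stringsAsFactors = FALSE)
  viol <- scan_violations(codons, cfg)
  iter <- 0L
  while (nrow(viol) > 0 && iter < cfg$max_repair_iterations) {
    iter <- iter + 1L
    for (k in seq_len(nrow(viol))) {
      i <- viol$codon_index[k]
      if (aas[i] == "*") next                   # trailing stop is untouchable
      fr <- allowed_codons(aas[i], cfg)
      if (viol$reason[k] == "forbidden_codon" && length(fr) == 0L) {
        stop("forbidden codon ", codons[i],
             " encodes a single-codon family: unsatisfiable")
      }
      if (length(fr) <= 1L && names(fr)[1] == codons[i]) next
      alt <- fr[names(fr) != codons[i]]
      # threshold-random mode repairs with the thresholded codon set too,
      # unless that leaves no alternative
      if (cfg$strategy == "threshold_random") {
        thr <- alt[alt >= cfg$frequency_threshold]
        if (any(thr > 0)) alt <- thr
      }
      if (length(alt) == 0L || all(alt <= 0)) next
      new <- if (length(alt) == 1L) names(alt) else {
        sample(names(alt), 1L, prob = alt / sum(alt))
      }
      log <- rbind(log, data.frame(iteration = iter, codon_index = i,
                                   reason = viol$reason[k], old = codons[i],
                                   new = new, stringsAsFactors = FALSE))
      codons[i] <- new
    }
    viol <- scan_violations(codons, cfg)
  }
  list(codons = codons, log = log, unresolved = viol)
}

#' Repair sequence complexity by synonymous resampling
#'
#' Rewrites codons that participate in forbidden codons, homopolymer runs
#' longer than `max_homopolymer`, exact direct repeats of at least
#' `max_direct_repeat` nt, or `gc_window`-nt windows with GC content outside
#' `gc_bounds`. Replacement codons are drawn from the same synonymous family
#' (weighted by synonymous fraction), so the encoded protein never changes.
#' The scan/resample loop runs until the sequence is clean or
#' `max_repair_iterations` is reached, in which case the best effort is
#' returned with the outstanding violations listed.
#'
#' @param dna A [coding_sequence()] (a trailing stop codon is preserved
#'   verbatim).
#' @param cfg An [optimization_config()]; its `seed` drives the resampling.
#' @return List with `dna` (repaired [coding_sequence()]), `repair_log`
#'   (data.frame: iteration, codon_index, reason, old, new) and `unresolved`
#'   (data.frame of violations still present, empty when clean).
#' @export
enforce_constraints <- function(dna, cfg) {
  stopifnot(inherits(dna, "coding_sequence"),
            inherits(cfg, "optimization_config"))
  codons <- split_codons(dna$nucleotides)
  res <- with_seed(cfg$seed, repair_codons(codons, cfg))
  list(
    dna = coding_sequence(dna$id, paste(res$codons, collapse = ""),
                          code = dna$code),
    repair_log = res$log,
    unresolved = res$unresolved
  )
}
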