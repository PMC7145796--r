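#' Pipeline configuration
#'
#' Assembles everything [run_pipeline()] needs: the proteins to optimize,
#' the usage tables (entire-genome and, optionally, a highly-expressed-gene
#' table), the strategies to run, an optional scaffold coding sequence for
#' mutation transfer, optional measured brightness tables, and the
#' per-stage configuration blocks. File paths and in-memory objects are
#' both accepted.
#'
#' @param proteins List of [protein_sequence()] objects, or a protein FASTA
#'   path.
#' @param usage_table A [codon_usage_table()] or usage-table file path
#'   (entire-genome reference; also the CAI reference).
#' @param usage_table_high Optional second table (highly-expressed-gene
#'   set) for the `"OPT High"` strategy.
#' @param strategies Subset of `c("IDT", "OPT Entire", "OPT High", "ATGme",
#'   "gamma-scaffold")`.
#' @param scaffold Optional [coding_sequence()] or CDS FASTA path (required
#'   by `"gamma-scaffold"`).
#' @param brightness,wildtype Optional data frames or TSV paths of measured
#'   replicate fluorescence (see [correct_and_summarize()]); when absent
#'   and `simulate = TRUE`, brightness is simulated.
#' @param simulate Simulate brightness when none is supplied?
#' @param synthetic A [synthetic_spec()] used for simulation.
#' @param table_id Genetic code table (default 12).
#' @param diagnostics A [diagnostics_config()].
#' @param fold A [fold_config()].
#' @param frequency_threshold,forbidden_codons Passed to
#'   [optimization_config()].
#' @param out_dir Output directory (created if needed); `NULL` for no file
#'   output.
#' @param seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, usage_table, usage_table_high = NULL,
                            strategies = c("IDT", "OPT Entire", "ATGme"),
                            scaffold = NULL,
                            brightness = NULL, wildtype = NULL,
                            simulate = TRUE,
                            synthetic = synthetic_spec(),
                            table_id = 12L,
                            diagnostics = diagnostics_config(),
                            fold = fold_config(),
                            frequency_threshold = 0.10,
                            forbidden_codons = NULL,
                            out_dir = NULL, seed = 1L) {
  code <- genetic_code(table_id)
  if (is.character(proteins)) proteins <- read_protein_fasta(proteins)
  if (is.character(usage_table)) usage_table <- read_codon_usage(usage_table, code)
  if (is.character(usage_table_high)) {
    usage_table_high <- read_codon_usage(usage_table_high, code)
  }
  if (is.character(scaffold)) scaffold <- read_cds_fasta(scaffold, code)[[1]]
  if (is.character(brightness)) {
    brightness <- utils::read.delim(brightness, stringsAsFactors = FALSE)
  }
  if (is.character(wildtype)) {
    wildtype <- utils::read.delim(wildtype, stringsAsFactors = FALSE)
  }
  known <- c("IDT", "OPT Entire", "OPT High", "ATGme", "gamma-scaffold")
  bad <- setdiff(strategies, known)
  if (length(bad) > 0) stop("unknown strategy: ", paste(bad, collapse = ", "))
  if ("OPT High" %in% strategies && is.null(usage_table_high)) {
    stop("strategy 'OPT High' requires usage_table_high")
  }
  if ("gamma-scaffold" %in% strategies && is.null(scaffold)) {
    stop("strategy 'gamma-scaffold' requires a scaffold")
  }
  structure(
    list(proteins = proteins, usage_table = usage_table,
         usage_table_high = usage_table_high, strategies = strategies,
         scaffold = scaffold, brightness = brightness, wildtype = wildtype,
         simulate = simulate, synthetic = synthetic, code = code,
         diagnostics = diagnostics, fold = fold,
         frequency_threshold = frequency_threshold,
         forbidden_codons = forbidden_codons,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

strategy_seed <- function(seed, i, j) {
  (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
}

#' Run the full in-silico pipeline
#'
#' For every protein x strategy: generates a coding variant, computes its
#' diagnostics (CAI, GC, rare-codon runs, full and 5' folding scores), then
#' — if brightness is supplied or simulated — corrects and summarizes
#' brightness, compares variants within each fluorescent-protein group
#' (ANOVA + Tukey, or t-test for two groups), and associates diagnostics
#' with normalized brightness. When `cfg$out_dir` is set, writes variant
#' FASTA, TSV tables and a JSON run manifest (seeds and config hash), so a
#' run can be reproduced exactly.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `variants`, `diagnostics`, and (when brightness is
#'   available) `summaries`, `comparisons`, `associations`, plus
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "input"
  result <- tryCatch({
    stage <- "optimize"
    variants <- list()
    for (i in seq_along(cfg$proteins)) {
      p <- cfg$proteins[[i]]
      for (j in seq_along(cfg$strategies)) {
        s <- cfg$strategies[[j]]
        tab <- if (s == "OPT High") cfg$usage_table_high else cfg$usage_table
        sd_ij <- strategy_seed(cfg$seed, i, j)
        ocfg <- optimization_config(
          strategy = switch(s, "IDT" = "threshold_random",
                            "OPT Entire" = , "OPT High" = "guided_random",
                            "ATGme" = "max_cai",
                            "gamma-scaffold" = "scaffold_transfer"),
          usage_table = tab, frequency_threshold = cfg$frequency_threshold,
          forbidden_codons = cfg$forbidden_codons, seed = sd_ij)
        v <- switch(s,
          "IDT" = optimize_threshold_random(p, ocfg),
          "OPT Entire" = optimize_guided_random(p, ocfg, label = "OPT Entire"),
          "OPT High" = optimize_guided_random(p, ocfg, label = "OPT High"),
          "ATGme" = optimize_max_cai(p, ocfg),
          "gamma-scaffold" = transfer_mutations(cfg$scaffold, p, ocfg))
        variants[[length(variants) + 1L]] <- v
      }
    }
    stage <- "diagnostics"
    diagnostics <- diagnose_variants(variants, cfg$usage_table,
                                     cfg$diagnostics, cfg$fold)
    out <- list(variants = variants, diagnostics = diagnostics)

    stage <- "brightness"
    brightness <- cfg$brightness
    wildtype <- cfg$wildtype
    if (is.null(brightness) && cfg$simulate) {
      spec <- cfg$synthetic
      spec$seed <- strategy_seed(cfg$seed, 0L, 0L)
      sim <- simulate_brightness(variants, diagnostics, spec)
      brightness <- sim$records
      wildtype <- sim$wildtype
    }
    if (!is.null(brightness)) {
      stage <- "expression"
      out$summaries <- correct_and_summarize(brightness, wildtype)
      out$comparisons <- lapply(split(brightness, brightness$fp), function(b) {
        wt_mean <- tapply(wildtype$raw_mean, wildtype$channel, mean)
        corrected <- b$raw_mean - as.numeric(wt_mean[b$channel])
        groups <- split(corrected, b$strain)
        if (length(groups) >= 2L) compare_variants(groups) else NULL
      })
      out$associations <- associate_parameters(out$summaries, diagnostics)
    }

    stage <- "report"
    out$manifest <- list(
      seed = cfg$seed, strategies = cfg$strategies,
      n_proteins = length(cfg$proteins),
      table_id = cfg$code$table_id,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    if (!is.null(cfg$out_dir)) {
      write_pipeline_outputs(out, cfg)
    }
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(cfg$out_dir, "variants.fasta")
  write_fasta(out$variants, fasta)
  utils::write.table(out$diagnostics, file.path(cfg$out_dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$summaries)) {
    utils::write.table(out$summaries, file.path(cfg$out_dir, "summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$associations,
                       file.path(cfg$out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tukey <- do.call(rbind, lapply(names(out$comparisons), function(fp) {
      cmp <- out$comparisons[[fp]]
      if (is.null(cmp) || cmp$test != "anova_tukey") return(NULL)
      cbind(fp = fp, cmp$tukey)
    }))
    if (!is.null(tukey)) {
      utils::write.table(tukey, file.path(cfg$out_dir, "comparisons.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- out$manifest
  manifest$config_hash <- unname(tools::md5sum(fasta))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Demo pipeline configuration
#'
#' A fully synthetic, self-contained configuration: a skewed usage table, a
#' panel of proteins and simulated brightness, sized to run in seconds.
#'
#' @param seed Integer master seed.
#' @param out_dir Optional output directory.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = NULL) {
  spec <- synthetic_spec(seed = seed, n_proteins = 4L, protein_length = 80L,
                         gene_set_size = 30L, gene_length = 200L)
  ref <- generate_reference_set(spec)
  pipeline_config(
    proteins = ref$proteins, usage_table = ref$table,
    strategies = c("IDT", "OPT Entire", "ATGme"),
    synthetic = spec, out_dir = out_dir, seed = seed
  )
}
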