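#' Autofluorescence correction and per-variant summary
#'
#' Processes replicate-level mean-fluorescence measurements the way FACS
#' brightness panels are assembled: each replicate is corrected by
#' subtracting the mean wild-type autofluorescence of its channel, the
#' corrected replicates are averaged per variant (mean +/- SEM), and each
#' variant's mean is normalized to the brightest variant within its
#' fluorescent-protein group, so the best variant scores 1. Variants dimmer
#' than the wild type keep their negative corrected means and are flagged.
#'
#' @param records Data frame of tagged-strain measurements with columns
#'   `strain`, `fp`, `strategy`, `replicate`, `channel`, `raw_mean`.
#' @param wildtype Data frame of wild-type (untagged) measurements with
#'   columns `channel`, `raw_mean` (other columns ignored).
#' @return Data frame, one row per strain: `strain`, `fp`, `strategy`, `n`,
#'   `corrected_mean`, `sem`, `normalized`, `brightest` (logical, exactly
#'   one `TRUE` per fp group), `negative_corrected`.
#' @examples
#' rec <- data.frame(strain = "v1", fp = "gfp", strategy = "IDT",
#'                   replicate = 1:3, channel = "green",
#'                   raw_mean = c(300, 320, 340))
#' wt <- data.frame(channel = "green", raw_mean = c(90, 100, 110))
#' correct_and_summarize(rec, wt)  # corrected mean 220, sem 11.55
#' @export
correct_and_summarize <- function(records, wildtype) {
  need <- c("strain", "fp", "strategy", "replicate", "channel", "raw_mean")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("channel", "raw_mean") %in% names(wildtype))) {
    stop("wildtype must have columns channel, raw_mean")
  }
  if (any(records$raw_mean < 0) || any(wildtype$raw_mean < 0)) {
    stop("raw fluorescence must be non-negative")
  }
  wt_mean <- tapply(wildtype$raw_mean, wildtype$channel, mean)
  missing <- setdiff(unique(records$channel), names(wt_mean))
  if (length(missing) > 0) {
    stop("no wild-type measurements for channel(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- unlist(tapply(records$replicate, records$strain,
                       function(r) anyDuplicated(r) > 0))
  if (any(dup)) stop("duplicate replicate index within strain")

  corrected <- records$raw_mean - as.numeric(wt_mean[records$channel])
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), records$strain),
    function(ix) {
      x <- corrected[ix]
      data.frame(strain = records$strain[ix[1]], fp = records$fp[ix[1]],
                 strategy = records$strategy[ix[1]], n = length(x),
                 corrected_mean = mean(x),
                 sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out$normalized <- NA_real_
  out$brightest <- FALSE
  for (fp in unique(out$fp)) {
    ix <- which(out$fp == fp)
    mx <- max(out$corrected_mean[ix])
    if (mx <= 0) {
      stop("all corrected means are <= 0 in fp group '", fp,
           "': no brightest variant definable")
    }
    out$normalized[ix] <- out$corrected_mean[ix] / mx
    out$brightest[ix[which.max(out$corrected_mean[ix])]] <- TRUE
  }
  out$negative_corrected <- out$corrected_mean < 0
  out[order(out$fp, -out$corrected_mean), , drop = FALSE]
}

#' Significance stars
#'
#' Star annotation convention: `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Compare variant brightness across groups
#'
#' With more than two groups: one-way ANOVA followed by Tukey's honest
#' significant difference over all pairwise contrasts (two-sided), with the
#' contrasts against the brightest group (largest mean) marked. With
#' exactly two groups: a two-sided, equal-variance two-sample Student's
#' t-test.
#'
#' @param groups Named list of numeric vectors, one per variant (replicate
#'   corrected means; >= 2 replicates each for ANOVA).
#' @return An object of class `comparison_result`: for ANOVA, a list with
#'   `test = "anova_tukey"`, `anova` (F statistic, df, p), `tukey`
#'   (data.frame: `group1`, `group2`, `diff`, `p_adj`, `stars`,
#'   `vs_brightest`) and `brightest`; for two groups, `test = "t_test"`
#'   with `statistic`, `df`, `p`, `stars`.
#' @export
compare_variants <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups")
  }
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must be uniquely named")
  }
  vars <- vapply(groups, function(g) if (length(g) > 1) stats::var(g) else 0,
                 numeric(1))
  if (all(vars == 0)) {
    stop("zero within-group variance in every group: degenerate comparison")
  }
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    return(structure(
      list(test = "t_test", group1 = names(groups)[1], group2 = names(groups)[2],
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, stars = significance_stars(tt$p.value)),
      class = "comparison_result"
    ))
  }
  if (any(lengths(groups) < 2L)) stop("ANOVA needs >= 2 replicates per group")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  brightest <- names(groups)[which.max(vapply(groups, mean, numeric(1)))]
  tukey <- data.frame(
    group1 = pairs[, 1], group2 = pairs[, 2],
    diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"]),
    stars = significance_stars(unname(tk[, "p adj"])),
    vs_brightest = pairs[, 1] == brightest | pairs[, 2] == brightest,
    stringsAsFactors = FALSE
  )
  structure(
    list(test = "anova_tukey",
         anova = list(statistic = an[["F value"]][1],
                      df = unname(an[["Df"]]), p = an[["Pr(>F)"]][1]),
         tukey = tukey, brightest = brightest),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$test == "t_test") {
    cat(sprintf("t-test %s vs %s: t = %.4g, df = %g, p = %.4g %s\n",
                x$group1, x$group2, x$statistic, x$df, x$p, x$stars))
  } else {
    cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g; Tukey vs brightest (%s):\n",
                x$anova$statistic, x$anova$p, x$brightest))
    print(x$tukey[x$tukey$vs_brightest, ], row.names = FALSE)
  }
  invisible(x)
}

#' Associate sequence parameters with brightness
#'
#' For each diagnostic parameter, computes the Pearson and Spearman
#' correlation between per-variant normalized brightness and the parameter.
#' With fewer than six variants the result is marked descriptive-only and
#' no p-values are emitted: at n = 4-5 a correlation test is not
#' meaningful. Constant parameters are flagged and their coefficients
#' omitted.
#'
#' @param summaries Output of [correct_and_summarize()] (or any data frame
#'   with `strain`/`variant` and `normalized` columns).
#' @param reports Output of [diagnose_variants()] (column `variant` plus
#'   parameter columns).
#' @param parameters Which report columns to associate.
#' @return Data frame: `parameter`, `n`, `pearson_r`, `spearman_rho`,
#'   `pearson_p`, `spearman_p` (NA when descriptive-only),
#'   `descriptive_only`, `constant`.
#' @export
associate_parameters <- function(summaries, reports,
                                 parameters = c("cai", "gc_percent",
                                                "rare_run_count", "mfe_full",
                                                "mfe_5prime")) {
  id_col <- if ("strain" %in% names(summaries)) "strain" else "variant"
  merged <- merge(summaries[, c(id_col, "normalized")], reports,
                  by.x = id_col, by.y = "variant")
  if (nrow(merged) < 3L) stop("need at least 3 matched variants")
  rows <- lapply(parameters, function(p) {
    x <- merged[[p]]
    y <- merged$normalized
    n <- sum(stats::complete.cases(x, y))
    descriptive <- n < 6L
    if (length(unique(x)) <= 1L) {
      return(data.frame(parameter = p, n = n, pearson_r = NA_real_,
                        spearman_rho = NA_real_, pearson_p = NA_real_,
                        spearman_p = NA_real_, descriptive_only = descriptive,
                        constant = TRUE, stringsAsFactors = FALSE))
    }
    pr <- stats::cor(x, y, method = "pearson")
    sp <- stats::cor(x, y, method = "spearman")
    pp <- sp_p <- NA_real_
    if (!descriptive) {
      pp <- stats::cor.test(x, y, method = "pearson")$p.value
      sp_p <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman")$p.value)
    }
    data.frame(parameter = p, n = n, pearson_r = pr, spearman_rho = sp,
               pearson_p = pp, spearman_p = sp_p,
               descriptive_only = descriptive, constant = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
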