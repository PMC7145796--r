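brightness_fixture <- function() {
  rec <- data.frame(
    strain = rep(c("v1", "v2", "v3"), each = 3),
    fp = "gfp", strategy = rep(c("IDT", "OPT Entire", "ATGme"), each = 3),
    replicate = rep(1:3, 3), channel = "green",
    raw_mean = c(300, 320, 340,   150, 160, 170,   90, 95, 100),
    stringsAsFactors = FALSE
  )
  wt <- data.frame(channel = "green", raw_mean = c(90, 100, 110),
                   stringsAsFactors = FALSE)
  list(rec = rec, wt = wt)
}

test_that("autofluorescence correction, SEM and normalization are exact", {
  fx <- brightness_fixture()
  s <- correct_and_summarize(fx$rec, fx$wt)
  v1 <- s[s$strain == "v1", ]
  expect_equal(v1$corrected_mean, 220)           # {300,320,340} - 100
  expect_equal(v1$sem, 20 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(v1$sem, 2), 11.55)
  expect_true(v1$brightest)
  expect_equal(v1$normalized, 1)
  v3 <- s[s$strain == "v3", ]
  expect_true(v3$negative_corrected)             # mean 95 < WT 100
  expect_lt(v3$normalized, 0)
  expect_equal(sum(s$brightest), 1L)             # exactly one per fp group
})

test_that("correction + normalization is scale-invariant", {
  fx <- brightness_fixture()
  s1 <- correct_and_summarize(fx$rec, fx$wt)
  fx$rec$raw_mean <- fx$rec$raw_mean * 7.3
  fx$wt$raw_mean <- fx$wt$raw_mean * 7.3
  s2 <- correct_and_summarize(fx$rec, fx$wt)
  expect_equal(s1$normalized, s2$normalized)
  expect_equal(s2$corrected_mean, s1$corrected_mean * 7.3)
})

test_that("missing wild-type channels and degenerate groups error", {
  fx <- brightness_fixture()
  fx$rec$channel[1:3] <- "red"
  expect_error(correct_and_summarize(fx$rec, fx$wt), "channel")
  fx2 <- brightness_fixture()
  fx2$rec$raw_mean <- 50                         # all dimmer than WT
  expect_error(correct_and_summarize(fx2$rec, fx2$wt), "brightest")
  expect_error(compare_variants(list(a = c(1, 1), b = c(2, 2), c = c(3, 3))),
               "degenerate")
})

test_that("identical groups give t = 0, p = 1; order flips the sign only", {
  r <- compare_variants(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_identical(r$test, "t_test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  x <- list(a = c(1.0, 1.2, 1.1), b = c(2.0, 2.1, 2.2))
  r1 <- compare_variants(x)
  r2 <- compare_variants(rev(x))
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("ANOVA + Tukey detects a shifted group and enumerates all pairs", {
  set.seed(21)
  groups <- lapply(1:5, function(i) rnorm(3, mean = 0, sd = 1))
  names(groups) <- paste0("v", 1:5)
  groups$v5 <- groups$v5 + 10                 # 10 within-sd units
  r <- compare_variants(groups)
  expect_identical(r$test, "anova_tukey")
  expect_lt(r$anova$p, 1e-3)
  expect_equal(nrow(r$tukey), 10L)            # k(k-1)/2, k = 5
  expect_identical(r$brightest, "v5")
  expect_equal(sum(r$tukey$vs_brightest), 4L)
  vsb <- r$tukey[r$tukey$vs_brightest, ]
  expect_true(all(vsb$p_adj < 0.01))
  expect_true(all(vsb$stars %in% c("**", "***", "****")))
})

test_that("star convention matches the panel annotations", {
  expect_identical(significance_stars(c(5e-5, 5e-4, 5e-3, 0.03, 0.2)),
                   c("****", "***", "**", "*", "ns"))
})

test_that("associations report coefficients, small-n flagging and constants", {
  summaries <- data.frame(strain = paste0("v", 1:5),
                          normalized = c(1.0, 0.8, 0.6, 0.4, 0.2))
  reports <- data.frame(variant = paste0("v", 1:5),
                        cai = c(0.9, 0.8, 0.7, 0.6, 0.5),
                        gc_percent = 42,
                        rare_run_count = c(0, 1, 2, 3, 4),
                        mfe_full = -c(100, 110, 120, 130, 140),
                        mfe_5prime = -c(50, 55, 60, 65, 70))
  a <- associate_parameters(summaries, reports)
  # perfectly monotone increasing with cai
  expect_equal(a$spearman_rho[a$parameter == "cai"], 1)
  # monotone decreasing with rare runs
  expect_equal(a$spearman_rho[a$parameter == "rare_run_count"], -1)
  # n = 5 -> descriptive only, no p-values
  expect_true(all(a$descriptive_only))
  expect_true(all(is.na(a$pearson_p)))
  # constant parameter flagged, coefficients omitted
  gc <- a[a$parameter == "gc_percent", ]
  expect_true(gc$constant)
  expect_true(is.na(gc$pearson_r))
  expect_error(associate_parameters(summaries[1:2, ], reports), "at least 3")
})

test_that("with n >= 6 p-values are emitted", {
  summaries <- data.frame(strain = paste0("v", 1:8),
                          normalized = seq(1, 0.3, length.out = 8))
  reports <- data.frame(variant = paste0("v", 1:8),
                        cai = seq(0.9, 0.2, length.out = 8) +
                          c(0.01, -0.01, 0.02, 0, 0.01, -0.02, 0, 0.01),
                        gc_percent = rnorm(8, 45),
                        rare_run_count = 8:1,
                        mfe_full = rnorm(8, -100),
                        mfe_5prime = rnorm(8, -50))
  a <- associate_parameters(summaries, reports)
  expect_false(any(a$descriptive_only))
  expect_true(all(is.finite(a$pearson_p)))
})
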