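small_battery_config <- function() {
  battery_config(
    rmea = list(window_s = 4, lag_max_s = 1, increment_s = 2),
    susy = list(segment_s = 4, lag_max_s = 1),
    suco = list(slope_window_s = 1, slope_increment_s = 0.4, segment_s = 4),
    pp = list(b = 50, tau_max = 25, alpha = 0.001, r2_cutoff = 0.25),
    mi = list(jackknife_blocks = 10, grid_size = 51),
    crqa = crqa_params(window_frames = 250, window_overlap = 125,
                       lag_band = 25))
}

test_that("measure battery fills all 21 columns and degrades gracefully", {
  dyads <- list(noise_dyad(L = 600, seed = 1), noise_dyad(L = 600, seed = 2))
  tab <- measure_battery(dyads, small_battery_config())
  expect_equal(nrow(tab), 2)
  expect_true(all(MEASURE_COLUMNS %in% names(tab)))
  expect_length(setdiff(names(tab), "dyad_id"), 21)

  # a dyad shorter than the CRQA window: wincrqa_* missing, others present
  short <- noise_dyad(L = 200, seed = 3)
  tab2 <- measure_battery(list(short), small_battery_config())
  expect_true(all(is.na(tab2[, c("wincrqa_rr", "wincrqa_det",
                                 "wincrqa_entr")])))
  expect_false(anyNA(tab2[, c("cc_raw", "rmea_wcc", "susy_es_abs")]))
  expect_gt(length(attr(tab2, "failures")), 0)

  # determinism: identical rerun
  tab3 <- measure_battery(dyads, small_battery_config())
  expect_identical(tab, tab3)
})

test_that("correlation matrix mixes Pearson and Spearman triangles correctly", {
  set.seed(11)
  toy <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  cm <- correlation_matrix(toy, measures = c("a", "b", "c"))
  for (i in 1:3) expect_equal(cm$values[i, i], 1)
  for (i in 2:3) for (j in seq_len(i - 1)) {
    expect_equal(cm$values[i, j], bf_pearson(toy[[i]], toy[[j]]),
                 tolerance = 1e-12)
    expect_equal(cm$values[j, i], bf_spearman(toy[[i]], toy[[j]]),
                 tolerance = 1e-12)
  }
  # constant column -> missing cells
  toy$d <- 5
  cm2 <- correlation_matrix(toy, measures = c("a", "d"))
  expect_true(is.na(cm2$values[2, 1]))
})

test_that("parallel analysis recovers planted factor counts", {
  one <- planted_factor_data(n = 200, k = 1, p_per = 6, load = 0.8, seed = 1)
  expect_equal(as.integer(parallel_analysis(one, measures = names(one),
                                            n_boot = 50, seed = 2)), 1L)
  two <- planted_factor_data(n = 200, k = 2, p_per = 4, load = 0.8, seed = 3)
  expect_equal(as.integer(parallel_analysis(two, measures = names(two),
                                            n_boot = 50, seed = 4)), 2L)
  set.seed(5)
  noise <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  expect_lte(as.integer(parallel_analysis(noise, measures = names(noise),
                                          n_boot = 50, seed = 6)), 1L)
  expect_error(parallel_analysis(noise[1:5, ], measures = names(noise)),
               "10 complete rows")
})

test_that("ML factor analysis with oblimin recovers planted loadings", {
  dat <- planted_factor_data(n = 200, k = 2, p_per = 4, load = 0.8, seed = 7)
  fs <- efa_ml(dat, n_factors = 2, measures = names(dat))
  L <- fs$loadings
  # align columns/signs to the planted pattern
  truth <- cbind(c(rep(0.8, 4), rep(0, 4)), c(rep(0, 4), rep(0.8, 4)))
  best <- Inf
  for (perm in list(1:2, 2:1)) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
    Lp <- L[, perm] %*% diag(c(s1, s2))
    best <- min(best, max(abs(Lp - truth)))
  }
  expect_lt(best, 0.1)
  # orthogonal generating factors: small inter-factor correlation
  expect_lt(abs(fs$factor_correlation[1, 2]), 0.15)
  expect_lt(fs$rmsea, 0.08)
  expect_gt(fs$tli, 0.9)
  expect_lt(fs$rmsr, 0.08)

  # saturated single-factor model on 3 indicators: RMSEA 0
  dat3 <- planted_factor_data(n = 150, k = 1, p_per = 3, load = 0.7, seed = 8)
  fs3 <- efa_ml(dat3, n_factors = 1, measures = names(dat3))
  expect_equal(fs3$rmsea, 0)
})

test_that("group comparison matches rank-test and Hedges-g formulas", {
  tab <- data.frame(group = rep(c("control", "patient"), each = 4),
                    m = c(1.1, 2.0, 1.4, 1.7, 2.2, 2.9, 2.4, 3.1))
  gc <- group_comparison(tab, measures = "m")
  expect_equal(gc$p_kw, kruskal.test(tab$m, factor(tab$group))$p.value)
  n1 <- 4; n2 <- 4
  sp <- sqrt(((n1 - 1) * var(tab$m[1:4]) + (n2 - 1) * var(tab$m[5:8])) /
               (n1 + n2 - 2))
  g_exp <- (mean(tab$m[5:8]) - mean(tab$m[1:4])) / sp * (1 - 3 / (4 * 8 - 9))
  expect_equal(gc$hedges_g, g_exp, tolerance = 1e-12)

  # identical groups: g = 0, p near 1
  tab0 <- data.frame(group = rep(c("control", "patient"), each = 4),
                     m = rep(c(1, 2, 3, 4), 2))
  gc0 <- group_comparison(tab0, measures = "m")
  expect_equal(gc0$hedges_g, 0)
  expect_gt(gc0$p_kw, 0.9)

  # exact 1-pooled-SD shift: g equals the small-sample correction factor
  x <- rnorm(500); x <- (x - mean(x)) / sd(x)
  tabs <- data.frame(group = rep(c("control", "patient"), each = 500),
                     m = c(x, x + 1))
  gcs <- group_comparison(tabs, measures = "m")
  expect_equal(gcs$hedges_g, 1 - 3 / (4 * 1000 - 9), tolerance = 1e-12)
})

test_that("symptom correlations mirror cor.test and flag degenerate input", {
  set.seed(13)
  tab <- data.frame(phq9 = sample(0:27, 20, TRUE),
                    gad7 = sample(0:21, 20, TRUE),
                    m1 = rnorm(20), m2 = rnorm(20))
  sc <- symptom_correlations(tab, measures = c("m1", "m2"))
  expect_equal(nrow(sc), 4)
  row <- sc[sc$measure == "m1" & sc$symptom == "phq9", ]
  ct <- cor.test(tab$m1, tab$phq9)
  expect_equal(row$r_pearson, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(row$p_pearson, ct$p.value, tolerance = 1e-12)

  tab$phq9 <- 7L
  expect_warning(sc2 <- symptom_correlations(tab, measures = "m1"),
                 "constant")
  expect_true(is.na(sc2$r_pearson[sc2$symptom == "phq9"]))
})

test_that("symptom slope direction is recovered across simulated cohorts", {
  hits <- 0
  for (r in 1:10) {
    set.seed(2000 + r)
    coupling <- rnorm(30, 1, 0.4)
    meas <- coupling + rnorm(30, 0, 0.3)       # a measure tracking coupling
    phq9 <- pmin(pmax(round(20 - 8 * coupling + rnorm(30, 0, 2)), 0), 27)
    tab <- data.frame(phq9 = phq9, gad7 = phq9, m = meas)
    sc <- symptom_correlations(tab, measures = "m")
    if (sc$r_pearson[sc$symptom == "phq9"] < 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
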