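make_rsq <- function(values, lags, mode = "WCLC", b = 20) {
  structure(list(values = values, row_starts = seq_len(nrow(values)),
                 lags = lags, mode = mode,
                 params = list(b = b, tau_max = max(abs(lags)), alpha = NULL,
                               L = nrow(values) + b - 1, fps = 25)),
            class = "rsq_matrix")
}

test_that("R-square matrices match brute-force regression on small dyads", {
  d <- noise_dyad(L = 400, seed = 41)
  for (alpha in list(NULL, 0.05)) {
    mc <- wclc_rsq_matrix(d, b = 30, tau_max = 10, alpha = alpha)
    expect_equal(mc$values, bf_wclc_rsq(d$A, d$B, 30, 10, alpha),
                 ignore_attr = TRUE, tolerance = 1e-10)
    mr <- wclr_rsq_matrix(d, b = 30, tau_max = 10, alpha = alpha)
    expect_equal(mr$values, bf_wclr_rsq(d$A, d$B, 30, 10, alpha),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  expect_true(all(mc$values >= 0 & mc$values <= 1, na.rm = TRUE))
  expect_error(wclc_rsq_matrix(noise_dyad(L = 30, seed = 1), b = 25,
                               tau_max = 10), "short")
})

test_that("noiseless lagged copies give unit R2 at the injected lag", {
  d <- copy_dyad(L = 1200, start = 300, end = 800, lag = 50, seed = 43)
  m <- wclc_rsq_matrix(d, b = 100, tau_max = 60, alpha = NULL)
  col <- match(50, m$lags)
  rows <- 300:(800 - 100)   # windows fully inside the coupled stretch
  vals <- m$values[rows, col]
  expect_true(all(vals[!is.na(vals)] > 0.999))

  # WCLR: B's window adds full incremental explanation where A's
  # autocorrelation does not already explain it
  mr <- wclr_rsq_matrix(d, b = 100, tau_max = 60, alpha = NULL)
  expect_true(all(mr$values >= 0 & mr$values <= 1, na.rm = TRUE))
  expect_equal(unname(mr$values[, match(0, mr$lags)][1]), 0)  # saturated at lag 0
})

test_that("WCLR discounts autocorrelation relative to WCLC on AR(1) members", {
  diffs <- vapply(1:20, function(i) {
    set.seed(500 + i)
    a <- as.numeric(arima.sim(list(ar = 0.9), 260)) + 10
    b <- as.numeric(arima.sim(list(ar = 0.9), 260)) + 10
    d <- dyad_ts(a, b)
    mc <- wclc_rsq_matrix(d, b = 40, tau_max = 10, alpha = NULL)
    mr <- wclr_rsq_matrix(d, b = 40, tau_max = 10, alpha = NULL)
    keep <- !is.na(mc$values) & !is.na(mr$values) & rep(mc$lags != 0,
                                                        each = nrow(mc$values))
    mean(mc$values[keep]) - mean(mr$values[keep])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("peak picking resolves the toy conflict exactly as specified", {
  v <- matrix(0.05, 6, 5)
  lags <- -2:2
  # same-lag maximum run at lag +1, rows 2-4
  v[2, 4] <- 0.4; v[3, 4] <- 0.5; v[4, 4] <- 0.45
  # conflicting single row-3 maximum at another lag, weaker
  v[3, 1] <- 0.3
  losi <- peak_picking(make_rsq(v, lags), r2_cutoff = 0.25)
  expect_equal(nrow(losi$intervals), 1)
  expect_equal(losi$intervals$row_start, 2)
  expect_equal(losi$intervals$row_end, 4)
  expect_equal(losi$intervals$lag, 1)
  expect_equal(losi$intervals$mean_strength, 0.45)

  # all cells below cutoff -> empty LOSI
  expect_equal(nrow(peak_picking(make_rsq(matrix(0.1, 4, 5), lags))$intervals),
               0)
})

test_that("peak picking equals the exhaustive-scan oracle on random matrices", {
  for (i in 1:5) {
    set.seed(600 + i)
    v <- matrix(round(runif(40 * 11), 2), 40, 11)   # rounded values force plateaus
    v[sample(length(v), 30)] <- NA
    lags <- -5:5
    got <- peak_picking(make_rsq(v, lags), r2_cutoff = 0.25)$intervals
    want <- bf_peak_picking(v, lags, cutoff = 0.25)
    got <- got[order(got$lag, got$row_start), ]; rownames(got) <- NULL
    want <- want[order(want$lag, want$row_start), ]; rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("selection is idempotent under zeroing of non-maximum cells", {
  set.seed(77)
  v <- matrix(runif(60 * 9, 0, 0.9), 60, 9)
  lags <- -4:4
  losi1 <- peak_picking(make_rsq(v, lags), r2_cutoff = 0.25)
  # zero all cells that are not per-row local maxima, then re-run
  v2 <- matrix(0, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      lok <- j == 1 || v[i, j - 1] < v[i, j]
      rok <- j == ncol(v) || v[i, j + 1] < v[i, j]
      if (lok && rok) v2[i, j] <- v[i, j]
    }
  }
  losi2 <- peak_picking(make_rsq(v2, lags), r2_cutoff = 0.25)
  expect_equal(losi1$intervals, losi2$intervals)
})

test_that("synchrony frequency and mean strength follow their conventions", {
  empty <- peak_picking(make_rsq(matrix(0.01, 10, 3), -1:1))
  expect_equal(sync_frequency(empty), 0)
  expect_warning(expect_true(is.na(sync_mean_r2(empty,
                                                make_rsq(matrix(0.01, 10, 3),
                                                         -1:1)))),
                 "empty")

  v <- matrix(0, 400, 3)
  v[101:220, 3] <- 0.5       # 120 covered rows at lag +1
  m <- make_rsq(v, -1:1)
  losi <- peak_picking(m, r2_cutoff = 0.25)
  expect_equal(sum(losi$intervals$row_end - losi$intervals$row_start + 1), 120)
  expect_equal(sync_frequency(losi), 0.3)
  expect_equal(sync_mean_r2(losi, m), 0.5)

  full <- matrix(0, 10, 3); full[, 2] <- 0.6
  lf <- peak_picking(make_rsq(full, -1:1))
  expect_equal(sync_frequency(lf), 1)

  # frame convention covers row_start .. row_end + b - 1
  expect_equal(sync_frequency(losi, convention = "frames"),
               (220 + 20 - 1 - 101 + 1) / (400 + 20 - 1))
})

test_that("injected intervals are recovered at the exact lag", {
  d <- noise_copy_dyad(L = 2000, start = 600, end = 1200, lag = 30, seed = 47)
  truth <- 600:(1200 - 125)
  for (mat_fun in list(wclc_rsq_matrix, wclr_rsq_matrix)) {
    m <- mat_fun(d, b = 125, tau_max = 60)
    losi <- peak_picking(m, r2_cutoff = 0.25)
    best <- losi$intervals[which.max(losi$intervals$mean_strength), ]
    expect_equal(best$lag, 30)
    got <- best$row_start:best$row_end
    jac <- length(intersect(truth, got)) / length(union(truth, got))
    expect_gte(jac, 0.5)
  }
})
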