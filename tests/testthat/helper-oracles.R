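# Brute-force reference implementations, written independently of the package
# internals (double loops, lm(), sort-and-pick-middle), used to pin down the
# windowed and aggregated quantities on small instances.

bf_motion_energy <- function(stack, roi, threshold = 12) {
  d <- dim(stack$frames)
  counts <- numeric(d[3] - 1)
  for (t in seq_len(d[3] - 1)) {
    cnt <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        if (roi$mask[i, j] &&
            abs(stack$frames[i, j, t + 1] - stack$frames[i, j, t]) >= threshold) {
          cnt <- cnt + 1
        }
      }
    }
    counts[t] <- cnt
  }
  counts
}

bf_moving_median <- function(x, bw) {
  h <- (bw - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(i - 1, n - i, h)   # symmetric shrink at the ends
    w <- sort(x[(i - k):(i + k)])
    w[k + 1]                     # middle of 2k+1 sorted values
  }, numeric(1))
}

bf_fisher_z <- function(r, eps = 1e-7) atanh(min(max(r, -(1 - eps)), 1 - eps))

# rMEA-style matrix: Fisher-Z of |cor| for every window start and lag
bf_wclc_matrix <- function(A, B, b, tau_max, inc) {
  L <- length(A)
  starts <- seq(1, L - b + 1, by = inc)
  lags <- seq(-tau_max, tau_max)
  out <- matrix(NA_real_, length(starts), length(lags))
  for (ti in seq_along(starts)) {
    t <- starts[ti]
    for (li in seq_along(lags)) {
      lo <- t + lags[li]; hi <- lo + b - 1
      if (lo < 1 || hi > L) next
      aw <- A[t:(t + b - 1)]; bw <- B[lo:hi]
      if (sd(aw) == 0 || sd(bw) == 0) next
      out[ti, li] <- bf_fisher_z(abs(cor(aw, bw)))
    }
  }
  out
}

bf_wclc_rsq <- function(A, B, b, tau_max, alpha = NULL) {
  L <- length(A)
  lags <- seq(-tau_max, tau_max)
  out <- matrix(NA_real_, L - b + 1, length(lags))
  crit <- if (is.null(alpha)) -Inf else qf(1 - alpha, 1, b - 2)
  for (t in seq_len(L - b + 1)) {
    for (li in seq_along(lags)) {
      lo <- t + lags[li]; hi <- lo + b - 1
      if (lo < 1 || hi > L) next
      aw <- A[t:(t + b - 1)]; bw <- B[lo:hi]
      if (sd(aw) == 0 || sd(bw) == 0) next
      r2 <- cor(aw, bw)^2
      f <- r2 * (b - 2) / (1 - r2)
      out[t, li] <- if (f < crit) 0 else r2
    }
  }
  out
}

bf_wclr_rsq <- function(A, B, b, tau_max, alpha = NULL) {
  L <- length(A)
  lags <- seq(-tau_max, tau_max)
  out <- matrix(NA_real_, L - b + 1, length(lags))
  crit <- if (is.null(alpha)) -Inf else qf(1 - alpha, 1, b - 3)
  for (t in seq_len(L - b + 1)) {
    for (li in seq_along(lags)) {
      tau <- lags[li]
      # positive lag: B follows A (reference for the regression is B)
      if (tau >= 0) { ref <- B; oth <- A } else { ref <- A; oth <- B }
      at <- abs(tau)
      if (t + at + b - 1 > L) next
      y <- ref[(t + at):(t + at + b - 1)]
      x1 <- ref[t:(t + b - 1)]
      x2 <- oth[t:(t + b - 1)]
      if (sd(y) == 0 || sd(x1) == 0 || sd(x2) == 0) next
      if (tau == 0) { out[t, li] <- 0; next }
      r2m1 <- summary(lm(y ~ x1))$r.squared
      r2m2 <- summary(lm(y ~ x1 + x2))$r.squared
      d <- max(0, r2m2 - r2m1)
      f <- (r2m2 - r2m1) * (b - 3) / (1 - r2m2)
      out[t, li] <- if (f < crit) 0 else d
    }
  }
  out
}

# peak picking by exhaustive scan of the documented rule
bf_peak_picking <- function(vals, lags, cutoff = 0.25) {
  nt <- nrow(vals); nl <- ncol(vals)
  maxima <- matrix(FALSE, nt, nl)
  for (i in seq_len(nt)) {
    for (j in seq_len(nl)) {
      v <- vals[i, j]
      if (is.na(v)) next
      # extend the plateau of equal values around j
      j0 <- j; while (j0 > 1 && !is.na(vals[i, j0 - 1]) && vals[i, j0 - 1] == v) j0 <- j0 - 1
      j1 <- j; while (j1 < nl && !is.na(vals[i, j1 + 1]) && vals[i, j1 + 1] == v) j1 <- j1 + 1
      left_ok <- j0 == 1 || is.na(vals[i, j0 - 1]) || vals[i, j0 - 1] < v
      right_ok <- j1 == nl || is.na(vals[i, j1 + 1]) || vals[i, j1 + 1] < v
      if (!(left_ok && right_ok)) next
      members <- j0:j1
      rep_col <- members[which.min(abs(lags[members]))]
      if (j == rep_col) maxima[i, j] <- TRUE
    }
  }
  iv <- NULL
  for (j in seq_len(nl)) {
    i <- 1
    while (i <= nt) {
      if (maxima[i, j]) {
        i2 <- i
        while (i2 < nt && maxima[i2 + 1, j]) i2 <- i2 + 1
        iv <- rbind(iv, data.frame(row_start = i, row_end = i2, lag = lags[j],
                                   mean_strength = mean(vals[i:i2, j])))
        i <- i2 + 1
      } else i <- i + 1
    }
  }
  if (is.null(iv)) return(data.frame(row_start = integer(0), row_end = integer(0),
                                     lag = integer(0), mean_strength = numeric(0)))
  ord <- order(-iv$mean_strength, iv$row_start, abs(iv$lag))
  occupied <- logical(nt)
  keep <- logical(nrow(iv))
  for (k in ord) {
    span <- iv$row_start[k]:iv$row_end[k]
    if (!any(occupied[span])) { keep[k] <- TRUE; occupied[span] <- TRUE }
  }
  iv <- iv[keep & iv$mean_strength > cutoff, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# SUSY scored with plain cor(); returns segment and surrogate-pair scores
bf_susy <- function(A, B, seg, lag_max) {
  L <- length(A)
  n <- L %/% seg
  starts <- (seq_len(n) - 1) * seg + 1
  score <- function(i, j) {
    a <- A[starts[i]:(starts[i] + seg - 1)]
    zs <- sapply(seq(-lag_max, lag_max), function(l) {
      lo <- starts[j] + l; hi <- lo + seg - 1
      if (lo < 1 || hi > L) return(NA_real_)
      bw <- B[lo:hi]
      if (sd(a) == 0 || sd(bw) == 0) return(NA_real_)
      bf_fisher_z(cor(a, bw))
    })
    c(abs = mean(abs(zs), na.rm = TRUE), noabs = mean(zs, na.rm = TRUE))
  }
  real <- t(sapply(seq_len(n), function(i) score(i, i)))
  surr <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) surr <- rbind(surr, score(i, j))
  }
  list(z_abs = mean(real[, "abs"]), z_noabs = mean(real[, "noabs"]),
       segment_abs = real[, "abs"], surr_abs = surr[, "abs"],
       surr_noabs = surr[, "noabs"])
}

# SUCO slope sequences via lm(), segment correlations and concordance index
bf_suco_slopes <- function(x, seg, w, inc, n) {
  lapply(seq_len(n), function(i) {
    s0 <- (i - 1) * seg
    ks <- seq(1, seg - w + 1, by = inc)
    sapply(ks, function(k) {
      win <- x[(s0 + k):(s0 + k + w - 1)]
      unname(coef(lm(win ~ seq_along(win)))[2])
    })
  })
}

bf_concordance <- function(r) {
  pos <- sum(r[r > 0]); neg <- sum(r[r < 0])
  if (pos <= 0 || neg >= 0) return(NA_real_)
  log(pos / abs(neg))
}

# CRQA of one window pair: full double loop + diagonal run-length scan
bf_crqa_window <- function(embA, embB, eps, band, minl = 2) {
  nA <- nrow(embA); nB <- nrow(embB)
  R <- matrix(NA, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    if (abs(i - j) <= band) {
      R[i, j] <- sqrt(sum((embA[i, ] - embB[j, ])^2)) < eps
    }
  }
  n_cells <- sum(!is.na(R)); n_rec <- sum(R, na.rm = TRUE)
  rr <- 100 * n_rec / n_cells
  lens <- integer(0)
  for (d in seq(-(nA - 1), nB - 1)) {
    if (abs(d) > band) next
    cells <- c()
    for (i in seq_len(nA)) {
      j <- i + d
      if (j >= 1 && j <= nB) cells <- c(cells, R[i, j])
    }
    if (length(cells)) {
      r <- rle(cells)
      lens <- c(lens, r$lengths[r$values])
    }
  }
  if (n_rec == 0) return(list(rr = 0, det = NA_real_, entr = 0))
  keep <- lens[lens >= minl]
  det <- 100 * sum(keep) / n_rec
  entr <- 0
  if (length(keep)) {
    p <- as.numeric(table(keep)); p <- p / sum(p)
    if (length(p) > 1) entr <- -sum(p * log(p)) / log(length(p))
  }
  list(rr = rr, det = det, entr = entr)
}

# Pearson and Spearman by textbook formulas
bf_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
}
bf_spearman <- function(x, y) bf_pearson(rank(x), rank(y))
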