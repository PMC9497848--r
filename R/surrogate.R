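#' Surrogate synchrony (SUSY)
#'
#' Computes the cross-correlation function segment-wise: the series is cut
#' into non-overlapping segments of `segment_s` seconds, and within each
#' segment the two members are correlated at every integer-frame lag in
#' `[-lag_max_s, +lag_max_s]` (the lagged partner window may read into
#' neighboring frames when available; lags running outside the series are
#' skipped). Each correlation is Fisher-Z transformed; a segment's synchrony
#' is the mean over lags of the absolute (Zabs) or signed (Znoabs) values,
#' and the dyad's synchrony is the mean of segment means. Surrogates re-pair
#' A's segment i with B's segment j for all ordered pairs i != j — the
#' exhaustive segment-shuffle ensemble of size n(n-1) — and the effect sizes
#' standardize the real values against them:
#' `ES_abs = (Zabs - mean(Zabs_surr)) / sd(Zabs_surr)`, analogously for
#' noabs.
#'
#' @param dyad a `dyad_ts`.
#' @param segment_s segment size in seconds (default 30).
#' @param lag_max_s maximum lag in seconds (default 5).
#' @param exhaustive_surrogates use all n(n-1) ordered segment pairs
#'   (default); if `FALSE`, sample `n_surrogates` pairs.
#' @param n_surrogates number of sampled surrogate pairs when not exhaustive.
#' @param seed seed for surrogate sampling (unused when exhaustive).
#' @return Object of class `susy_result`: `z_abs`, `z_noabs`, `es_abs`,
#'   `es_noabs`, `n_segments`, `n_surrogates`, plus the per-segment and
#'   per-surrogate scores.
#' @export
susy <- function(dyad, segment_s = 30, lag_max_s = 5,
                 exhaustive_surrogates = TRUE, n_surrogates = 100, seed = 1) {
  stopifnot(inherits(dyad, "dyad_ts"))
  seg <- round(segment_s * dyad$fps)
  lag_max <- round(lag_max_s * dyad$fps)
  L <- length(dyad$A)
  n <- L %/% seg
  if (n < 2) stop("need at least 2 full segments")
  sc <- segment_scores(dyad$A, dyad$B, seg, lag_max, n, L)
  real_abs <- sc$abs[cbind(seq_len(n), seq_len(n))]
  real_noabs <- sc$noabs[cbind(seq_len(n), seq_len(n))]
  if (sum(!is.na(real_abs)) < 2) stop("fewer than 2 valid segments")
  pairs <- which(row(sc$abs) != col(sc$abs))
  if (!exhaustive_surrogates) {
    withr_seed(seed)
    pairs <- sample(pairs, min(n_surrogates, length(pairs)))
  }
  surr_abs <- sc$abs[pairs]; surr_noabs <- sc$noabs[pairs]
  z_abs <- mean(real_abs, na.rm = TRUE)
  z_noabs <- mean(real_noabs, na.rm = TRUE)
  structure(list(
    z_abs = z_abs, z_noabs = z_noabs,
    es_abs = (z_abs - mean(surr_abs, na.rm = TRUE)) /
      stats::sd(surr_abs[!is.na(surr_abs)]),
    es_noabs = (z_noabs - mean(surr_noabs, na.rm = TRUE)) /
      stats::sd(surr_noabs[!is.na(surr_noabs)]),
    n_segments = n, n_surrogates = length(pairs),
    segment_abs = real_abs, segment_noabs = real_noabs,
    surrogate_abs = surr_abs, surrogate_noabs = surr_noabs),
    class = "susy_result")
}

#' @export
print.susy_result <- function(x, ...) {
  cat(sprintf("<susy_result> n = %d segments, %d surrogates\n  Zabs %.4f (ES %.2f)  Znoabs %.4f (ES %.2f)\n",
              x$n_segments, x$n_surrogates, x$z_abs, x$es_abs,
              x$z_noabs, x$es_noabs))
  invisible(x)
}

# score every ordered (A-segment i, B-segment j) pair: mean over lags of
# |Z| and of signed Z of the lagged segment correlations
segment_scores <- function(A, B, seg, lag_max, n, L) {
  starts <- (seq_len(n) - 1) * seg + 1
  lags <- seq(-lag_max, lag_max)
  # centre globally (correlations unchanged, one-pass sums stay conditioned)
  A <- A - mean(A); B <- B - mean(B)
  cB <- c(0, cumsum(B)); cB2 <- c(0, cumsum(B * B))
  sabs <- snoabs <- matrix(NA_real_, n, n)
  aseg <- lapply(starts, function(s) A[s:(s + seg - 1)])
  a_mu <- vapply(aseg, mean, numeric(1))
  a_ss <- vapply(seq_len(n), function(i) sum((aseg[[i]] - a_mu[i])^2),
                 numeric(1))
  for (i in seq_len(n)) {
    a <- aseg[[i]]
    if (a_ss[i] <= 0) next
    for (j in seq_len(n)) {
      zs <- rep(NA_real_, length(lags))
      for (k in seq_along(lags)) {
        lo <- starts[j] + lags[k]; hi <- lo + seg - 1
        if (lo < 1 || hi > L) next
        sb <- cB[hi + 1] - cB[lo]
        sb2 <- cB2[hi + 1] - cB2[lo]
        vb <- sb2 - sb * sb / seg
        if (vb <= (sb2 + 1e-300) * 1e-12) next
        sxy <- sum(a * B[lo:hi]) - a_mu[i] * sb
        r <- sxy / sqrt(a_ss[i] * vb)
        zs[k] <- as.numeric(fisher_z(min(max(r, -1), 1)))
      }
      if (any(!is.na(zs))) {
        sabs[i, j] <- mean(abs(zs), na.rm = TRUE)
        snoabs[i, j] <- mean(zs, na.rm = TRUE)
      }
    }
  }
  list(abs = sabs, noabs = snoabs)
}

#' Surrogate concordance (SUCO)
#'
#' Local slopes are fit by least squares in overlapping windows of
#' `slope_window_s` seconds stepped by `slope_increment_s`, aligned to the
#' starts of the non-overlapping `segment_s` segments (a slope window must
#' fit inside its segment). Within each segment i, A's slope sequence is
#' Pearson-correlated with B's, giving r_i. The absolute r_i are Fisher-Z
#' transformed and averaged into Z'abs. The concordance index is
#' `CO = ln(sum of positive r_i / |sum of negative r_i|)`, reported missing
#' when all r_i share one sign. Surrogates re-pair segments as in SUSY:
#' ES_abs standardizes Z'abs against all n(n-1) ordered pairs; ES-CO
#' standardizes CO against the n-1 cyclic-shift surrogate dyads (shift d
#' pairs A segment i with B segment 1 + ((i-1+d) mod n)), each of which
#' yields a full concordance index.
#'
#' @param dyad a `dyad_ts`.
#' @param slope_window_s slope window in seconds (default 3).
#' @param slope_increment_s slope window step in seconds (default 1).
#' @param segment_s segment size in seconds (default 30).
#' @return Object of class `suco_result`: `z_abs_prime`, `co`, `es_abs`,
#'   `es_co`, `segment_correlations`, `n_segments`, `co_missing` flag.
#' @export
suco <- function(dyad, slope_window_s = 3, slope_increment_s = 1,
                 segment_s = 30) {
  stopifnot(inherits(dyad, "dyad_ts"))
  fps <- dyad$fps
  seg <- round(segment_s * fps)
  w <- round(slope_window_s * fps)
  inc <- max(1L, round(slope_increment_s * fps))
  L <- length(dyad$A)
  n <- L %/% seg
  if (n < 2) stop("need at least 2 full segments")
  n_win <- (seg - w) %/% inc + 1
  if (n_win < 3) stop("segment too short to hold >= 3 slope windows")
  slopes <- function(x) {
    t(vapply(seq_len(n), function(i) {
      s0 <- (i - 1) * seg
      vapply(seq_len(n_win), function(k) {
        win <- x[(s0 + (k - 1) * inc + 1):(s0 + (k - 1) * inc + w)]
        ols_slope(win)
      }, numeric(1))
    }, numeric(n_win)))
  }
  SA <- slopes(dyad$A); SB <- slopes(dyad$B)  # n x n_win
  # a slope sequence is degenerate when its spread is at rounding level
  # relative to its magnitude (e.g. every window sees the same linear trend)
  nondeg <- function(S) {
    apply(S, 1, stats::sd) > 1e-8 * pmax(apply(abs(S), 1, max), 1e-300)
  }
  rmat <- matrix(NA_real_, n, n)
  ok <- outer(nondeg(SA), nondeg(SB), "&")
  if (any(ok)) {
    cc <- suppressWarnings(stats::cor(t(SA), t(SB)))
    rmat[ok] <- cc[ok]
  }
  r_real <- rmat[cbind(seq_len(n), seq_len(n))]
  valid <- !is.na(r_real)
  if (sum(valid) < 2) stop("fewer than 2 segments with valid slope correlations")
  z_abs_prime <- mean(as.numeric(fisher_z(abs(r_real[valid]))))
  co <- concordance_index(r_real[valid])
  # surrogate ensembles
  pairs <- which(row(rmat) != col(rmat) & !is.na(rmat))
  surr_z <- as.numeric(fisher_z(abs(rmat[pairs])))
  es_abs <- (z_abs_prime - mean(surr_z)) / stats::sd(surr_z)
  co_surr <- vapply(seq_len(n - 1), function(d) {
    idx <- cbind(seq_len(n), 1 + ((seq_len(n) - 1 + d) %% n))
    concordance_index(stats::na.omit(rmat[idx]))
  }, numeric(1))
  co_surr_ok <- co_surr[is.finite(co_surr)]
  es_co <- if (!is.finite(co) || length(co_surr_ok) < 2) NA_real_ else
    (co - mean(co_surr_ok)) / stats::sd(co_surr_ok)
  structure(list(z_abs_prime = z_abs_prime, co = co,
                 es_abs = es_abs, es_co = es_co,
                 segment_correlations = r_real,
                 n_segments = n, co_missing = !is.finite(co),
                 surrogate_z = surr_z, surrogate_co = co_surr),
            class = "suco_result")
}

#' @export
print.suco_result <- function(x, ...) {
  cat(sprintf("<suco_result> n = %d segments\n  Z'abs %.4f (ES %.2f)  CO %s (ES %s)\n",
              x$n_segments, x$z_abs_prime, x$es_abs,
              if (x$co_missing) "missing" else sprintf("%.4f", x$co),
              if (is.na(x$es_co)) "missing" else sprintf("%.2f", x$es_co)))
  invisible(x)
}

# natural log of (sum of positive r) / |sum of negative r|; NA when either
# side is empty
concordance_index <- function(r) {
  pos <- sum(r[r > 0]); neg <- sum(r[r < 0])
  if (pos <= 0 || neg >= 0) return(NA_real_)
  log(pos / abs(neg))
}

# least-squares slope of values on frame index
ols_slope <- function(y) {
  n <- length(y)
  t0 <- seq_len(n) - (n + 1) / 2
  sum(t0 * (y - mean(y))) / sum(t0 * t0)
}
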