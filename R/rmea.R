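#' Windowed cross-lagged correlation matrix (rMEA style)
#'
#' Splits the interaction into windows of `window_s` seconds stepped by
#' `increment_s`, and correlates each reference window of member A with the
#' window of member B starting `tau` frames later, for every lag
#' `tau = -lag_max ... +lag_max` (in frames). Entries are Fisher-Z transforms
#' of absolute correlations, so all finite values are >= 0. Rows where the
#' reference window does not fit are dropped; cells whose lagged window falls
#' outside the series, or whose windows have zero variance, are `NA`.
#'
#' @param dyad a `dyad_ts`.
#' @param window_s window width in seconds (default 60).
#' @param lag_max_s maximum lag in seconds (default 5).
#' @param increment_s step between reference windows in seconds (default 30).
#' @return Object of class `wclc_matrix`: list with `values`
#'   (rows = reference window starts, columns = lags), `row_starts`, `lags`
#'   (frames), and `params`.
#' @export
wclc_matrix <- function(dyad, window_s = 60, lag_max_s = 5, increment_s = 30) {
  stopifnot(inherits(dyad, "dyad_ts"))
  fps <- dyad$fps
  b <- round(window_s * fps)
  tau_max <- round(lag_max_s * fps)
  inc <- max(1L, round(increment_s * fps))
  L <- length(dyad$A)
  if (L < b + tau_max) stop("series too short for window + lag")
  row_starts <- seq(1L, L - b + 1L, by = inc)
  lags <- seq(-tau_max, tau_max)
  vals <- matrix(NA_real_, length(row_starts), length(lags),
                 dimnames = list(NULL, lags))
  for (j in seq_along(lags)) {
    r <- roll_lagged_cor(dyad$A, dyad$B, b, lags[j])
    vals[, j] <- as.numeric(fisher_z(abs(r[row_starts])))
  }
  structure(list(values = vals, row_starts = row_starts, lags = lags,
                 params = list(b = b, tau_max = tau_max, increment = inc,
                               L = L, fps = fps)),
            class = "wclc_matrix")
}

#' @export
print.wclc_matrix <- function(x, ...) {
  cat(sprintf("<wclc_matrix> %d window starts x %d lags (b = %d, tau_max = %d, increment = %d)\n",
              nrow(x$values), ncol(x$values), x$params$b, x$params$tau_max,
              x$params$increment))
  invisible(x)
}

#' Average windowed cross-correlation (lag 0 only)
#'
#' Mean of the lag-0 column of the WCLC matrix over non-missing rows.
#' @param matrix a `wclc_matrix`.
#' @return scalar synchrony value (Fisher-Z units).
#' @export
rmea_wcc <- function(matrix) {
  stopifnot(inherits(matrix, "wclc_matrix"))
  col0 <- matrix$values[, match(0, matrix$lags)]
  if (all(is.na(col0))) stop("no valid lag-0 entries")
  mean(col0, na.rm = TRUE)
}

#' Average windowed cross-lagged correlation (all lags)
#'
#' Grand mean over all non-missing cells of the WCLC matrix.
#' @param matrix a `wclc_matrix`.
#' @return scalar synchrony value (Fisher-Z units).
#' @export
rmea_wclc <- function(matrix) {
  stopifnot(inherits(matrix, "wclc_matrix"))
  v <- matrix$values
  if (all(is.na(v))) stop("no valid entries")
  mean(v, na.rm = TRUE)
}

#' Person-shuffling pseudo-synchrony test
#'
#' For each dyad, re-pairs its member A with the member B of another,
#' randomly drawn dyad (`n_shuffles` times, with replacement over foreign
#' partners), truncates the pair to the shorter length, recomputes the WCLC
#' measure, and standardizes the real value against the surrogate
#' distribution: `z = (real - mean(surrogate)) / sd(surrogate)`.
#'
#' @param cohort list of `dyad_ts` (>= 2 dyads).
#' @param measure `"wclc"` (grand mean, default) or `"wcc"` (lag-0 mean).
#' @param n_shuffles surrogate re-pairings per dyad (default 100).
#' @param seed integer seed controlling the pairings.
#' @param ... passed to [wclc_matrix()] (window, lag, increment).
#' @return data frame with one row per dyad: `real`, `surr_mean`, `surr_sd`,
#'   `z`, `p` (two-sided normal tail), plus attribute `"surrogates"` holding
#'   the per-dyad surrogate value matrix.
#' @export
person_shuffle_test <- function(cohort, measure = c("wclc", "wcc"),
                                n_shuffles = 100, seed = 1, ...) {
  measure <- match.arg(measure)
  n <- length(cohort)
  if (n < 2) stop("need >= 2 dyads (no foreign partners otherwise)")
  score <- function(A, B, fps) {
    m <- wclc_matrix(dyad_ts(A, B, fps = fps), ...)
    if (measure == "wclc") rmea_wclc(m) else rmea_wcc(m)
  }
  withr_seed(seed)
  partner <- matrix(0L, n, n_shuffles)
  for (i in seq_len(n)) {
    partner[i, ] <- sample(setdiff(seq_len(n), i), n_shuffles, replace = TRUE)
  }
  real <- numeric(n)
  surr <- matrix(NA_real_, n, n_shuffles)
  for (i in seq_len(n)) {
    di <- cohort[[i]]
    real[i] <- score(di$A, di$B, di$fps)
    for (s in seq_len(n_shuffles)) {
      dj <- cohort[[partner[i, s]]]
      len <- min(length(di$A), length(dj$B))
      surr[i, s] <- score(di$A[seq_len(len)], dj$B[seq_len(len)], di$fps)
    }
  }
  mu <- rowMeans(surr); sdv <- apply(surr, 1, stats::sd)
  z <- (real - mu) / sdv
  out <- data.frame(dyad = seq_len(n), real = real, surr_mean = mu,
                    surr_sd = sdv, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  attr(out, "surrogates") <- surr
  attr(out, "measure") <- measure
  out
}
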