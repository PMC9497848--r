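#' Windowed cross-lagged correlation R-square matrix (WCLC)
#'
#' For every reference window start `t = 1 ... L - b + 1` (unit increment)
#' and every lag `tau = -tau_max ... +tau_max`, the squared Pearson
#' correlation between A's window at `t` and B's window at `t + tau`.
#' Lagged windows that fall outside the series, and zero-variance windows,
#' give missing cells. When `alpha` is non-NULL (default 0.001), cells whose
#' correlation is not significant by the F test with (1, b - 2) degrees of
#' freedom are set to 0, so the surface holds only significant local
#' associations.
#'
#' @param dyad a `dyad_ts`.
#' @param b window width in frames (default 125, i.e. 5 s at 25 fps).
#' @param tau_max maximum lag in frames (default 125).
#' @param alpha significance level of the per-cell test; `NULL` disables the
#'   filter.
#' @return Object of class `rsq_matrix` (`mode = "WCLC"`): `values`
#'   (rows = window starts at unit increment, columns = lags), `lags`,
#'   `row_starts`, `params`.
#' @export
wclc_rsq_matrix <- function(dyad, b = 125, tau_max = 125, alpha = 0.001) {
  stopifnot(inherits(dyad, "dyad_ts"))
  L <- length(dyad$A)
  if (L < b + tau_max) stop("series too short for window + lag")
  lags <- seq(-tau_max, tau_max)
  nt <- L - b + 1L
  vals <- matrix(NA_real_, nt, length(lags), dimnames = list(NULL, lags))
  crit <- if (is.null(alpha)) NULL else stats::qf(1 - alpha, 1, b - 2)
  for (j in seq_along(lags)) {
    r <- roll_lagged_cor(dyad$A, dyad$B, b, lags[j])
    r2 <- pmin(r * r, 1)
    if (!is.null(crit)) {
      f <- r2 * (b - 2) / pmax(1 - r2, 1e-300)
      r2[!is.na(f) & f < crit] <- 0
    }
    vals[, j] <- r2
  }
  structure(list(values = vals, row_starts = seq_len(nt), lags = lags,
                 mode = "WCLC",
                 params = list(b = b, tau_max = tau_max, alpha = alpha,
                               L = L, fps = dyad$fps)),
            class = "rsq_matrix")
}

#' Windowed cross-lagged regression Delta-R-square matrix (WCLR)
#'
#' Removes the autocorrelation bias of WCLC by a two-model comparison. The
#' lag axis keeps the WCLC semantics (positive `tau`: B follows A). For
#' `tau > 0`, model 1 predicts B's window at `t + tau` from B's window at `t`
#' (autocorrelation only); model 2 adds A's window at `t` as a second
#' predictor. The cell value is `DeltaR2 = R2_M2 - R2_M1`, floored at 0, the
#' share of the follower's window variance explained by the partner beyond
#' the follower's own autocorrelation. For `tau < 0` the member roles are
#' mirrored (A's lagged window regressed on A's and B's windows); at
#' `tau = 0` model 1 is saturated and the cell is 0 by construction. Cells whose incremental F
#' test with (1, b - 3) degrees of freedom is not significant at `alpha` are
#' set to 0; collinear predictor windows give 0.
#'
#' @inheritParams wclc_rsq_matrix
#' @param alpha significance level of the incremental F test (default 0.001).
#' @return Object of class `rsq_matrix` (`mode = "WCLR"`).
#' @export
wclr_rsq_matrix <- function(dyad, b = 125, tau_max = 125, alpha = 0.001) {
  stopifnot(inherits(dyad, "dyad_ts"))
  L <- length(dyad$A)
  if (L < b + tau_max) stop("series too short for window + lag")
  lags <- seq(-tau_max, tau_max)
  nt <- L - b + 1L
  vals <- matrix(NA_real_, nt, length(lags), dimnames = list(NULL, lags))
  crit <- if (is.null(alpha)) NULL else stats::qf(1 - alpha, 1, b - 3)
  r12_AB <- roll_lagged_cor(dyad$A, dyad$B, b, 0L)  # cor(A@t, B@t)
  for (j in seq_along(lags)) {
    tau <- lags[j]
    if (tau == 0) {
      vals[, j] <- ifelse(is.na(r12_AB), NA_real_, 0)
      next
    }
    if (tau > 0) {  # B follows A: B at t+tau explained by B at t (+ A at t)
      ry1 <- roll_lagged_cor(dyad$B, dyad$B, b, tau)
      ry2 <- roll_lagged_cor(dyad$A, dyad$B, b, tau)
      r12 <- r12_AB
    } else {        # mirrored: A at t+|tau| explained by A at t (+ B at t)
      ry1 <- roll_lagged_cor(dyad$A, dyad$A, b, -tau)
      ry2 <- roll_lagged_cor(dyad$B, dyad$A, b, -tau)
      r12 <- r12_AB
    }
    denom <- 1 - r12 * r12
    collinear <- !is.na(denom) & denom < 1e-10
    r2m1 <- ry1 * ry1
    r2m2 <- (ry1 * ry1 + ry2 * ry2 - 2 * ry1 * ry2 * r12) / denom
    r2m2 <- pmin(pmax(r2m2, 0), 1)
    d <- pmax(r2m2 - r2m1, 0)
    if (!is.null(crit)) {
      f <- (r2m2 - r2m1) * (b - 3) / pmax(1 - r2m2, 1e-300)
      d[!is.na(f) & f < crit] <- 0
    }
    d[collinear] <- 0
    vals[, j] <- d
  }
  structure(list(values = vals, row_starts = seq_len(nt), lags = lags,
                 mode = "WCLR",
                 params = list(b = b, tau_max = tau_max, alpha = alpha,
                               L = L, fps = dyad$fps)),
            class = "rsq_matrix")
}

#' @export
print.rsq_matrix <- function(x, ...) {
  cat(sprintf("<rsq_matrix> %s: %d window starts x %d lags (b = %d, tau_max = %d)\n",
              x$mode, nrow(x$values), ncol(x$values), x$params$b,
              x$params$tau_max))
  invisible(x)
}

#' Peak picking: R-square matrix to list of synchronization intervals
#'
#' Detects, for each reference-window row, the local maxima of the (Delta)R2
#' values along the lag axis; chains maxima with equal lag in directly
#' consecutive rows into candidate intervals; resolves row-sharing conflicts
#' by keeping the interval with the largest mean value (the losing interval
#' is discarded entirely); finally drops intervals whose mean does not exceed
#' `r2_cutoff`.
#'
#' Local maximum rule: within a row, maximal runs of equal non-missing values
#' qualify when the values immediately flanking the run are strictly smaller
#' or absent (missing cells and row edges count as absent); a plateau is
#' represented by its member with the smallest |lag| (tie: the negative lag).
#'
#' @param matrix an `rsq_matrix`.
#' @param r2_cutoff minimal mean interval strength (default 0.25).
#' @return Object of class `losi`: data frame `intervals` (`row_start`,
#'   `row_end`, `lag`, `mean_strength`), plus `n_rows`, `b`, `L`.
#' @export
peak_picking <- function(matrix, r2_cutoff = 0.25) {
  stopifnot(inherits(matrix, "rsq_matrix"))
  vals <- matrix$values
  lags <- matrix$lags
  nt <- nrow(vals)
  # per-row local maxima (row index, lag column)
  abs_lag <- abs(lags)
  cols_l <- vector("list", nt)
  for (i in seq_len(nt)) {
    v <- vals[i, ]
    v[is.na(v)] <- -Inf
    r <- rle(v)
    k <- length(r$values)
    if (k == 0) next
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    left_ok <- c(TRUE, r$values[-k] < r$values[-1])
    right_ok <- c(r$values[-k] > r$values[-1], TRUE)
    is_max <- which(left_ok & right_ok & is.finite(r$values))
    if (length(is_max)) {
      cols_l[[i]] <- vapply(is_max, function(m) {
        members <- starts[m]:ends[m]
        members[which.min(abs_lag[members])]
      }, integer(1))
    }
  }
  max_rows <- rep(seq_len(nt), lengths(cols_l))
  max_cols <- unlist(cols_l, use.names = FALSE)
  if (is.null(max_cols)) max_cols <- integer(0)
  intervals <- chain_maxima(max_rows, max_cols, vals, lags)
  intervals <- resolve_conflicts(intervals, nt)
  intervals <- intervals[!is.na(intervals$mean_strength) &
                           intervals$mean_strength > r2_cutoff, , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, n_rows = nt,
                 b = matrix$params$b, L = matrix$params$L,
                 r2_cutoff = r2_cutoff),
            class = "losi")
}

# chain same-lag maxima over consecutive rows into candidate intervals
chain_maxima <- function(rows, cols, vals, lags) {
  out <- data.frame(row_start = integer(0), row_end = integer(0),
                    lag = integer(0), mean_strength = numeric(0))
  if (!length(rows)) return(out)
  ord <- order(cols, rows)
  rows <- rows[ord]; cols <- cols[ord]
  brk <- which(c(TRUE, diff(cols) != 0 | diff(rows) != 1))
  r0 <- rows[brk]
  r1 <- rows[c(brk[-1] - 1L, length(rows))]
  cl <- cols[brk]
  strength <- vapply(seq_along(brk), function(g) {
    mean(vals[r0[g]:r1[g], cl[g]])
  }, numeric(1))
  data.frame(row_start = r0, row_end = r1, lag = lags[cl],
             mean_strength = strength)
}

# greedy selection by descending mean strength; an interval sharing any row
# with an already-selected (stronger) interval is discarded entirely
resolve_conflicts <- function(intervals, nt) {
  if (nrow(intervals) < 2) return(intervals)
  ord <- order(-intervals$mean_strength, intervals$row_start,
               abs(intervals$lag))
  taken <- logical(nt)
  keep <- logical(nrow(intervals))
  for (i in ord) {
    span <- intervals$row_start[i]:intervals$row_end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  intervals[keep, , drop = FALSE]
}

#' @export
print.losi <- function(x, ...) {
  cat(sprintf("<losi> %d synchronization interval(s) over %d window rows (cutoff %g)\n",
              nrow(x$intervals), x$n_rows, x$r2_cutoff))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Frequency of movement synchrony
#'
#' Proportion of the interaction covered by synchronization intervals. The
#' default convention counts covered reference-window start rows relative to
#' all rows of the matrix; `convention = "frames"` instead counts frames
#' covered by the intervals' windows (`row_start` to `row_end + b - 1`)
#' relative to the series length.
#'
#' @param losi a `losi`.
#' @param convention `"rows"` (default) or `"frames"`.
#' @return F in \[0, 1\].
#' @export
sync_frequency <- function(losi, convention = c("rows", "frames")) {
  stopifnot(inherits(losi, "losi"))
  convention <- match.arg(convention)
  iv <- losi$intervals
  if (!nrow(iv)) return(0)
  if (convention == "rows") {
    covered <- logical(losi$n_rows)
    for (i in seq_len(nrow(iv))) covered[iv$row_start[i]:iv$row_end[i]] <- TRUE
    sum(covered) / losi$n_rows
  } else {
    covered <- logical(losi$L)
    for (i in seq_len(nrow(iv))) {
      covered[iv$row_start[i]:min(losi$L, iv$row_end[i] + losi$b - 1)] <- TRUE
    }
    sum(covered) / losi$L
  }
}

#' Mean R-square within synchronization intervals
#'
#' Average interrelatedness inside the detected intervals: the mean of the
#' matrix cells (row, interval lag) over all member rows of all retained
#' intervals.
#'
#' @param losi a `losi` produced from `matrix`.
#' @param matrix the `rsq_matrix` the intervals were picked from.
#' @return mean (Delta)R2, or `NA` (with a warning) for an empty LOSI.
#' @export
sync_mean_r2 <- function(losi, matrix) {
  stopifnot(inherits(losi, "losi"), inherits(matrix, "rsq_matrix"))
  iv <- losi$intervals
  if (!nrow(iv)) {
    warning("empty LOSI: mean R2 undefined")
    return(NA_real_)
  }
  cells <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    col <- match(iv$lag[i], matrix$lags)
    matrix$values[iv$row_start[i]:iv$row_end[i], col]
  }))
  mean(cells)
}
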