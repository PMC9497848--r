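#' Motion-energy series
#'
#' A motion-energy series is one interactant's movement intensity per frame.
#' Raw series hold changed-pixel counts; standardized series hold the count as
#' a percentage of the region-of-interest (ROI) size, so values lie in
#' \[0, 100\] with 0 = no motion and 100 = the entire ROI activated.
#'
#' @param values numeric vector of per-frame values.
#' @param fps frames per second (default 25).
#' @param kind one of `"raw-count"`, `"standardized"`, `"smoothed"`.
#' @return An object of class `me_series`: a numeric vector with `fps` and
#'   `kind` attributes.
#' @export
me_series <- function(values, fps = 25, kind = c("standardized", "raw-count", "smoothed")) {
  kind <- match.arg(kind)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (fps <= 0) stop("`fps` must be positive")
  if (kind %in% c("standardized", "smoothed") &&
      length(values) && (min(values) < 0 || max(values) > 100)) {
    stop("standardized motion-energy values must lie in [0, 100]")
  }
  structure(as.numeric(values), fps = fps, kind = kind, class = "me_series")
}

#' @export
print.me_series <- function(x, ...) {
  cat(sprintf("<me_series> %d frames @ %g fps (%s)\n",
              length(x), attr(x, "fps"), attr(x, "kind")))
  if (length(x)) {
    cat(sprintf("  range [%.3g, %.3g], mean %.3g\n", min(x), max(x), mean(x)))
  }
  invisible(x)
}

#' Dyadic time series
#'
#' Aligned pair of motion-energy series for the two members of a dyad,
#' optionally carrying the ground-truth coupling schedule used to generate it.
#'
#' @param A,B numeric vectors (or `me_series`) of equal length.
#' @param fps frames per second.
#' @param id dyad identifier.
#' @param schedule optional data frame of ground-truth coupling intervals
#'   (columns `start`, `end`, `lag`, `beta`, `sign`), the reference list of
#'   synchronization intervals for this dyad.
#' @return An object of class `dyad_ts`.
#' @export
dyad_ts <- function(A, B, fps = 25, id = NA_character_, schedule = NULL) {
  A <- as.numeric(A); B <- as.numeric(B)
  if (length(A) != length(B)) stop("member series must have equal length")
  if (!is.null(schedule)) schedule <- validate_schedule(schedule, length(A))
  structure(list(A = A, B = B, fps = fps, id = id, schedule = schedule),
            class = "dyad_ts")
}

#' @export
print.dyad_ts <- function(x, ...) {
  cat(sprintf("<dyad_ts> %s: %d frames @ %g fps", x$id, length(x$A), x$fps))
  if (!is.null(x$schedule)) {
    cat(sprintf(", %d ground-truth coupling interval(s)", nrow(x$schedule)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.dyad_ts <- function(x) length(x$A)

validate_schedule <- function(schedule, L) {
  schedule <- as.data.frame(schedule)
  need <- c("start", "end", "lag", "beta", "sign")
  if (!all(need %in% names(schedule))) {
    stop("schedule needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(schedule)) {
    with(schedule, {
      if (any(start < 1 | start >= end)) stop("schedule: need 1 <= start < end")
      if (any(end > L + 1)) stop("schedule interval exceeds series bounds")
      if (any(beta < 0)) stop("schedule: beta must be >= 0")
      if (any(!sign %in% c(-1, 1))) stop("schedule: sign must be +1 or -1")
      tgt_lo <- start + lag; tgt_hi <- end - 1 + lag
      if (any(tgt_lo < 1 | tgt_hi > L)) {
        stop("schedule interval exceeds series bounds after lag shift")
      }
    })
    ord <- order(schedule$start)
    s <- schedule[ord, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("schedule intervals overlap")
    }
    # overlap after lag shift (on the follower side)
    t0 <- s$start + s$lag; t1 <- s$end - 1 + s$lag
    ord2 <- order(t0)
    if (nrow(s) > 1 && any(t0[ord2][-1] <= t1[ord2][-nrow(s)])) {
      stop("schedule intervals overlap after lag shift")
    }
  }
  schedule
}

# ---- Fisher Z ---------------------------------------------------------------

#' Fisher Z transform with clamping
#'
#' `atanh(r)` after capping `|r|` at `1 - clamp_eps`, so that perfect
#' correlations (which occur in noiseless fixtures) do not map to infinity.
#'
#' @param r correlation value(s).
#' @param clamp_eps cap distance from 1 (default `1e-7`).
#' @return numeric vector; attribute `clamped` flags entries that were capped.
#' @export
fisher_z <- function(r, clamp_eps = 1e-7) {
  clamped <- !is.na(r) & abs(r) >= 1 - clamp_eps
  out <- atanh(pmin(pmax(r, -(1 - clamp_eps)), 1 - clamp_eps))
  attr(out, "clamped") <- clamped
  out
}

# ---- rolling windowed cross-correlation engine ------------------------------

# Windowed lagged Pearson correlations via running sums.
# ccf_win(x, y, b, tau)[t] = cor(x[t:(t+b-1)], y[(t+tau):(t+tau+b-1)])
# for every reference start t = 1 .. L-b+1; NA where the lagged window does
# not fit inside the series or either window has (numerically) zero variance.
# Series are centred globally first, which leaves correlations unchanged but
# protects the one-pass sums from cancellation.
roll_lagged_cor <- function(x, y, b, tau) {
  L <- length(x)
  stopifnot(length(y) == L, b >= 2, b <= L)
  nt <- L - b + 1
  out <- rep(NA_real_, nt)
  # reference t range for which both windows fit
  t_lo <- max(1L, 1L - tau)
  t_hi <- min(nt, L - tau - b + 1L)
  if (t_lo > t_hi) return(out)
  xs <- x - mean(x); ys <- y - mean(y)
  idx <- t_lo:t_hi
  xw <- xs[t_lo:(t_hi + b - 1L)]
  yw <- ys[(t_lo + tau):(t_hi + tau + b - 1L)]
  # windowed sums over the aligned stretches
  sx  <- roll_sum(xw, b); sy  <- roll_sum(yw, b)
  sxx <- roll_sum(xw * xw, b); syy <- roll_sum(yw * yw, b)
  sxy <- roll_sum(xw * yw, b)
  vx <- sxx - sx * sx / b
  vy <- syy - sy * sy / b
  cxy <- sxy - sx * sy / b
  # guard zero-variance windows (scale-aware tolerance)
  tolx <- pmax(sxx, sx * sx / b) * 1e-12 + 1e-300
  toly <- pmax(syy, sy * sy / b) * 1e-12 + 1e-300
  r <- ifelse(vx <= tolx | vy <= toly, NA_real_, cxy / sqrt(pmax(vx, 0) * pmax(vy, 0)))
  out[idx] <- pmin(pmax(r, -1), 1)
  out
}

# running window sums of length b over v; result length(v) - b + 1
roll_sum <- function(v, b) {
  c0 <- cumsum(v)
  c0[b:length(v)] - c(0, c0[seq_len(length(v) - b)])
}

# ---- I/O --------------------------------------------------------------------

#' Write / read a dyad as two-column CSV
#'
#' Frame index is implicit (row order); the header names the two members.
#' @param dyad a `dyad_ts`.
#' @param path file path.
#' @param col_names column names for the two members.
#' @return `read_dyad_csv` returns a `dyad_ts` (without schedule).
#' @export
write_dyad_csv <- function(dyad, path, col_names = c("A", "B")) {
  df <- data.frame(dyad$A, dyad$B)
  names(df) <- col_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dyad_csv
#' @param fps frames per second to attach on read.
#' @param id dyad id to attach on read.
#' @export
read_dyad_csv <- function(path, fps = 25, id = NA_character_) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("dyad CSV needs two columns")
  dyad_ts(df[[1]], df[[2]], fps = fps, id = id)
}

#' Write / read a ground-truth coupling schedule as JSON
#'
#' The schedule is stored as a list of objects with fields
#' `start`, `end`, `lag`, `beta`, `sign`.
#' @param schedule data frame with those columns.
#' @param path file path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(schedule), path, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a cohort measure table as CSV
#' @param table data frame, one row per dyad.
#' @param path file path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
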