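#' Parameters for windowed cross-recurrence quantification analysis
#'
#' @param radius_eps recurrence threshold on the Euclidean distance between
#'   embedded states of the unit-rescaled series (default 0.05).
#' @param embedding_dim embedding dimension (default 3).
#' @param embedding_delay embedding delay in frames (default 1).
#' @param window_frames window width (default 1500 frames = 60 s at 25 fps).
#' @param window_overlap overlap of consecutive windows (default 750).
#' @param lag_band maximal time lag: half-width of the diagonal band of the
#'   recurrence matrix that is evaluated (default 125 frames = 5 s); `NULL`
#'   evaluates the full matrix.
#' @param min_diag_line minimal diagonal line length for DET/ENTR (default 2).
#' @return A list of class `crqa_params`.
#' @export
crqa_params <- function(radius_eps = 0.05, embedding_dim = 3,
                        embedding_delay = 1, window_frames = 1500,
                        window_overlap = 750, lag_band = 125,
                        min_diag_line = 2) {
  if (radius_eps <= 0) stop("radius_eps must be > 0")
  if (embedding_dim < 1 || embedding_delay < 1) stop("invalid embedding")
  if (window_overlap >= window_frames) stop("overlap must be < window")
  span <- (embedding_dim - 1) * embedding_delay + 1
  if (window_frames <= span) stop("window must exceed the embedding span")
  structure(list(radius_eps = radius_eps,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_delay = as.integer(embedding_delay),
                 window_frames = as.integer(window_frames),
                 window_overlap = as.integer(window_overlap),
                 lag_band = if (is.null(lag_band)) NULL else as.integer(lag_band),
                 min_diag_line = as.integer(min_diag_line)),
            class = "crqa_params")
}

#' Rescale a series to the unit interval
#'
#' Linear min-max rescale: the minimum maps to 0 and the maximum to 1.
#' @param series numeric vector (non-constant).
#' @return numeric vector in \[0, 1\].
#' @export
unit_rescale <- function(series) {
  x <- as.numeric(series)
  r <- range(x)
  if (r[1] == r[2]) stop("constant series cannot be rescaled")
  (x - r[1]) / (r[2] - r[1])
}

#' Time-delay embedding
#'
#' State vector k is `(x_k, x_{k+delay}, ..., x_{k+(dim-1)*delay})`; the
#' number of states is `length(x) - (dim - 1) * delay`.
#' @param series numeric vector.
#' @param dim embedding dimension (`dim = 1` is the identity embedding).
#' @param delay embedding delay in frames.
#' @return matrix with one state per row and `dim` columns.
#' @export
embed_series <- function(series, dim = 3, delay = 1) {
  x <- as.numeric(series)
  span <- (dim - 1) * delay
  if (length(x) < span + 1) stop("series too short for this embedding")
  n <- length(x) - span
  out <- vapply(seq_len(dim),
                function(d) x[(1 + (d - 1) * delay):(n + (d - 1) * delay)],
                numeric(n))
  matrix(out, nrow = n, ncol = dim)
}

#' Cross-recurrence measures of one window pair
#'
#' Builds the binary cross-recurrence matrix `R(i, j) = 1` iff the Euclidean
#' distance between A-state i and B-state j is below `radius_eps`, restricted
#' to the diagonal band `|i - j| <= lag_band`, and summarizes it:
#' RR = percentage of recurrent cells among band cells; DET = percentage of
#' recurrent points lying on diagonal runs of length >= `min_diag_line`;
#' ENTR = Shannon entropy of the distribution of those diagonal run lengths,
#' normalized by the log of the number of distinct observed lengths (0 when
#' fewer than 2 distinct lengths). DET is missing when RR = 0.
#'
#' @param embA,embB embedded state matrices (rows = states) from
#'   unit-rescaled series.
#' @param params a [crqa_params()].
#' @return list with `rr`, `det`, `entr`, `n_recurrent`, `n_cells`.
#' @export
cross_recurrence_window <- function(embA, embB, params) {
  stopifnot(inherits(params, "crqa_params"))
  nA <- nrow(embA); nB <- nrow(embB)
  band <- if (is.null(params$lag_band)) max(nA, nB) else params$lag_band
  eps2 <- params$radius_eps^2
  offsets <- seq(max(-band, -(nA - 1)), min(band, nB - 1))
  if (!length(offsets)) stop("no cells inside the lag band")
  n_cells <- 0L; n_rec <- 0L
  run_lengths <- integer(0)
  runs_acc <- vector("list", length(offsets))
  for (oi in seq_along(offsets)) {
    d <- offsets[oi]
    i_lo <- max(1L, 1L - d); i_hi <- min(nA, nB - d)
    if (i_lo > i_hi) next
    ii <- i_lo:i_hi
    dist2 <- rowSums((embA[ii, , drop = FALSE] -
                        embB[ii + d, , drop = FALSE])^2)
    rec <- dist2 < eps2
    n_cells <- n_cells + length(rec)
    n_rec <- n_rec + sum(rec)
    r <- rle(rec)
    rl <- r$lengths[r$values]
    if (length(rl)) runs_acc[[oi]] <- rl
  }
  if (n_cells == 0) stop("no cells inside the lag band")
  run_lengths <- unlist(runs_acc, use.names = FALSE)
  rr <- 100 * n_rec / n_cells
  if (n_rec == 0) {
    return(list(rr = 0, det = NA_real_, entr = 0,
                n_recurrent = 0L, n_cells = n_cells))
  }
  keep <- run_lengths[run_lengths >= params$min_diag_line]
  det <- 100 * sum(keep) / n_rec
  entr <- 0
  if (length(keep)) {
    tab <- table(keep)
    p <- as.numeric(tab) / sum(tab)
    if (length(p) > 1) entr <- -sum(p * log(p)) / log(length(p))
  }
  list(rr = rr, det = det, entr = entr,
       n_recurrent = as.integer(n_rec), n_cells = n_cells)
}

#' Windowed cross-recurrence quantification analysis
#'
#' Rescales both members to the unit interval, embeds them, slides a window
#' of `window_frames` stepped by `window_frames - window_overlap` over the
#' series, computes RR/DET/ENTR per window and averages them arithmetically
#' over windows. Windows in which a member is constant (not embeddable after
#' rescaling) or without recurrent points (DET undefined) are skipped for
#' the affected quantity.
#'
#' @param dyad a `dyad_ts`.
#' @param params a [crqa_params()].
#' @return Object of class `crqa_result`: `rr`, `det`, `entr` (averages),
#'   `n_windows`, and the per-window data frame `windows`.
#' @export
wincrqa <- function(dyad, params = crqa_params()) {
  stopifnot(inherits(dyad, "dyad_ts"), inherits(params, "crqa_params"))
  L <- length(dyad$A)
  w <- params$window_frames
  if (L < w) stop("series shorter than one window")
  A <- unit_rescale(dyad$A)
  B <- unit_rescale(dyad$B)
  step <- w - params$window_overlap
  starts <- seq(1L, L - w + 1L, by = step)
  res <- lapply(starts, function(s) {
    aw <- A[s:(s + w - 1)]; bw <- B[s:(s + w - 1)]
    tryCatch({
      r <- cross_recurrence_window(
        embed_series(aw, params$embedding_dim, params$embedding_delay),
        embed_series(bw, params$embedding_dim, params$embedding_delay),
        params)
      data.frame(start = s, rr = r$rr, det = r$det, entr = r$entr)
    }, error = function(e) data.frame(start = s, rr = NA_real_,
                                      det = NA_real_, entr = NA_real_))
  })
  win <- do.call(rbind, res)
  if (all(is.na(win$rr))) stop("no analyzable window")
  structure(list(rr = mean(win$rr, na.rm = TRUE),
                 det = mean(win$det, na.rm = TRUE),
                 entr = mean(win$entr, na.rm = TRUE),
                 n_windows = sum(!is.na(win$rr)),
                 windows = win, params = params),
            class = "crqa_result")
}

#' @export
print.crqa_result <- function(x, ...) {
  cat(sprintf("<crqa_result> %d windows: RR %.2f%%  DET %.2f%%  ENTR %.3f\n",
              x$n_windows, x$rr, x$det, x$entr))
  invisible(x)
}
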