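#' Global cross-correlation measures of a dyad
#'
#' The simplest synchrony measures: the zero-lag Pearson correlation of the
#' two full-length series (CC-raw) and three monotone transforms that address
#' the sign problem of averaging correlations — the absolute value (CC-abs),
#' Fisher's Z (CC-Z, clamped near |r| = 1) and the coefficient of
#' determination (CC-R2). No time lag is modeled.
#'
#' @param dyad a `dyad_ts` with both members of length >= 3 and nonzero
#'   variance.
#' @param clamp_eps Fisher-Z clamp distance from 1.
#' @return A list of class `cc_result` with fields `raw`, `abs`, `z`, `r2`
#'   and a logical `clamped` flag.
#' @export
compute_cc <- function(dyad, clamp_eps = 1e-7) {
  stopifnot(inherits(dyad, "dyad_ts"))
  A <- dyad$A; B <- dyad$B
  if (length(A) < 3) stop("series too short (need length >= 3)")
  if (stats::sd(A) == 0 || stats::sd(B) == 0) stop("degenerate variance")
  raw <- stats::cor(A, B)
  z <- fisher_z(raw, clamp_eps)
  structure(list(raw = raw, abs = abs(raw), z = as.numeric(z), r2 = raw^2,
                 clamped = any(attr(z, "clamped"))),
            class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("<cc_result> raw %.4f  abs %.4f  Z %.4f  R2 %.4f%s\n",
              x$raw, x$abs, x$z, x$r2,
              if (x$clamped) "  [Z clamped]" else ""))
  invisible(x)
}
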