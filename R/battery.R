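#' Configuration of the full measure battery
#'
#' Bundles the parameters of every synchrony algorithm; defaults are the
#' standard settings for 25-fps motion-energy series (60 s / 5 s / 30 s
#' rMEA windows, 30 s SUSY segments, 3 s / 1 s SUCO slope windows, 125-frame
#' peak-picking windows with alpha = 0.001 and R2 cutoff 0.25, 50 jackknife
#' blocks for MI, and 1500/750/125 CRQA windowing with eps = 0.05).
#'
#' @param rmea list: `window_s`, `lag_max_s`, `increment_s`.
#' @param susy list: `segment_s`, `lag_max_s`.
#' @param suco list: `slope_window_s`, `slope_increment_s`, `segment_s`.
#' @param pp list: `b`, `tau_max`, `alpha`, `r2_cutoff`.
#' @param mi list: `jackknife_blocks`, `grid_size`.
#' @param crqa a [crqa_params()].
#' @return list of class `battery_config`.
#' @export
battery_config <- function(
    rmea = list(window_s = 60, lag_max_s = 5, increment_s = 30),
    susy = list(segment_s = 30, lag_max_s = 5),
    suco = list(slope_window_s = 3, slope_increment_s = 1, segment_s = 30),
    pp = list(b = 125, tau_max = 125, alpha = 0.001, r2_cutoff = 0.25),
    mi = list(jackknife_blocks = 50, grid_size = 101),
    crqa = crqa_params()) {
  structure(list(rmea = rmea, susy = susy, suco = suco, pp = pp, mi = mi,
                 crqa = crqa),
            class = "battery_config")
}

#' Compute the full 21-measure battery for a cohort of dyads
#'
#' Applies every synchrony algorithm to each dyad and assembles the cohort
#' measure table (one row per dyad, one column per measure). A measure that
#' fails on a dyad — e.g. a series shorter than one CRQA window — is
#' recorded as missing, with the reason collected in the `"failures"`
#' attribute; the remaining columns of that dyad are still filled. The
#' computation is deterministic (the surrogate ensembles are exhaustive and
#' the person-shuffle test is not part of the 21 columns).
#'
#' @param dyads list of `dyad_ts`.
#' @param config a [battery_config()].
#' @param skeleton optional data frame (e.g. from [generate_cohort()]) whose
#'   rows align with `dyads`; measure columns are appended to it.
#' @return data frame with `dyad_id` and the 21 measure columns (appended to
#'   `skeleton` when given); attribute `"failures"` lists per-dyad errors.
#' @export
measure_battery <- function(dyads, config = battery_config(), skeleton = NULL) {
  if (!length(dyads)) stop("need at least one dyad")
  failures <- list()
  rows <- lapply(seq_along(dyads), function(i) {
    d <- dyads[[i]]
    vals <- stats::setNames(rep(NA_real_, length(MEASURE_COLUMNS)),
                            MEASURE_COLUMNS)
    note <- function(what, e) {
      failures[[length(failures) + 1]] <<-
        sprintf("dyad %s / %s: %s", d$id, what, conditionMessage(e))
    }
    tryCatch({
      cc <- compute_cc(d)
      vals[c("cc_raw", "cc_abs", "cc_z", "cc_r2")] <-
        c(cc$raw, cc$abs, cc$z, cc$r2)
    }, error = function(e) note("cc", e))
    tryCatch({
      m <- wclc_matrix(d, window_s = config$rmea$window_s,
                       lag_max_s = config$rmea$lag_max_s,
                       increment_s = config$rmea$increment_s)
      vals["rmea_wcc"] <- rmea_wcc(m)
      vals["rmea_wclc"] <- rmea_wclc(m)
    }, error = function(e) note("rmea", e))
    tryCatch({
      s <- susy(d, segment_s = config$susy$segment_s,
                lag_max_s = config$susy$lag_max_s)
      vals[c("susy_es_abs", "susy_es_noabs")] <- c(s$es_abs, s$es_noabs)
    }, error = function(e) note("susy", e))
    tryCatch({
      s <- suco(d, slope_window_s = config$suco$slope_window_s,
                slope_increment_s = config$suco$slope_increment_s,
                segment_s = config$suco$segment_s)
      vals[c("suco_co", "suco_es_abs", "suco_es_co")] <-
        c(s$co, s$es_abs, s$es_co)
    }, error = function(e) note("suco", e))
    tryCatch({
      mat <- wclc_rsq_matrix(d, b = config$pp$b, tau_max = config$pp$tau_max,
                             alpha = config$pp$alpha)
      losi <- peak_picking(mat, r2_cutoff = config$pp$r2_cutoff)
      vals["wclc_pp_f"] <- sync_frequency(losi)
      vals["wclc_pp_r2"] <- if (nrow(losi$intervals)) {
        sync_mean_r2(losi, mat)
      } else NA_real_
    }, error = function(e) note("wclc_pp", e))
    tryCatch({
      mat <- wclr_rsq_matrix(d, b = config$pp$b, tau_max = config$pp$tau_max,
                             alpha = config$pp$alpha)
      losi <- peak_picking(mat, r2_cutoff = config$pp$r2_cutoff)
      vals["wclr_pp_f"] <- sync_frequency(losi)
      vals["wclr_pp_r2"] <- if (nrow(losi$intervals)) {
        sync_mean_r2(losi, mat)
      } else NA_real_
    }, error = function(e) note("wclr_pp", e))
    tryCatch({
      mi <- mutual_information(d, jackknife_blocks = config$mi$jackknife_blocks,
                               grid_size = config$mi$grid_size)
      vals[c("mi_raw", "mi_cor", "mi_z")] <- c(mi$raw, mi$cor, mi$z)
    }, error = function(e) note("mi", e))
    tryCatch({
      cr <- wincrqa(d, params = config$crqa)
      vals[c("wincrqa_rr", "wincrqa_det", "wincrqa_entr")] <-
        c(cr$rr, cr$det, cr$entr)
    }, error = function(e) note("wincrqa", e))
    c(list(dyad_id = d$id), as.list(vals))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (!is.null(skeleton)) {
    stopifnot(nrow(skeleton) == nrow(out))
    keep <- setdiff(names(skeleton), names(out))
    out <- cbind(skeleton[, c("dyad_id", setdiff(keep, "dyad_id")),
                          drop = FALSE],
                 out[, setdiff(names(out), "dyad_id"), drop = FALSE])
  }
  attr(out, "failures") <- failures
  out
}
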