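#' Measure columns of the cohort table
#'
#' The 21 synchrony measures of the battery, in canonical column order.
#' @export
MEASURE_COLUMNS <- c(
  "cc_raw", "cc_abs", "cc_z", "cc_r2",
  "rmea_wcc", "rmea_wclc",
  "susy_es_abs", "susy_es_noabs",
  "suco_co", "suco_es_abs", "suco_es_co",
  "wclc_pp_f", "wclc_pp_r2", "wclr_pp_f", "wclr_pp_r2",
  "mi_raw", "mi_cor", "mi_z",
  "wincrqa_rr", "wincrqa_det", "wincrqa_entr")

#' Convergent-validity correlation matrix
#'
#' Pairwise correlations between all measure columns: Pearson coefficients in
#' the lower-left triangle, Spearman in the upper-right, 1 on the diagonal
#' (the standard mixed-triangle layout of measure-validity tables). Cells use
#' pairwise deletion and are missing when fewer than `min_pairs` complete
#' pairs exist or a column is constant. Two-sided p-values accompany each
#' cell; `stars` marks p < 0.05.
#'
#' @param table cohort data frame.
#' @param measures columns to include (default: the intersection of
#'   [MEASURE_COLUMNS] with `names(table)`).
#' @param min_pairs minimal complete pairs per cell (default 4).
#' @return Object of class `sync_cor_matrix`: `values` (mixed triangle),
#'   `pearson`, `spearman`, `p_pearson`, `p_spearman`, `stars`.
#' @export
correlation_matrix <- function(table, measures = NULL, min_pairs = 4) {
  measures <- resolve_measures(table, measures)
  m <- length(measures)
  pear <- spear <- pp <- ps <- matrix(NA_real_, m, m,
                                      dimnames = list(measures, measures))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) { pear[i, j] <- spear[i, j] <- 1; next }
      x <- table[[measures[i]]]; y <- table[[measures[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < min_pairs) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      tp <- stats::cor.test(x[ok], y[ok], method = "pearson")
      ts <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      pear[i, j] <- unname(tp$estimate); pp[i, j] <- tp$p.value
      spear[i, j] <- unname(ts$estimate); ps[i, j] <- ts$p.value
    }
  }
  mixed <- pear
  mixed[upper.tri(mixed)] <- spear[upper.tri(spear)]
  stars <- matrix("", m, m, dimnames = list(measures, measures))
  stars[lower.tri(stars)][which(pp[lower.tri(pp)] < 0.05)] <- "*"
  stars[upper.tri(stars)][which(ps[upper.tri(ps)] < 0.05)] <- "*"
  structure(list(values = mixed, pearson = pear, spearman = spear,
                 p_pearson = pp, p_spearman = ps, stars = stars,
                 n = nrow(table)),
            class = "sync_cor_matrix")
}

#' @export
print.sync_cor_matrix <- function(x, digits = 2, ...) {
  cat("<sync_cor_matrix> Pearson below / Spearman above diagonal, * p < 0.05\n")
  v <- format(round(x$values, digits))
  v[] <- paste0(v, ifelse(x$stars == "*", "*", " "))
  print(v, quote = FALSE)
  invisible(x)
}

resolve_measures <- function(table, measures) {
  if (is.null(measures)) {
    measures <- intersect(MEASURE_COLUMNS, names(table))
    if (!length(measures)) {
      measures <- names(table)[vapply(table, is.numeric, logical(1))]
    }
  }
  missing_cols <- setdiff(measures, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  }
  measures
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the 95th
#' percentile (configurable) of eigenvalues obtained from `n_boot` resampled
#' data sets. Resampling draws each column independently with replacement
#' from its observed values, which breaks the dependence structure while
#' keeping the marginals; `method = "simulate"` draws standard-normal data
#' of the same shape instead. The retained number of factors is the count of
#' leading observed eigenvalues exceeding their resampled percentile.
#'
#' @param table cohort data frame.
#' @param measures columns to include (default: available measure columns).
#' @param n_boot number of resampled data sets (default 100).
#' @param seed integer seed.
#' @param quantile percentile of the resampled eigenvalues (default 0.95).
#' @param method `"resample"` (default) or `"simulate"`.
#' @return integer number of factors, with attribute `"eigenvalues"`
#'   (observed) and `"thresholds"`.
#' @export
parallel_analysis <- function(table, measures = NULL, n_boot = 100, seed = 1,
                              quantile = 0.95,
                              method = c("resample", "simulate")) {
  method <- match.arg(method)
  measures <- resolve_measures(table, measures)
  X <- as.matrix(table[, measures, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 complete rows")
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  withr_seed(seed)
  boot <- matrix(NA_real_, n_boot, p)
  for (b in seq_len(n_boot)) {
    Xb <- if (method == "resample") {
      apply(X, 2, function(col) sample(col, n, replace = TRUE))
    } else {
      matrix(stats::rnorm(n * p), n, p)
    }
    boot[b, ] <- eigen(stats::cor(Xb), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  thr <- apply(boot, 2, stats::quantile, probs = quantile)
  above <- obs > thr
  k <- if (all(above)) p else which.min(above) - 1L
  structure(as.integer(k), eigenvalues = obs, thresholds = thr)
}

#' Maximum-likelihood exploratory factor analysis with oblimin rotation
#'
#' ML extraction (via [stats::factanal()]) on the Pearson correlation matrix
#' of the selected measures, followed by an oblique oblimin (direct
#' quartimin) rotation computed by gradient projection, so factors are
#' allowed to correlate. Reports the rotated loadings, inter-factor
#' correlations and the fit indices RMSR, RMSEA and TLI (acceptable fit is
#' conventionally RMSEA < 0.08 and TLI > 0.9). Heywood cases (uniqueness at
#' its lower bound) are flagged but the solution is still returned.
#'
#' @param table cohort data frame.
#' @param n_factors number of factors to extract.
#' @param measures columns to include.
#' @return Object of class `factor_solution`: `loadings`,
#'   `factor_correlation`, `uniquenesses`, `rmsr`, `rmsea`, `tli`,
#'   `n_factors`, `variance_explained`, `heywood`, `n_obs`.
#' @export
efa_ml <- function(table, n_factors, measures = NULL) {
  measures <- resolve_measures(table, measures)
  X <- as.matrix(table[, measures, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n_factors < 1) stop("n_factors must be >= 1")
  R <- stats::cor(X)
  if (n <= p) {
    warning(sprintf(
      "only %d complete rows for %d measures: correlation matrix is singular/ill-conditioned; fit indices are reported but fragile", n, p))
  }
  fit <- stats::factanal(covmat = R, factors = n_factors, n.obs = n,
                         rotation = "none")
  A <- unclass(fit$loadings)
  if (n_factors > 1) {
    rot <- oblimin_rotate(A)
    load <- rot$loadings
    phi <- rot$Phi
  } else {
    load <- A
    phi <- matrix(1, 1, 1)
  }
  dimnames(load) <- list(measures, paste0("F", seq_len(n_factors)))
  uniq <- fit$uniquenesses
  heywood <- any(uniq <= 0.005 + 1e-8)
  implied <- load %*% phi %*% t(load) + diag(uniq)
  resid <- R - implied
  rmsr <- sqrt(mean(resid[lower.tri(resid)]^2))
  chi2 <- if (!is.null(fit$STATISTIC)) unname(fit$STATISTIC) else 0
  df <- unname(fit$dof)
  if (df > 0) {
    rmsea <- sqrt(max(0, chi2 / df - 1) / (n - 1))
    c_null <- (n - 1) - (2 * p + 5) / 6
    chi2_null <- -c_null * determinant(R, logarithm = TRUE)$modulus[1]
    df_null <- p * (p - 1) / 2
    tli <- ((chi2_null / df_null) - (chi2 / df)) / ((chi2_null / df_null) - 1)
  } else {
    rmsea <- 0; tli <- 1
  }
  ve <- colSums(load^2) / p
  structure(list(loadings = load, factor_correlation = phi,
                 uniquenesses = uniq, rmsr = rmsr, rmsea = rmsea, tli = tli,
                 n_factors = n_factors, variance_explained = ve,
                 heywood = heywood, n_obs = n),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> %d factor(s), n = %d%s\n", x$n_factors,
              x$n_obs, if (x$heywood) "  [Heywood case]" else ""))
  print(round(x$loadings, 3))
  if (x$n_factors > 1) {
    cat("factor correlations:\n"); print(round(x$factor_correlation, 3))
  }
  cat(sprintf("RMSR %.3f  RMSEA %.3f  TLI %.3f\n", x$rmsr, x$rmsea, x$tli))
  invisible(x)
}

# oblique oblimin (gamma = 0, i.e. direct quartimin) rotation by gradient
# projection (Bernaards & Jennrich algorithm); deterministic identity start
oblimin_rotate <- function(A, maxit = 1000, eps = 1e-6) {
  k <- ncol(A)
  Tm <- diag(k)
  vgq <- function(L) {
    L2 <- L * L
    M <- matrix(1, k, k); diag(M) <- 0
    list(f = sum(L2 * (L2 %*% M)) / 4, Gq = L * (L2 %*% M))
  }
  al <- 1
  L <- A %*% t(solve(Tm))
  V <- vgq(L)
  G <- -t(t(L) %*% V$Gq %*% solve(Tm))
  f <- V$f
  s <- Inf
  for (iter in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))
    s <- sqrt(sum(Gp * Gp))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:20) {
      X <- Tm - al * Gp
      v <- 1 / sqrt(colSums(X * X))
      Tt <- X %*% diag(v)
      Lt <- A %*% t(solve(Tt))
      Vt <- vgq(Lt)
      if (Vt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; L <- Lt; f <- Vt$f
    G <- -t(t(L) %*% Vt$Gq %*% solve(Tm))
  }
  list(loadings = L, Phi = t(Tm) %*% Tm, converged = s < eps, f = f)
}

#' Group comparison of synchrony measures
#'
#' Per measure: group means and SDs, the Kruskal-Wallis test p-value, and
#' Hedges g (pooled-SD standardized mean difference times the small-sample
#' correction `1 - 3 / (4 * (n1 + n2) - 9)`; sign convention: patient minus
#' control).
#'
#' @param table cohort data frame with a `group` column
#'   (`"control"` / `"patient"`).
#' @param measures columns to compare.
#' @return data frame with one row per measure: group means/SDs, `p_kw`,
#'   `hedges_g`, and effect-size labels (small/moderate/large at 0.2/0.5/0.8).
#' @export
group_comparison <- function(table, measures = NULL) {
  measures <- resolve_measures(table, measures)
  if (!"group" %in% names(table)) stop("table needs a `group` column")
  g <- table$group
  if (length(unique(g[!is.na(g)])) != 2) stop("need exactly two groups")
  ctrl <- g == "control"
  rows <- lapply(measures, function(m) {
    x <- table[[m]]
    ok <- !is.na(x) & !is.na(g)
    x1 <- x[ok & ctrl]; x2 <- x[ok & !ctrl]
    n1 <- length(x1); n2 <- length(x2)
    p <- if (n1 && n2 && stats::sd(x[ok]) > 0) {
      stats::kruskal.test(x[ok], factor(g[ok]))$p.value
    } else NA_real_
    sp2 <- if (n1 + n2 > 2) {
      ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
    } else NA_real_
    gg <- if (!is.na(sp2) && sp2 > 0) {
      (mean(x2) - mean(x1)) / sqrt(sp2) * (1 - 3 / (4 * (n1 + n2) - 9))
    } else NA_real_
    data.frame(measure = m,
               mean_control = mean(x1), sd_control = stats::sd(x1),
               mean_patient = mean(x2), sd_patient = stats::sd(x2),
               p_kw = p, hedges_g = gg,
               g_label = effect_label(abs(gg), c(0.2, 0.5, 0.8)))
  })
  do.call(rbind, rows)
}

effect_label <- function(v, cuts) {
  if (is.na(v)) return(NA_character_)
  c("negligible", "small", "moderate", "large")[findInterval(v, cuts) + 1]
}

#' Symptom correlations of synchrony measures
#'
#' Pearson and Spearman correlations of each measure with the PHQ9 and GAD7
#' sum scores (with two-sided p-values), mirroring a predictive-validity
#' table. Constant symptom columns give missing cells with a warning.
#'
#' @param table cohort data frame with `phq9` and `gad7` columns.
#' @param measures columns to correlate.
#' @param symptoms symptom columns (default `c("phq9", "gad7")`).
#' @return data frame: one row per measure x symptom with `r_pearson`,
#'   `p_pearson`, `r_spearman`, `p_spearman`, `r_label`.
#' @export
symptom_correlations <- function(table, measures = NULL,
                                 symptoms = c("phq9", "gad7")) {
  measures <- resolve_measures(table, measures)
  if (!all(symptoms %in% names(table))) {
    stop("table lacks symptom columns: ",
         paste(setdiff(symptoms, names(table)), collapse = ", "))
  }
  rows <- list()
  for (s in symptoms) {
    y <- table[[s]]
    for (m in measures) {
      x <- table[[m]]
      ok <- stats::complete.cases(x, y)
      rp <- pp <- rs <- ps <- NA_real_
      if (sum(ok) >= 4 && stats::sd(y[ok]) > 0 && stats::sd(x[ok]) > 0) {
        tp <- stats::cor.test(x[ok], y[ok], method = "pearson")
        ts <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        rp <- unname(tp$estimate); pp <- tp$p.value
        rs <- unname(ts$estimate); ps <- ts$p.value
      } else if (sum(ok) >= 4 && stats::sd(y[ok]) == 0) {
        warning(sprintf("symptom column `%s` is constant", s))
      }
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, symptom = s, r_pearson = rp, p_pearson = pp,
        r_spearman = rs, p_spearman = ps,
        r_label = effect_label(abs(rp), c(0.1, 0.3, 0.5)))
    }
  }
  do.call(rbind, rows)
}
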