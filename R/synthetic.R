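#' Configuration for one synthetic motion-energy series
#'
#' The generator emulates the burst-like structure of motion-energy recordings
#' of seated interactants: long near-zero stretches interrupted by contiguous
#' movement episodes ("bursts"), values bounded to \[0, 100\] (percent of the
#' ROI activated), sampled at 25 frames per second.
#'
#' @param length_frames series length in frames.
#' @param fps frames per second (default 25).
#' @param burst_rate expected bursts per minute.
#' @param burst_duration_frames burst length in frames.
#' @param burst_amplitude burst plateau height, in (0, 100].
#' @param noise_sd standard deviation of additive Gaussian measurement noise.
#' @param baseline resting motion level added everywhere.
#' @return A list of class `dyad_config`.
#' @export
dyad_config <- function(length_frames = 15000, fps = 25, burst_rate = 3,
                        burst_duration_frames = 125, burst_amplitude = 20,
                        noise_sd = 1, baseline = 0.5) {
  if (length_frames < 1) stop("length_frames must be positive")
  if (fps <= 0) stop("fps must be positive")
  if (burst_rate < 0) stop("burst_rate must be >= 0")
  if (burst_duration_frames < 1) stop("burst_duration_frames must be positive")
  if (burst_amplitude <= 0 || burst_amplitude > 100) {
    stop("burst_amplitude must be in (0, 100]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline < 0) stop("baseline must be >= 0")
  structure(list(length_frames = as.integer(length_frames), fps = fps,
                 burst_rate = burst_rate,
                 burst_duration_frames = as.integer(burst_duration_frames),
                 burst_amplitude = burst_amplitude, noise_sd = noise_sd,
                 baseline = baseline),
            class = "dyad_config")
}

#' Ground-truth coupling interval
#'
#' Formalizes a synchronization interval for the simulator: between
#' `start_frame` and `end_frame` (half-open) the follower's series is a
#' lagged, scaled copy of the driver's, `B[t + lag] = sign * beta * A[t] +
#' noise`; outside all intervals the members move independently.
#'
#' @param start_frame,end_frame frame indices, `1 <= start < end`.
#' @param lag_tau lag in frames (positive: B follows A).
#' @param strength_beta coupling coefficient, `>= 0`.
#' @param sign `+1` (in-phase) or `-1` (anti-phase).
#' @return One-row data frame with columns `start`, `end`, `lag`, `beta`, `sign`.
#' @export
coupling_interval <- function(start_frame, end_frame, lag_tau = 0,
                              strength_beta = 1, sign = 1) {
  if (start_frame < 1 || start_frame >= end_frame) {
    stop("need 1 <= start_frame < end_frame")
  }
  if (strength_beta < 0) stop("strength_beta must be >= 0")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  data.frame(start = as.integer(start_frame), end = as.integer(end_frame),
             lag = as.integer(lag_tau), beta = strength_beta, sign = sign)
}

#' Generate a burst-like motion-energy series
#'
#' Bursts arrive as a renewal process calibrated to `burst_rate` per minute
#' (exponential gaps between bursts, so placements are Poisson-like but
#' non-overlapping by construction); each burst raises the series by
#' `burst_amplitude` for `burst_duration_frames` frames. A burst that would
#' run past the series end is truncated. Gaussian noise and the baseline are
#' added and the result is clipped to \[0, 100\].
#'
#' @param config a [dyad_config()].
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @return An `me_series` of length `config$length_frames`.
#' @export
generate_burst_series <- function(config, seed) {
  stopifnot(inherits(config, "dyad_config"))
  L <- config$length_frames
  if (L < 1) stop("non-positive series length")
  env <- numeric(L)
  rate_f <- config$burst_rate / (60 * config$fps)  # bursts per frame
  if (rate_f > 0) {
    mean_gap <- 1 / rate_f - config$burst_duration_frames
    if (mean_gap <= 0) {
      stop("burst_rate too high for burst_duration_frames (bursts would overlap)")
    }
    starts <- local({
      withr_seed(seed)
      s <- c(); pos <- 0
      repeat {
        pos <- pos + stats::rexp(1, rate = 1 / mean_gap)
        start <- ceiling(pos) + 1
        if (start > L) break
        s <- c(s, start)
        pos <- start + config$burst_duration_frames - 1
      }
      s
    })
    for (s in starts) {
      e <- min(L, s + config$burst_duration_frames - 1)
      env[s:e] <- env[s:e] + config$burst_amplitude
    }
  } else {
    withr_seed(seed)
  }
  noise <- if (config$noise_sd > 0) stats::rnorm(L, 0, config$noise_sd) else 0
  vals <- pmin(pmax(env + config$baseline + noise, 0), 100)
  me_series(vals, fps = config$fps, kind = "standardized")
}

# set.seed without leaking: generators own their RNG stream deliberately, but
# keep a single entry point so the seeding discipline is uniform.
withr_seed <- function(seed) {
  if (is.na(seed) || seed != round(seed)) stop("seed must be an integer")
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Generate a coupled dyad with ground-truth synchronization intervals
#'
#' Both members are independent burst series except inside the scheduled
#' coupling intervals, where the follower copies the driver's (lagged, scaled)
#' signal plus independent noise: for each interval,
#' `B[t + lag] = sign * beta * A[t] + offset + noise` for `t` in
#' `[start, end)`, with `offset = beta * burst_amplitude` when `sign = -1` so
#' anti-phase coupling stays inside \[0, 100\]. When `config$noise_sd = 0` the
#' copy is exact.
#'
#' @param config a [dyad_config()] shared by both members.
#' @param schedule data frame of coupling intervals (see [coupling_interval()]);
#'   may be empty. Intervals must be non-overlapping (also after lag shift)
#'   and fit inside the series.
#' @param seed integer seed.
#' @param id dyad identifier.
#' @param coupling_noise_sd noise added to the copied signal inside coupling
#'   intervals; defaults to `config$noise_sd`. Set to 0 for noiseless
#'   (exact-copy) coupling on top of noisy member series.
#' @return A `dyad_ts` carrying `schedule` as ground truth.
#' @export
generate_coupled_dyad <- function(config, schedule = NULL, seed = 1,
                                  id = NA_character_,
                                  coupling_noise_sd = NULL) {
  stopifnot(inherits(config, "dyad_config"))
  L <- config$length_frames
  if (is.null(schedule)) {
    schedule <- coupling_interval(1, 2)[0, ]  # empty, right columns
  }
  schedule <- validate_schedule(schedule, L)
  if (is.null(coupling_noise_sd)) coupling_noise_sd <- config$noise_sd
  A <- as.numeric(generate_burst_series(config, seed = seed))
  B <- as.numeric(generate_burst_series(config, seed = seed + 1))
  if (nrow(schedule)) {
    withr_seed(seed + 2)
    for (k in seq_len(nrow(schedule))) {
      iv <- schedule[k, ]
      src <- iv$start:(iv$end - 1)
      tgt <- src + iv$lag
      offset <- if (iv$sign < 0) iv$beta * config$burst_amplitude else 0
      noise <- if (coupling_noise_sd > 0) {
        stats::rnorm(length(src), 0, coupling_noise_sd)
      } else 0
      B[tgt] <- pmin(pmax(iv$sign * iv$beta * A[src] + offset + noise, 0), 100)
    }
  }
  dyad_ts(A, B, fps = config$fps, id = id, schedule = schedule)
}

#' Configuration for a synthetic cohort
#'
#' Emulates a two-group study design: dyads are split into groups whose mean
#' latent coupling strength differs by `coupling_effect`, and questionnaire
#' sum scores are generated from the latent coupling (so that, by default,
#' higher symptom load goes with weaker synchronization).
#'
#' @param n_dyads number of dyads (>= 4).
#' @param group_fractions two proportions summing to 1 (group 1 = control).
#' @param coupling_effect difference in mean latent coupling between group 1
#'   and group 2 (group 2 lower).
#' @param coupling_mean,coupling_sd latent coupling distribution of group 1.
#' @param symptom_model list with `intercept`, `slope` (on latent coupling)
#'   and `noise_sd`, shared by the PHQ9-like and GAD7-like scores before
#'   truncation to their instrument ranges.
#' @param dyad a [dyad_config()] describing every member series.
#' @param n_intervals coupling intervals injected per dyad.
#' @param interval_frames length of each coupling interval.
#' @param lag_max_frames maximal |lag| drawn for intervals.
#' @param seed master seed; per-dyad sub-seeds are drawn from the stream it
#'   initializes (documented splitting rule: cohort-level draws happen first,
#'   then one sub-seed per dyad via `sample.int`).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 30, group_fractions = c(0.5, 0.5),
                          coupling_effect = 0.4,
                          coupling_mean = 0.9, coupling_sd = 0.2,
                          symptom_model = list(intercept = 20, slope = -15,
                                               noise_sd = 3),
                          dyad = dyad_config(),
                          n_intervals = 6, interval_frames = 750,
                          lag_max_frames = 50, seed = 1) {
  if (n_dyads < 4) stop("n_dyads must be >= 4")
  if (length(group_fractions) != 2 || any(group_fractions <= 0) ||
      any(group_fractions >= 1) || abs(sum(group_fractions) - 1) > 1e-8) {
    stop("group_fractions must be two proportions in (0,1) summing to 1")
  }
  structure(list(n_dyads = as.integer(n_dyads),
                 group_fractions = group_fractions,
                 coupling_effect = coupling_effect,
                 coupling_mean = coupling_mean, coupling_sd = coupling_sd,
                 symptom_model = symptom_model, dyad = dyad,
                 n_intervals = as.integer(n_intervals),
                 interval_frames = as.integer(interval_frames),
                 lag_max_frames = as.integer(lag_max_frames),
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort of coupled dyads
#'
#' Group labels are allocated exactly by `group_fractions` (`control` first).
#' Each dyad receives a latent coupling strength drawn from its group's
#' Gaussian (floored at 0), a random non-overlapping schedule of coupling
#' intervals with that strength, and integer symptom scores
#' `round(intercept + slope * coupling + noise)` truncated to the PHQ9 range
#' 0-27 and GAD7 range 0-21.
#'
#' @param config a [cohort_config()].
#' @return list with `dyads` (list of `dyad_ts`) and `table` (data frame with
#'   columns `dyad_id`, `group`, `coupling`, `phq9`, `gad7` — the skeleton the
#'   measure battery fills).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_dyads
  if (n < 4) stop("n_dyads must be >= 4")
  n1 <- round(n * config$group_fractions[1])
  group <- rep(c("control", "patient"), c(n1, n - n1))
  withr_seed(config$seed)
  mu <- ifelse(group == "control", config$coupling_mean,
               config$coupling_mean - config$coupling_effect)
  coupling <- pmax(stats::rnorm(n, mu, config$coupling_sd), 0)
  sm <- config$symptom_model
  lin <- sm$intercept + sm$slope * coupling
  phq9 <- pmin(pmax(round(lin + stats::rnorm(n, 0, sm$noise_sd)), 0), 27)
  gad7 <- pmin(pmax(round(lin * 21 / 27 + stats::rnorm(n, 0, sm$noise_sd)), 0), 21)
  sub_seeds <- sample.int(.Machine$integer.max - 3L, n)
  dyads <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- random_schedule(config, coupling[i], sub_seeds[i])
    dyads[[i]] <- generate_coupled_dyad(config$dyad, sched,
                                        seed = sub_seeds[i],
                                        id = sprintf("dyad%02d", i))
  }
  skeleton <- data.frame(dyad_id = vapply(dyads, `[[`, "", "id"),
                         group = group, coupling = coupling,
                         phq9 = as.integer(phq9), gad7 = as.integer(gad7),
                         stringsAsFactors = FALSE)
  list(dyads = dyads, table = skeleton)
}

# non-overlapping random interval schedule; lags drawn uniform in
# [-lag_max, lag_max]; placement by sampling starts on a margin-safe grid
random_schedule <- function(config, beta, seed) {
  withr_seed(seed * 7919 %% .Machine$integer.max)
  L <- config$dyad$length_frames
  m <- config$lag_max_frames
  dur <- config$interval_frames
  k <- config$n_intervals
  if (k < 1 || beta <= 0) return(coupling_interval(1, 2)[0, ])
  # slot the series into k equal blocks and put one interval per block,
  # guaranteeing non-overlap even after lag shift
  usable <- L - 2 * m
  block <- usable %/% k
  if (block <= dur + 2 * m) stop("series too short for requested intervals")
  starts <- m + (seq_len(k) - 1) * block +
    sample.int(block - dur - 2 * m, k, replace = TRUE)
  lags <- sample(seq(-m, m), k, replace = TRUE)
  do.call(rbind, lapply(seq_len(k), function(i) {
    coupling_interval(starts[i], starts[i] + dur, lags[i], beta, 1)
  }))
}

#' Generate a moving-rectangle frame stack
#'
#' Grayscale fixture for the motion-energy stage: a bright square translating
#' horizontally by `step_px` per frame over a black background. The start
#' column is randomized by `seed`; the changed-pixel count between frames is
#' known analytically (symmetric difference of two offset squares).
#'
#' @param height,width frame dimensions in pixels.
#' @param n_frames number of frames.
#' @param object_size side of the bright square in pixels.
#' @param step_px horizontal translation per frame (>= 0).
#' @param seed integer seed (start position only).
#' @param intensity gray value of the square (default 255).
#' @return A `frame_stack` (see [frame_stack()]).
#' @export
generate_frame_stack <- function(height, width, n_frames, object_size,
                                 step_px, seed = 1, intensity = 255) {
  travel <- step_px * (n_frames - 1)
  max_start <- width - object_size + 1 - travel
  if (object_size > height || max_start < 1) {
    stop("object leaves frame: reduce step_px, n_frames or object_size")
  }
  withr_seed(seed)
  col0 <- sample.int(max_start, 1)
  row0 <- if (height > object_size) sample.int(height - object_size + 1, 1) else 1
  frames <- array(0L, dim = c(height, width, n_frames))
  for (f in seq_len(n_frames)) {
    c0 <- col0 + (f - 1) * step_px
    frames[row0:(row0 + object_size - 1), c0:(c0 + object_size - 1), f] <- intensity
  }
  frame_stack(frames, fps = 25)
}
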