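#' Simulation configuration for one synthetic TUG recording
#'
#' The generator emulates the statistical structure a waist-mounted sensor
#' sees during a 3-m out-and-back TUG: quiet sitting, an anterior-posterior
#' hill rising to the first "M" peak over the sit-to-stand transition,
#' step-frequency oscillation in the vertical axis (with per-step timing
#' jitter) and stride-frequency sway in the medial-lateral axis during
#' walking, a second hill with its apex at the start of stand-to-sit, a
#' gravity offset of 1 g on V, and additive Gaussian noise on all axes.
#' Each transition hill is asymmetric (an opposite-sign dip before/after
#' the apex) so that the two-part jerk slopes differ and the transition
#' split point is recoverable.
#'
#' @param rate sampling frequency, Hz.
#' @param rest_pre,rest_post quiet sitting before and after the test, s.
#' @param sist_dur,stsi_dur transition durations, s.
#' @param path_length walked distance, m (3 m out + 3 m back).
#' @param gait_speed walking speed, m/s (walk duration =
#'   `path_length / gait_speed`).
#' @param cadence steps per minute.
#' @param hill_amp_sist,hill_amp_stsi AP hill apex amplitudes, g.
#' @param dip_frac opposite-sign dip amplitude as a fraction of the hill
#'   apex.
#' @param walk_amp_v,walk_amp_ml,walk_amp_ap walking oscillation amplitudes
#'   per axis, g.
#' @param step_jitter_sd SD of per-step duration jitter, s.
#' @param noise_sd additive Gaussian noise SD, g.
#' @param pitch_deg,roll_deg sensor tilt applied to the output (zero =
#'   already gravity-aligned).
#' @param seed optional seed for reproducibility.
#' @return Named list of generator parameters for [simulate_recording()].
#' @export
sim_config <- function(rate = 45, rest_pre = 2, rest_post = 2,
                       sist_dur = 1.5, stsi_dur = 1.8, path_length = 6,
                       gait_speed = 1.0, cadence = 105,
                       hill_amp_sist = 0.35, hill_amp_stsi = 0.30,
                       dip_frac = 0.25, walk_amp_v = 0.25,
                       walk_amp_ml = 0.10, walk_amp_ap = 0.06,
                       step_jitter_sd = 0.015, noise_sd = 0.02,
                       pitch_deg = 0, roll_deg = 0, seed = NULL) {
  cfg <- list(rate = rate, rest_pre = rest_pre, rest_post = rest_post,
              sist_dur = sist_dur, stsi_dur = stsi_dur,
              path_length = path_length, gait_speed = gait_speed,
              cadence = cadence, hill_amp_sist = hill_amp_sist,
              hill_amp_stsi = hill_amp_stsi, dip_frac = dip_frac,
              walk_amp_v = walk_amp_v, walk_amp_ml = walk_amp_ml,
              walk_amp_ap = walk_amp_ap, step_jitter_sd = step_jitter_sd,
              noise_sd = noise_sd, pitch_deg = pitch_deg,
              roll_deg = roll_deg, seed = seed)
  pos <- c("rate", "rest_pre", "rest_post", "sist_dur", "stsi_dur",
           "path_length", "gait_speed", "cadence", "hill_amp_sist",
           "hill_amp_stsi")
  for (f in pos) if (cfg[[f]] <= 0)
    abort_argument(paste(f, "must be positive"))
  cfg
}

# asymmetric SiSt rise on u in [0,1): dip to -dip_amp, then rise to apex
rise_shape <- function(u, amp, dip_amp) {
  ifelse(u < 0.5, -dip_amp * sin(2 * pi * u),
         amp * (1 - cos(2 * pi * (u - 0.5))) / 2)
}

#' Simulate one synthetic TUG recording with ground truth
#'
#' @param config list from [sim_config()].
#' @return Object of class `tug_simulation`: `recording` (an uncalibrated
#'   [tug_recording()]) and `truth`, a list with the landmark indices
#'   `p1..p4` (1-based), landmark times `t1..t4` (s), true step-event times
#'   (s, absolute), the true phase durations and the config used.
#' @export
simulate_recording <- function(config = sim_config()) {
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rate <- cfg$rate
  walk_dur <- cfg$path_length / cfg$gait_speed
  t1 <- cfg$rest_pre
  t2 <- t1 + cfg$sist_dur
  t3 <- t2 + walk_dur
  t4 <- t3 + cfg$stsi_dur
  total <- t4 + cfg$rest_post
  n <- round(total * rate)
  tt <- (seq_len(n) - 1) / rate

  ap <- numeric(n); v <- rep(1, n); ml <- numeric(n)

  # SiSt hill: dip + rise over [t1, t2), apex at t2, 0.5 s decay after
  u <- (tt - t1) / cfg$sist_dur
  in_rise <- u >= 0 & u < 1
  ap[in_rise] <- rise_shape(u[in_rise], cfg$hill_amp_sist,
                            cfg$dip_frac * cfg$hill_amp_sist)
  fall <- 0.5
  vfall <- (tt - t2) / fall
  in_fall <- vfall >= 0 & vfall <= 1
  ap[in_fall] <- ap[in_fall] +
    cfg$hill_amp_sist * (1 + cos(pi * vfall[in_fall])) / 2

  # StSi hill: 0.5 s pre-rise to apex at t3, then decay + opposite dip
  pre <- (t3 - tt) / fall
  in_pre <- pre > 0 & pre <= 1
  ap[in_pre] <- ap[in_pre] +
    cfg$hill_amp_stsi * (1 + cos(pi * pre[in_pre])) / 2
  w <- (tt - t3) / cfg$stsi_dur
  in_dec <- w >= 0 & w < 1
  ap[in_dec] <- ap[in_dec] + ifelse(
    w[in_dec] < 0.5,
    cfg$hill_amp_stsi * (1 + cos(2 * pi * w[in_dec])) / 2,
    -cfg$dip_frac * cfg$hill_amp_stsi * sin(2 * pi * (w[in_dec] - 0.5)))

  # walking: jittered step cycles; one vertical peak per step
  base_step <- 60 / cfg$cadence
  starts <- numeric(); durs <- numeric()
  s <- t2
  while (s + base_step <= t3) {
    d <- max(0.25 * base_step,
             base_step + stats::rnorm(1, 0, cfg$step_jitter_sd))
    if (s + d > t3) break
    starts <- c(starts, s); durs <- c(durs, d)
    s <- s + d
  }
  step_events <- starts + durs / 2
  for (k in seq_along(starts)) {
    seg <- tt >= starts[k] & tt < starts[k] + durs[k]
    uu <- (tt[seg] - starts[k]) / durs[k]
    v[seg] <- v[seg] + cfg$walk_amp_v * (1 - cos(2 * pi * uu)) / 2
    ml[seg] <- ml[seg] + cfg$walk_amp_ml * sin(pi * (k - 1 + uu))
    ap[seg] <- ap[seg] + cfg$walk_amp_ap * sin(2 * pi * uu)
  }

  if (cfg$noise_sd > 0) {
    v <- v + stats::rnorm(n, 0, cfg$noise_sd)
    ml <- ml + stats::rnorm(n, 0, cfg$noise_sd)
    ap <- ap + stats::rnorm(n, 0, cfg$noise_sd)
  }

  samples <- cbind(v, ml, ap)
  if (cfg$pitch_deg != 0 || cfg$roll_deg != 0) {
    # inverse of the calibration rotation: tilt the gravity-aligned signal
    th <- cfg$pitch_deg * pi / 180; ph <- cfg$roll_deg * pi / 180
    Rp <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
    Rr <- rbind(c(cos(ph), sin(ph), 0), c(-sin(ph), cos(ph), 0), c(0, 0, 1))
    samples <- samples %*% (Rr %*% Rp)   # rows right-multiplied: x -> (RrRp)^T x
  }

  idx <- function(t) round(t * rate) + 1L
  truth <- list(p1 = idx(t1), p2 = idx(t2), p3 = idx(t3), p4 = idx(t4),
                t1 = t1, t2 = t2, t3 = t3, t4 = t4,
                step_events = step_events, n_steps = length(step_events),
                durations = list(tug = t4 - t1, sist = cfg$sist_dur,
                                 walk = walk_dur, stsi = cfg$stsi_dur),
                config = cfg)
  structure(list(recording = tug_recording(samples, rate,
                                           calibrated = FALSE),
                 truth = truth),
            class = "tug_simulation")
}

#' @export
print.tug_simulation <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "<tug_simulation> TUG %.2f s (SiSt %.2f, walk %.2f, StSi %.2f), %d steps\n",
    tr$durations$tug, tr$durations$sist, tr$durations$walk,
    tr$durations$stsi, tr$n_steps))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' A latent balance ability b ~ Normal(latent_mean, latent_sd) per
#' participant jointly drives gait parameters (monotone linkages: higher
#' balance means faster gait, higher cadence, less step-timing jitter,
#' quicker postural transitions) and the seven ordinal SFBBS item scores,
#' obtained by thresholding b plus item noise onto {0, 2, 4}. Item
#' difficulties are graded so early items are easy and the feet-in-line /
#' single-leg items are hard. Demographics mimic a community-dwelling
#' elderly cohort (age ~ Normal(72, 7), truncated at 65; about 79% women).
#'
#' @param n cohort size (default 85, a typical single-site study).
#' @param latent_mean,latent_sd latent balance distribution.
#' @param item_noise_sd SD of the per-item noise added to b before
#'   thresholding.
#' @param item_centers length-7 vector of item difficulty centers on the
#'   latent scale; score thresholds are `center - gap` and `center + gap`.
#' @param gap half-distance between the 0/2 and 2/4 thresholds.
#' @param speed_slope,cadence_slope,jitter_slope,sist_slope,stsi_slope
#'   linkage coefficients from latent balance to the generator parameters.
#' @param noise_sd recording noise SD, g.
#' @param max_tilt_deg per-participant sensor tilt is drawn uniformly in
#'   `[-max_tilt_deg, max_tilt_deg]` for pitch and roll.
#' @param seed master seed.
#' @return Named list for [simulate_cohort()].
#' @export
cohort_config <- function(n = 85, latent_mean = 0, latent_sd = 1,
                          item_noise_sd = 0.6,
                          item_centers = c(-1.6, -2.6, -0.2, -0.8, -1.2,
                                           0.2, 0.7),
                          gap = 0.8,
                          speed_slope = 0.22, cadence_slope = 7,
                          jitter_slope = 0.008, sist_slope = 0.18,
                          stsi_slope = 0.2, noise_sd = 0.02,
                          max_tilt_deg = 5, seed = 1) {
  if (n < 2) abort_argument("cohort needs at least 2 participants")
  if (length(item_centers) != 7) abort_argument("need 7 item centers")
  as.list(environment())
}

#' Simulate a cohort of participants with known ground truth
#'
#' @param config list from [cohort_config()].
#' @return Object of class `tug_cohort`: `participants` (list of
#'   [participant_record()]s with uncalibrated recordings) and `truth`
#'   (data.frame of the hidden latent balance and all generative
#'   parameters, one row per participant).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n
  b <- stats::rnorm(n, cfg$latent_mean, cfg$latent_sd)
  if (stats::sd(b) < 1e-12)
    warning("degenerate linkage: latent balance identical across cohort")
  age <- pmin(pmax(round(72.12 + 6.99 *
                           (-0.3 * scale_safe(b) +
                              sqrt(0.91) * stats::rnorm(n))), 65), 109)
  gender <- stats::rbinom(n, 1, 0.79)
  rec_seeds <- sample.int(2^31 - 2, n)
  item_noise <- matrix(stats::rnorm(n * 7, 0, cfg$item_noise_sd), n, 7)
  tilt <- matrix(stats::runif(n * 2, -cfg$max_tilt_deg, cfg$max_tilt_deg),
                 n, 2)

  participants <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    speed <- clamp(1.0 + cfg$speed_slope * b[i], 0.4, 1.6)
    cad <- clamp(105 + cfg$cadence_slope * b[i], 70, 140)
    jit <- clamp(0.02 - cfg$jitter_slope * b[i], 0.004, 0.05)
    sist <- clamp(1.5 - cfg$sist_slope * b[i], 0.8, 2.8)
    stsi <- clamp(1.8 - cfg$stsi_slope * b[i], 0.9, 3.2)
    sim <- simulate_recording(sim_config(
      gait_speed = speed, cadence = cad, step_jitter_sd = jit,
      sist_dur = sist, stsi_dur = stsi, noise_sd = cfg$noise_sd,
      pitch_deg = tilt[i, 1], roll_deg = tilt[i, 2],
      seed = rec_seeds[i]))
    z <- b[i] + item_noise[i, ]
    items <- ifelse(z < cfg$item_centers - cfg$gap, 0,
                    ifelse(z < cfg$item_centers + cfg$gap, 2, 4))
    sf <- sfbbs_record(items)
    id <- sprintf("P%03d", i)
    participants[[i]] <- participant_record(id, age[i], gender[i],
                                            sim$recording, sf)
    rows[[i]] <- data.frame(id = id, b = b[i], age = age[i],
                            gender = gender[i], gait_speed = speed,
                            cadence = cad, step_jitter_sd = jit,
                            sist_dur = sist, stsi_dur = stsi,
                            sfbbs_total = sf$total,
                            t(stats::setNames(items, paste0("item", 1:7))),
                            stringsAsFactors = FALSE)
  }
  structure(list(participants = participants,
                 truth = do.call(rbind, rows), config = cfg),
            class = "tug_cohort")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
}

#' @export
print.tug_cohort <- function(x, ...) {
  cat(sprintf(
    "<tug_cohort> %d participants, SFBBS total %d-%d (mean %.1f), seed %d\n",
    length(x$participants), min(x$truth$sfbbs_total),
    max(x$truth$sfbbs_total), mean(x$truth$sfbbs_total), x$config$seed))
  invisible(x)
}
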