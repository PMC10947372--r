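#' Default scene geometry
#'
#' Lays out a supine body seen from a ceiling-mounted depth sensor:
#' static upper-body and lower-body polygons, nominal head and hand
#' boxes (the dynamic tracker jitters around these), and a chest patch
#' that carries the respiration oscillation. All regions scale with the
#' frame size so that scenes can be rendered at reduced resolution.
#'
#' @param width,height Frame size in pixels (nominally 512 x 424).
#' @return List with an [roi_layout()] plus `head_box`, `hand_boxes`
#'   (list of two), and `chest_box`, each `c(x, y, w, h)`.
#' @export
default_scene_geometry <- function(width = 512, height = 424) {
  w <- width; h <- height
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  # body occupies the central column; upper body = top 45% of rows,
  # lower body = bottom 35%, separated by a hip gap.
  upper <- rect(0.25 * w, 0.05 * h, 0.75 * w, 0.50 * h)
  lower <- rect(0.25 * w, 0.60 * h, 0.75 * w, 0.95 * h)
  layout <- roi_layout(upper, lower, width = w, height = h)
  list(
    layout = layout,
    head_box  = c(0.42 * w, 0.06 * h, 0.16 * w, 0.12 * h),
    hand_boxes = list(c(0.27 * w, 0.30 * h, 0.10 * w, 0.08 * h),
                      c(0.63 * w, 0.30 * h, 0.10 * w, 0.08 * h)),
    chest_box = c(0.38 * w, 0.22 * h, 0.24 * w, 0.14 * h)
  )
}

#' Synthetic scene configuration
#'
#' Parameters of the rendered depth scene. Distances are millimetres
#' from the sensor: the mattress plane sits at `bed_depth` and the body
#' surface `body_depth_offset` closer to the camera. Event and noise
#' magnitudes are plausible for a Kinect-v2-class time-of-flight sensor
#' and are fully configurable.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param fps Frame rate, frames per second.
#' @param bed_depth Sensor-to-mattress distance, mm.
#' @param body_depth_offset Body surface elevation above the mattress, mm.
#' @param respiration_amplitude Peak chest displacement, mm.
#' @param respiration_freq Breathing frequency, Hz (must lie in
#'   (0.05, 1.0)).
#' @param noise_sigma Per-pixel Gaussian sensor noise SD, mm.
#' @param event_displacement Depth displacement of a moving patch, mm.
#' @param roi_geometry Geometry as from [default_scene_geometry()].
#' @param track_dropout_prob Probability that the head (resp. hand pair)
#'   box is missing from the track output in a given frame.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(frame_width = 512, frame_height = 424, fps = 30,
                         bed_depth = 2600, body_depth_offset = 350,
                         respiration_amplitude = 4, respiration_freq = 0.25,
                         noise_sigma = 5, event_displacement = 50,
                         roi_geometry = default_scene_geometry(frame_width,
                                                               frame_height),
                         track_dropout_prob = 0) {
  assert_that(fps > 0, "fps must be > 0")
  assert_that(frame_width > 0 && frame_height > 0, "frame dims must be > 0")
  assert_that(respiration_freq > 0.05 && respiration_freq < 1.0,
              "respiration_freq must lie in (0.05, 1.0) Hz")
  assert_that(track_dropout_prob >= 0 && track_dropout_prob <= 1,
              "track_dropout_prob must lie in [0, 1]")
  assert_that(body_depth_offset >= 0 && bed_depth <= 8000,
              "depth geometry out of range")
  structure(list(frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height), fps = fps,
                 bed_depth = bed_depth,
                 body_depth_offset = body_depth_offset,
                 respiration_amplitude = respiration_amplitude,
                 respiration_freq = respiration_freq,
                 noise_sigma = noise_sigma,
                 event_displacement = event_displacement,
                 roi_geometry = roi_geometry,
                 track_dropout_prob = track_dropout_prob),
            class = "scene_config")
}

#' Generate a synthetic hypnogram
#'
#' Builds a 30-s epoch sequence over stages W/N1/N2/N3/R with a
#' requested amount of REM split into a requested number of contiguous
#' REM periods, roughly evenly spaced through the night (emulating
#' ultradian cycling). Non-REM epochs are drawn from a fixed realistic
#' stage mix.
#'
#' @param total_min Night length in minutes (>= 30).
#' @param rem_fraction Fraction of the night spent in REM (0 to < 0.5).
#' @param n_rem_periods Number of contiguous REM blocks.
#' @param seed RNG seed.
#' @return A [hypnogram()]; total R time is within one epoch of
#'   `total_min * rem_fraction` and R epochs form exactly
#'   `n_rem_periods` blocks (when `rem_fraction > 0`).
#' @export
generate_hypnogram <- function(total_min, rem_fraction, n_rem_periods = 4,
                               seed = 1) {
  assert_that(total_min >= 30, "total_min must be >= 30")
  assert_that(rem_fraction >= 0 && rem_fraction < 0.5,
              "rem_fraction must lie in [0, 0.5)")
  n_epochs <- as.integer(round(total_min * 2))
  n_r <- as.integer(round(n_epochs * rem_fraction))
  if (n_r == 0L) {
    return(with_local_seed(seed, hypnogram(
      sample(c("W", "N1", "N2", "N3"), n_epochs, replace = TRUE,
             prob = c(0.08, 0.10, 0.52, 0.30)))))
  }
  assert_that(n_rem_periods >= 1, "n_rem_periods must be >= 1")
  if (n_r < n_rem_periods)
    stop_rbd("requested REM time too small for ", n_rem_periods, " periods")
  # block sizes near-equal; gaps need at least one non-R epoch
  sizes <- rep(n_r %/% n_rem_periods, n_rem_periods)
  extra <- n_r - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  n_other <- n_epochs - n_r
  if (n_other < n_rem_periods - 1L)
    stop_rbd("infeasible: REM blocks longer than the night allows")
  with_local_seed(seed, {
    # split non-R epochs into n_rem_periods + 1 gaps (interior gaps >= 1)
    k <- n_rem_periods + 1L
    interior <- k - 2L
    free <- n_other - interior
    cuts <- if (k > 1L) sort(sample.int(free + k - 1L, k - 1L)) else integer()
    gaps <- diff(c(0L, cuts, free + k)) - 1L
    if (interior > 0L) gaps[2:(k - 1L)] <- gaps[2:(k - 1L)] + 1L
    stages <- character(0)
    nrem_mix <- function(n) sample(c("W", "N1", "N2", "N3"), n, replace = TRUE,
                                   prob = c(0.08, 0.10, 0.52, 0.30))
    for (b in seq_len(n_rem_periods)) {
      stages <- c(stages, nrem_mix(gaps[b]), rep("R", sizes[b]))
    }
    stages <- c(stages, nrem_mix(gaps[k]))
    hypnogram(stages)
  })
}

# normalise rate input to a data.frame(roi, bin, rate)
as_rate_table <- function(rates) {
  if (is.data.frame(rates)) {
    assert_that(all(c("roi", "bin", "rate") %in% names(rates)),
                "rates data frame needs roi, bin, rate columns")
    return(rates)
  }
  # named list: rates$lower_body$short etc.
  out <- do.call(rbind, lapply(names(rates), function(r) {
    data.frame(roi = r, bin = names(rates[[r]]),
               rate = unlist(rates[[r]], use.names = FALSE))
  }))
  out
}

#' Plant ground-truth movement events
#'
#' Draws, per ROI and duration bin, a homogeneous Poisson number of
#' events over the REM time of the hypnogram, places them uniformly
#' inside REM intervals with durations drawn inside the bin, and
#' enforces a minimum inter-event gap per ROI so that planted events can
#' never be fused by the 1-s merge rule.
#'
#' @param hypno A [hypnogram()].
#' @param rates Events per hour of REM, either a data frame
#'   `(roi, bin, rate)` or a nested named list `rates$roi$bin`.
#' @param durations Named list of `c(min, max)` duration ranges (s) per
#'   bin, drawn uniformly; defaults stay clear of the bin edges.
#' @param min_gap_s Minimum gap between events of the same ROI (> 1 s).
#' @param seed RNG seed.
#' @return Data frame `(roi, start_s, end_s, bin, in_rem)` sorted by
#'   ROI and onset; the retained ground truth.
#' @export
plant_events <- function(hypno, rates,
                         durations = list(short = c(0.3, 1.8),
                                          medium = c(2.5, 12),
                                          long = c(16, 60)),
                         min_gap_s = 2, seed = 1) {
  assert_that(min_gap_s > 1.0, "min_gap_s must be > 1 s (merge rule)")
  rt <- as_rate_table(rates)
  assert_that(all(rt$rate >= 0), "rates must be >= 0")
  ri <- rem_intervals(hypno)
  rh <- rem_hours(hypno)
  if (rh == 0 && any(rt$rate > 0))
    stop_rbd("cannot plant events: hypnogram has no REM sleep")
  with_local_seed(seed, {
    out <- list()
    for (roi in unique(rt$roi)) {
      sub <- rt[rt$roi == roi & rt$rate > 0, , drop = FALSE]
      if (nrow(sub) == 0L) next
      # draw counts and durations per bin, then place jointly per ROI
      durs <- numeric(0); bins <- character(0)
      for (i in seq_len(nrow(sub))) {
        n_i <- stats::rpois(1L, sub$rate[i] * rh)
        if (n_i == 0L) next
        rng <- durations[[sub$bin[i]]]
        assert_that(!is.null(rng), paste("no duration range for bin",
                                         sub$bin[i]))
        durs <- c(durs, stats::runif(n_i, rng[1], rng[2]))
        bins <- c(bins, rep(sub$bin[i], n_i))
      }
      if (length(durs) == 0L) next
      if (sum(durs + min_gap_s) > 0.9 * rh * 3600)
        stop_rbd("requested intensity too high to respect min_gap in ", roi)
      placed <- place_in_rem(durs, ri, min_gap_s, max_tries = 200L)
      if (is.null(placed))
        stop_rbd("could not place events with min_gap in ", roi,
                 "; requested intensity too high")
      out[[roi]] <- data.frame(roi = roi, start_s = placed,
                               end_s = placed + durs, bin = bins,
                               in_rem = TRUE)
    }
    if (length(out) == 0L)
      return(data.frame(roi = character(), start_s = numeric(),
                        end_s = numeric(), bin = character(),
                        in_rem = logical()))
    ev <- do.call(rbind, out)
    ev <- ev[order(ev$roi, ev$start_s), ]
    rownames(ev) <- NULL
    ev
  })
}

# rejection-sample onsets so each event fits inside one REM interval and
# same-ROI events are separated by more than min_gap_s
place_in_rem <- function(durs, ri, min_gap_s, max_tries = 200L) {
  lens <- ri$end_s - ri$start_s
  total <- sum(lens)
  cum <- cumsum(c(0, lens))
  ord <- order(-durs)  # place long events first
  for (try in seq_len(max_tries)) {
    starts <- rep(NA_real_, length(durs))
    ok <- TRUE
    for (j in ord) {
      placed_j <- FALSE
      for (attempt in seq_len(200L)) {
        u <- stats::runif(1, 0, total)
        k <- findInterval(u, cum, rightmost.closed = TRUE)
        s <- ri$start_s[k] + (u - cum[k])
        if (s + durs[j] > ri$end_s[k]) next
        prev <- which(!is.na(starts))
        if (length(prev)) {
          ps <- starts[prev]; pe <- ps + durs[prev]
          conflict <- !(pe + min_gap_s <= s | s + durs[j] + min_gap_s <= ps)
          if (any(conflict)) next
        }
        starts[j] <- s
        placed_j <- TRUE
        break
      }
      if (!placed_j) { ok <- FALSE; break }
    }
    if (ok) return(starts)
  }
  NULL
}

#' Render a synthetic depth video with tracker output
#'
#' Draws the static scene (mattress at `bed_depth`, body polygons
#' elevated by `body_depth_offset`), superimposes a sinusoidal chest
#' oscillation, displaces the patch of each planted event towards the
#' camera for the event's duration, adds white sensor noise, and emits
#' per-frame head/hand boxes with Bernoulli dropouts.
#'
#' During an event the displaced patch alternates between the full and
#' half displacement on consecutive frames: a moving body part changes
#' the depth map from frame to frame, whereas a statically held offset
#' would be invisible to frame differencing except at its edges.
#'
#' @param events Planted events from [plant_events()] (may be empty).
#' @param hypno A [hypnogram()] defining the clip length
#'   (unless `duration_s` is given).
#' @param scene A [scene_config()].
#' @param seed RNG seed (noise and track dropouts).
#' @param duration_s Optional clip length override in seconds.
#' @return List with `seq` (a [depth_sequence()]) and `tracks`
#'   (a [track_set()]).
#' @export
render_depth_video <- function(events, hypno, scene, seed = 1,
                               duration_s = NULL) {
  assert_that(inherits(scene, "scene_config"), "scene must be a scene_config")
  dur <- duration_s %||% (length(hypno$stages) * hypno$epoch_len_s)
  nf <- as.integer(round(dur * scene$fps))
  w <- scene$frame_width; h <- scene$frame_height
  geo <- scene$roi_geometry
  if (nrow(events) > 0 && any(events$end_s > dur + 1e-9))
    stop_rbd("event extends beyond the rendered clip")
  body_mask <- geo$layout$masks$upper_body | geo$layout$masks$lower_body
  chest <- box_mask(geo$chest_box, w, h)
  patch_for_roi <- function(roi) {
    switch(roi,
      lower_body = geo$layout$masks$lower_body,
      upper_body = geo$layout$masks$upper_body &
        !box_mask(geo$head_box, w, h) &
        !(box_mask(geo$hand_boxes[[1]], w, h) |
          box_mask(geo$hand_boxes[[2]], w, h)),
      head = box_mask(geo$head_box, w, h),
      hands = box_mask(geo$hand_boxes[[1]], w, h) |
        box_mask(geo$hand_boxes[[2]], w, h),
      stop_rbd("unknown roi: ", roi))
  }
  rois_present <- unique(events$roi)
  patches <- lapply(stats::setNames(rois_present, rois_present),
                    patch_for_roi)
  base <- matrix(scene$bed_depth, nrow = h, ncol = w)
  base[body_mask] <- scene$bed_depth - scene$body_depth_offset
  with_local_seed(seed, {
    frames <- array(0L, dim = c(h, w, nf))
    # precompute per-frame active events: list of (roi, start frame)
    ev_fr <- NULL
    if (nrow(events) > 0) {
      ev_fr <- data.frame(roi = events$roi,
                          f0 = as.integer(floor(events$start_s * scene$fps)),
                          f1 = as.integer(ceiling(events$end_s * scene$fps)))
      ev_fr$f1 <- pmin(ev_fr$f1, nf)
      if (any(ev_fr$f0 < 0)) stop_rbd("event starts before clip start")
    }
    for (t in seq_len(nf)) {
      fr <- base
      resp <- scene$respiration_amplitude *
        sin(2 * pi * scene$respiration_freq * (t - 1L) / scene$fps)
      fr[chest] <- fr[chest] - resp
      if (!is.null(ev_fr)) {
        act <- which(ev_fr$f0 <= (t - 1L) & (t - 1L) < ev_fr$f1)
        for (i in act) {
          # frame-to-frame jitter: full vs half displacement
          d <- scene$event_displacement *
            if ((t - 1L - ev_fr$f0[i]) %% 2L == 0L) 1 else 0.5
          p <- patches[[ev_fr$roi[i]]]
          fr[p] <- fr[p] - d
        }
      }
      if (scene$noise_sigma > 0)
        fr <- fr + matrix(stats::rnorm(h * w, 0, scene$noise_sigma), h, w)
      frames[, , t] <- pmax(0L, pmin(8000L, as.integer(round(fr))))
    }
    # tracker output: nominal boxes with per-frame Bernoulli dropout;
    # head and the hand pair drop out independently
    head_ok <- stats::runif(nf) >= scene$track_dropout_prob
    hands_ok <- stats::runif(nf) >= scene$track_dropout_prob
    hb <- geo$head_box
    h1 <- geo$hand_boxes[[1]]; h2 <- geo$hand_boxes[[2]]
    tr <- rbind(
      data.frame(frame = 0:(nf - 1L), roi = "head", x = hb[1], y = hb[2],
                 w = hb[3], h = hb[4], valid = head_ok),
      data.frame(frame = 0:(nf - 1L), roi = "hands", x = h1[1], y = h1[2],
                 w = h1[3], h = h1[4], valid = hands_ok),
      data.frame(frame = 0:(nf - 1L), roi = "hands", x = h2[1], y = h2[2],
                 w = h2[3], h = h2[4], valid = hands_ok))
    list(seq = depth_sequence(frames, fps = scene$fps, start_time = 0),
         tracks = track_set(tr))
  })
}

#' Reference cohort feature calibration
#'
#' Group-level calibration of the 3D-rate and 3D-ratio features per ROI
#' and duration bin, as median and interquartile range, for the iRBD and
#' no-RBD groups of a published 181-subject clinical v-PSG cohort
#' (53 iRBD vs 128 no-RBD). These values are the default targets of the
#' synthetic cohort sampler.
#'
#' @return Data frame with columns `group`, `roi` (`HE`, `HAs`, `UB`,
#'   `LB`), `bin`, `feature` (`rate`/`ratio`), `median`, `q25`, `q75`.
#' @export
cohort_reference <- function() {
  tab <- rbind(
    # roi, bin, feature, irbd med/q25/q75, norbd med/q25/q75
    c("HE", "short",  "rate",  15.85,  9.17,  30.17,  7.46, 2.91, 11.71),
    c("HE", "short",  "ratio", 12.02,  8.00,  19.91,  6.17, 2.51,  9.90),
    c("HE", "medium", "rate",   5.43,  3.18,   8.01,  4.05, 1.43,  6.48),
    c("HE", "medium", "ratio", 25.80, 13.27,  34.59, 21.10, 5.31, 33.76),
    c("HE", "long",   "rate",   0,     0,      0,     0,    0,     0),
    c("HE", "long",   "ratio",  0,     0,      0,     0,    0,     0),
    c("HAs", "short",  "rate",  17.38,  6.63,  33.32,  7.19, 2.37, 15.33),
    c("HAs", "short",  "ratio", 13.52,  4.77,  27.41,  5.01, 1.52, 11.82),
    c("HAs", "medium", "rate",   3.96,  1.37,  11.97,  1.55, 0,     5.86),
    c("HAs", "medium", "ratio", 14.43,  4.64,  41.96,  5.03, 0,    21.81),
    c("HAs", "long",   "rate",   0,     0,      0,     0,    0,     0),
    c("HAs", "long",   "ratio",  0,     0,      0,     0,    0,     0),
    c("UB", "short",  "rate",  31.88, 18.65,  82.10,  9.64, 4.44, 14.96),
    c("UB", "short",  "ratio", 26.67, 12.34,  53.09,  7.69, 3.26, 11.63),
    c("UB", "medium", "rate",   9.80,  5.60,  16.49,  5.11, 2.37,  9.85),
    c("UB", "medium", "ratio", 50.19, 28.69,  75.82, 30.28, 12.31, 56.79),
    c("UB", "long",   "rate",   0.47,  0,      1.69,  0,    0,     1.14),
    c("UB", "long",   "ratio",  9.72,  0,     32.37,  0,    0,    19.36),
    c("LB", "short",  "rate",  44.12, 32.93,  63.73, 10.90, 5.94, 19.17),
    c("LB", "short",  "ratio", 50.03, 38.43,  77.06, 12.45, 6.54, 21.24),
    c("LB", "medium", "rate",  51.75, 34.57,  82.24, 16.01, 10.10, 25.01),
    c("LB", "medium", "ratio", 247.5, 154.8, 379.59, 81.71, 45.67, 124.39),
    c("LB", "long",   "rate",   2.23,  0.38,   4.34,  0.94, 0,     2.23),
    c("LB", "long",   "ratio", 45.34,  7.38,  98.07, 17.88, 0,    49.00))
  base <- data.frame(roi = tab[, 1], bin = tab[, 2], feature = tab[, 3],
                     stringsAsFactors = FALSE)
  irbd <- cbind(group = "iRBD", base,
                median = as.numeric(tab[, 4]), q25 = as.numeric(tab[, 5]),
                q75 = as.numeric(tab[, 6]))
  norbd <- cbind(group = "no-RBD", base,
                 median = as.numeric(tab[, 7]), q25 = as.numeric(tab[, 8]),
                 q75 = as.numeric(tab[, 9]))
  rbind(irbd, norbd)
}

#' Cohort sampling specification
#'
#' Validates per-cell calibration and attaches per-group sample sizes
#' and zero-inflation probabilities. Each cell (group x ROI x bin x
#' feature) is sampled as zero with probability `zero_inflation`,
#' otherwise from a log-normal matched to the printed median and
#' quartile ratio (see [sample_cohort_features()]).
#'
#' @param cells Data frame as [cohort_reference()] (columns `group`,
#'   `roi`, `bin`, `feature`, `median`, `q25`, `q75`, optionally
#'   `zero_inflation`).
#' @param n Named integer vector of subjects per group,
#'   e.g. `c("iRBD" = 53, "no-RBD" = 128)`.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells = cohort_reference(),
                        n = c("iRBD" = 53, "no-RBD" = 128)) {
  need <- c("group", "roi", "bin", "feature", "median", "q25", "q75")
  assert_that(all(need %in% names(cells)),
              paste("cells need columns:", paste(need, collapse = ", ")))
  assert_that(all(cells$q25 <= cells$median & cells$median <= cells$q75),
              "each cell must satisfy q25 <= median <= q75")
  if (!"zero_inflation" %in% names(cells)) {
    cells$zero_inflation <- NA_real_
  }
  explicit <- !is.na(cells$zero_inflation)
  if (any(explicit & cells$median == 0 & cells$zero_inflation < 0.5))
    stop_rbd("median 0 requires zero_inflation >= 0.5 ",
             "(a log-normal cannot reach median 0)")
  assert_that(all(!explicit | (cells$zero_inflation >= 0 &
                               cells$zero_inflation <= 1)),
              "zero_inflation must lie in [0, 1]")
  # default zero inflation by cell degeneracy
  zi <- cells$zero_inflation
  zi[!explicit & cells$median == 0] <- 0.6
  zi[!explicit & cells$median > 0 & cells$q25 == 0] <- 0.3
  zi[!explicit & cells$q25 > 0] <- 0
  cells$zero_inflation <- zi
  assert_that(all(names(n) %in% cells$group) && all(n >= 1),
              "n must name groups present in cells")
  structure(list(cells = cells, n = n), class = "cohort_spec")
}

# log-normal parameters for the non-zero part of one cell.
# Regular cells (q25 > 0): location ln(median), scale ln(q75/q25)/(2*z75)
# with z75 = qnorm(0.75) = 0.67449. Degenerate cells use documented
# fallback conventions (see vignette).
cell_lognormal <- function(median, q25, q75) {
  z75 <- stats::qnorm(0.75)
  if (q25 > 0) {
    list(meanlog = log(median), sdlog = log(q75 / q25) / (2 * z75))
  } else if (median > 0) {
    list(meanlog = log(median), sdlog = log(q75 / median) / z75)
  } else if (q75 > 0) {
    list(meanlog = log(q75), sdlog = 0.75)
  } else {
    list(meanlog = log(0.5), sdlog = 0.75)
  }
}

#' Sample a synthetic cohort feature table
#'
#' Draws per-subject feature values cell by cell: exact zero with the
#' cell's zero-inflation probability, otherwise log-normal with location
#' `ln(median)` and scale `ln(q75/q25) / (2 * 0.67449)` (quantile
#' matching of the printed median and interquartile range). Cells are
#' drawn independently unless a shared per-subject severity factor is
#' requested, which multiplies all of a subject's non-zero values by a
#' common log-normal factor (inducing positive cross-cell correlation).
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed.
#' @param severity_sdlog SD (log scale) of the optional shared
#'   per-subject severity factor; 0 (default) disables it.
#' @return Wide data frame: `subject_id`, `group`, then 24 feature
#'   columns named `{roi}_{bin}_{rate|ratio}` (e.g. `LB_short_rate`).
#' @export
sample_cohort_features <- function(spec, seed = 1, severity_sdlog = 0) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  cells <- spec$cells
  with_local_seed(seed, {
    rows <- list()
    sid <- 0L
    for (g in names(spec$n)) {
      gc <- cells[cells$group == g, , drop = FALSE]
      ng <- spec$n[[g]]
      sev <- if (severity_sdlog > 0)
        stats::rlnorm(ng, -severity_sdlog^2 / 2, severity_sdlog)
      else rep(1, ng)
      vals <- matrix(0, nrow = ng, ncol = nrow(gc))
      colnames(vals) <- paste(gc$roi, gc$bin, gc$feature, sep = "_")
      for (j in seq_len(nrow(gc))) {
        par <- cell_lognormal(gc$median[j], gc$q25[j], gc$q75[j])
        nonzero <- stats::runif(ng) >= gc$zero_inflation[j]
        v <- numeric(ng)
        v[nonzero] <- stats::rlnorm(sum(nonzero), par$meanlog, par$sdlog) *
          sev[nonzero]
        vals[, j] <- v
      }
      rows[[g]] <- data.frame(
        subject_id = sprintf("S%03d", sid + seq_len(ng)),
        group = g, vals, check.names = FALSE)
      sid <- sid + ng
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
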