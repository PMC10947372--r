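#' Movement detector parameters
#'
#' Thresholds of the frame-differencing movement detector. The original
#' clinical pipeline's internal thresholds are not published; these
#' defaults are configurable reconstructions.
#'
#' @param pixel_delta_mm Minimum per-pixel depth change between
#'   consecutive frames to count the pixel as changed, mm.
#' @param min_area_px Minimum changed-pixel count per ROI per frame for
#'   the frame to be flagged; a named vector over
#'   `head`, `hands`, `upper_body`, `lower_body`.
#' @param resp_band_hz Respiration frequency band `c(low, high)` in Hz
#'   targeted by the suppression filter.
#' @param resp_suppress Whether to suppress periodic respiration
#'   components from the per-ROI changed-area signals.
#' @param median_window Odd window (frames) of a running-median impulse
#'   rejector applied to the area signals after suppression; removes
#'   isolated single-frame spikes (sensor glitches, quantisation jitter
#'   at respiration threshold crossings) while leaving runs of two or
#'   more frames untouched. 1 disables it.
#' @return Object of class `detector_params`.
#' @export
detector_params <- function(pixel_delta_mm = 10,
                            min_area_px = c(head = 20, hands = 20,
                                            upper_body = 50,
                                            lower_body = 50),
                            resp_band_hz = c(0.15, 0.5),
                            resp_suppress = TRUE,
                            median_window = 3L) {
  assert_that(pixel_delta_mm > 0, "pixel_delta_mm must be > 0")
  rois <- c("head", "hands", "upper_body", "lower_body")
  if (length(min_area_px) == 1L && is.null(names(min_area_px)))
    min_area_px <- stats::setNames(rep(min_area_px, 4), rois)
  assert_that(all(rois %in% names(min_area_px)) && all(min_area_px >= 1),
              "min_area_px must cover all four ROIs with values >= 1")
  assert_that(length(resp_band_hz) == 2 && resp_band_hz[1] > 0 &&
              resp_band_hz[1] < resp_band_hz[2],
              "resp_band_hz must be c(low, high) with 0 < low < high")
  assert_that(median_window >= 1 && median_window %% 2 == 1,
              "median_window must be an odd positive integer")
  structure(list(pixel_delta_mm = pixel_delta_mm,
                 min_area_px = min_area_px[rois],
                 resp_band_hz = resp_band_hz,
                 resp_suppress = isTRUE(resp_suppress),
                 median_window = as.integer(median_window)),
            class = "detector_params")
}

#' Frame differencing
#'
#' Marks, for every consecutive frame pair, the pixels whose depth
#' changed by more than `pixel_delta_mm`. Raster `t` (1-based) compares
#' frames `t` and `t + 1` and is attributed to the arrival frame
#' `t + 1` downstream.
#'
#' @param seq A [depth_sequence()] with at least two frames.
#' @param pixel_delta_mm Per-pixel change threshold, mm.
#' @return Logical array `H x W x (n_frames - 1)`. For long sequences
#'   prefer [detect_motion()], which streams instead of materialising
#'   all rasters.
#' @export
frame_difference <- function(seq, pixel_delta_mm = 10) {
  assert_that(inherits(seq, "depth_sequence"), "seq must be a depth_sequence")
  nf <- n_frames(seq)
  if (nf < 2L) stop_rbd("need at least 2 frames to difference")
  d <- dim(seq$frames)
  out <- array(FALSE, dim = c(d[1], d[2], nf - 1L))
  for (t in seq_len(nf - 1L)) {
    out[, , t] <- abs(seq$frames[, , t + 1L] - seq$frames[, , t]) >
      pixel_delta_mm
  }
  out
}

#' Effective per-frame ROI masks
#'
#' Resolves the precedence rule between the static layout and the
#' dynamic head/hand tracker: when head/hand boxes are validly detected
#' in a frame, their pixels are claimed by the head/hands ROIs and
#' removed from the upper-body mask; when the tracker misses them, their
#' movements fall back to the upper-body ROI. The lower-body mask is
#' static. Every pixel belongs to at most one ROI.
#'
#' @param layout An [roi_layout()].
#' @param tracks A [track_set()].
#' @param frame 0-based frame index.
#' @return Named list of four logical `H x W` masks
#'   (`head`, `hands`, `upper_body`, `lower_body`).
#' @export
effective_masks <- function(layout, tracks, frame) {
  assert_that(inherits(layout, "roi_layout"), "layout must be an roi_layout")
  w <- layout$width; h <- layout$height
  boxes <- tracks_at_frame(tracks, frame)
  head_mask <- matrix(FALSE, h, w)
  if (nrow(boxes$head)) {
    for (i in seq_len(nrow(boxes$head)))
      head_mask <- head_mask | box_mask(boxes$head[i, ], w, h)
  }
  hands_mask <- matrix(FALSE, h, w)
  if (nrow(boxes$hands)) {
    for (i in seq_len(nrow(boxes$hands)))
      hands_mask <- hands_mask | box_mask(boxes$hands[i, ], w, h)
  }
  hands_mask <- hands_mask & !head_mask  # head box wins overlaps
  upper <- layout$masks$upper_body & !head_mask & !hands_mask
  list(head = head_mask, hands = hands_mask,
       upper_body = upper, lower_body = layout$masks$lower_body)
}

#' Suppress periodic respiration from an area signal
#'
#' Removes narrowband periodic content from a per-ROI changed-area
#' signal while preserving broadband movement transients. The dominant
#' frequency inside `resp_band_hz` is located by fine-grid periodogram
#' maximisation (refined with golden-section search), and a least-squares
#' harmonic fit (fundamental plus harmonics up to the Nyquist limit) is
#' subtracted. A stationary in-band sinusoid is
#' attenuated essentially completely (>= 20 dB); a 1-s rectangular pulse
#' projects onto the harmonic basis only weakly and keeps >= 70% of its
#' peak.
#'
#' @param x Numeric per-frame area signal (length >= 4 s of frames).
#' @param fps Sampling rate of `x`, frames per second.
#' @param resp_band_hz `c(low, high)` band in Hz; `high` must be below
#'   the Nyquist frequency `fps / 2`.
#' @return Filtered signal, same length as `x`.
#' @export
respiration_suppress <- function(x, fps, resp_band_hz = c(0.15, 0.5)) {
  n <- length(x)
  assert_that(n >= 4 * fps, "signal must be at least 4 s long")
  lo <- resp_band_hz[1]; hi <- resp_band_hz[2]
  if (!(lo > 0 && lo < hi && hi < fps / 2))
    stop_rbd("respiration band must satisfy 0 < low < high < fps/2")
  if (all(x == 0)) return(x)
  xc <- x - mean(x)
  tt <- (seq_len(n) - 1L) / fps
  bandpow <- function(f) {
    c1 <- sum(xc * cos(2 * pi * f * tt)); s1 <- sum(xc * sin(2 * pi * f * tt))
    c1 * c1 + s1 * s1
  }
  grid <- seq(lo, hi, length.out = max(50L, ceiling((hi - lo) * n / fps * 4)))
  pows <- vapply(grid, bandpow, numeric(1))
  i0 <- which.max(pows)
  f_lo <- grid[max(1L, i0 - 1L)]; f_hi <- grid[min(length(grid), i0 + 1L)]
  f0 <- stats::optimize(bandpow, c(f_lo, f_hi), maximum = TRUE,
                        tol = 1e-7)$maximum
  # rectified / clipped respiration waveforms carry power well above the
  # fundamental, so fit the full harmonic stack up to Nyquist (capped)
  k_max <- max(1L, min(20L, as.integer(floor((fps / 2 - 1e-9) / f0))))
  design <- matrix(1, nrow = n, ncol = 1L + 2L * k_max)
  for (k in seq_len(k_max)) {
    design[, 2L * k] <- cos(2 * pi * k * f0 * tt)
    design[, 2L * k + 1L] <- sin(2 * pi * k * f0 * tt)
  }
  fit <- stats::lm.fit(design, x)
  coefs <- fit$coefficients[-1L]
  coefs[is.na(coefs)] <- 0
  periodic <- design[, -1L, drop = FALSE] %*% coefs
  x - as.numeric(periodic)
}

#' Detect per-ROI motion from a depth sequence
#'
#' Streams over consecutive frame pairs: per-pixel depth changes above
#' `pixel_delta_mm` are counted inside the effective mask of each ROI
#' (precedence rule of [effective_masks()]), the four changed-area
#' signals are optionally respiration-suppressed, and a frame is flagged
#' for an ROI when its (filtered) changed area reaches that ROI's
#' `min_area_px`.
#'
#' @param seq A [depth_sequence()].
#' @param layout An [roi_layout()] matching the frame size.
#' @param tracks A [track_set()] (may mark everything invalid).
#' @param params A [detector_params()].
#' @return Object of class `motion_trace`: list with `area` (raw
#'   changed-area matrix, `(n_frames - 1) x 4`), `filtered` (after
#'   suppression), `flag` (logical matrix), `fps`, `start_time` and
#'   `params`. Row `t` describes arrival frame `t` (0-based), covering
#'   time `[t/fps, (t+1)/fps)`.
#' @export
detect_motion <- function(seq, layout, tracks, params = detector_params()) {
  assert_that(inherits(seq, "depth_sequence"), "seq must be a depth_sequence")
  d <- dim(seq$frames)
  assert_that(d[1] == layout$height && d[2] == layout$width,
              "layout frame size does not match the sequence")
  nf <- d[3]
  if (nf < 2L) stop_rbd("need at least 2 frames")
  rois <- c("head", "hands", "upper_body", "lower_body")
  area <- matrix(0, nrow = nf - 1L, ncol = 4L,
                 dimnames = list(NULL, rois))
  # track boxes indexed once for speed
  tdf <- tracks$df[tracks$df$valid, , drop = FALSE]
  by_frame <- split(tdf, tdf$frame)
  prev <- seq$frames[, , 1L]
  for (t in seq_len(nf - 1L)) {
    cur <- seq$frames[, , t + 1L]
    diff <- abs(cur - prev) > params$pixel_delta_mm
    prev <- cur
    key <- as.character(t)  # boxes of the arrival frame
    fb <- by_frame[[key]]
    head_mask <- NULL; hands_mask <- NULL
    if (!is.null(fb) && nrow(fb)) {
      hrows <- fb[fb$roi == "head", , drop = FALSE]
      if (nrow(hrows)) {
        head_mask <- matrix(FALSE, d[1], d[2])
        for (i in seq_len(nrow(hrows)))
          head_mask <- head_mask |
            box_mask(as.numeric(hrows[i, c("x", "y", "w", "h")]),
                     d[2], d[1])
      }
      arows <- fb[fb$roi == "hands", , drop = FALSE]
      if (nrow(arows)) {
        hands_mask <- matrix(FALSE, d[1], d[2])
        for (i in seq_len(nrow(arows)))
          hands_mask <- hands_mask |
            box_mask(as.numeric(arows[i, c("x", "y", "w", "h")]),
                     d[2], d[1])
        if (!is.null(head_mask)) hands_mask <- hands_mask & !head_mask
      }
    }
    upper <- layout$masks$upper_body
    if (!is.null(head_mask)) {
      area[t, "head"] <- sum(diff & head_mask)
      upper <- upper & !head_mask
    }
    if (!is.null(hands_mask)) {
      area[t, "hands"] <- sum(diff & hands_mask)
      upper <- upper & !hands_mask
    }
    area[t, "upper_body"] <- sum(diff & upper)
    area[t, "lower_body"] <- sum(diff & layout$masks$lower_body)
  }
  filtered <- area
  if (params$resp_suppress && nrow(area) >= 4 * seq$fps) {
    for (j in seq_len(4L)) {
      filtered[, j] <- respiration_suppress(area[, j], seq$fps,
                                            params$resp_band_hz)
    }
  }
  if (params$median_window > 1L && nrow(filtered) > params$median_window) {
    for (j in seq_len(4L)) {
      filtered[, j] <- stats::runmed(filtered[, j], params$median_window)
    }
  }
  flag <- sweep(filtered, 2L, params$min_area_px[rois], `>=`)
  structure(list(area = area, filtered = filtered, flag = flag,
                 fps = seq$fps, start_time = seq$start_time,
                 params = params),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames at %g fps; flagged: %s\n",
              nrow(x$flag), x$fps,
              paste(sprintf("%s=%d", colnames(x$flag), colSums(x$flag)),
                    collapse = " ")))
  invisible(x)
}

#' Convert a motion trace to a data frame
#'
#' Long format `(frame, roi, area_px, flag)`; `area_px` is the
#' post-suppression magnitude.
#' @param x A `motion_trace`.
#' @param ... Unused.
#' @export
as.data.frame.motion_trace <- function(x, ...) {
  rois <- colnames(x$flag)
  do.call(rbind, lapply(rois, function(r) {
    data.frame(frame = seq_len(nrow(x$flag)), roi = r,
               area_px = x$filtered[, r], flag = x$flag[, r])
  }))
}
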