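make_seq <- function(frames, fps = 10) depth_sequence(frames, fps = fps)

test_that("frame differencing marks exactly the changed pixels", {
  f1 <- matrix(1000L, 8, 8)
  f2 <- f1; f2[3, 4] <- 1020L  # 2 x pixel_delta
  f3 <- f2
  seq <- make_seq(array(c(f1, f2, f3), dim = c(8, 8, 3)))
  d <- frame_difference(seq, pixel_delta_mm = 10)
  expect_equal(sum(d[, , 1]), 1)
  expect_true(d[3, 4, 1])
  expect_equal(sum(d[, , 2]), 0)
  expect_error(frame_difference(make_seq(array(0L, dim = c(4, 4, 1)))),
               "2 frames")
})

test_that("sub-threshold noise rarely crosses the pixel threshold", {
  set.seed(77)
  delta <- 10
  n <- 40
  frames <- array(as.integer(round(2000 +
    rnorm(16 * 16 * n, 0, delta / 5))), dim = c(16, 16, n))
  d <- frame_difference(make_seq(frames), pixel_delta_mm = delta)
  expect_lt(mean(d), 0.01)  # > 5 sigma Gaussian tail on the difference
})

test_that("effective masks implement the head/hands precedence rule", {
  sq <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  lay <- roi_layout(sq(0, 0, 20, 10), sq(0, 12, 20, 20), 20, 20)
  tr <- track_set(data.frame(
    frame = c(0L, 0L, 1L, 1L),
    roi = c("head", "hands", "head", "hands"),
    x = c(2, 10, 2, 10), y = c(2, 2, 2, 2), w = 4, h = 4,
    valid = c(TRUE, TRUE, TRUE, FALSE)))

  # frame 0: both valid; upper mask loses both boxes
  m0 <- effective_masks(lay, tr, 0)
  expect_equal(sum(m0$head), 16)
  expect_equal(sum(m0$hands), 16)
  expect_equal(sum(m0$upper_body), sum(lay$masks$upper_body) - 32)
  expect_false(any(m0$upper_body & (m0$head | m0$hands)))

  # frame 1: hands dropped out -> their pixels stay in the upper mask
  m1 <- effective_masks(lay, tr, 1)
  expect_equal(sum(m1$hands), 0)
  expect_equal(sum(m1$upper_body), sum(lay$masks$upper_body) - 16)

  # frame 2: nothing tracked -> full upper polygon
  m2 <- effective_masks(lay, tr, 2)
  expect_equal(sum(m2$head), 0)
  expect_equal(m2$upper_body, lay$masks$upper_body)
  # lower body unaffected throughout
  expect_equal(m0$lower_body, lay$masks$lower_body)
})

test_that("respiration suppression attenuates in-band sinusoids >= 20 dB", {
  fps <- 10
  t <- (0:5999) / fps
  x <- 30 * sin(2 * pi * 0.25 * t + 0.7)
  y <- respiration_suppress(x, fps, c(0.15, 0.4))
  expect_lte(sqrt(mean(y^2)), 0.10 * sqrt(mean(x^2)))
})

test_that("respiration suppression preserves broadband transients", {
  fps <- 10
  n <- 600 * fps
  x <- numeric(n)
  x[3000:3009] <- 100  # 1-s rectangular pulse
  y <- respiration_suppress(x, fps, c(0.15, 0.5))
  expect_gte(max(y[3000:3009]), 70)
  # zero in, zero out
  expect_equal(respiration_suppress(numeric(100), 10, c(0.15, 0.5)),
               numeric(100))
})

test_that("suppression removes at most the band's share of white noise", {
  set.seed(13)
  fps <- 10
  x <- rnorm(6000)
  y <- respiration_suppress(x, fps, c(0.15, 0.5))
  band_share <- (0.5 - 0.15) / (fps / 2)
  reduction <- 1 - sqrt(mean(y^2)) / sqrt(mean(x^2))
  expect_lte(reduction, band_share + 0.05)
})

test_that("suppression rejects bands outside Nyquist", {
  expect_error(respiration_suppress(rnorm(100), 10, c(0.15, 6)),
               "Nyquist|fps/2")
  expect_error(respiration_suppress(rnorm(10), 10, c(0.15, 0.5)),
               "4 s")
})

test_that("detector recovers a planted event within one frame", {
  sc <- test_scene()
  h <- hypnogram(rep("R", 2))
  ev <- data.frame(roi = "lower_body", start_s = 20, end_s = 21)
  rv <- render_depth_video(ev, h, sc, seed = 3)
  tr <- detect_motion(rv$seq, sc$roi_geometry$layout, rv$tracks,
                      detector_params(resp_suppress = FALSE))
  events <- merge_events(trace_to_events(tr))
  lb <- events[events$roi == "lower_body", ]
  expect_equal(nrow(lb), 1L)
  expect_lte(abs(lb$start_s - 20), 1 / sc$fps + 1e-9)
  expect_lte(abs(lb$end_s - 21), 1 / sc$fps + 1e-9)
  expect_equal(nrow(events[events$roi != "lower_body", ]), 0L)
})

test_that("head movements with a valid track are not upper-body movements", {
  sc <- test_scene()
  h <- hypnogram(rep("R", 2))
  ev <- data.frame(roi = "head", start_s = 15, end_s = 16)
  # small frames shrink the head box below the default upper-body area
  # threshold, so scale min_area accordingly for both detections
  params <- detector_params(min_area_px = c(head = 20, hands = 20,
                                            upper_body = 30,
                                            lower_body = 50),
                            resp_suppress = FALSE)
  rv <- render_depth_video(ev, h, sc, seed = 4)
  tr <- detect_motion(rv$seq, sc$roi_geometry$layout, rv$tracks, params)
  expect_gt(sum(tr$flag[, "head"]), 0)
  expect_equal(sum(tr$flag[, "upper_body"]), 0)

  # with the tracker fully dropped out, the same movement falls back
  # to the upper body ROI
  rv2 <- render_depth_video(ev, h, test_scene(track_dropout_prob = 1),
                            seed = 4)
  tr2 <- detect_motion(rv2$seq, sc$roi_geometry$layout, rv2$tracks, params)
  expect_equal(sum(tr2$flag[, "head"]), 0)
  expect_gt(sum(tr2$flag[, "upper_body"]), 0)
})

test_that("changed pixels contribute to exactly one ROI", {
  sc <- test_scene()
  h <- hypnogram(rep("R", 1))
  ev <- data.frame(roi = c("head", "lower_body"), start_s = c(5, 5),
                   end_s = c(8, 8))
  rv <- render_depth_video(ev, h, sc, seed = 6)
  params <- detector_params(resp_suppress = FALSE)
  tr <- detect_motion(rv$seq, sc$roi_geometry$layout, rv$tracks, params)
  d <- frame_difference(rv$seq, params$pixel_delta_mm)
  masks_all <- sc$roi_geometry$layout$masks
  for (t in c(52, 60, 71)) {
    m <- effective_masks(sc$roi_geometry$layout, rv$tracks, t)
    total_in_rois <- sum(d[, , t] & (m$head | m$hands | m$upper_body |
                                     m$lower_body))
    expect_equal(sum(tr$area[t, ]), total_in_rois)
  }
})

test_that("raising thresholds never increases flagged frames", {
  sc <- test_scene(noise_sigma = 6)
  h <- hypnogram(rep("R", 1))
  ev <- data.frame(roi = "lower_body", start_s = c(5, 15), end_s = c(6, 17))
  rv <- render_depth_video(ev, h, sc, seed = 10)
  lay <- sc$roi_geometry$layout
  flags <- vapply(c(5, 10, 20, 40), function(delta) {
    tr <- detect_motion(rv$seq, lay, rv$tracks,
                        detector_params(pixel_delta_mm = delta,
                                        resp_suppress = FALSE))
    sum(tr$flag)
  }, numeric(1))
  expect_true(all(diff(flags) <= 0))
  flags2 <- vapply(c(10, 30, 80, 200), function(area) {
    tr <- detect_motion(rv$seq, lay, rv$tracks,
                        detector_params(min_area_px = area,
                                        resp_suppress = FALSE))
    sum(tr$flag)
  }, numeric(1))
  expect_true(all(diff(flags2) <= 0))
})

test_that("respiration-driven area signals are suppressed in the pipeline", {
  # exaggerated respiration so that frame differencing sees it at all:
  # chest displacement rate must exceed the pixel threshold per frame
  sc <- test_scene(respiration_amplitude = 100, respiration_freq = 0.18)
  h <- hypnogram(rep("R", 12))  # 6 min
  none <- data.frame(roi = character(), start_s = numeric(),
                     end_s = numeric())
  rv <- render_depth_video(none, h, sc, seed = 2)
  lay <- sc$roi_geometry$layout
  tr_off <- detect_motion(rv$seq, lay, rv$tracks,
                          detector_params(resp_suppress = FALSE))
  tr_on <- detect_motion(rv$seq, lay, rv$tracks,
                         detector_params(resp_suppress = TRUE))
  expect_gt(sum(tr_off$flag[, "upper_body"]), 0)
  expect_equal(sum(tr_on$flag), 0)
})
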