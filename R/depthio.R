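#' Depth frame sequence
#'
#' Container for one night (or clip) of time-of-flight depth frames.
#' Frames hold per-pixel distance from the ceiling-mounted sensor to the
#' reflecting surface (bed or patient), in millimetres.
#'
#' @param frames Integer array of dimension `height x width x n_frames`,
#'   or a list of equally sized integer matrices. Values in `[0, 8000]` mm.
#' @param fps Frame rate in frames per second (nominally 30).
#' @param start_time Offset in seconds of frame 0 relative to the
#'   hypnogram clock. Frame `i` covers `[start_time + i/fps,
#'   start_time + (i+1)/fps)`.
#' @return An object of class `depth_sequence` with elements `frames`
#'   (H x W x N integer array), `fps` and `start_time`.
#' @export
depth_sequence <- function(frames, fps, start_time = 0) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    assert_that(length(dims) == 1L, "all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  assert_that(is.array(frames) && length(dim(frames)) == 3L,
              "frames must be an H x W x N array or list of matrices")
  storage.mode(frames) <- "integer"
  assert_that(is.numeric(fps) && length(fps) == 1L && fps > 0,
              "fps must be a positive scalar")
  rng <- range(frames)
  assert_that(rng[1] >= 0 && rng[2] <= 8000,
              "depth values must lie in [0, 8000] mm")
  structure(list(frames = frames, fps = as.numeric(fps),
                 start_time = as.numeric(start_time)),
            class = "depth_sequence")
}

#' @export
print.depth_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<depth_sequence> %d frames of %d x %d px at %g fps (%.1f s)\n",
              d[3], d[2], d[1], x$fps, d[3] / x$fps))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[3]

#' Write / read a depth sequence as a directory of 16-bit frames
#'
#' The on-disk layout is one losslessly coded 16-bit grayscale TIFF per
#' frame (`frame_000000.tif`, zero-padded) plus a `meta.json` sidecar
#' holding `fps`, `width`, `height`, `n_frames` and `start_time`.
#' The round trip is bit-exact.
#'
#' @param seq A [depth_sequence()].
#' @param path Directory to create/read.
#' @return `write_depth_dir` returns `path` invisibly; `read_depth_dir`
#'   returns a [depth_sequence()].
#' @export
write_depth_dir <- function(seq, path) {
  assert_that(inherits(seq, "depth_sequence"), "seq must be a depth_sequence")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(seq$frames)
  meta <- list(fps = seq$fps, width = d[2], height = d[1],
               n_frames = d[3], start_time = seq$start_time)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  for (i in seq_len(d[3])) {
    tiff::writeTIFF(seq$frames[, , i] / 65535,
                    file.path(path, sprintf("frame_%06d.tif", i - 1L)),
                    bits.per.sample = 16L, compression = "none")
  }
  invisible(path)
}

#' @rdname write_depth_dir
#' @export
read_depth_dir <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop_rbd("missing meta.json sidecar in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0L) stop_rbd("no frames found in ", path)
  frames <- array(0L, dim = c(meta$height, meta$width, length(files)))
  for (i in seq_along(files)) {
    f <- tiff::readTIFF(files[i], as.is = TRUE)
    if (!is.matrix(f))
      stop_rbd("frame is not single-channel 16-bit grayscale: ", files[i])
    if (attr(f, "bits.per.sample") %||% 16L != 16L)
      stop_rbd("frame is not 16-bit: ", files[i])
    if (nrow(f) != meta$height || ncol(f) != meta$width)
      stop_rbd("frame shape mismatch vs meta.json: ", files[i])
    frames[, , i] <- f
  }
  depth_sequence(frames, fps = meta$fps, start_time = meta$start_time)
}

#' Hypnogram of 30-s sleep-stage epochs
#'
#' @param stages Character vector of stage codes among
#'   `W`, `N1`, `N2`, `N3`, `R`.
#' @param epoch_len_s Epoch length in seconds; clinical scoring uses 30.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30) {
  stages <- as.character(stages)
  assert_that(length(stages) > 0, "hypnogram must be non-empty")
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad))
    stop_rbd("unknown stage code(s): ", paste(bad, collapse = ", "))
  assert_that(epoch_len_s == 30, "epoch_len_s must be 30")
  structure(list(stages = stages, epoch_len_s = 30),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs (%.1f min), REM %.1f min\n",
              length(x$stages), length(x$stages) / 2,
              rem_hours(x) * 60))
  invisible(x)
}

#' Read / write a hypnogram TSV (`epoch<TAB>stage`)
#' @param path File path.
#' @param h A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character"))
  hypnogram(df$stage[order(df$epoch)])
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(h, path) {
  assert_that(inherits(h, "hypnogram"), "h must be a hypnogram")
  utils::write.table(
    data.frame(epoch = seq_along(h$stages) - 1L, stage = h$stages),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hours of REM sleep in a hypnogram
#' @param h A [hypnogram()].
#' @return Hours of stage R: `30 * count(R) / 3600`.
#' @export
rem_hours <- function(h) {
  assert_that(inherits(h, "hypnogram"), "h must be a hypnogram")
  sum(h$stages == "R") * h$epoch_len_s / 3600
}

#' REM sleep intervals
#'
#' Maximal runs of R epochs as half-open `[start_s, end_s)` intervals on
#' the hypnogram clock. Their total length always equals
#' `3600 * rem_hours(h)`.
#'
#' @param h A [hypnogram()].
#' @return Data frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @export
rem_intervals <- function(h) {
  assert_that(inherits(h, "hypnogram"), "h must be a hypnogram")
  r <- rle(h$stages == "R")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start_s = starts[keep] * h$epoch_len_s,
             end_s = ends[keep] * h$epoch_len_s)
}

#' Static region-of-interest layout
#'
#' Manually drawn polygons, in pixel coordinates, for the upper body
#' (region above the hip, which also contains head and hands when the
#' dynamic tracker misses them) and the lower body (knees and below).
#'
#' @param upper_body,lower_body Matrices of `(x, y)` polygon vertices.
#' @param width,height Frame dimensions in pixels the polygons live in.
#' @return Object of class `roi_layout`.
#' @export
roi_layout <- function(upper_body, lower_body, width, height) {
  polys <- list(upper_body = as.matrix(upper_body),
                lower_body = as.matrix(lower_body))
  for (nm in names(polys)) {
    p <- polys[[nm]]
    assert_that(ncol(p) == 2 && nrow(p) >= 3,
                paste(nm, "must have >= 3 (x, y) vertices"))
    assert_that(all(p[, 1] >= 0 & p[, 1] <= width &
                    p[, 2] >= 0 & p[, 2] <= height),
                paste(nm, "polygon extends outside the frame"))
    if (polygon_self_intersects(p))
      stop_rbd(nm, " polygon is self-intersecting")
  }
  ub <- rasterize_polygon(polys$upper_body, width, height)
  lb <- rasterize_polygon(polys$lower_body, width, height)
  if (any(ub & lb))
    stop_rbd("upper_body and lower_body regions overlap")
  structure(list(upper_body = polys$upper_body,
                 lower_body = polys$lower_body,
                 width = as.integer(width), height = as.integer(height),
                 masks = list(upper_body = ub, lower_body = lb)),
            class = "roi_layout")
}

#' Read / write an ROI layout as JSON
#' @param path File path.
#' @param layout An [roi_layout()].
#' @export
read_roi_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_poly <- function(rows) {
    do.call(rbind, lapply(rows, function(v) as.numeric(unlist(v))))
  }
  roi_layout(upper_body = as_poly(j$upper_body),
             lower_body = as_poly(j$lower_body),
             width = j$width, height = j$height)
}

#' @rdname read_roi_layout
#' @export
write_roi_layout <- function(layout, path) {
  assert_that(inherits(layout, "roi_layout"), "layout must be an roi_layout")
  row_list <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  j <- list(width = layout$width, height = layout$height,
            upper_body = row_list(layout$upper_body),
            lower_body = row_list(layout$lower_body))
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  invisible(path)
}

#' Head/hand bounding-box tracks
#'
#' Per-frame output of the external head/hand detector: zero or one head
#' box and up to two hand boxes per frame, each with a validity flag
#' (FALSE rows model detector dropouts).
#'
#' @param df Data frame with columns `frame` (0-based), `roi`
#'   (`"head"` or `"hands"`), `x`, `y`, `w`, `h`, `valid` (logical).
#' @return Object of class `track_set`.
#' @export
track_set <- function(df) {
  need <- c("frame", "roi", "x", "y", "w", "h", "valid")
  assert_that(all(need %in% names(df)),
              paste("tracks need columns:", paste(need, collapse = ", ")))
  assert_that(all(df$roi %in% c("head", "hands")),
              "track roi must be 'head' or 'hands'")
  df <- df[order(df$frame), need]
  df$valid <- as.logical(df$valid)
  structure(list(df = df), class = "track_set")
}

#' Read / write tracks CSV (`frame,roi,x,y,w,h,valid`)
#' @param path File path.
#' @param tracks A [track_set()].
#' @export
read_tracks <- function(path) {
  track_set(utils::read.csv(path))
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  assert_that(inherits(tracks, "track_set"), "tracks must be a track_set")
  utils::write.csv(tracks$df, path, row.names = FALSE)
  invisible(path)
}

# Valid boxes for one frame: list(head = matrix, hands = matrix) with
# rows c(x, y, w, h); zero-row matrices when dropped out.
tracks_at_frame <- function(tracks, frame) {
  df <- tracks$df[tracks$df$frame == frame & tracks$df$valid, , drop = FALSE]
  out <- list(head = NULL, hands = NULL)
  for (r in c("head", "hands")) {
    sub <- df[df$roi == r, c("x", "y", "w", "h"), drop = FALSE]
    out[[r]] <- as.matrix(sub)
  }
  out
}

#' Subject records
#'
#' @param df Data frame with columns `subject_id`, `group` (one of
#'   `iRBD`, `SRBD`, `RLS`, `PLMS`, `INS`, `NREMP`, `NRSD`) and optional
#'   `sinbar_index` (% of REM with qualifying EMG activity, in `[0, 100]`).
#' @return Validated data frame of class `subject_records`.
#' @export
subject_records <- function(df) {
  assert_that(all(c("subject_id", "group") %in% names(df)),
              "records need subject_id and group columns")
  bad <- setdiff(unique(df$group),
                 c("iRBD", "SRBD", "RLS", "PLMS", "INS", "NREMP", "NRSD"))
  if (length(bad))
    stop_rbd("unknown group(s): ", paste(bad, collapse = ", "))
  if ("sinbar_index" %in% names(df)) {
    si <- df$sinbar_index
    assert_that(all(is.na(si) | (si >= 0 & si <= 100)),
                "sinbar_index must lie in [0, 100]")
  }
  class(df) <- c("subject_records", class(df))
  df
}

#' Read / write subject labels CSV (`subject_id,group[,sinbar_index]`)
#' @param path File path.
#' @param records A [subject_records()] data frame.
#' @export
read_labels <- function(path) subject_records(utils::read.csv(path))

#' @rdname read_labels
#' @export
write_labels <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read / write movement events CSV (`roi,start_s,end_s[,bin]`)
#' @param path File path.
#' @param events Events data frame.
#' @export
read_events <- function(path) utils::read.csv(path)

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a wide feature table CSV
#'
#' Columns: `subject_id`, `group`, then `{roi}_{bin}_{rate|ratio}`
#' (e.g. `LB_short_rate`), as produced by [compute_features()] or
#' [sample_cohort_features()].
#' @param path File path.
#' @param features Feature data frame.
#' @export
read_features <- function(path) utils::read.csv(path)

#' @rdname read_features
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
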