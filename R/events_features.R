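#' Duration bin definitions
#'
#' Movement-duration categories: short `[0.1, 2)` s, medium `[2, 15)` s,
#' long `[15, 300]` s, with the 1-s merge rule (two movements are
#' separate only when the inter-movement interval exceeds 1 s).
#' Boundaries are half-open at 2 and 15 s and closed at 300 s so that
#' assignment is deterministic; durations below 0.1 s or above 300 s
#' are dropped.
#'
#' @param merge_gap_s Merge gap in seconds.
#' @return List with `short`, `medium`, `long` ranges and `merge_gap_s`.
#' @export
duration_bins <- function(merge_gap_s = 1.0) {
  list(short = c(0.1, 2), medium = c(2, 15), long = c(15, 300),
       merge_gap_s = merge_gap_s)
}

# ROI label used in feature column names
roi_code <- c(head = "HE", hands = "HAs", upper_body = "UB",
              lower_body = "LB")

empty_events <- function() {
  data.frame(roi = character(), start_s = numeric(), end_s = numeric())
}

#' Extract raw events from a motion trace
#'
#' Maximal runs of flagged frames become events: a run over trace rows
#' `[f0, f1]` (arrival frames, 0-based frame indices `f0..f1`) yields
#' the half-open interval `[f0/fps, (f1+1)/fps)` shifted by the
#' sequence `start_time`.
#'
#' @param trace A `motion_trace` from [detect_motion()].
#' @return Data frame `(roi, start_s, end_s)` sorted by ROI and onset.
#' @export
trace_to_events <- function(trace) {
  assert_that(inherits(trace, "motion_trace"), "trace must be a motion_trace")
  out <- list()
  for (r in colnames(trace$flag)) {
    v <- trace$flag[, r]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    out[[r]] <- data.frame(
      roi = r,
      start_s = trace$start_time + starts[keep] / trace$fps,
      end_s = trace$start_time + (ends[keep] + 1L) / trace$fps)
  }
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$roi, ev$start_s), ]
  rownames(ev) <- NULL
  ev
}

#' Merge events separated by short gaps
#'
#' Fuses consecutive same-ROI events whose inter-movement interval is
#' at most `merge_gap_s` (two movements are separate only when the gap
#' is strictly above it). Idempotent; all output gaps exceed
#' `merge_gap_s`.
#'
#' @param events Data frame `(roi, start_s, end_s)`, sorted and
#'   non-overlapping within each ROI.
#' @param merge_gap_s Merge gap, seconds (default 1).
#' @return Merged events data frame.
#' @export
merge_events <- function(events, merge_gap_s = 1.0) {
  if (nrow(events) == 0L) return(events)
  assert_that(all(events$end_s > events$start_s),
              "events must have end_s > start_s")
  out <- lapply(split(events, events$roi), function(ev) {
    if (is.unsorted(ev$start_s))
      stop_rbd("events must be sorted by start_s within each ROI")
    if (nrow(ev) > 1L &&
        any(ev$start_s[-1L] < ev$end_s[-nrow(ev)]))
      stop_rbd("events overlap within an ROI")
    s <- ev$start_s; e <- ev$end_s
    ms <- s[1]; me <- e[1]
    res_s <- numeric(0); res_e <- numeric(0)
    for (i in seq_len(nrow(ev))[-1L]) {
      if (s[i] - me <= merge_gap_s) {
        me <- max(me, e[i])
      } else {
        res_s <- c(res_s, ms); res_e <- c(res_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
    data.frame(roi = ev$roi[1], start_s = c(res_s, ms),
               end_s = c(res_e, me))
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$roi, ev$start_s), ]
  rownames(ev) <- NULL
  ev
}

#' Restrict events to REM sleep
#'
#' An event is kept if and only if its onset falls inside a REM
#' interval; kept events retain their full (unclipped) duration. The
#' onset rule is order-independent and avoids double counting at
#' REM boundaries.
#'
#' @param events Events data frame `(roi, start_s, end_s)`.
#' @param rem Data frame of half-open REM intervals from
#'   [rem_intervals()].
#' @return Subset of `events`.
#' @export
restrict_to_rem <- function(events, rem) {
  if (nrow(events) == 0L || nrow(rem) == 0L)
    return(events[integer(0), , drop = FALSE])
  keep <- vapply(events$start_s, function(s) {
    any(rem$start_s <= s & s < rem$end_s)
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign duration bins
#'
#' Drops events shorter than 0.1 s or longer than 300 s; otherwise
#' assigns `short` `[0.1, 2)`, `medium` `[2, 15)` or `long` `[15, 300]`.
#'
#' @param events Merged events data frame.
#' @param bins Bin definitions from [duration_bins()].
#' @return `events` with a `bin` column; out-of-range events removed.
#' @export
bin_by_duration <- function(events, bins = duration_bins()) {
  if (nrow(events) == 0L) {
    events$bin <- character(0)
    return(events)
  }
  d <- events$end_s - events$start_s
  bin <- rep(NA_character_, length(d))
  bin[d >= bins$short[1] & d < bins$short[2]] <- "short"
  bin[d >= bins$medium[1] & d < bins$medium[2]] <- "medium"
  bin[d >= bins$long[1] & d <= bins$long[2]] <- "long"
  out <- events[!is.na(bin), , drop = FALSE]
  out$bin <- bin[!is.na(bin)]
  rownames(out) <- NULL
  out
}

#' Compute movement-rate and movement-ratio features
#'
#' For each ROI and duration bin, the 3D rate is the number of REM
#' movement events per hour of REM sleep, and the 3D ratio is the total
#' movement time in REM per hour of REM sleep scaled by 3600 — i.e.
#' seconds of movement per REM hour, so that movement occupying all of
#' REM gives exactly 3600.
#'
#' @param events Binned REM events (`roi`, `start_s`, `end_s`, `bin`).
#' @param rem_hours Hours of REM sleep (> 0).
#' @return One-row data frame with 24 columns
#'   `{HE|HAs|UB|LB}_{short|medium|long}_{rate|ratio}`.
#' @export
compute_features <- function(events, rem_hours) {
  if (rem_hours <= 0) stop_rbd("no REM sleep: rem_hours must be > 0")
  rois <- names(roi_code)
  bins <- c("short", "medium", "long")
  out <- list()
  for (r in rois) {
    for (b in bins) {
      sub <- events[events$roi == r & events$bin == b, , drop = FALSE]
      n <- nrow(sub)
      tot <- if (n) sum(sub$end_s - sub$start_s) else 0
      out[[paste0(roi_code[[r]], "_", b, "_rate")]] <- n / rem_hours
      out[[paste0(roi_code[[r]], "_", b, "_ratio")]] <- tot / rem_hours
    }
  }
  as.data.frame(out)
}

#' Full trace-to-features pipeline
#'
#' Run-length extraction, 1-s merge, REM restriction (onset rule),
#' duration binning and feature computation in the fixed order that
#' prevents REM-boundary fragmentation (merge before restriction).
#'
#' @param trace A `motion_trace`.
#' @param hypno A [hypnogram()].
#' @param bins Bin definitions from [duration_bins()].
#' @return List with `events` (binned REM events) and `features`
#'   (one-row feature data frame).
#' @export
movement_features <- function(trace, hypno, bins = duration_bins()) {
  ev <- trace_to_events(trace)
  ev <- merge_events(ev, bins$merge_gap_s)
  ev <- restrict_to_rem(ev, rem_intervals(hypno))
  ev <- bin_by_duration(ev, bins)
  list(events = ev, features = compute_features(ev, rem_hours(hypno)))
}
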