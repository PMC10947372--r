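# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (loops, enumeration) and share no code with the
# package implementation they check.

# ---- event pipeline reference -------------------------------------------

# single-pass naive reference: merge -> REM-restrict -> bin -> features
reference_features <- function(events, rem, rem_hours, merge_gap = 1.0) {
  rois <- c(head = "HE", hands = "HAs", upper_body = "UB",
            lower_body = "LB")
  bins <- c("short", "medium", "long")
  res <- list()
  for (r in names(rois)) {
    ev <- events[events$roi == r, , drop = FALSE]
    ev <- ev[order(ev$start_s), , drop = FALSE]
    # merge
    merged <- list()
    i <- 1L
    while (i <= nrow(ev)) {
      s <- ev$start_s[i]; e <- ev$end_s[i]
      j <- i + 1L
      while (j <= nrow(ev) && ev$start_s[j] - e <= merge_gap) {
        e <- max(e, ev$end_s[j]); j <- j + 1L
      }
      merged[[length(merged) + 1L]] <- c(s, e)
      i <- j
    }
    count <- sapply(bins, function(b) 0)
    tot <- sapply(bins, function(b) 0)
    for (m in merged) {
      # onset-in-REM rule
      in_rem <- FALSE
      if (nrow(rem)) {
        for (k in seq_len(nrow(rem))) {
          if (rem$start_s[k] <= m[1] && m[1] < rem$end_s[k]) in_rem <- TRUE
        }
      }
      if (!in_rem) next
      d <- m[2] - m[1]
      b <- if (d >= 0.1 && d < 2) "short"
           else if (d >= 2 && d < 15) "medium"
           else if (d >= 15 && d <= 300) "long"
           else NA_character_
      if (is.na(b)) next
      count[b] <- count[b] + 1
      tot[b] <- tot[b] + d
    }
    for (b in bins) {
      res[[paste0(rois[[r]], "_", b, "_rate")]] <- count[[b]] / rem_hours
      res[[paste0(rois[[r]], "_", b, "_ratio")]] <- tot[[b]] / rem_hours
    }
  }
  as.data.frame(res)
}

# random non-overlapping event list + hypnogram for oracle comparisons
random_event_case <- function(max_n = 60) {
  hypno <- hypnogram(sample(c("W", "N1", "N2", "N3", "R"),
                            sample(20:80, 1), replace = TRUE,
                            prob = c(0.1, 0.1, 0.35, 0.2, 0.25)))
  rois <- c("head", "hands", "upper_body", "lower_body")
  evs <- list()
  for (r in rois) {
    k <- sample(0:max_n, 1)
    if (k == 0) next
    gaps <- rexp(k, rate = 1 / 40)
    durs <- exp(runif(k, log(0.01), log(400)))  # spans drop rules
    starts <- cumsum(gaps) + cumsum(c(0, durs[-k]))
    evs[[r]] <- data.frame(roi = r, start_s = starts,
                           end_s = starts + durs)
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(roi = character(), start_s = numeric(), end_s = numeric())
  list(hypno = hypno, events = events)
}

# package-side pipeline on a raw event list (same entry point the
# reference emulates)
pipeline_features <- function(events, hypno) {
  ev <- merge_events(events[order(events$roi, events$start_s), ,
                            drop = FALSE])
  ev <- restrict_to_rem(ev, rem_intervals(hypno))
  ev <- bin_by_duration(ev)
  compute_features(ev, rem_hours(hypno))
}

# ---- statistical enumeration oracles ------------------------------------

# exact two-sided Mann-Whitney p by enumeration of group assignments
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(na))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided signed-rank p by enumeration of all sign patterns
sr_enum_p <- function(a, b) {
  d <- (a - b)[a - b != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Spearman via direct rank formula + t approximation
spearman_direct <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2))
}

# permute a vector under a temporary seed (restores RNG state)
with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x)
}

# ---- scene helpers -------------------------------------------------------

# small noiseless test scene used by the motion tests; any scene_config
# argument can be overridden
test_scene <- function(width = 48, height = 48, fps = 10, ...) {
  args <- list(frame_width = width, frame_height = height, fps = fps,
               noise_sigma = 0, respiration_amplitude = 0,
               track_dropout_prob = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_config, args)
}
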