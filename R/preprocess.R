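## Event isolation: baseline removal, moving-window detection, clipping.

#' Raw voltage-clamp trace
#'
#' @param samples Current samples (pA), as recorded (inward events are
#'   negative deflections on the holding current).
#' @param dt Sampling interval (ms).
#' @param experiment,cell Identifiers for multilevel analysis.
#' @param v_hold Holding potential (mV).
#' @param id Trace identifier.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(samples, dt, experiment = NA_character_,
                      cell = NA_character_, v_hold = NA_real_, id = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), dt = dt,
                 meta = list(experiment = experiment, cell = cell,
                             v_hold = v_hold, id = id)),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d samples @ %g ms (%g ms)\n",
              if (is.null(x$meta$id)) "?" else x$meta$id,
              length(x$samples), x$dt, length(x$samples) * x$dt))
  invisible(x)
}

#' Isolated single-event trace
#'
#' Produced by [clip_event()]: baseline-subtracted current magnitudes
#' (event polarity flipped to positive) up to the 20%-of-peak clip point.
#'
#' @param samples Current magnitudes (pA).
#' @param dt Sampling interval (ms).
#' @param peak_index Sample index of the maximum magnitude.
#' @param clip_index Last retained sample index.
#' @param status `"accepted"`, `"rejected_short"` or `"rejected_overlap"`.
#' @param onset_time Detected onset, ms from the first retained sample.
#' @param clipped `TRUE` when the decay reached the clip level inside the
#'   window (`FALSE`: the event ran into the end of the recording).
#' @param meta Metadata list carried over from the raw trace.
#' @return An object of class `event_trace`.
#' @export
event_trace <- function(samples, dt, peak_index, clip_index,
                        status = "accepted", onset_time = NA_real_,
                        clipped = TRUE, meta = list()) {
  structure(list(samples = as.numeric(samples), dt = dt,
                 peak_index = as.integer(peak_index),
                 peak_amplitude = as.numeric(samples[peak_index]),
                 clip_index = as.integer(clip_index),
                 status = status, onset_time = onset_time,
                 clipped = clipped, meta = meta),
            class = "event_trace")
}

#' @export
print.event_trace <- function(x, ...) {
  cat(sprintf("<event_trace> %s: %s, peak %.1f pA @ %.2f ms, %d samples\n",
              if (is.null(x$meta$id)) "?" else x$meta$id, x$status,
              x$peak_amplitude, (x$peak_index - 1) * x$dt,
              length(x$samples)))
  invisible(x)
}

#' Moving-window width used by detection and the running-mean cost
#'
#' Width is `max(1 ms, 20 * dt)`, capped at 5% of the trace duration: wide
#' enough to average noise yet narrower than the fast rise of an event.
#'
#' @param dt Sampling interval (ms).
#' @param n Number of samples in the trace.
#' @return Window width in samples (>= 2).
#' @export
moving_window_samples <- function(dt, n) {
  w_ms <- max(1, 20 * dt)
  w_ms <- min(w_ms, 0.05 * n * dt)
  max(2L, as.integer(round(w_ms / dt)))
}

# robust noise SD from first differences (insensitive to slow events)
.noise_sd <- function(x) stats::mad(diff(x)) / sqrt(2)

# onset: last pre-peak sample whose deviation magnitude is below the
# noise-based threshold
.find_onset <- function(dev_mag, peak_idx, sigma) {
  thr <- max(3 * sigma, 1e-3 * max(dev_mag))
  below <- which(dev_mag[seq_len(peak_idx - 1)] < thr)
  if (!length(below)) 1L else max(below)
}

#' Remove holding and baseline current
#'
#' Subtracts the mean of the baseline window (the `baseline_ms` immediately
#' preceding the detected event onset; the onset is the last pre-peak
#' sample whose deviation stays below 3 times the noise SD).
#'
#' @param trace A [raw_trace()].
#' @param baseline_ms Baseline window length (ms), > 0.
#' @return The trace with baseline removed; the subtracted value is stored
#'   in the `baseline` field.
#' @export
remove_baseline <- function(trace, baseline_ms = 5) {
  stopifnot(inherits(trace, "raw_trace"))
  if (!is.finite(baseline_ms) || baseline_ms <= 0)
    stop("baseline window must have positive length", call. = FALSE)
  x <- trace$samples
  nb <- as.integer(round(baseline_ms / trace$dt))
  if (length(x) <= nb)
    stop("trace shorter than the baseline window", call. = FALSE)
  # the leading baseline_ms anchor the holding-current estimate; the
  # subtracted value is then refined to the window just before the onset
  base0 <- stats::median(x[seq_len(nb)])
  dev <- x - base0
  out <- trace
  if (max(abs(dev)) == 0) {          # flat trace: everything is baseline
    out$samples <- dev
    out$baseline <- base0
    out$onset_index <- length(x)
    return(out)
  }
  peak_idx <- which.max(abs(dev))
  sigma <- .noise_sd(x[seq_len(nb)])
  onset <- .find_onset(abs(dev), max(peak_idx, 2L), sigma)
  if (onset - 1 < nb)
    stop("no pre-event segment of baseline-window length before the onset",
         call. = FALSE)
  win <- (onset - nb):(onset - 1)
  out <- trace
  out$samples <- x - mean(x[win])
  out$baseline <- mean(x[win])
  out$onset_index <- onset
  out
}

# rolling range (max - min) over windows of k samples; value at window start
.roll_range <- function(x, k) {
  n <- length(x)
  if (k >= n) return(max(x) - min(x))
  vapply(seq_len(n - k + 1), function(i) {
    w <- x[i:(i + k - 1)]
    max(w) - min(w)
  }, numeric(1))
}

#' Detect candidate events in a baseline-free trace
#'
#' Slides a moving window over the trace and marks regions where the
#' within-window range of the current exceeds `threshold_frac` of the
#' trace's global peak magnitude.  Contiguous marked regions (merged when
#' closer than one window) become candidate event windows; each window runs
#' from its region start to the start of the next region.  Regions whose
#' peak magnitude stays below `snr_floor` noise SDs are discarded, so a
#' pure-noise trace yields no windows.
#'
#' @param trace A baseline-free [raw_trace()] (see [remove_baseline()]).
#' @param threshold_frac Detection threshold as a fraction of the global
#'   peak magnitude (default 0.10).
#' @param window_ms Moving-window width (ms); default
#'   [moving_window_samples()].
#' @param snr_floor Minimum region peak in noise-SD units (default 5).
#' @return List of windows, each `list(start, end, peak_index)` in sample
#'   indices; empty if nothing is detected.
#' @export
detect_events <- function(trace, threshold_frac = 0.10, window_ms = NULL,
                          snr_floor = 5) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  n <- length(x)
  m <- abs(x)
  P <- max(m)
  if (P == 0) return(list())
  k <- if (is.null(window_ms)) moving_window_samples(trace$dt, n)
       else max(2L, as.integer(round(window_ms / trace$dt)))
  r <- .roll_range(x, k)
  sigma <- .noise_sd(x)
  # floor the range criterion at 6 noise SDs: the within-window range of
  # pure noise must not saturate detection on noisy recordings
  mask <- r > max(threshold_frac * P, 6 * sigma)
  if (!any(mask)) return(list())
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  reg <- cbind(starts[runs$values], pmin(ends[runs$values] + k - 1L, n))
  # merge regions that belong to one deflection: either closer than one
  # window, or with no valley below the detection level between them (the
  # range statistic goes quiet over the flat top of a slow event, which
  # must not split it into a rise and a decay region)
  sm <- .running_mean(m, k)
  merged <- reg[1, , drop = FALSE]
  for (i in seq_len(nrow(reg))[-1]) {
    gap_lo <- merged[nrow(merged), 2]
    valley <- min(sm[gap_lo:reg[i, 1]])
    if (reg[i, 1] - gap_lo < k || valley > threshold_frac * P)
      merged[nrow(merged), 2] <- reg[i, 2]
    else merged <- rbind(merged, reg[i, ])
  }
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    max(m[merged[i, 1]:merged[i, 2]]) >= snr_floor * sigma
  }, logical(1))
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(list())
  lapply(seq_len(nrow(merged)), function(i) {
    start <- merged[i, 1]
    end <- if (i < nrow(merged)) merged[i + 1, 1] - 1L else n
    list(start = as.integer(start), end = as.integer(end),
         peak_index = as.integer(start - 1L +
                                   which.max(m[start:end])))
  })
}

#' Clip a detected event and assign its status
#'
#' Cuts the event at the first post-peak sample whose magnitude (on a
#' 3-sample median-filtered copy, to ignore single noise spikes) decays to
#' `clip_frac` of the peak.  The event is `rejected_short` when less than
#' `min_post_peak_ms` survive after the peak, and `rejected_overlap` when a
#' second deflection larger than `threshold_frac` of the peak rises before
#' the decay reaches the clip level.  Event polarity is flipped so the
#' retained samples are positive magnitudes.
#'
#' @param trace A baseline-free [raw_trace()].
#' @param window A window from [detect_events()].
#' @param clip_frac Decay fraction of the peak at which to clip (default
#'   0.20).
#' @param min_post_peak_ms Minimum retained time after the peak (default
#'   5 ms).
#' @param threshold_frac Second-deflection threshold for overlap rejection
#'   (default 0.10).
#' @param pre_ms Pre-window context retained before the detected start
#'   (default 2 ms), so the onset time can be fitted.
#' @return An [event_trace()].
#' @export
clip_event <- function(trace, window, clip_frac = 0.20,
                       min_post_peak_ms = 5, threshold_frac = 0.10,
                       pre_ms = 2) {
  stopifnot(inherits(trace, "raw_trace"))
  dt <- trace$dt
  start <- max(1L, window$start - as.integer(round(pre_ms / dt)))
  seg <- trace$samples[start:window$end]
  pol <- sign(seg[window$peak_index - start + 1L])
  if (pol == 0) pol <- 1
  y <- pol * seg
  peak_idx <- window$peak_index - start + 1L
  peak <- y[peak_idx]
  # the 20% crossing is judged on a moving-window mean of the (3-sample
  # median-filtered) trace: single noise excursions must not clip the
  # event early, which would both shorten borderline events below the
  # 5 ms rule and bias the retained tail low
  mf <- if (length(y) >= 3) stats::runmed(y, 3) else y
  kw <- moving_window_samples(dt, length(y))
  sm <- .running_mean(mf, kw)
  post <- seq.int(peak_idx + 1L, length.out = max(0L, length(y) - peak_idx))
  clip_idx <- length(y)
  clipped <- FALSE
  if (length(post)) {
    hit <- post[sm[post] <= clip_frac * peak]
    if (length(hit)) { clip_idx <- hit[1]; clipped <- TRUE }
  }
  status <- "accepted"
  # second deflection before the decay reached the clip level?  judged on
  # the same smoothed copy so single noise excursions do not count; the
  # scan starts half a window past the peak, where the centered mean no
  # longer straddles the rise
  scan_from <- peak_idx + kw %/% 2L + 1L
  if (clip_idx > scan_from) {
    dec <- sm[scan_from:clip_idx]
    rebound <- dec - cummin(dec)
    if (any(rebound > threshold_frac * peak)) status <- "rejected_overlap"
  }
  if (status == "accepted" && (clip_idx - peak_idx) * dt < min_post_peak_ms)
    status <- "rejected_short"
  sigma <- .noise_sd(y)
  onset <- .find_onset(abs(y), max(peak_idx, 2L), sigma)
  event_trace(samples = y[seq_len(clip_idx)], dt = dt,
              peak_index = peak_idx, clip_index = clip_idx,
              status = status, onset_time = (onset - 1) * dt,
              clipped = clipped, meta = trace$meta)
}

#' Full preprocessing of one raw trace
#'
#' Baseline removal, event detection, and clipping, returning one
#' [event_trace()] per detected window (possibly none).
#'
#' @param trace A [raw_trace()].
#' @param baseline_ms Baseline window (ms), see [remove_baseline()].
#' @param threshold_frac,clip_frac,min_post_peak_ms See [detect_events()]
#'   and [clip_event()].
#' @return List of [event_trace()] objects.
#' @export
preprocess_trace <- function(trace, baseline_ms = 5, threshold_frac = 0.10,
                             clip_frac = 0.20, min_post_peak_ms = 5) {
  bl <- remove_baseline(trace, baseline_ms = baseline_ms)
  wins <- detect_events(bl, threshold_frac = threshold_frac)
  lapply(wins, function(w)
    clip_event(bl, w, clip_frac = clip_frac,
               min_post_peak_ms = min_post_peak_ms,
               threshold_frac = threshold_frac))
}

#' Read and write delimited-text traces
#'
#' A trace file is a CSV with `#`-prefixed header lines carrying metadata
#' (`dt`, `experiment`, `cell`, `v_hold`, `id`) and columns `t_ms`,
#' `i_pA`.  `read_trace_csv()` also accepts two-column files without
#' metadata, taking `dt` from the time column.
#'
#' @param trace A [raw_trace()].
#' @param file Path to read or write.
#' @return `read_trace_csv()` returns a [raw_trace()];
#'   `write_trace_csv()` returns `file` invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(file, "w")
  on.exit(close(con))
  meta <- trace$meta
  writeLines(c(
    sprintf("# dt=%.17g", trace$dt),
    sprintf("# experiment=%s", meta$experiment),
    sprintf("# cell=%s", meta$cell),
    sprintf("# v_hold=%.17g", meta$v_hold),
    sprintf("# id=%s", if (is.null(meta$id)) NA else meta$id),
    "t_ms,i_pA"), con)
  t <- trace$dt * (seq_along(trace$samples) - 1)
  writeLines(sprintf("%.17g,%.17g", t, trace$samples), con)
  invisible(file)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(experiment = NA_character_, cell = NA_character_,
               v_hold = NA_real_, id = NULL)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)=(.*)$", hdr))
  for (m in kv) {
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (ncol(tab) < 2) stop("trace file needs two columns", call. = FALSE)
  dt <- if (!is.null(meta$dt)) as.numeric(meta$dt)
        else stats::median(diff(tab[[1]]))
  raw_trace(tab[[2]], dt = dt,
            experiment = as.character(meta$experiment),
            cell = as.character(meta$cell),
            v_hold = as.numeric(meta$v_hold),
            id = if (is.null(meta$id) || identical(meta$id, "NA")) NULL
                 else meta$id)
}

#' Write per-event CSVs and a manifest
#'
#' One CSV per event plus `events_manifest.tsv` with trace id, status,
#' peak amplitude (pA) and clip time (ms).
#'
#' @param events List of [event_trace()] objects.
#' @param dir Output directory.
#' @return The manifest as a data.frame, invisibly.
#' @export
write_event_manifest <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    id <- if (!is.null(ev$meta$id)) ev$meta$id else sprintf("event_%03d", i)
    if (identical(ev$status, "accepted")) {
      f <- file.path(dir, paste0(id, "_event.csv"))
      t <- ev$dt * (seq_along(ev$samples) - 1)
      utils::write.csv(data.frame(t_ms = t, i_pA = ev$samples), f,
                       row.names = FALSE)
    }
    data.frame(trace_id = id, status = ev$status,
               peak_pA = ev$peak_amplitude,
               clip_ms = (ev$clip_index - 1) * ev$dt,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "events_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
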