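# fractional zero-crossing positions (in samples, 1-based) of a trace;
# direction "pn" = positive-to-negative, "np" = negative-to-positive
.zero_crossings <- function(x, direction) {
  n <- length(x)
  i <- seq_len(n - 1L)
  hit <- if (direction == "pn") x[i] > 0 & x[i + 1L] <= 0 else x[i] < 0 & x[i + 1L] >= 0
  i <- which(hit)
  i + x[i] / (x[i] - x[i + 1L])
}

# the four identification criteria for one candidate wave; returns a named
# logical vector so each criterion can be examined independently
.so_criteria <- function(trough_uv, p2p_uv, halfwave_s, span_s,
                         min_trough = -80, min_p2p = 80,
                         halfwave_range = c(0.3, 1.0), max_span = 10) {
  c(amplitude = trough_uv <= min_trough,
    peak_to_peak = p2p_uv >= min_p2p,
    halfwave = halfwave_s >= halfwave_range[1] & halfwave_s <= halfwave_range[2],
    span = span_s <= max_span)
}

#' Detect slow oscillations on one channel
#'
#' Candidate waves are delimited by zero crossings of the 0.1-4 Hz filtered
#' trace: a candidate starts at a positive-to-negative crossing, its
#' negative half-wave ends at the next negative-to-positive crossing, and
#' the candidate ends at the following positive-to-negative crossing. A
#' candidate is emitted as an SO iff (1) its trough is at or below -80 uV,
#' (2) its peak-to-peak range is at least 80 uV, (3) the negative half-wave
#' (first to second zero crossing) lasts 300 ms to 1 s, (4) the whole
#' candidate spans at most 10 s, and the trough sample lies inside the
#' sleep-stage mask. When two candidates share samples the one with the
#' deeper trough is kept.
#'
#' @param filtered numeric vector: the band-pass (0.1-4 Hz) filtered trace.
#' @param mask logical vector (same length): stage mask from [stage_mask];
#'   `NULL` means all samples eligible.
#' @param fs sampling rate in Hz.
#' @param channel channel label recorded in the output.
#' @param stages optional per-30-s-epoch labels used to annotate each event.
#' @return data frame of class `so_events`: channel, trough_time (s),
#'   trough_uv, p2p_uv, zc1_s, zc2_s, span_start_s, span_end_s, stage;
#'   sorted by trough time. Zero rows when nothing is detected.
#' @export
detect_sos <- function(filtered, mask = NULL, fs, channel = "?", stages = NULL) {
  stopifnot(is.numeric(filtered), fs > 0)
  n <- length(filtered)
  if (is.null(mask)) mask <- rep(TRUE, n)
  pn <- .zero_crossings(filtered, "pn")
  np <- .zero_crossings(filtered, "np")
  rows <- list()
  for (z1 in pn) {
    z2 <- np[np > z1][1]
    if (is.na(z2)) next
    z3 <- pn[pn > z2][1]
    if (is.na(z3)) next
    neg_idx <- seq(ceiling(z1), floor(z2))
    if (!length(neg_idx)) next
    span_idx <- seq(ceiling(z1), floor(z3))
    trough_i <- neg_idx[which.min(filtered[neg_idx])]
    trough_uv <- filtered[trough_i]
    p2p <- max(filtered[span_idx]) - min(filtered[span_idx])
    crit <- .so_criteria(trough_uv, p2p, (z2 - z1) / fs, (z3 - z1) / fs)
    if (!all(crit)) next
    if (!mask[trough_i]) next
    stage <- if (is.null(stages)) NA_character_ else
      stages[min(length(stages), (trough_i - 1L) %/% as.integer(30 * fs) + 1L)]
    rows[[length(rows) + 1L]] <- data.frame(
      channel = channel, trough_time = (trough_i - 1) / fs,
      trough_uv = trough_uv, p2p_uv = p2p,
      zc1_s = (z1 - 1) / fs, zc2_s = (z2 - 1) / fs,
      span_start_s = (z1 - 1) / fs, span_end_s = (z3 - 1) / fs,
      stage = stage)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(), trough_time = numeric(),
               trough_uv = numeric(), p2p_uv = numeric(), zc1_s = numeric(),
               zc2_s = numeric(), span_start_s = numeric(),
               span_end_s = numeric(), stage = character())
  # overlap resolution: keep the deeper trough
  if (nrow(ev) > 1) {
    ev <- ev[order(ev$trough_time), ]
    keep <- rep(TRUE, nrow(ev))
    for (i in seq_len(nrow(ev) - 1L)) {
      if (!keep[i]) next
      j <- i + 1L
      if (ev$span_start_s[j] < ev$span_end_s[i] &&
          ev$span_end_s[j] > ev$span_start_s[i]) {
        if (ev$trough_uv[j] < ev$trough_uv[i]) keep[i] <- FALSE else keep[j] <- FALSE
      }
    }
    ev <- ev[keep, ]
  }
  rownames(ev) <- NULL
  class(ev) <- c("so_events", "data.frame")
  ev
}

#' Detect slow oscillations on every channel of a recording
#'
#' Applies the 0.1-4 Hz detection band-pass and runs [detect_sos] per
#' channel with the N2/SWS stage mask.
#'
#' @param recording an `so_recording` (raw; the detection filter is applied
#'   internally).
#' @param channels channel labels to scan (default: all).
#' @return combined `so_events` data frame.
#' @export
detect_sos_all <- function(recording, channels = recording$labels) {
  stopifnot(inherits(recording, "so_recording"))
  mask <- stage_mask(recording)
  out <- lapply(channels, function(ch) {
    i <- match(tolower(ch), tolower(recording$labels))
    if (is.na(i)) stop("unknown channel: ", ch)
    tr <- bandpass_detection(recording$data[i, ], recording$fs)
    detect_sos(tr, mask, recording$fs, channel = recording$labels[i],
               stages = recording$stages)
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$trough_time), ]
  rownames(ev) <- NULL
  class(ev) <- c("so_events", "data.frame")
  ev
}

#' @export
print.so_events <- function(x, ...) {
  cat("Detected slow oscillations:", nrow(x), "events on",
      length(unique(x$channel)), "channel(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Export detected SOs as a BED-like interval file
#'
#' Writes one line per event: channel, span start, span end (0-based,
#' half-open, in integer milliseconds) and the trough time as the score
#' column — a plain interval format other toolchains can ingest.
#'
#' @param so_events an `so_events` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_so_events_bed <- function(so_events, path) {
  df <- data.frame(chrom = so_events$channel,
                   start = as.integer(floor(so_events$span_start_s * 1000)),
                   end = as.integer(ceiling(so_events$span_end_s * 1000)),
                   name = sprintf("SO_%d", seq_len(nrow(so_events))),
                   score = as.integer(round(so_events$trough_time * 1000)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sample non-SO control windows
#'
#' Draws 0.5-s control windows whose centers are more than `margin_s`
#' (default 10 s) away from every detected SO trough on any channel and
#' which lie entirely inside an N2 or SWS epoch. One window per SO is the
#' convention of the analysis (`n_windows` defaults to the event count);
#' the source channel of each window is drawn uniformly from the four
#' midline sources.
#'
#' @param so_events an `so_events` data frame (all channels pooled).
#' @param mask logical stage mask from [stage_mask].
#' @param fs sampling rate in Hz.
#' @param n_windows number of windows to draw.
#' @param seed integer RNG seed (recorded draw is deterministic given seed).
#' @param margin_s exclusion margin around each trough, seconds.
#' @param window_s window length, seconds.
#' @param stages optional per-epoch labels to annotate each window.
#' @return data frame: channel, center_time (s), length_s, stage.
#' @export
sample_non_so_windows <- function(so_events, mask, fs,
                                  n_windows = nrow(so_events), seed = 1,
                                  margin_s = 10, window_s = 0.5,
                                  stages = NULL) {
  stopifnot(is.logical(mask), fs > 0, n_windows >= 0)
  n <- length(mask)
  half <- as.integer(round(window_s * fs / 2))
  eligible <- mask
  # window must fit entirely inside the masked region
  if (half > 0) {
    ok <- rep(TRUE, n)
    cm <- cumsum(mask)
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half - 1L)
    full <- (cm[hi] - cm[lo] + mask[lo]) == (hi - lo + 1L)
    ok <- full & (seq_len(n) - half >= 1) & (seq_len(n) + half - 1 <= n)
    eligible <- eligible & ok
  }
  if (nrow(so_events)) {
    for (t0 in so_events$trough_time) {
      i0 <- max(1L, floor((t0 - margin_s) * fs) + 1L)
      i1 <- min(n, ceiling((t0 + margin_s) * fs) + 1L)
      eligible[i0:i1] <- FALSE
    }
  }
  pos <- which(eligible)
  if (!length(pos))
    stop("no eligible non-SO positions: every in-stage sample is within ",
         margin_s, " s of an SO trough")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  centers <- sample(pos, n_windows, replace = TRUE)
  chans <- sample(names(region_scheme()$sources), n_windows, replace = TRUE)
  stage <- if (is.null(stages)) NA_character_ else
    stages[pmin(length(stages), (centers - 1L) %/% as.integer(30 * fs) + 1L)]
  data.frame(channel = chans, center_time = (centers - 1) / fs,
             length_s = window_s, stage = stage)
}
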