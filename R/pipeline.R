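#' Write a self-contained synthetic study to disk
#'
#' Simulates `n_subjects` recordings (each with its own seed derived from
#' `seed`), writes them as plain-text matrices with JSON sidecars and text
#' hypnograms, plus per-subject spindle-event CSVs, ground-truth JSON and a
#' behavioural table. Subjects differ in their coupling-boost gain; the
#' behavioural improvement ratio is generated from that gain (the true
#' driver of measured outflow), so the planted flow-behaviour dependence is
#' recoverable downstream.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects number of subjects (default 6).
#' @param seed master seed.
#' @param duration_s,so_rate,... forwarded to [so_sim_config].
#' @param behavior_slope,behavior_noise_sd planted improvement dependence.
#' @return invisible list: `dir`, `subjects` (ids), `behavior` data frame.
#' @export
make_demo <- function(dir, n_subjects = 6, seed = 1, duration_s = 600,
                      so_rate = 1, behavior_slope = 0.2,
                      behavior_noise_sd = 0.05, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("s%02d", seq_len(n_subjects))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  boosts <- stats::runif(n_subjects, 2, 10)
  for (i in seq_len(n_subjects)) {
    cfg <- so_sim_config(duration_s = duration_s, so_rate = so_rate,
                         coupling_boost = boosts[i],
                         seed = seed * 1000L + i, ...)
    sim <- simulate_subject(cfg)
    base <- file.path(dir, ids[i])
    write_recording(sim$recording, base)
    utils::write.csv(sim$truth$spindle_events,
                     paste0(base, ".spindles.csv"), row.names = FALSE)
    truth <- sim$truth
    truth$so_events <- as.list(truth$so_events)
    jsonlite::write_json(truth, paste0(base, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  improvement <- if (n_subjects >= 3) {
    generate_behavior(boosts, behavior_slope, behavior_noise_sd,
                      seed = seed + 7L)
  } else {
    # too few subjects to standardize a flow summary; improvement is noise
    # around 1 and the behavioural regressions downstream will be skipped
    1 + stats::rnorm(n_subjects, sd = behavior_noise_sd)
  }
  presleep <- rep(0.7, n_subjects)
  behavior <- data.frame(subject_id = ids, presleep = presleep,
                         postsleep = presleep * improvement)
  utils::write.csv(behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_subjects = n_subjects,
                            duration_s = duration_s, so_rate = so_rate,
                            coupling_boost = boosts,
                            behavior_slope = behavior_slope,
                            behavior_noise_sd = behavior_noise_sd),
                       file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, subjects = ids, behavior = behavior))
}

#' Read a study directory written by [make_demo]
#'
#' @param dir study directory.
#' @return list with `subjects` (named list of `recording` + `spindles`)
#'   and `behavior` (with an `improvement` column).
#' @export
read_study <- function(dir) {
  beh <- utils::read.csv(file.path(dir, "behavior.csv"))
  if (any(beh$presleep <= 0)) stop("presleep scores must be positive")
  beh$improvement <- beh$postsleep / beh$presleep
  ids <- beh$subject_id
  subjects <- lapply(ids, function(id) {
    base <- file.path(dir, id)
    list(recording = read_recording(base),
         spindles = utils::read.csv(paste0(base, ".spindles.csv")))
  })
  names(subjects) <- ids
  list(subjects = subjects, behavior = beh)
}

# per-subject phase-resolved quantifier analysis: detects nothing itself --
# it consumes detected source-channel events and returns (a) subject-average
# phase series per (so_channel, source, sink) overall and within cluster /
# coupling strata, and (b) the long peak table rows
.subject_phase_analysis <- function(recording, events, order = 13,
                                    freqs = default_freq_grid(),
                                    freq_average = "magnitude",
                                    taper = 0.1, subject = "s",
                                    hp = highpass_connectivity(recording),
                                    ...) {
  scheme <- region_scheme()
  fs <- recording$fs
  half <- as.integer(fs)  # 1-s epoch half-width
  sinks <- c("ALL", names(scheme$regions))
  # detection-band traces are filtered on the full record (as the detector
  # sees them), then cut into epochs: filtering short epochs in isolation
  # would shift the zero crossings that anchor the phase
  bp_cache <- new.env(parent = emptyenv())
  bp_trace <- function(ch) {
    key <- tolower(ch)
    if (is.null(bp_cache[[key]])) {
      i <- match(key, tolower(recording$labels))
      bp_cache[[key]] <- bandpass_detection(recording$data[i, ], fs)
    }
    bp_cache[[key]]
  }
  # per-SO resampled series, grouped by (so_channel, source, sink)
  acc <- list()
  meta <- list()
  for (e in seq_len(nrow(events))) {
    t0 <- events$trough_time[e]
    qs <- suppressWarnings(
      so_epoch_quantifiers(hp, t0, order = order, freqs = freqs,
                           freq_average = freq_average, ...))
    if (is.null(qs)) next
    idx <- as.integer(round(t0 * fs)) + 1L
    epoch <- bp_trace(events$channel[e])[(idx - half):(idx + half - 1L)]
    ph <- so_phase(epoch, taper = taper)
    vr <- suppressWarnings(monotonic_valid_range(ph))
    if (is.null(vr)) next
    centers_idx <- as.integer(round(qs$centers_ms / 1000 * fs)) + half + 1L
    ph_centers <- ph[centers_idx]
    in_valid <- centers_idx >= vr[1] & centers_idx <= vr[2]
    if (sum(in_valid) < 2) next
    for (src in names(scheme$sources)) {
      for (sk in sinks) {
        v <- quantifier_trace(qs, src, sk)
        ps <- suppressWarnings(
          resample_to_phase(v[in_valid], ph_centers[in_valid]))
        if (is.null(ps)) next
        key <- paste(events$channel[e], src, sk, sep = "|")
        acc[[key]] <- c(acc[[key]], list(ps))
        meta[[key]] <- c(meta[[key]],
                         list(data.frame(event = e,
                                         cluster = events$cluster_label[e],
                                         coupled = events$coupling_code[e])))
      }
    }
  }
  list(series = acc, meta = meta, subject = subject)
}

# peak rows (pre + post) from an averaged series, with predictor codings
.peak_rows <- function(series, subject, so_channel, source, sink,
                       cluster_code = NA, coupling_code = NA) {
  pk <- tryCatch(extract_peaks(series), error = function(e) NULL)
  if (is.null(pk)) return(NULL)
  base <- data.frame(subject = subject, so_channel = so_channel,
                     source = source, sink = sink,
                     source_idx = channel_position(source),
                     so_channel_idx = channel_position(so_channel),
                     d_source_so = d_source_so(source, so_channel),
                     d_sink_so = if (sink == "ALL") NA_integer_ else
                       d_sink_so(sink, so_channel),
                     d_source_sink = if (sink == "ALL") NA_integer_ else
                       d_source_sink(source, sink),
                     cluster_code = cluster_code,
                     coupling_code = coupling_code)
  rbind(cbind(base, phase_code = 1L, peak_value = pk$prepeak_value,
              peak_phase = pk$prepeak_phase),
        cbind(base, phase_code = 2L, peak_value = pk$postpeak_value,
              peak_phase = pk$postpeak_phase))
}

#' Run the full analysis pipeline on a study
#'
#' Executes detection, clustering, coupling, sliding-window GPDC, phase
#' resampling, peak extraction and the inferential stage on a study (a
#' directory written by [make_demo] or the list returned by [read_study]),
#' and optionally writes all tables plus a manifest to `output_dir`. The
#' run is deterministic given the seeds in the manifest.
#'
#' @param study study directory path or [read_study] list.
#' @param output_dir optional directory for CSV/JSON outputs.
#' @param order MVAR order (default 13).
#' @param n_freq number of frequency bins.
#' @param freq_average `"magnitude"` or `"power"` (see [gpdc]).
#' @param taper phase-epoch taper fraction.
#' @param cluster_reps,cluster_seed K-modes restarts and seed.
#' @param nonso_seed seed of the non-SO window draw.
#' @param reselect_order when TRUE, re-selects the MVAR order by AIC on a
#'   sample of SO windows (up to `p_max`) instead of using `order`.
#' @param p_max upper bound for AIC re-selection.
#' @return list with `events`, `footprints`, `clusters`, `peaks` (long
#'   table), `phase_series` (per-subject averages), `nonso`, `stats`
#'   (list of `so_stats` results), `behavior`, `manifest`.
#' @export
run_pipeline <- function(study, output_dir = NULL, order = 13, n_freq = 128,
                         freq_average = "magnitude", taper = 0.1,
                         cluster_reps = 200, cluster_seed = 11,
                         nonso_seed = 17, reselect_order = FALSE,
                         p_max = 20) {
  if (is.character(study)) study <- read_study(study)
  subjects <- study$subjects
  behavior <- study$behavior
  freqs <- default_freq_grid(n_freq)
  scheme <- region_scheme()
  sources <- names(scheme$sources)

  all_events <- list(); all_fp <- list(); nonso_rows <- list()
  phase_acc <- list()
  for (id in names(subjects)) {
    rec <- subjects[[id]]$recording
    ev <- detect_sos_all(rec)
    if (!nrow(ev)) next
    fp <- build_footprints(ev, channels = rec$labels)
    ev$subject <- id
    ev$coupling_code <- flag_coupling(ev, subjects[[id]]$spindles)
    all_events[[id]] <- ev
    all_fp[[id]] <- fp
  }
  if (!length(all_events)) stop("no SOs detected in any subject")
  events <- do.call(rbind, all_events)
  footprints <- do.call(rbind, all_fp)
  cl <- kmeans_hamming(footprints, K = 2, reps = cluster_reps,
                       seed = cluster_seed)
  events$cluster_code <- cl$labels
  events$cluster_label <- cl$cluster_names[cl$labels]

  if (reselect_order) {
    samp <- list()
    for (id in names(subjects)) {
      hp <- highpass_connectivity(subjects[[id]]$recording)
      x <- analysis_matrix(hp)
      ev <- events[events$subject == id & events$channel %in% sources, ]
      for (t0 in utils::head(ev$trough_time, 3)) {
        i0 <- as.integer(round(t0 * hp$fs)) - 63L
        if (i0 >= 1 && i0 + 127 <= ncol(x))
          samp[[length(samp) + 1L]] <- x[, i0:(i0 + 127)]
      }
    }
    order <- select_order_aic(samp, p_max)
  }

  peaks <- list()
  for (id in names(subjects)) {
    rec <- subjects[[id]]$recording
    ev <- events[events$subject == id & events$channel %in% sources, ,
                 drop = FALSE]
    if (!nrow(ev)) next
    hp <- highpass_connectivity(rec)
    pa <- .subject_phase_analysis(rec, ev, order = order, freqs = freqs,
                                  freq_average = freq_average, taper = taper,
                                  subject = id, hp = hp)
    phase_acc[[id]] <- pa
    for (key in names(pa$series)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      series_all <- average_phase_series(pa$series[[key]])
      meta <- do.call(rbind, pa$meta[[key]])
      peaks[[length(peaks) + 1L]] <-
        .peak_rows(series_all, id, parts[1], parts[2], parts[3])
      for (cc in unique(meta$cluster)) {
        sub <- which(meta$cluster == cc)
        s <- tryCatch(average_phase_series(pa$series[[key]][sub]),
                      error = function(e) NULL)
        if (!is.null(s))
          peaks[[length(peaks) + 1L]] <-
            .peak_rows(s, id, parts[1], parts[2], parts[3],
                       cluster_code = match(cc, cl$cluster_names))
      }
      for (cp in unique(meta$coupled)) {
        sub <- which(meta$coupled == cp)
        s <- tryCatch(average_phase_series(pa$series[[key]][sub]),
                      error = function(e) NULL)
        if (!is.null(s))
          peaks[[length(peaks) + 1L]] <-
            .peak_rows(s, id, parts[1], parts[2], parts[3],
                       coupling_code = cp)
      }
    }
    # non-SO control windows: one per SO of this subject
    mask <- stage_mask(rec)
    nw <- tryCatch(
      sample_non_so_windows(events[events$subject == id, ], mask, rec$fs,
                            n_windows = nrow(ev), seed = nonso_seed,
                            stages = rec$stages),
      error = function(e) NULL)
    if (!is.null(nw) && nrow(nw)) {
      q <- non_so_quantifiers(hp, nw, order = order, freqs = freqs,
                              freq_average = freq_average)
      q$subject <- id
      nonso_rows[[id]] <- q
    }
  }
  peaks <- do.call(rbind, peaks)
  nonso <- if (length(nonso_rows)) do.call(rbind, nonso_rows) else NULL

  stats_out <- list()
  # SO-phase versus non-SO comparison (outflow, subject-level)
  if (!is.null(nonso)) {
    ph_rows <- list()
    for (id in names(phase_acc)) {
      pa <- phase_acc[[id]]
      keys <- names(pa$series)[endsWith(names(pa$series), "|ALL")]
      if (!length(keys)) next
      fv <- sapply(keys, function(k)
        tryCatch(extract_peaks(average_phase_series(pa$series[[k]]))$phase_values,
                 error = function(e) rep(NA_real_, 5)))
      mv <- rowMeans(matrix(fv, nrow = 5), na.rm = TRUE)
      ph_rows[[id]] <- data.frame(subject = id,
                                  condition = c("-pi", "-pi/2", "0", "pi/2", "pi"),
                                  value = mv)
    }
    nonso_mean <- stats::aggregate(value ~ subject,
                                   data = nonso[nonso$sink == "ALL", ],
                                   FUN = mean)
    nonso_mean$condition <- "nonSO"
    so_nonso <- rbind(do.call(rbind, ph_rows),
                      nonso_mean[, c("subject", "condition", "value")])
    stats_out$so_vs_nonso <- tryCatch(compare_so_vs_nonso(so_nonso),
                                      error = function(e) e$message)
  }
  # LME variants
  out_rows <- peaks[peaks$sink == "ALL" & is.na(peaks$cluster_code) &
                      is.na(peaks$coupling_code), ]
  flow_rows <- peaks[peaks$sink != "ALL" & is.na(peaks$cluster_code) &
                       is.na(peaks$coupling_code), ]
  stats_out$lme_outflow <- tryCatch(
    peak_height_lme(out_rows, c("source_idx", "so_channel_idx",
                                "d_source_so", "phase_code")),
    error = function(e) e$message)
  stats_out$lme_flow <- tryCatch(
    peak_height_lme(flow_rows, c("so_channel_idx", "d_source_so",
                                 "d_sink_so", "d_source_sink", "phase_code")),
    error = function(e) e$message)
  cl_rows <- peaks[peaks$sink != "ALL" & !is.na(peaks$cluster_code), ]
  stats_out$lme_flow_cluster <- tryCatch(
    peak_height_lme(cl_rows, c("so_channel_idx", "d_source_so", "d_sink_so",
                               "phase_code", "cluster_code")),
    error = function(e) e$message)
  cp_rows <- peaks[peaks$sink != "ALL" & !is.na(peaks$coupling_code), ]
  stats_out$lme_flow_coupling <- tryCatch(
    peak_height_lme(cp_rows, c("so_channel_idx", "d_source_so", "d_sink_so",
                               "phase_code", "coupling_code")),
    error = function(e) e$message)
  # WPA regressions on post-peak values
  if (!is.null(behavior)) {
    behav <- data.frame(subject = behavior$subject_id,
                        improvement = behavior$improvement)
    post_out <- out_rows[out_rows$phase_code == 2L, ]
    stats_out$wpa_d_source_so <- tryCatch(
      wpa_regressions(data.frame(subject = post_out$subject,
                                 group = post_out$d_source_so,
                                 value = post_out$peak_value), behav),
      error = function(e) e$message)
    post_flow <- flow_rows[flow_rows$phase_code == 2L &
                             flow_rows$d_source_sink >= 1, ]
    stats_out$wpa_d_source_sink <- tryCatch(
      wpa_regressions(data.frame(subject = post_flow$subject,
                                 group = post_flow$d_source_sink,
                                 value = post_flow$peak_value), behav),
      error = function(e) e$message)
    rel <- flow_rows$d_sink_so - flow_rows$d_source_so
    post_rel <- flow_rows[flow_rows$phase_code == 2L, ]
    rel <- rel[flow_rows$phase_code == 2L]
    stats_out$wpa_relative_distance <- tryCatch(
      wpa_regressions(data.frame(subject = post_rel$subject,
                                 group = sign(rel),
                                 value = post_rel$peak_value), behav),
      error = function(e) e$message)
  }

  manifest <- list(order = order, n_freq = n_freq,
                   freq_average = freq_average, taper = taper,
                   cluster_reps = cluster_reps, cluster_seed = cluster_seed,
                   nonso_seed = nonso_seed,
                   n_subjects = length(subjects),
                   n_events = nrow(events),
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  out <- list(events = events, footprints = footprints, clusters = cl,
              peaks = peaks, phase_series = phase_acc, nonso = nonso,
              stats = stats_out, behavior = behavior, manifest = manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(events, file.path(output_dir, "so_events.csv"),
                     row.names = FALSE)
    utils::write.csv(peaks, file.path(output_dir, "peak_table.csv"),
                     row.names = FALSE)
    if (!is.null(nonso))
      utils::write.csv(nonso, file.path(output_dir, "nonso_quantifiers.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(footprints),
                     file.path(output_dir, "footprints.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
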