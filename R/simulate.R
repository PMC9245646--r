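#' Configuration of the synthetic sleep-EEG generator
#'
#' Bundles and validates every knob of the simulator: a 22-channel, 256-Hz
#' recording of alternating Stage-2/SWS blocks, stable VAR background
#' activity with directed coupling that is boosted in a window around each
#' planted slow-oscillation trough, SO waveforms with controllable trough
#' amplitude, half-wave duration, channel footprint (global versus local)
#' and propagation lags, spindle bursts overlapping a configurable fraction
#' of SOs, and a planted linear dependence of behavioural improvement on a
#' flow summary.
#'
#' @param n_channels montage size (default 22).
#' @param fs sampling rate, Hz.
#' @param duration_s recording length, seconds.
#' @param var_order order of the background VAR process.
#' @param base_coupling N x N x var_order coefficient array; `NULL` builds
#'   the default: AR(1) diagonal 0.55 with weak directed coupling 0.04 from
#'   Fz into the other analysis channels.
#' @param noise_sd innovation standard deviation, microvolts.
#' @param so_rate planted SO events per minute per seed channel.
#' @param so_amplitude trough amplitude, microvolts (negative).
#' @param so_halfwave_ms negative half-wave duration (300-1000 ms).
#' @param so_pos_amplitude_uv positive-lobe peak of the planted waveform;
#'   `NULL` (default) uses half the trough magnitude. Equal amplitudes give
#'   a nearly sinusoidal wave whose Hilbert phase advances linearly.
#' @param global_fraction fraction of planted SOs given the global
#'   footprint.
#' @param footprint_global channel labels receiving every global SO
#'   (default: all channels).
#' @param propagation_lag_ms per-montage-step propagation lag of the SO
#'   waveform (capped at 4 steps).
#' @param coupling_boost multiplicative gain applied to the off-diagonal
#'   background coupling at the peak of each boost bump.
#' @param boost_offsets_ms centres of the Gaussian coupling-boost bumps
#'   relative to each trough (ms). The default places one bump at each edge
#'   of the negative half-wave (`+/- so_halfwave_ms / 2`), i.e. at SO
#'   phases -pi/2 and +pi/2, with coupling back at baseline at the trough
#'   itself -- the pre/post-peak flow signature.
#' @param boost_sigma_ms standard deviation of each boost bump (ms).
#' @param spindle_coupling_fraction fraction of planted SOs overlapped by a
#'   spindle burst (0-1).
#' @param behavior_slope,behavior_noise_sd parameters of the planted
#'   improvement-on-flow dependence (see [generate_behavior]).
#' @param seed RNG seed; the whole simulation is deterministic given the
#'   config.
#' @return validated list of class `so_sim_config`.
#' @export
so_sim_config <- function(n_channels = 22, fs = 256, duration_s = 600,
                          var_order = 1, base_coupling = NULL,
                          noise_sd = 15,
                          so_rate = 1, so_amplitude = -120,
                          so_halfwave_ms = 800, so_pos_amplitude_uv = NULL,
                          global_fraction = 0.5,
                          footprint_global = NULL,
                          propagation_lag_ms = 15,
                          coupling_boost = 8,
                          boost_offsets_ms = c(-1, 1) * so_halfwave_ms / 2,
                          boost_sigma_ms = 120,
                          spindle_coupling_fraction = 0.5,
                          behavior_slope = 0.2, behavior_noise_sd = 0.05,
                          seed = 1) {
  stopifnot(fs > 0, duration_s > 0, n_channels >= 12,
            so_halfwave_ms >= 300, so_halfwave_ms <= 1000,
            spindle_coupling_fraction >= 0, spindle_coupling_fraction <= 1,
            so_amplitude < 0, global_fraction >= 0, global_fraction <= 1)
  labels <- default_channel_labels()[seq_len(n_channels)]
  if (is.null(base_coupling)) {
    A <- diag(0.55, n_channels)
    from <- match("Fz", labels)
    to <- match(setdiff(region_scheme()$channels, "Fz"), labels)
    A[to, from] <- 0.05
    base_coupling <- array(A, dim = c(n_channels, n_channels, 1))
    var_order <- 1
  }
  if (is.matrix(base_coupling))
    base_coupling <- array(base_coupling, dim = c(dim(base_coupling), 1))
  stopifnot(dim(base_coupling)[1] == n_channels,
            dim(base_coupling)[3] == var_order)
  if (var_spectral_radius(base_coupling) >= 1)
    stop("base VAR coupling is unstable")
  boosted <- .boost_coeffs(base_coupling, coupling_boost)
  if (var_spectral_radius(boosted) >= 1)
    stop("boosted VAR coupling is unstable; lower coupling_boost")
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 var_order = var_order, base_coupling = base_coupling,
                 noise_sd = noise_sd, so_rate = so_rate,
                 so_amplitude = so_amplitude, so_halfwave_ms = so_halfwave_ms,
                 so_pos_amplitude_uv = so_pos_amplitude_uv,
                 global_fraction = global_fraction,
                 footprint_global = footprint_global,
                 propagation_lag_ms = propagation_lag_ms,
                 coupling_boost = coupling_boost,
                 boost_offsets_ms = boost_offsets_ms,
                 boost_sigma_ms = boost_sigma_ms,
                 spindle_coupling_fraction = spindle_coupling_fraction,
                 behavior_slope = behavior_slope,
                 behavior_noise_sd = behavior_noise_sd,
                 seed = seed, labels = labels),
            class = "so_sim_config")
}

# multiply every off-diagonal coefficient by the boost gain
.boost_coeffs <- function(A, gain) {
  B <- A
  n <- dim(A)[1]
  for (k in seq_len(dim(A)[3])) {
    off <- B[, , k]
    diag_vals <- diag(off)
    off <- off * gain
    diag(off) <- diag_vals
    B[, , k] <- off
  }
  B
}

#' Slow-oscillation waveform template
#'
#' One triphasic SO cycle built from half-sine lobes: a positive lead lobe
#' (the up-state peak preceding the down-state, SO phase -pi), the negative
#' half-wave whose trough equals `amplitude_uv` exactly and whose zero
#' crossings are `halfwave_ms` apart (phase -pi/2 to +pi/2, trough at 0),
#' and a positive trailing lobe (the following up-state, phase +pi). With
#' the default half-amplitude positive lobes of equal duration the template
#' is zero-mean and its Hilbert phase advances nearly linearly across the
#' cycle.
#'
#' @param amplitude_uv trough value in microvolts (negative).
#' @param halfwave_ms negative half-wave duration, ms.
#' @param fs sampling rate, Hz.
#' @param pos_amplitude_uv peak of the positive lobes (default half the
#'   trough magnitude).
#' @param pos_halfwave_ms duration of the trailing positive lobe (default
#'   `halfwave_ms`).
#' @param lead_in_ms duration of the leading positive lobe (default
#'   `halfwave_ms`).
#' @return numeric waveform with attributes `trough_index` (sample of the
#'   trough) and `fs`.
#' @export
#' @examples
#' w <- make_so_template(-100, 500, 256)
#' min(w)  # exactly -100
make_so_template <- function(amplitude_uv, halfwave_ms, fs,
                             pos_amplitude_uv = abs(amplitude_uv) / 2,
                             pos_halfwave_ms = halfwave_ms,
                             lead_in_ms = halfwave_ms) {
  stopifnot(amplitude_uv < 0, fs > 0)
  if (halfwave_ms <= 0 || pos_halfwave_ms <= 0 || lead_in_ms <= 0)
    stop("non-positive half-wave duration")
  half_sine <- function(amp, dur_ms) {
    m <- max(3L, round(dur_ms / 1000 * fs) - 1L)
    s <- sin(pi * seq_len(m) / (m + 1))
    amp * s / max(s)
  }
  lead <- half_sine(pos_amplitude_uv, lead_in_ms)
  neg <- half_sine(amplitude_uv, halfwave_ms)
  pos <- half_sine(pos_amplitude_uv, pos_halfwave_ms)
  w <- c(lead, 0, neg, 0, pos)
  structure(w, trough_index = length(lead) + 1L + which.min(neg), fs = fs)
}

# trough times with a minimum global separation, drawn as a jittered grid
# inside [t0, t1]
.place_troughs <- function(n, t0, t1, min_gap = 4.5) {
  if (n < 1) return(numeric(0))
  span <- t1 - t0
  if (n * min_gap > span)
    stop("SO rate too high: ", n, " events cannot keep ", min_gap,
         " s spacing within ", round(span), " s")
  slot <- span / n
  jitter_max <- max(slot - min_gap, 0.01)
  t0 + (seq_len(n) - 1) * slot + stats::runif(n, 0, jitter_max)
}

#' Simulate one subject's recording with full ground truth
#'
#' Generates a stable VAR background, embeds slow-oscillation templates on
#' global or local channel footprints with per-channel propagation lags,
#' boosts the off-diagonal VAR coupling in smooth bumps at configurable
#' offsets from each trough (so the planted flow increase is genuinely
#' autoregressive, not additive),
#' overlays spindle bursts (13 Hz, windowed sinusoid) on a configurable
#' fraction of SOs, and annotates alternating 5-min Stage-2/SWS blocks.
#' SOs are planted in the first 65% of each stage block, leaving SO-free
#' stretches from which non-SO control windows can be drawn. Deterministic
#' given the config seed.
#'
#' @param config an [so_sim_config].
#' @return list with `recording` (an `so_recording`) and `truth`, a ground
#'   truth list: `so_events` (channel, trough_time, amplitude, cluster,
#'   footprint), `spindle_events`, `boost_intervals`, `stages`.
#' @export
simulate_subject <- function(config) {
  stopifnot(inherits(config, "so_sim_config"))
  fs <- config$fs
  n_samples <- as.integer(round(config$duration_s * fs))
  labels <- config$labels
  n <- config$n_channels
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  # hypnogram: alternating 5-min N2 / SWS blocks
  n_epochs <- max(1L, floor(config$duration_s / 30))
  block <- 10L  # epochs per 5-min block
  stages <- rep(c("N2", "SWS"), each = block,
                length.out = n_epochs + block)[seq_len(n_epochs)]

  # planted troughs: jittered grid inside the first 65% of each stage block,
  # one stream per seed channel
  sources <- names(region_scheme()$sources)
  n_per_channel <- round(config$so_rate * config$duration_s / 60)
  block_s <- block * 30
  plant <- list()
  for (b in seq_len(ceiling(config$duration_s / block_s))) {
    b0 <- (b - 1) * block_s
    b1 <- min(b0 + 0.65 * block_s, config$duration_s - 2)
    plant[[b]] <- c(max(b0, 2), b1)
  }
  events <- NULL
  if (n_per_channel > 0 && config$so_rate > 0) {
    if (60 / config$so_rate < 4)
      stop("SO rate too high: inter-trough spacing below 4 s")
    total <- n_per_channel * length(sources)
    usable <- sum(vapply(plant, function(w) max(0, w[2] - w[1]), numeric(1)))
    troughs <- numeric(0)
    for (w in plant) {
      n_here <- round(total * max(0, w[2] - w[1]) / usable)
      troughs <- c(troughs, .place_troughs(n_here, w[1], w[2]))
    }
    troughs <- sort(troughs)
    ch <- sample(rep(sources, length.out = length(troughs)))
    is_global <- seq_along(troughs) %in%
      sample(length(troughs), round(config$global_fraction * length(troughs)))
    events <- data.frame(channel = ch, trough_time = troughs,
                         amplitude = config$so_amplitude,
                         cluster = ifelse(is_global, "Global", "Local"))
  }

  # background VAR with a smooth time-varying coupling gain: Gaussian bumps
  # centred at the configured offsets from each trough, so the directed
  # coupling rises at the negative half-wave edges (phases +/- pi/2) and is
  # back at baseline at the trough itself
  p <- config$var_order
  boosted <- .boost_coeffs(config$base_coupling, config$coupling_boost)
  gain <- rep(0, n_samples)
  boost_centers <- NULL
  if (!is.null(events)) {
    sig <- config$boost_sigma_ms / 1000
    tgrid <- (seq_len(n_samples) - 1) / fs
    for (t0 in events$trough_time) {
      for (off in config$boost_offsets_ms / 1000) {
        tc <- t0 + off
        i0 <- max(1L, floor((tc - 4 * sig) * fs))
        i1 <- min(n_samples, ceiling((tc + 4 * sig) * fs))
        if (i0 > i1) next
        gain[i0:i1] <- pmax(gain[i0:i1],
                            exp(-0.5 * ((tgrid[i0:i1] - tc) / sig)^2))
      }
    }
    boost_centers <- data.frame(
      trough_time = rep(events$trough_time, each = length(config$boost_offsets_ms)),
      center_s = rep(events$trough_time, each = length(config$boost_offsets_ms)) +
        rep(config$boost_offsets_ms / 1000, nrow(events)),
      sigma_s = sig, peak_gain = config$coupling_boost)
  }
  burn <- max(10L * p, 200L)
  w_innov <- matrix(stats::rnorm(n * (n_samples + burn), sd = config$noise_sd),
                    n, n_samples + burn)
  dA <- boosted - config$base_coupling
  x <- matrix(0, n, n_samples + burn)
  for (t in seq(p + 1, n_samples + burn)) {
    g <- if (t > burn) gain[t - burn] else 0
    acc <- w_innov[, t]
    for (k in seq_len(p)) {
      A <- if (g > 0) config$base_coupling[, , k] + g * dA[, , k] else
        config$base_coupling[, , k]
      acc <- acc + A %*% x[, t - k]
    }
    x[, t] <- acc
  }
  x <- x[, (burn + 1):(burn + n_samples), drop = FALSE]

  # embed SO templates on the event footprints with propagation lags
  footprints <- list()
  if (!is.null(events)) {
    template <- make_so_template(
      config$so_amplitude, config$so_halfwave_ms, fs,
      pos_amplitude_uv = if (is.null(config$so_pos_amplitude_uv))
        abs(config$so_amplitude) / 2 else config$so_pos_amplitude_uv)
    tri <- attr(template, "trough_index")
    fp_global <- if (is.null(config$footprint_global)) labels else
      config$footprint_global
    members <- region_scheme()$members
    ch_region <- region_scheme()$channel_region
    for (e in seq_len(nrow(events))) {
      seed_ch <- events$channel[e]
      fp <- if (events$cluster[e] == "Global") fp_global else
        members[[ch_region[[match(seed_ch, region_scheme()$channels)]]]]
      footprints[[e]] <- fp
      i_seed <- match(seed_ch, labels)
      t_idx <- as.integer(round(events$trough_time[e] * fs)) + 1L
      for (ch in fp) {
        j <- match(ch, labels)
        lag <- round(config$propagation_lag_ms / 1000 * fs *
                       min(4L, abs(j - i_seed)))
        i0 <- t_idx - tri + 1L + lag
        i1 <- i0 + length(template) - 1L
        if (i0 < 1 || i1 > n_samples) next
        x[j, i0:i1] <- x[j, i0:i1] + template
      }
    }
    events$footprint <- vapply(footprints, paste, character(1), collapse = ",")
  }

  # spindle bursts on a fraction of SOs (plus the ground-truth intervals)
  spindles <- data.frame(channel = character(), start_s = numeric(),
                         end_s = numeric())
  if (!is.null(events) && config$spindle_coupling_fraction > 0) {
    n_sp <- round(config$spindle_coupling_fraction * nrow(events))
    which_sp <- sample(nrow(events), n_sp)
    dur <- 0.8
    for (e in which_sp) {
      t0 <- events$trough_time[e] + 0.25
      i0 <- as.integer(round(t0 * fs)) + 1L
      i1 <- i0 + as.integer(dur * fs) - 1L
      if (i1 > n_samples) next
      j <- match(events$channel[e], labels)
      tt <- seq(0, dur - 1 / fs, by = 1 / fs)
      burst <- 20 * sin(2 * pi * 13 * tt) * 0.5 * (1 - cos(2 * pi * tt / dur))
      x[j, i0:i1] <- x[j, i0:i1] + burst
      spindles <- rbind(spindles,
                        data.frame(channel = events$channel[e],
                                   start_s = t0, end_s = t0 + dur))
    }
    if (!is.null(events))
      events$coupled <- seq_len(nrow(events)) %in% which_sp
  }

  rec <- recording(x, fs = fs, labels = labels, stages = stages)
  truth <- list(so_events = events, spindle_events = spindles,
                boost_schedule = boost_centers, stages = stages,
                config_seed = config$seed)
  list(recording = rec, truth = truth)
}

#' Planted behavioural improvement ratios
#'
#' Generates per-subject word-pair-association improvement ratios with a
#' linear dependence on a per-subject flow summary:
#' `improvement_i = 1 + slope * standardize(flow_i) + e_i`,
#' `e ~ N(0, noise_sd^2)`.
#'
#' @param flow_summaries per-subject numeric summary of flow (>= 3
#'   subjects, non-zero variance).
#' @param slope planted slope on the standardized flow.
#' @param noise_sd residual standard deviation.
#' @param seed RNG seed.
#' @return numeric vector of improvement ratios, names preserved.
#' @export
generate_behavior <- function(flow_summaries, slope, noise_sd, seed = 1) {
  if (length(flow_summaries) < 3)
    stop("need at least 3 subjects")
  if (stats::sd(flow_summaries) == 0)
    stop("zero-variance flow summaries: standardization undefined")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  z <- as.numeric(scale(flow_summaries))
  out <- 1 + slope * z + stats::rnorm(length(z), sd = noise_sd)
  names(out) <- names(flow_summaries)
  out
}
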