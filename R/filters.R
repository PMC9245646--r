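#' Butterworth filter as second-order sections
#'
#' Designs a digital Butterworth low- or high-pass filter of arbitrary order
#' and returns it as a cascade of second-order sections (biquads). High-order
#' Butterworth designs (the connectivity preprocessing uses order 46) are
#' numerically unusable in expanded transfer-function form; the cascade form
#' keeps each section well conditioned.
#'
#' @param order filter order (>= 1).
#' @param fc cutoff frequency in Hz (-3 dB point).
#' @param fs sampling rate in Hz.
#' @param type `"high"` or `"low"`.
#' @return an object of class `butter_sos`: a list with a `sos` matrix
#'   (one row per section, columns b0 b1 b2 a0 a1 a2) and the design
#'   parameters.
#' @keywords internal
butter_sos <- function(order, fc, fs, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fs > 0, fc < fs / 2)
  # analog prototype poles (Butterworth, unit cutoff, left half-plane)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p <- complex(modulus = 1, argument = theta)
  warp <- tan(pi * fc / fs)        # bilinear pre-warped analog cutoff
  if (type == "low") {
    p <- p * warp
    z_ref <- 1 + 0i                # DC: unity gain reference
    zero_z <- -1                   # n zeros at z = -1
  } else {
    p <- warp / p
    z_ref <- -1 + 0i               # Nyquist reference
    zero_z <- 1                    # n zeros at z = +1
  }
  # bilinear transform s = (z - 1)/(z + 1)
  pz <- (1 + p) / (1 - p)
  # pair conjugate poles into biquads; odd order leaves one real pole
  ord <- order(Im(pz))             # conjugates symmetric about real axis
  pz <- pz[ord]
  sos <- NULL
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    pi1 <- pz[i]
    if (abs(Im(pi1)) < 1e-12) {
      j <- which(!used & abs(Im(pz)) < 1e-12 & seq_len(order) != i)
      if (length(j)) {             # pair two real poles
        j <- j[1]
        a <- c(1, -Re(pi1 + pz[j]), Re(pi1 * pz[j]))
        b <- c(1, -2 * zero_z, 1)
        used[c(i, j)] <- TRUE
      } else {                     # first-order section
        a <- c(1, -Re(pi1), 0)
        b <- c(1, -zero_z, 0)
        used[i] <- TRUE
      }
    } else {
      j <- which(!used & abs(pz - Conj(pi1)) < 1e-9)[1]
      a <- c(1, -2 * Re(pi1), abs(pi1)^2)
      b <- c(1, -2 * zero_z, 1)
      used[c(i, j)] <- TRUE
    }
    # normalise each section to unit gain at the reference frequency
    g <- sum(b * z_ref^(0:-2)) / sum(a * z_ref^(0:-2))
    sos <- rbind(sos, c(b / abs(Re(g)), a))
  }
  # slowest pole governs transient decay, hence the filtfilt padding length
  rmax <- max(Mod(pz))
  structure(list(sos = sos, order = order, fc = fc, fs = fs, type = type,
                 pole_radius = rmax),
            class = "butter_sos")
}

# direct-form II transposed single-section filter (vectorised inner state)
.filter_ba <- function(b, a, x) {
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Applies each biquad forward and backward (filtfilt), with odd-reflection
#' padding at both ends to suppress edge transients, so the overall filter
#' has exactly zero phase and squared magnitude response.
#'
#' @param filt a `butter_sos` object.
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @keywords internal
sos_filtfilt <- function(filt, x) {
  stopifnot(inherits(filt, "butter_sos"))
  n <- length(x)
  # demeaning is exact for a high-pass (DC gain 0) and is restored for a
  # low-pass (DC gain 1); it prevents a large step transient at the pad edge
  m <- mean(x)
  x <- x - m
  tc <- 6 / max(1e-6, 1 - filt$pole_radius)
  npad <- min(n - 1L, max(3L * filt$order, ceiling(tc)))
  left <- 2 * x[1] - x[seq(npad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - npad)]
  y <- c(left, x, right)
  for (s in seq_len(nrow(filt$sos))) {
    b <- filt$sos[s, 1:3]; a <- filt$sos[s, 4:6]
    y <- .filter_ba(b, a, y)
    y <- rev(.filter_ba(b, a, rev(y)))
  }
  y <- y[seq(npad + 1, npad + n)]
  if (filt$type == "low") y + m else y
}

#' High-pass preprocessing for the connectivity stage
#'
#' Filters every channel of a recording with a zero-phase order-46
#' Butterworth high-pass (stopband edge 0.5 Hz; -3 dB cutoff 0.6 Hz),
#' removing DC and slow drifts before MVAR fitting. Forward-backward
#' application keeps event timing (trough latency) unshifted.
#'
#' Only the 12 analysis channels are filtered (they are the only ones the
#' connectivity stage reads); other channels are retained untouched.
#'
#' @param recording a [recording] object.
#' @param fc -3 dB cutoff in Hz.
#' @param order filter order of the underlying one-way Butterworth design.
#' @param channels channel labels to filter (default: the analysis set).
#' @return the recording with filtered `data`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(22 * 2560), 22), fs = 256,
#'                  labels = default_channel_labels(),
#'                  stages = c("N2", "N2", "N2", "N2", "N2", "N2", "N2",
#'                             "N2", "N2", "N2"))
#' hp <- highpass_connectivity(rec)
highpass_connectivity <- function(recording, fc = 0.6, order = 46,
                                  channels = NULL) {
  stopifnot(inherits(recording, "so_recording"))
  if (recording$fs < 2) stop("sampling rate below 2 Hz; cannot filter")
  filt <- butter_sos(order, fc, recording$fs, "high")
  rows <- if (is.null(channels)) unname(recording$analysis_index) else
    match(tolower(channels), tolower(recording$labels))
  for (i in rows)
    recording$data[i, ] <- sos_filtfilt(filt, recording$data[i, ])
  recording$filtered <- "highpass"
  recording
}

#' Band-pass filtering for SO detection and phase estimation
#'
#' Zero-phase 0.1-4 Hz band-pass (order-4 Butterworth high- and low-pass in
#' cascade), the band in which slow-oscillation zero crossings and Hilbert
#' phase are evaluated.
#'
#' @param recording a [recording] object, or a numeric matrix
#'   (channels x samples) with attribute-free data plus `fs`.
#' @param fs sampling rate (only needed when `recording` is a bare matrix).
#' @param band numeric length-2, passband edges in Hz.
#' @return same shape as the input, filtered.
#' @export
bandpass_detection <- function(recording, fs = NULL, band = c(0.1, 4)) {
  if (inherits(recording, "so_recording")) {
    recording$data <- bandpass_detection(recording$data, recording$fs, band)
    recording$filtered <- "bandpass"
    return(recording)
  }
  x <- recording
  stopifnot(is.numeric(fs), fs > 0)
  hp <- butter_sos(4, band[1], fs, "high")
  lp <- butter_sos(4, band[2], fs, "low")
  f1 <- function(ch) sos_filtfilt(lp, sos_filtfilt(hp, ch))
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}
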