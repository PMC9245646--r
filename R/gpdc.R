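#' Default normalized frequency grid
#'
#' 128 uniformly spaced bins on normalized frequency (0, 0.5], i.e. 1-Hz
#' spacing (1-128 Hz) at a 256-Hz sampling rate.
#' @param n_bins number of bins.
#' @return numeric vector of normalized frequencies.
#' @export
default_freq_grid <- function(n_bins = 128) seq_len(n_bins) / (2 * n_bins)

#' Spectral transfer matrix of an MVAR coefficient set
#'
#' Computes `Abar_ij(f) = delta_ij - sum_k a_ij(k) exp(-2 pi i f k)` on a
#' grid of normalized frequencies.
#'
#' @param A N x N x p coefficient array.
#' @param freqs normalized frequencies in `[0, 0.5]`.
#' @return complex array N x N x length(freqs).
#' @export
mvar_transfer <- function(A, freqs) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1))
  n <- dim(A)[1]; p <- dim(A)[3]; nf <- length(freqs)
  E <- exp(-2i * pi * outer(seq_len(p), freqs))          # p x F
  Amat <- matrix(A, n * n, p)                            # vec over (i,j)
  Aw <- Amat %*% E                                       # (N^2) x F complex
  Abar <- -Aw
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)
  Abar[diag_idx, ] <- Abar[diag_idx, ] + 1
  array(Abar, dim = c(n, n, nf))
}

#' Generalized partial directed coherence of a fitted MVAR model
#'
#' From the coefficient spectrum `Abar(f)` and the innovation covariance
#' `Sigma`, computes
#' `|pibar_ij(f)| = (1/sigma_i) |Abar_ij(f)| /
#'    sqrt( sum_k (1/sigma_k^2) |Abar_kj(f)|^2 )`
#' with `sigma_i = sqrt(Sigma_ii)`. Column j holds the directed flow from
#' channel j to every channel i; each column is normalized so the squared
#' entries sum to one at every frequency, so flows are comparable only
#' within a column. The residual-variance weighting makes the measure
#' insensitive to amplitude differences between channels.
#'
#' @param model an [mvar] fit (or a list with `A` and `Sigma`).
#' @param freqs normalized frequency grid (default [default_freq_grid]).
#' @param freq_average `"magnitude"` averages `|pibar|` over frequencies;
#'   `"power"` averages `|pibar|^2` and stores the root, so that squaring
#'   the averaged matrix recovers the mean squared coherence.
#' @return an object of class `gpdc`: list with `pi_f` (N x N x F array of
#'   `|pibar_ij(f)|`), `pi_avg` (N x N frequency-averaged matrix), `freqs`,
#'   `labels`.
#' @export
#' @examples
#' x <- simulate_var(matrix(c(0.5, 0.5, 0, 0), 2, 2), diag(2), 2000, seed = 1)
#' g <- gpdc(mvar(x, 1))
#' g$pi_avg
gpdc <- function(model, freqs = default_freq_grid(),
                 freq_average = c("magnitude", "power")) {
  freq_average <- match.arg(freq_average)
  A <- model$A; Sigma <- model$Sigma
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1))
  n <- dim(A)[1]; nf <- length(freqs)
  sdiag <- diag(Sigma)
  if (any(sdiag <= 0)) stop("innovation covariance has non-positive diagonal")
  sdv <- sqrt(sdiag)
  Abar <- mvar_transfer(A, freqs)
  P <- Mod(Abar)^2                                       # |Abar|^2
  wP <- P * (1 / sdiag)                                  # row-weighted
  denom <- matrix(colSums(matrix(wP, n, n * nf)), n, nf) # j x f
  num <- Mod(Abar) * (1 / sdv)
  D <- aperm(array(sqrt(denom), dim = c(n, nf, n)), c(3, 1, 2))
  pi_f <- num / D
  pi_avg <- if (freq_average == "magnitude") {
    matrix(rowMeans(matrix(pi_f, n * n, nf)), n, n)
  } else {
    matrix(sqrt(rowMeans(matrix(pi_f^2, n * n, nf))), n, n)
  }
  labels <- model$labels
  if (!is.null(labels)) dimnames(pi_avg) <- list(labels, labels)
  structure(list(pi_f = pi_f, pi_avg = pi_avg, freqs = freqs,
                 labels = labels, freq_average = freq_average),
            class = "gpdc")
}

#' @export
print.gpdc <- function(x, ...) {
  n <- nrow(x$pi_avg)
  cat("GPDC over", length(x$freqs), "frequency bins,", n, "channels (",
      x$freq_average, "average )\n")
  cat("Frequency-averaged flow matrix (columns = sources):\n")
  print(round(x$pi_avg, 3))
  invisible(x)
}

#' Flow quantifiers from a frequency-averaged GPDC matrix
#'
#' Two event-level summaries of directed flow out of a source channel CH:
#' the flow into one sink region, `CH->R = sum_{i in R} pi(i, CH)^2`, and the
#' total outflow `CHoutflow = sum over sink regions other than CH's own
#' region of CH->R` (same-region channels are excluded by construction).
#'
#' @param pi_avg 12 x 12 frequency-averaged GPDC matrix in the fixed
#'   analysis-channel order ([region_scheme]`()$channels`).
#' @param source source channel label, one of Fz, Cz, Pz, POz.
#' @param scheme a [region_scheme] list.
#' @return named numeric vector: `ALL` (CHoutflow) then `F`, `C`, `P`, `O`
#'   (CH->R per region).
#' @export
quantifiers <- function(pi_avg, source, scheme = region_scheme()) {
  if (!source %in% names(scheme$sources))
    stop("unknown source channel: ", source)
  stopifnot(all(dim(pi_avg) == length(scheme$channels)))
  j <- match(source, scheme$channels)
  src_region <- scheme$channel_region[[j]]
  col <- pi_avg[, j]
  by_region <- vapply(names(scheme$members), function(r) {
    sum(col[match(scheme$members[[r]], scheme$channels)]^2)
  }, numeric(1))
  outflow <- sum(by_region[names(by_region) != src_region])
  c(ALL = outflow, by_region)
}

#' Sliding-window GPDC around one slow-oscillation trough
#'
#' Extracts the 2-s epoch (1 s either side of the trough) of the 12
#' analysis channels, slides a 0.5-s window with a 2-sample stride
#' (7.8 ms at 256 Hz; 193 windows), fits an MVAR model per window
#' (demeaned), computes GPDC, and evaluates the flow quantifiers for all
#' four source channels. Values are assigned to the central sample of each
#' window, so window centers span -750 ms to +750 ms around the trough.
#'
#' @param recording an `so_recording`, already high-pass filtered
#'   ([highpass_connectivity]).
#' @param trough_time trough time in seconds from recording start.
#' @param order MVAR model order (default 13).
#' @param freqs normalized frequency grid.
#' @param window_s window length in seconds.
#' @param stride stride in samples.
#' @param half_epoch_s epoch half-width in seconds.
#' @param freq_average passed to [gpdc].
#' @param method passed to [mvar].
#' @return an object of class `so_quantifier_series`: list with
#'   `centers_ms` (window centers relative to the trough), `pi_avg`
#'   (12 x 12 x n_windows array), and `series` (long data frame: source,
#'   sink in ALL/F/C/P/O, center_ms, value). Returns `NULL` with a warning
#'   when the epoch crosses a record edge.
#' @export
so_epoch_quantifiers <- function(recording, trough_time, order = 13,
                                 freqs = default_freq_grid(),
                                 window_s = 0.5, stride = 2L,
                                 half_epoch_s = 1,
                                 freq_average = "magnitude",
                                 method = "auto") {
  stopifnot(inherits(recording, "so_recording"))
  fs <- recording$fs
  x <- analysis_matrix(recording)
  half <- as.integer(round(half_epoch_s * fs))
  idx <- as.integer(round(trough_time * fs)) + 1L
  if (idx - half < 1 || idx + half - 1 > ncol(x)) {
    warning("epoch at t = ", trough_time, " s crosses the record edge; skipped")
    return(NULL)
  }
  epoch <- x[, (idx - half):(idx + half - 1), drop = FALSE]
  wlen <- as.integer(round(window_s * fs))
  starts <- seq(1L, ncol(epoch) - wlen + 1L, by = stride)
  centers_ms <- (starts + wlen / 2 - (half + 1)) / fs * 1000
  scheme <- region_scheme()
  n <- nrow(epoch)
  srcs <- names(scheme$sources)
  sink_names <- c("ALL", names(scheme$regions))
  pi_stack <- array(NA_real_, dim = c(n, n, length(starts)))
  qarr <- array(NA_real_, dim = c(5L, length(srcs), length(starts)))
  for (w in seq_along(starts)) {
    win <- epoch[, starts[w]:(starts[w] + wlen - 1L), drop = FALSE]
    fit <- mvar(win, order, method = method)
    g <- gpdc(fit, freqs, freq_average)
    pi_stack[, , w] <- g$pi_avg
    for (s in seq_along(srcs))
      qarr[, s, w] <- quantifiers(g$pi_avg, srcs[s], scheme)
  }
  series <- data.frame(
    source = rep(rep(srcs, each = 5L), length(starts)),
    sink = rep(sink_names, length(srcs) * length(starts)),
    center_ms = rep(centers_ms, each = 5L * length(srcs)),
    value = as.vector(qarr))
  structure(list(centers_ms = centers_ms,
                 pi_avg = pi_stack,
                 series = series,
                 trough_time = trough_time, fs = fs, order = order),
            class = "so_quantifier_series")
}

#' @export
print.so_quantifier_series <- function(x, ...) {
  cat("SO-locked quantifier series:", length(x$centers_ms), "windows,",
      "centers", min(x$centers_ms), "to", max(x$centers_ms), "ms,",
      "MVAR order", x$order, "\n")
  invisible(x)
}

#' Extract one quantifier trace from an `so_quantifier_series`
#' @param qs an `so_quantifier_series`.
#' @param source source channel label.
#' @param sink `"ALL"` for CHoutflow or a region letter F/C/P/O.
#' @return numeric vector, one value per window center.
#' @export
quantifier_trace <- function(qs, source, sink = "ALL") {
  s <- qs$series
  v <- s$value[s$source == source & s$sink == sink]
  if (!length(v)) stop("no such source/sink combination")
  v
}

#' GPDC quantifiers in non-SO control windows
#'
#' Fits one MVAR + GPDC per 0.5-s control window and returns the flow
#' quantifiers for the window's designated source channel.
#'
#' @param recording high-pass filtered `so_recording`.
#' @param windows data frame with columns `channel` (source label) and
#'   `center_time` (seconds), as produced by [sample_non_so_windows].
#' @param order MVAR order.
#' @param freqs normalized frequency grid.
#' @param window_s window length in seconds.
#' @param freq_average,method passed through.
#' @return data frame: channel, center_time, sink, value.
#' @export
non_so_quantifiers <- function(recording, windows, order = 13,
                               freqs = default_freq_grid(), window_s = 0.5,
                               freq_average = "magnitude", method = "auto") {
  stopifnot(inherits(recording, "so_recording"), is.data.frame(windows))
  fs <- recording$fs
  x <- analysis_matrix(recording)
  wlen <- as.integer(round(window_s * fs))
  scheme <- region_scheme()
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    c_idx <- as.integer(round(windows$center_time[i] * fs)) + 1L
    i0 <- c_idx - wlen %/% 2L
    i1 <- i0 + wlen - 1L
    if (i0 < 1 || i1 > ncol(x))
      stop("non-SO window at t = ", windows$center_time[i],
           " s overlaps the record edge")
    fit <- mvar(x[, i0:i1, drop = FALSE], order, method = method)
    g <- gpdc(fit, freqs, freq_average)
    q <- quantifiers(g$pi_avg, windows$channel[i], scheme)
    out[[i]] <- data.frame(channel = windows$channel[i],
                           center_time = windows$center_time[i],
                           sink = names(q), value = unname(q))
  }
  do.call(rbind, out)
}
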