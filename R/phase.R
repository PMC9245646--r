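# analytic signal via the frequency-domain Hilbert transform
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# unwrap a wrapped phase sequence (inverse of wrapping to (-pi, pi])
.unwrap <- function(p) {
  dp <- diff(p)
  dp <- (dp + pi) %% (2 * pi) - pi
  cumsum(c(p[1], dp))
}

#' Instantaneous slow-oscillation phase of a trough-centred epoch
#'
#' Computes the Hilbert-transform phase of the negated 0.1-4 Hz filtered
#' epoch (negation maps the SO trough onto the analytic-signal peak), with
#' an optional cosine taper on the outer fraction of the epoch to limit
#' edge artifacts. The unwrapped phase is shifted so the value at the
#' trough sample is exactly zero: the trough is phase 0, the preceding
#' positive EEG peak is near -pi and the following one near +pi.
#'
#' @param epoch numeric vector: band-passed trace 1 s either side of the
#'   trough (trough at sample `length(epoch)/2 + 1`).
#' @param taper fraction (0-0.5) of the epoch length tapered at each end;
#'   0 disables tapering.
#' @return numeric vector of unwrapped phase (radians), one per sample,
#'   zero at the trough sample; attribute `"center"` holds the trough index.
#' @export
#' @examples
#' t <- seq(0, 2 - 1 / 256, by = 1 / 256)
#' epoch <- -cos(2 * pi * 0.5 * (t - 1))   # trough at t = 1 s
#' ph <- so_phase(epoch, taper = 0)
#' ph[[257]]  # 0 at the trough
so_phase <- function(epoch, taper = 0.1) {
  stopifnot(is.numeric(epoch), length(epoch) >= 8)
  if (stats::sd(epoch) == 0) stop("zero-variance epoch: phase undefined")
  n <- length(epoch)
  center <- n %/% 2 + 1L
  x <- -epoch
  if (taper > 0) {
    m <- max(1L, floor(taper * n))
    w <- rep(1, n)
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
    w[seq_len(m)] <- ramp
    w[seq(n, n - m + 1)] <- ramp
    x <- x * w
  }
  ph <- .unwrap(Arg(.analytic(x)))
  ph <- ph - ph[center]
  attr(ph, "center") <- center
  ph
}

#' Largest monotonic phase interval around the trough
#'
#' Returns the largest contiguous sample interval containing the trough on
#' which the unwrapped phase increases strictly, intersected with phase in
#' `[-pi, pi]`. Only this interval is used when resampling quantifiers onto
#' the phase grid.
#'
#' @param phase unwrapped phase from [so_phase] (attribute `"center"` used
#'   as the trough index unless `center` is given).
#' @param center trough sample index.
#' @return integer vector `c(first, last)` of the valid interval, or `NULL`
#'   (with a warning) when the interval is shorter than 3 samples.
#' @export
monotonic_valid_range <- function(phase, center = attr(phase, "center")) {
  stopifnot(is.numeric(phase), !is.null(center))
  n <- length(phase)
  inc <- diff(phase) > 0
  lo <- center
  while (lo > 1 && inc[lo - 1]) lo <- lo - 1
  hi <- center
  while (hi < n && inc[hi]) hi <- hi + 1
  # clip to [-pi, pi]; phase is increasing on [lo, hi]
  idx <- lo:hi
  idx <- idx[phase[idx] >= -pi & phase[idx] <= pi]
  if (length(idx) < 3) {
    warning("monotonic phase interval shorter than 3 samples; event skipped")
    return(NULL)
  }
  c(min(idx), max(idx))
}

#' The fixed slow-oscillation phase grid
#'
#' 129 phases from -pi to pi in steps of pi/64.
#' @return numeric vector of length 129.
#' @export
so_phase_grid <- function() seq(-pi, pi, by = pi / 64)

#' Resample a quantifier time series onto the SO phase grid
#'
#' Maps each window-centre value to its SO phase and linearly interpolates
#' onto the fixed grid (-pi to pi, step pi/64). Grid points outside the
#' covered phase range are missing (NA).
#'
#' @param values quantifier values, one per window centre.
#' @param phases unwrapped SO phase at each window centre (same length).
#' @param valid optional `c(first, last)` index interval (from
#'   [monotonic_valid_range], expressed in window indices) restricting the
#'   pairs used.
#' @param grid phase grid (default [so_phase_grid]).
#' @return object of class `phase_series`: list with `grid`, `values`
#'   (NA outside the covered range) and `n` (1 where defined), or `NULL`
#'   (with a warning) when fewer than 2 valid pairs exist.
#' @export
resample_to_phase <- function(values, phases, valid = NULL,
                              grid = so_phase_grid()) {
  stopifnot(length(values) == length(phases))
  keep <- is.finite(values) & is.finite(phases)
  if (!is.null(valid)) {
    sel <- rep(FALSE, length(values))
    sel[valid[1]:valid[2]] <- TRUE
    keep <- keep & sel
  }
  if (sum(keep) < 2) {
    warning("fewer than 2 valid (phase, value) pairs; event skipped")
    return(NULL)
  }
  v <- stats::approx(phases[keep], values[keep], xout = grid,
                     method = "linear", rule = 1, ties = "ordered")$y
  structure(list(grid = grid, values = v, n = as.integer(!is.na(v))),
            class = "phase_series")
}

#' Average phase series pointwise
#'
#' Pointwise available-case mean over a group of per-SO phase series
#' (missing grid points are ignored per point); the per-point contributing
#' count is retained.
#'
#' @param series_list non-empty list of `phase_series` objects (NULL
#'   entries, e.g. skipped events, are dropped).
#' @return a `phase_series` whose `values` are pointwise means and `n` the
#'   per-point counts.
#' @export
average_phase_series <- function(series_list) {
  series_list <- Filter(Negate(is.null), series_list)
  if (!length(series_list)) stop("empty group: no phase series to average")
  grid <- series_list[[1]]$grid
  V <- vapply(series_list, function(s) s$values, numeric(length(grid)))
  V <- matrix(V, nrow = length(grid))
  n <- rowSums(!is.na(V))
  m <- rowSums(V, na.rm = TRUE) / ifelse(n > 0, n, NA)
  structure(list(grid = grid, values = m, n = n), class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("Phase series on", length(x$grid), "grid points;",
      sum(!is.na(x$values)), "defined\n")
  invisible(x)
}

#' @export
plot.phase_series <- function(x, ...) {
  graphics::plot(x$grid, x$values, type = "l", xlab = "SO phase (rad)",
                 ylab = "quantifier", xaxt = "n", ...)
  graphics::axis(1, at = c(-pi, -pi / 2, 0, pi / 2, pi),
                 labels = expression(-pi, -pi / 2, 0, pi / 2, pi))
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Pre- and post-trough peak extraction from a subject phase series
#'
#' The prepeak is the maximum over grid points with phase in (-pi, 0), the
#' postpeak the maximum over (0, pi); the trough value is the value at
#' phase 0. Values at the five canonical phases -pi, -pi/2, 0, pi/2 and pi
#' are returned as well for the SO versus non-SO comparison. Ties are
#' broken toward the earliest grid point.
#'
#' @param series a `phase_series` (typically a per-subject average).
#' @return list with `prepeak_value`, `prepeak_phase`, `postpeak_value`,
#'   `postpeak_phase`, `trough_value` and `phase_values` (named numeric,
#'   the five canonical phases).
#' @export
extract_peaks <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  g <- series$grid; v <- series$values
  i0 <- which.min(abs(g))               # phase 0
  if (is.na(v[i0])) stop("series undefined at phase 0")
  pre <- which(g > -pi & g < 0)
  post <- which(g > 0 & g < pi)
  pick <- function(idx) {
    ok <- idx[!is.na(v[idx])]
    if (!length(ok)) stop("series undefined on a half-range")
    ok[which.max(v[ok])]
  }
  ip <- pick(pre); iq <- pick(post)
  five <- c(-pi, -pi / 2, 0, pi / 2, pi)
  iv <- vapply(five, function(p) which.min(abs(g - p)), integer(1))
  list(prepeak_value = v[ip], prepeak_phase = g[ip],
       postpeak_value = v[iq], postpeak_phase = g[iq],
       trough_value = v[i0],
       phase_values = stats::setNames(v[iv],
                                      c("-pi", "-pi/2", "0", "pi/2", "pi")))
}
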