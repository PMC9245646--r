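#' Companion matrix and spectral radius of a VAR coefficient set
#'
#' @param A coefficient array N x N x p (or N x N matrix for p = 1);
#'   `A[i, j, k]` is the effect of channel j at lag k on channel i.
#' @return the Np x Np companion matrix.
#' @keywords internal
var_companion <- function(A) {
  if (is.matrix(A)) A <- array(A, dim = c(nrow(A), ncol(A), 1))
  n <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[1:n, ((k - 1) * n + 1):(k * n)] <- A[, , k]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  C
}

#' @rdname var_companion
#' @return `var_spectral_radius`: the modulus of the largest eigenvalue; the
#'   process is (covariance-)stationary iff this is < 1.
#' @keywords internal
var_spectral_radius <- function(A) {
  max(Mod(eigen(var_companion(A), only.values = TRUE)$values))
}

#' Stationary covariance of a stable VAR process
#'
#' Solves the discrete Lyapunov equation for the companion form,
#' `P = C P C' + Q`, by the closed-form vectorisation
#' `vec(P) = (I - C %x% C)^{-1} vec(Q)`, and returns the top-left N x N
#' block (the stationary covariance of the observed vector).
#'
#' @inheritParams var_companion
#' @param noise_cov innovation covariance, N x N.
#' @return N x N stationary covariance matrix.
#' @export
var_stationary_cov <- function(A, noise_cov) {
  if (is.matrix(A)) A <- array(A, dim = c(nrow(A), ncol(A), 1))
  n <- dim(A)[1]; p <- dim(A)[3]
  C <- var_companion(A)
  Q <- matrix(0, n * p, n * p)
  Q[1:n, 1:n] <- noise_cov
  m <- n * p
  vecP <- solve(diag(m * m) - C %x% C, as.vector(Q))
  matrix(vecP, m, m)[1:n, 1:n]
}

#' Simulate a stable vector autoregressive process
#'
#' Generates `X(t) = sum_k A_k X(t-k) + w(t)` with Gaussian innovations
#' `w ~ N(0, noise_cov)`. A burn-in of `max(10 p, 200)` samples is generated
#' and discarded so the returned series is (approximately) stationary.
#'
#' @param coeffs N x N x p coefficient array (N x N matrix accepted for
#'   p = 1).
#' @param noise_cov N x N symmetric positive-definite innovation covariance.
#' @param n_samples number of samples to return.
#' @param seed optional integer; when given, the RNG state is set locally.
#' @return N x n_samples numeric matrix.
#' @export
#' @examples
#' x <- simulate_var(matrix(0.9), matrix(1), 1000, seed = 1)
simulate_var <- function(coeffs, noise_cov, n_samples, seed = NULL) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, dim = c(dim(coeffs), 1))
  n <- dim(coeffs)[1]; p <- dim(coeffs)[3]
  stopifnot(dim(coeffs)[2] == n, all(dim(noise_cov) == n), n_samples >= 1)
  rho <- var_spectral_radius(coeffs)
  if (rho >= 1)
    stop("unstable VAR coefficients: companion spectral radius ",
         format(rho, digits = 4), " >= 1")
  if (max(abs(noise_cov - t(noise_cov))) > 1e-8)
    stop("noise covariance must be symmetric")
  L <- tryCatch(chol(noise_cov),
                error = function(e) stop("noise covariance is not positive definite"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  burn <- max(10L * p, 200L)
  total <- n_samples + burn
  w <- t(L) %*% matrix(stats::rnorm(n * total), n, total)
  x <- matrix(0, n, total)
  for (t in seq(p + 1, total)) {
    acc <- w[, t]
    for (k in seq_len(p)) acc <- acc + coeffs[, , k] %*% x[, t - k]
    x[, t] <- acc
  }
  x[, (burn + 1):total, drop = FALSE]
}

#' Fit a multivariate autoregressive (MVAR) model to a data window
#'
#' Models `X(t) = sum_{k=1}^p A_k X(t-k) + w(t)` on a channels x samples
#' window. Two estimators are available: multivariate least squares over
#' lag-stacked regressors (`"ls"`), and block Yule-Walker on biased sample
#' autocovariances (`"yw"`), the standard short-window MVAR estimator. Least
#' squares requires more equations than unknowns (`W - p > N * p`); the
#' default `"auto"` uses least squares when that holds and Yule-Walker
#' otherwise, which is what the 0.5-s sliding windows of the connectivity
#' stage need at the default order 13 with 12 channels.
#'
#' @param x numeric matrix, channels x samples (N x W).
#' @param order model order p (number of lags).
#' @param method `"auto"`, `"ls"` or `"yw"`.
#' @param demean subtract each channel's window mean first (default TRUE).
#' @return an object of class `mvar` with components `A` (N x N x p
#'   coefficient array; `A[i, j, k]` = effect of channel j at lag k on
#'   channel i), `Sigma` (residual covariance), `order`, `method`, `nobs`,
#'   `labels`, and (for `"ls"`) `resid`.
#' @export
#' @examples
#' x <- simulate_var(matrix(c(0.5, 0.3, 0, 0.4), 2, 2), diag(2), 2000, seed = 1)
#' fit <- mvar(x, order = 1)
#' coef(fit)[, , 1]
mvar <- function(x, order, method = c("auto", "ls", "yw"), demean = TRUE) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), is.numeric(x), order >= 1)
  n <- nrow(x); w <- ncol(x); p <- as.integer(order)
  if (w <= p) stop("window of ", w, " samples cannot support order ", p)
  mu <- rowMeans(x)
  if (demean) x <- x - mu
  enough <- (w - p) > n * p
  if (method == "ls" && !enough)
    stop("insufficient equations for least squares: ", w - p, " < ", n * p,
         "; lower the order or use method = \"yw\"")
  if (method == "auto") method <- if (enough) "ls" else "yw"
  if (method == "ls") {
    Y <- t(x[, (p + 1):w, drop = FALSE])                 # (W-p) x N
    Z <- matrix(0, w - p, n * p)
    for (k in seq_len(p))
      Z[, ((k - 1) * n + 1):(k * n)] <- t(x[, (p + 1 - k):(w - k), drop = FALSE])
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z))
      stop("singular regressor matrix; lower the model order")
    B <- qr.coef(qrz, Y)                                  # (N p) x N
    E <- Y - Z %*% B
    Sigma <- crossprod(E) / (w - p)
    A <- array(0, dim = c(n, n, p))
    for (k in seq_len(p)) A[, , k] <- t(B[((k - 1) * n + 1):(k * n), , drop = FALSE])
    resid <- t(E)
  } else {
    # biased autocovariances keep the block-Toeplitz system positive definite
    Ck <- lapply(0:p, function(k)
      tcrossprod(x[, (1 + k):w, drop = FALSE], x[, 1:(w - k), drop = FALSE]) / w)
    G <- matrix(0, n * p, n * p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      d <- j - i
      blk <- if (d >= 0) Ck[[d + 1]] else t(Ck[[-d + 1]])
      G[((i - 1) * n + 1):(i * n), ((j - 1) * n + 1):(j * n)] <- blk
    }
    b <- do.call(cbind, Ck[2:(p + 1)])                    # N x (N p)
    # short windows (W - p <= N p) make G rank deficient; escalating
    # diagonal loading keeps the solve defined while barely perturbing
    # well-conditioned systems
    lambda <- 0
    Astack <- NULL
    # under-determined windows (W - p <= N p): G is structurally rank
    # deficient, so start the ladder at a non-trivial loading instead of
    # letting a numerically borderline Cholesky interpolate the window
    lam_ladder <- if (enough) c(0, mean(diag(G)) * 10^(-6:-2)) else
      mean(diag(G)) * 10^(-3:-1)
    for (lam in lam_ladder) {
      Gl <- G + diag(lam, nrow(G))
      Astack <- tryCatch({
        ch <- chol(Gl)
        t(backsolve(ch, backsolve(ch, t(b), transpose = TRUE)))
      }, error = function(e) NULL)
      if (!is.null(Astack)) { lambda <- lam; break }
    }
    if (is.null(Astack))
      stop("singular autocovariance system; lower the model order")
    A <- array(0, dim = c(n, n, p))
    for (k in seq_len(p))
      A[, , k] <- Astack[, ((k - 1) * n + 1):(k * n), drop = FALSE]
    # residual covariance from the data (not the Yule-Walker identity),
    # so it stays positive semi-definite under the loading
    E <- x[, (p + 1):w, drop = FALSE]
    for (k in seq_len(p))
      E <- E - A[, , k] %*% x[, (p + 1 - k):(w - k), drop = FALSE]
    Sigma <- tcrossprod(E) / (w - p)
    resid <- NULL
  }
  if (any(diag(Sigma) <= 0))
    stop("residual covariance has a non-positive diagonal; the window is degenerate")
  structure(list(A = A, Sigma = Sigma, order = p, method = method,
                 nobs = w, means = mu, labels = rownames(x),
                 resid = resid, call = match.call()),
            class = "mvar")
}

#' @export
coef.mvar <- function(object, ...) object$A

#' @export
residuals.mvar <- function(object, ...) {
  if (is.null(object$resid))
    stop("residuals are only available for least-squares fits")
  object$resid
}

#' @export
print.mvar <- function(x, ...) {
  n <- dim(x$A)[1]
  cat("MVAR(", x$order, ") model: ", n, " channels, ", x$nobs,
      " samples, method = ", x$method, "\n", sep = "")
  cat("Companion spectral radius:",
      format(var_spectral_radius(x$A), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.mvar <- function(object, ...) {
  rho <- var_spectral_radius(object$A)
  out <- list(order = object$order, n = dim(object$A)[1],
              nobs = object$nobs, method = object$method,
              spectral_radius = rho, stable = rho < 1,
              sigma_diag = diag(object$Sigma),
              max_coef = max(abs(object$A)))
  class(out) <- "summary.mvar"
  out
}

#' @export
print.summary.mvar <- function(x, ...) {
  cat("MVAR(", x$order, ") fit on ", x$n, " channels, ", x$nobs,
      " samples (", x$method, ")\n", sep = "")
  cat("  stable:", x$stable, " (spectral radius",
      format(x$spectral_radius, digits = 4), ")\n")
  cat("  innovation variances:",
      paste(format(x$sigma_diag, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
simulate.mvar <- function(object, nsim = object$nobs, seed = NULL, ...) {
  simulate_var(object$A, object$Sigma, nsim, seed = seed)
}

#' One-step-ahead predictions from a fitted MVAR model
#' @param object an `mvar` fit.
#' @param newdata channels x samples matrix (defaults: not retained; must be
#'   supplied).
#' @param ... unused.
#' @return N x (W - p) matrix of one-step predictions for samples p+1..W.
#' @export
predict.mvar <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  p <- object$order; w <- ncol(newdata)
  x <- newdata - object$means
  out <- matrix(0, nrow(newdata), w - p)
  for (t in seq(p + 1, w)) {
    acc <- numeric(nrow(newdata))
    for (k in seq_len(p)) acc <- acc + object$A[, , k] %*% x[, t - k]
    out[, t - p] <- acc
  }
  out + object$means
}

#' Select a single global MVAR order by Akaike's information criterion
#'
#' Computes `AIC(p) = log det Sigma_hat(p) + 2 p N^2 / W` for each candidate
#' order on every supplied window, takes the median AIC across windows per
#' order, and returns the minimising order. A single order for all windows
#' mirrors fitting the whole sliding-window analysis with one p.
#'
#' @param windows list of channels x samples matrices.
#' @param p_max largest candidate order (>= 1).
#' @param method passed to [mvar].
#' @return the selected order (integer).
#' @export
select_order_aic <- function(windows, p_max, method = "auto") {
  stopifnot(p_max >= 1, length(windows) >= 1)
  aic <- matrix(NA_real_, length(windows), p_max)
  for (i in seq_along(windows)) {
    w <- ncol(windows[[i]])
    for (p in seq_len(p_max)) {
      fit <- tryCatch(mvar(windows[[i]], p, method = method), error = function(e) NULL)
      if (is.null(fit)) next
      d <- determinant(fit$Sigma, logarithm = TRUE)
      if (d$sign <= 0) next
      aic[i, p] <- as.numeric(d$modulus) + 2 * p * nrow(windows[[i]])^2 / w
    }
  }
  med <- apply(aic, 2, stats::median, na.rm = TRUE)
  if (all(is.na(med))) stop("all MVAR fits failed during order selection")
  which.min(med)
}
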