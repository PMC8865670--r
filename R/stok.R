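#' Fit a time-varying MVAR model by adaptive recursive least squares
#'
#' Estimates a time-varying multivariate autoregressive model from epoched
#' data with an adaptive Kalman-type recursive scheme: at each time step all
#' trials enter as repeated measurements of the same regression, and the
#' past is exponentially down-weighted by the filter (forgetting) factor
#' `c`. The regressor covariance is solved with eigenvalue truncation
#' (components below `1e-8` of the largest eigenvalue are discarded), with a
#' warning when truncation occurs. With `c = 1` the estimate at time t is
#' the cumulative ordinary least-squares solution over all samples up to t.
#'
#' @param epochs an [epoch_set()].
#' @param p model order in samples (>= 1, below the epoch length).
#' @param c filter (forgetting) factor in (0, 1].
#'
#' @return A `tvmvar` object: coefficient array `A` (time x lag x target
#'   channel x source channel), global residual covariance `Sigma`, per-time
#'   exponentially averaged covariance `Sigma_t`, model order `p`, filter
#'   factor `c`, sampling rate, time axis, channel metadata, and a logical
#'   `burnin` flag per time point (the first `p` samples carry
#'   initialization values).
#' @export
fit_tvmvar <- function(epochs, p, c = 0.98) {
  if (c <= 0 || c > 1) stopf("filter factor c must be in (0, 1], got %g", c)
  d <- dim(epochs$signals)
  n_trials <- d[1]; n <- d[2]; n_t <- d[3]
  if (p < 1) stopf("model order p must be >= 1")
  if (p >= n_t) stopf("model order p (%d) must be below the epoch length (%d)", p, n_t)

  np <- n * p
  R <- diag(1e-8, np)           # regressor covariance accumulator
  S <- matrix(0, np, n)         # cross-covariance accumulator
  A <- array(0, dim = c(n_t, p, n, n))
  Sigma_t <- array(0, dim = c(n_t, n, n))
  Sigma_acc <- matrix(0, n, n)
  Sigma_prev <- diag(apply(epochs$signals, 2, function(z) var(as.numeric(z))), n)
  B <- matrix(0, np, n)
  truncated <- FALSE
  n_used <- 0L

  # signals as [channel, trial, time] for fast lag slicing
  x <- aperm(epochs$signals, c(2, 1, 3))

  for (t in (p + 1):n_t) {
    Z <- matrix(0, n_trials, np)
    for (l in seq_len(p)) {
      Z[, ((l - 1) * n + 1):(l * n)] <- t(x[, , t - l, drop = TRUE])
    }
    if (n_trials == 1) Z <- matrix(Z, 1, np)
    Y <- t(matrix(x[, , t, drop = TRUE], n, n_trials))
    # one-step-ahead prediction error with the previous coefficients
    E <- Y - Z %*% B
    Sw <- crossprod(E) / n_trials
    Sigma_t[t, , ] <- c * Sigma_prev + (1 - c) * Sw
    Sigma_prev <- Sigma_t[t, , ]
    Sigma_acc <- Sigma_acc + Sw
    n_used <- n_used + 1L

    R <- c * R + crossprod(Z)
    S <- c * S + crossprod(Z, Y)
    eig <- eigen(R, symmetric = TRUE)
    keep <- eig$values > 1e-8 * eig$values[1]
    if (!all(keep)) truncated <- TRUE
    V <- eig$vectors[, keep, drop = FALSE]
    B <- V %*% ((crossprod(V, S)) / eig$values[keep])
    # A[t, l, i, j]: coefficient of channel j at lag l predicting channel i
    A[t, , , ] <- aperm(array(B, dim = c(n, p, n)), c(2, 3, 1))
  }
  for (t in seq_len(p)) {
    A[t, , , ] <- A[p + 1, , , ]
    Sigma_t[t, , ] <- Sigma_t[p + 1, , ]
  }
  if (truncated) warnf("ill-conditioned regressor covariance; eigenvalue-truncated solve used")
  Sigma <- Sigma_acc / n_used
  structure(
    list(A = A, Sigma = Sigma, Sigma_t = Sigma_t, p = p, c = c,
         fs = epochs$fs, time = epochs$time, channels = epochs$channels,
         burnin = seq_along(epochs$time) <= p,
         condition = epochs$condition, animal = epochs$animal),
    class = "tvmvar"
  )
}

#' @export
print.tvmvar <- function(x, ...) {
  cat(sprintf("<tvmvar> %d channels, order %d (%g ms), filter factor %g, %d time points\n",
              dim(x$A)[3], x$p, 1000 * x$p / x$fs, x$c, dim(x$A)[1]))
  invisible(x)
}

#' @export
glance.tvmvar <- function(x, ...) {
  tibble::tibble(
    n_channels = dim(x$A)[3], order = x$p, filter_factor = x$c, fs = x$fs,
    n_time = dim(x$A)[1],
    mean_resid_var = mean(diag(x$Sigma))
  )
}

#' Parametric power spectral density of a tvMVAR model
#'
#' Evaluates, at every time point, `diag(H(f) Sigma H(f)^H)` with
#' `H(f) = Abar(f)^-1` and `Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs)`.
#'
#' @param model a `tvmvar` object.
#' @param freqs frequencies in Hz (all at most `fs / 2`).
#' @param times optional subset of time indices (default: all).
#'
#' @return A numeric array time x frequency x channel.
#' @export
parametric_psd <- function(model, freqs, times = NULL) {
  if (any(freqs > model$fs / 2)) {
    stopf("frequencies above Nyquist (%g Hz): %s", model$fs / 2,
          paste(freqs[freqs > model$fs / 2], collapse = ", "))
  }
  times <- times %||% seq_len(dim(model$A)[1])
  n <- dim(model$A)[3]
  out <- array(0, dim = c(length(times), length(freqs), n))
  Abar_all <- spectral_coeffs(model, freqs, times = times)
  for (ti in seq_along(times)) {
    for (fi in seq_along(freqs)) {
      Abar <- Abar_all[ti, fi, , ]
      if (n == 1) Abar <- matrix(Abar, 1, 1)
      H <- tryCatch(solve(Abar), error = function(e) {
        stopf("singular spectral coefficient matrix at f = %g Hz", freqs[fi])
      })
      out[ti, fi, ] <- Re(diag(H %*% model$Sigma %*% Conj(t(H))))
    }
  }
  out
}

#' Select the tvMVAR model order against reference spectra
#'
#' Fits a model per candidate order and returns the order minimizing the
#' mean squared difference between the log parametric spectra and the log
#' reference spectra (averaged over time, frequency and channel, after
#' removing each channel's mean log offset so that arbitrary scale
#' differences between estimators do not enter). Ties go to the smallest
#' order.
#'
#' @param epochs an [epoch_set()].
#' @param candidates candidate model orders (non-empty).
#' @param reference numeric array time x frequency x channel of reference
#'   power (e.g. from [wavelet_reference()] or an analytic spectrum); the
#'   time axis must match the epochs.
#' @param freqs frequencies (Hz) of the reference's second axis.
#' @param c filter factor passed to [fit_tvmvar()].
#'
#' @return The selected order (integer). The per-candidate error profile is
#'   attached as attribute `"errors"`.
#' @export
select_model_order <- function(epochs, candidates, reference, freqs, c = 0.98) {
  if (!length(candidates)) stopf("empty candidate order list")
  candidates <- sort(unique(as.integer(candidates)))
  burn <- max(candidates) + 5L
  n_t <- dim(epochs$signals)[3]
  valid <- (burn + 1):n_t
  log_ref <- log(pmax(reference[valid, , , drop = FALSE], 1e-300))
  errs <- vapply(candidates, function(p) {
    model <- suppressWarnings(fit_tvmvar(epochs, p = p, c = c))
    psd <- parametric_psd(model, freqs, times = valid)
    log_psd <- log(pmax(psd, 1e-300))
    diffs <- log_psd - log_ref
    # per-channel scale offset removed
    for (ch in seq_len(dim(diffs)[3])) {
      diffs[, , ch] <- diffs[, , ch] - mean(diffs[, , ch])
    }
    mean(diffs^2)
  }, 0)
  sel <- candidates[which.min(errs)]
  attr(sel, "errors") <- setNames(errs, candidates)
  sel
}

#' Nonparametric reference spectra from Morlet wavelets
#'
#' Trial-averaged wavelet power on the same axes as [parametric_psd()],
#' for use as the reference in model-order selection.
#'
#' @inheritParams morlet_psd
#' @return A numeric array time x frequency x channel of raw power.
#' @export
wavelet_reference <- function(epochs, freqs, omega = 6, padding = 1) {
  morlet_power(epochs, freqs, omega = omega, padding = padding)
}
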