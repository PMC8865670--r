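#' Fourier-domain coefficient matrices of a tvMVAR model
#'
#' Computes `Abar(f, t) = I - sum_{k=1..p} A_k(t) exp(-i 2 pi f k / fs)`.
#'
#' @param model a `tvmvar` object.
#' @param freqs frequencies in Hz (at most `fs / 2`).
#' @param times optional subset of time indices (default: all).
#'
#' @return A complex array time x frequency x target x source.
#' @export
spectral_coeffs <- function(model, freqs, times = NULL) {
  if (any(freqs > model$fs / 2)) {
    stopf("frequencies above Nyquist (%g Hz)", model$fs / 2)
  }
  times <- times %||% seq_len(dim(model$A)[1])
  p <- model$p; n <- dim(model$A)[3]
  # phase matrix: lag x frequency
  ph <- exp(-1i * 2 * pi * outer(seq_len(p), freqs) / model$fs)
  eye <- diag(n)
  out <- array(0i, dim = c(length(times), length(freqs), n, n))
  for (ti in seq_along(times)) {
    At <- matrix(model$A[times[ti], , , , drop = TRUE], p, n * n) # lag x (i,j)
    if (p == 1) At <- matrix(model$A[times[ti], 1, , ], 1, n * n)
    proj <- crossprod(ph, At) # freq x (i,j)
    for (fi in seq_along(freqs)) {
      out[ti, fi, , ] <- eye - matrix(proj[fi, ], n, n)
    }
  }
  out
}

#' Information partial directed coherence
#'
#' Normalizes the Fourier-transformed tvMVAR coefficients into the
#' information PDC: for source channel j and target channel i,
#' `|Abar_ij(f,t)| * sigma_ii^(-1/2) / sqrt(abar_j(f,t)^H Sigma^-1
#' abar_j(f,t))`, where `abar_j` is column j of `Abar` and `sigma_ii` the
#' i-th residual variance. Magnitudes (not squares) are stored. With
#' diagonal residual covariance this reduces to the generalized PDC, whose
#' squared values sum to one over targets for every (source, f, t).
#'
#' @param model a `tvmvar` object with invertible residual covariance.
#' @param freqs frequencies in Hz.
#' @param times optional subset of time indices (default: all).
#'
#' @return An `ipdc_array`: nonnegative array `values` (target x source x
#'   time x frequency) plus axes and channel metadata.
#' @export
ipdc <- function(model, freqs, times = NULL) {
  times <- times %||% seq_len(dim(model$A)[1])
  n <- dim(model$A)[3]
  Sigma <- model$Sigma
  Sinv <- tryCatch(solve(Sigma), error = function(e) {
    stopf("residual covariance is singular; cannot compute iPDC")
  })
  s_ii <- sqrt(diag(Sigma))
  Abar <- spectral_coeffs(model, freqs, times = times)
  vals <- array(0, dim = c(n, n, length(times), length(freqs)))
  for (ti in seq_along(times)) {
    for (fi in seq_along(freqs)) {
      Af <- matrix(Abar[ti, fi, , ], n, n)
      denom <- sqrt(Re(colSums(Conj(Af) * (Sinv %*% Af)))) # per source column
      vals[, , ti, fi] <- (Mod(Af) / s_ii) / rep(denom, each = n)
    }
  }
  structure(
    list(values = vals, time = model$time[times], freqs = freqs,
         channels = model$channels, condition = model$condition,
         animal = model$animal),
    class = "ipdc_array"
  )
}

#' @export
print.ipdc_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ipdc_array> %d x %d channels, %d time points, %d frequencies\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Five-way connectivity tensor
#'
#' Container for nonnegative iPDC values on labeled axes source layer x
#' target layer x time x frequency x between-area connection.
#'
#' @param values nonnegative 5-d array.
#' @param layers,time,freqs,connections axis labels.
#' @param animals animal ids averaged into the tensor.
#' @param condition condition label.
#' @return A `conn_tensor` object.
#' @export
conn_tensor <- function(values, layers, time, freqs, connections,
                        animals = character(0), condition = NA_character_) {
  stopifnot(length(dim(values)) == 5L)
  if (any(values < 0)) stopf("connectivity tensor values must be nonnegative")
  d <- dim(values)
  if (d[1] != length(layers) || d[2] != length(layers) ||
      d[3] != length(time) || d[4] != length(freqs) ||
      d[5] != length(connections)) {
    stopf("tensor dimensions do not match axis labels")
  }
  structure(
    list(values = values, layers = layers, time = time, freqs = freqs,
         connections = connections, animals = animals, condition = condition),
    class = "conn_tensor"
  )
}

#' @export
print.conn_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<conn_tensor> %d x %d layers x %d time x %d freq x %d connections (%d animal(s))\n",
              d[1], d[2], d[3], d[4], d[5], max(length(x$animals), 1)))
  invisible(x)
}

#' @export
dim.conn_tensor <- function(x) dim(x$values)

#' Unfold per-animal iPDC arrays into the group 5-way tensor
#'
#' Reorganizes each animal's channel x channel iPDC array into source layer
#' x target layer x time x frequency x between-area connection (within-area
#' blocks are dropped), then averages element-wise over animals. Animals
#' lacking an area simply contribute nothing to that connection (the mean is
#' taken over available animals); a connection observed in no animal is an
#' error.
#'
#' @param ipdc_list list of `ipdc_array` objects with matching time and
#'   frequency axes.
#' @param areas area labels ordering the connection axis; defaults to the
#'   union of areas in hierarchy order (V1, LM, RL, AL, PM, AM).
#' @param layers layer labels; defaults to the union of layers present.
#'
#' @return A `conn_tensor`.
#' @export
build_group_tensor <- function(ipdc_list, areas = NULL, layers = NULL) {
  if (!length(ipdc_list)) stopf("need at least one animal")
  all_areas <- unique(unlist(lapply(ipdc_list, function(x) x$channels$area)))
  areas <- areas %||% intersect(c(default_areas(), sort(all_areas)), all_areas)
  layers <- layers %||% sort(unique(unlist(lapply(ipdc_list, function(x) x$channels$layer))))
  ct <- connection_table(areas)
  tmpl <- ipdc_list[[1]]
  n_l <- length(layers); n_t <- length(tmpl$time); n_f <- length(tmpl$freqs)
  acc <- array(0, dim = c(n_l, n_l, n_t, n_f, nrow(ct)))
  cnt <- integer(nrow(ct))
  for (x in ipdc_list) {
    ch <- x$channels
    for (ci in seq_len(nrow(ct))) {
      src <- match(paste(ct$source_area[ci], layers), paste(ch$area, ch$layer))
      tgt <- match(paste(ct$target_area[ci], layers), paste(ch$area, ch$layer))
      if (anyNA(src) || anyNA(tgt)) next
      # values[target, source, time, freq] -> [source_layer, target_layer, time, freq]
      block <- abs(x$values[tgt, src, , , drop = FALSE])
      acc[, , , , ci] <- acc[, , , , ci] + aperm(block, c(2, 1, 3, 4))
      cnt[ci] <- cnt[ci] + 1L
    }
  }
  if (any(cnt == 0)) {
    stopf("no animal provides connection(s): %s",
          paste(ct$connection[cnt == 0], collapse = ", "))
  }
  for (ci in seq_len(nrow(ct))) acc[, , , , ci] <- acc[, , , , ci] / cnt[ci]
  conn_tensor(acc, layers = layers, time = tmpl$time, freqs = tmpl$freqs,
              connections = ct$connection,
              animals = unlist(lapply(ipdc_list, `[[`, "animal")),
              condition = tmpl$condition)
}

# Trial-averaged Morlet wavelet power: time x frequency x channel.
morlet_power <- function(epochs, freqs, omega = 6, padding = 1) {
  d <- dim(epochs$signals)
  n_t <- d[3]
  n_fft <- stats::nextn((padding + 1) * n_t, 2)
  fft_freqs <- (seq_len(n_fft) - 1) / n_fft * epochs$fs
  out <- array(0, dim = c(n_t, length(freqs), d[2]))
  # frequency-domain Morlet kernels (analytic, zero at negative frequencies)
  kernels <- vapply(freqs, function(f) {
    sigma_f <- f / omega
    k <- exp(-(fft_freqs - f)^2 / (2 * sigma_f^2))
    k[fft_freqs > epochs$fs / 2] <- 0
    k
  }, numeric(n_fft))
  for (ch in seq_len(d[2])) {
    spec_acc <- matrix(0, n_t, length(freqs))
    for (tr in seq_len(d[1])) {
      X <- fft(c(epochs$signals[tr, ch, ], rep(0, n_fft - n_t)))
      for (fi in seq_along(freqs)) {
        w <- fft(X * kernels[, fi], inverse = TRUE)[seq_len(n_t)] / n_fft
        spec_acc[, fi] <- spec_acc[, fi] + Mod(w)^2
      }
    }
    out[, , ch] <- spec_acc / d[1]
  }
  out
}

#' Morlet wavelet power as percent change from baseline
#'
#' Computes trial-averaged Morlet wavelet power per channel and expresses
#' it, per frequency, as `100 * (P - Pbase) / Pbase` with `Pbase` the mean
#' power over the baseline window.
#'
#' @param epochs an [epoch_set()].
#' @param freqs frequencies in Hz.
#' @param omega Morlet central frequency (cycles; width parameter).
#' @param padding zero-padding factor (1 doubles the signal length).
#' @param baseline length-2 numeric, baseline window in seconds (must lie
#'   inside the epoch).
#'
#' @return A numeric array time x frequency x channel of percent change,
#'   with the time and frequency axes as attributes.
#' @export
morlet_psd <- function(epochs, freqs, omega = 6, padding = 1,
                       baseline = c(-0.3, -0.05)) {
  if (baseline[1] < min(epochs$time) - 1e-9 ||
      baseline[2] > max(epochs$time) + 1e-9) {
    stopf("baseline window [%g, %g] outside the epoch [%g, %g]",
          baseline[1], baseline[2], min(epochs$time), max(epochs$time))
  }
  pow <- morlet_power(epochs, freqs, omega = omega, padding = padding)
  base_idx <- which(epochs$time >= baseline[1] & epochs$time <= baseline[2])
  for (ch in seq_len(dim(pow)[3])) {
    m <- matrix(pow[, , ch], dim(pow)[1], dim(pow)[2])
    base <- colMeans(m[base_idx, , drop = FALSE])
    pow[, , ch] <- 100 * sweep(m, 2, base, function(x, b) (x - b) / b)
  }
  attr(pow, "time") <- epochs$time
  attr(pow, "freqs") <- freqs
  pow
}
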