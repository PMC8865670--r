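# Tensor utilities -------------------------------------------------------

# mode-n unfolding (mode n to the rows, remaining modes in increasing
# order along the columns, first fastest)
unfold_tensor <- function(X, mode) {
  d <- dim(X)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(X, perm), d[mode], prod(d[-mode]))
}

# Khatri-Rao product of the factor matrices, skipping `skip`, with the
# first remaining mode fastest (matches unfold_tensor's column ordering).
krao_skip <- function(factors, skip) {
  keep <- setdiff(seq_along(factors), skip)
  Z <- factors[[keep[1]]]
  for (m in keep[-1]) {
    Fm <- factors[[m]]
    Z <- Z[rep(seq_len(nrow(Z)), times = nrow(Fm)), , drop = FALSE] *
      Fm[rep(seq_len(nrow(Fm)), each = nrow(Z)), , drop = FALSE]
  }
  Z
}

# reconstruct the full tensor from CP factors
cp_reconstruct <- function(factors) {
  d <- vapply(factors, nrow, 0L)
  Z <- krao_skip(factors, 1)
  array(factors[[1]] %*% t(Z), dim = d)
}

# Nonnegative PARAFAC objects ---------------------------------------------

new_parafac_model <- function(factors, axes, evar, iterations, converged,
                              seed, corcondia = NA_real_) {
  names(factors) <- names(axes) <- c("source_layer", "target_layer", "time",
                                     "freq", "connection")[seq_along(factors)]
  structure(
    list(K = ncol(factors[[1]]), loadings = factors, axes = axes,
         evar = evar, corcondia = corcondia, iterations = iterations,
         converged = converged, seed = seed),
    class = "parafac_model"
  )
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("<parafac_model> K = %d, explained variance %.1f%%, %d iterations%s\n",
              x$K, 100 * x$evar, x$iterations,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' @export
glance.parafac_model <- function(x, ...) {
  tibble::tibble(K = x$K, evar = x$evar, corcondia = x$corcondia,
                 iterations = x$iterations, converged = x$converged)
}

#' @export
tidy.parafac_model <- function(x, ...) {
  purrr::imap_dfr(x$loadings, function(mat, mode) {
    ax <- x$axes[[mode]]
    purrr::map_dfr(seq_len(ncol(mat)), function(k) {
      tibble::tibble(component = k, mode = mode,
                     index = if (is.numeric(ax)) ax else seq_along(ax),
                     label = as.character(ax),
                     loading = mat[, k])
    })
  })
}

#' Nonnegative PARAFAC decomposition of a connectivity tensor
#'
#' Fits a K-component canonical polyadic model under a nonnegativity
#' constraint by alternating least squares with exact column-wise updates.
#' On exit, the source-layer, target-layer, frequency, and connection
#' loading columns are normalized to unit variance and the scale is carried
#' by the temporal loadings; components are ordered by descending amplitude
#' share (mean temporal loading). The best of `n_starts` random
#' initializations is kept; given the same tensor and seed the result is
#' reproducible.
#'
#' @param tensor a `conn_tensor` (or a bare nonnegative 5-d array).
#' @param K number of components (>= 1).
#' @param seed integer seed for the random initializations.
#' @param n_starts number of random restarts (best fit kept).
#' @param max_iter maximum ALS iterations.
#' @param tol relative fit-change convergence tolerance.
#'
#' @return A `parafac_model` with loadings `source_layer` (a),
#'   `target_layer` (b), `time` (c), `freq` (d), `connection` (e),
#'   explained-variance fraction, Corcondia score, iteration count,
#'   convergence flag, and the seed used.
#' @export
fit_parafac <- function(tensor, K, seed = 1, n_starts = 3, max_iter = 2000,
                        tol = 1e-8) {
  if (K < 1) stopf("K must be >= 1")
  X <- if (inherits(tensor, "conn_tensor")) tensor$values else tensor
  if (all(X == 0)) stopf("cannot decompose an all-zero tensor")
  if (any(X < 0)) stopf("tensor must be nonnegative")
  d <- dim(X)
  ssx <- sum(X^2)
  unfolds <- lapply(seq_along(d), function(m) unfold_tensor(X, m))
  seeds <- child_seeds(seed, n_starts)

  best <- NULL
  for (s in seq_len(n_starts)) {
    # first start: nonnegative higher-order SVD initialization (leading
    # singular vectors of each unfolding, magnitudes); further starts random
    factors <- with_seed(seeds[s], {
      if (s == 1) {
        lapply(seq_along(d), function(m) {
          ev <- eigen(tcrossprod(unfolds[[m]]), symmetric = TRUE)$vectors
          k_avail <- min(K, d[m])
          f <- abs(ev[, seq_len(k_avail), drop = FALSE]) + 1e-3
          if (K > k_avail) {
            f <- cbind(f, matrix(runif(d[m] * (K - k_avail), 0.1, 1),
                                 d[m], K - k_avail))
          }
          f
        })
      } else {
        lapply(d, function(nd) matrix(runif(nd * K, 0.1, 1), nd, K))
      }
    })
    grams <- lapply(factors, crossprod)
    err_prev <- Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      for (m in seq_along(d)) {
        Z <- krao_skip(factors, m)
        W <- unfolds[[m]] %*% Z
        G <- Reduce(`*`, grams[-m])
        Am <- factors[[m]]
        for (r in seq_len(K)) {
          grr <- max(G[r, r], 1e-12)
          ar <- Am[, r] + (W[, r] - Am %*% G[, r]) / grr
          Am[, r] <- pmax(ar, 0)
        }
        factors[[m]] <- Am
        grams[[m]] <- crossprod(Am)
      }
      # squared error via the last-updated mode's sufficient statistics
      m <- length(d)
      Gm <- Reduce(`*`, grams[-m])
      err <- ssx - 2 * sum(factors[[m]] * W) + sum(grams[[m]] * Gm)
      err <- max(err, 0)
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, 1e-300)) {
        converged <- TRUE
        err_prev <- err
        break
      }
      err_prev <- err
    }
    fit <- list(factors = factors, err = err_prev, iterations = it,
                converged = converged)
    if (is.null(best) || fit$err < best$err) best <- fit
  }

  factors <- normalize_cp(best$factors)
  axes <- if (inherits(tensor, "conn_tensor")) {
    list(tensor$layers, tensor$layers, tensor$time, tensor$freqs,
         tensor$connections)
  } else {
    lapply(d, seq_len)
  }
  model <- new_parafac_model(
    factors, axes, evar = 1 - best$err / ssx,
    iterations = best$iterations, converged = best$converged, seed = seed
  )
  model$corcondia <- tryCatch(corcondia(model, tensor), error = function(e) NA_real_)
  model
}

# unit-variance normalization of a, b, d, e with scale absorbed into the
# time mode; components ordered by descending mean temporal loading
normalize_cp <- function(factors) {
  K <- ncol(factors[[1]])
  time_mode <- 3L
  for (m in setdiff(seq_along(factors), time_mode)) {
    s <- apply(factors[[m]], 2, sd)
    s[s < 1e-300] <- 1
    factors[[m]] <- sweep(factors[[m]], 2, s, "/")
    factors[[time_mode]] <- sweep(factors[[time_mode]], 2, s, "*")
  }
  ord <- order(colMeans(factors[[time_mode]]), decreasing = TRUE)
  lapply(factors, function(f) f[, ord, drop = FALSE])
}

#' Core consistency diagnostic (Corcondia)
#'
#' Computes the least-squares core tensor implied by the model's loadings
#' and scores its closeness to the superdiagonal CP target:
#' `100 * (1 - sum((g - t)^2) / sum(t^2))`. For the scale convention used
#' here the superdiagonal target carries the component scales.
#'
#' @param model a `parafac_model`.
#' @param tensor the `conn_tensor` (or array) the model was fitted on.
#'
#' @return The Corcondia score (at most 100; can be negative).
#' @export
corcondia <- function(model, tensor) {
  X <- if (inherits(tensor, "conn_tensor")) tensor$values else tensor
  K <- model$K
  # carry scales on the factors so that the target superdiagonal is 1
  factors <- model$loadings
  norms <- lapply(factors, function(f) {
    nrm <- sqrt(colSums(f^2))
    if (any(nrm < 1e-300)) stopf("degenerate (all-zero) loading column")
    nrm
  })
  scale_k <- Reduce(`*`, norms)
  factors <- purrr::map2(factors, norms, function(f, nrm) sweep(f, 2, nrm, "/"))
  # G = X x_1 pinv(A1) ... x_5 pinv(A5), evaluated by sequential mode products
  G <- X
  for (m in seq_along(factors)) {
    G <- ttm(G, pinv_mat(factors[[m]]), m)
  }
  tgt <- array(0, dim = rep(K, length(factors)))
  idx <- matrix(rep(seq_len(K), length(factors)), K, length(factors))
  tgt[idx] <- scale_k
  100 * (1 - sum((G - tgt)^2) / sum(tgt^2))
}

# mode-m product of tensor G with matrix P (rows replace dimension m)
ttm <- function(G, P, m) {
  d <- dim(G)
  perm <- c(m, setdiff(seq_along(d), m))
  Gm <- matrix(aperm(G, perm), d[m], prod(d[-m]))
  out <- array(P %*% Gm, dim = c(nrow(P), d[-m]))
  aperm(out, order(perm))
}

pinv_mat <- function(A, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}
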