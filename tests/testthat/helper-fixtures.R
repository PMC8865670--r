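# Shared fixtures: small simulated processes and tensors built in code.

# epoch_set from a stationary VAR(1) process
make_var1_epochs <- function(A1, n_trials, n_time, fs = 250, sd = 1, seed = 1,
                             warmup = 50) {
  n <- nrow(A1)
  set.seed(seed)
  x <- array(0, dim = c(n_trials, n, n_time))
  for (tr in seq_len(n_trials)) {
    v <- rep(0, n)
    for (t in seq_len(n_time + warmup)) {
      v <- A1 %*% v + rnorm(n, sd = sd)
      if (t > warmup) x[tr, , t - warmup] <- v
    }
  }
  meta <- tibble::tibble(area = rep("V1", n), layer = paste0("L", seq_len(n)),
                         depth = 100 * seq_len(n))
  epoch_set(x, fs, (seq_len(n_time) - 1) / fs, meta)
}

# hand-built tvmvar object with known coefficients (single time point)
make_static_model <- function(A_lags, Sigma, fs = 250,
                              areas = NULL, layers = NULL) {
  p <- dim(A_lags)[1]
  n <- dim(A_lags)[2]
  A <- array(0, dim = c(1, p, n, n))
  A[1, , , ] <- A_lags
  areas <- areas %||% rep("V1", n)
  layers <- layers %||% paste0("L", seq_len(n))
  structure(
    list(A = A, Sigma = Sigma, Sigma_t = NULL, p = p, c = 1, fs = fs,
         time = 0, channels = tibble::tibble(area = areas, layer = layers,
                                             depth = 100 * seq_len(n)),
         burnin = FALSE, condition = NA_character_, animal = NA_character_),
    class = "tvmvar"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random CP factor list for a given dimension vector
random_cp_factors <- function(dims, K, seed = 1) {
  set.seed(seed)
  lapply(dims, function(nd) matrix(runif(nd * K, 0.2, 1), nd, K))
}

# small random conn_tensor (nonnegative)
random_conn_tensor <- function(dims = c(3, 3, 8, 6, 6), K = 2, seed = 1,
                               noise = 0) {
  facs <- random_cp_factors(dims, K, seed)
  X <- laminet:::cp_reconstruct(facs)
  if (noise > 0) {
    set.seed(seed + 1)
    X <- pmax(X + array(rnorm(length(X), 0, noise * sd(X)), dim = dims), 0)
  }
  conn_tensor(X, layers = paste0("L", seq_len(dims[1])),
              time = seq_len(dims[3]) / 100, freqs = seq_len(dims[4]) * 5,
              connections = paste0("c", seq_len(dims[5])))
}

# deterministic spike table for binning tests
make_spike_table <- function() {
  tibble::tibble(
    unit = c("u1", "u1", "u1", "u2", "u3"),
    area = "V1",
    layer = c("L4", "L4", "L4", "L4", "L5"),
    time_s = c(0.002, 0.006, 0.010, 0.5, 0.25),
    snr = c(5, 5, 5, 5, 2)
  )
}
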