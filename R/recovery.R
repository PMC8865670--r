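#' Score recovery of planted networks from a fitted decomposition
#'
#' Matches each planted component to the fitted component with the highest
#' mean loading correlation over the scored modes (source layer, target
#' layer, frequency, connection; the time mode carries the model scale and
#' is not scored), and reports the per-mode correlations.
#'
#' @param planted a `planted_networks` object.
#' @param model a fitted `parafac_model` (its `K` may exceed 4; extra
#'   components, e.g. one absorbing the estimation noise floor, are simply
#'   not matched).
#' @param freqs frequency axis of the fitted model (Hz).
#' @param design score against the design spectra (`TRUE`, for tensors
#'   built directly from the loadings) or the realized FIR responses
#'   (`FALSE`, for recordings simulated through the generative model).
#'
#' @return A tibble with columns `component` (planted label),
#'   `matched` (fitted component index), `source_layer`, `target_layer`,
#'   `freq`, `connection` (correlations), and `min_cor`.
#' @export
recovery_scores <- function(planted, model, freqs, design = TRUE) {
  gt <- planted_loadings(planted, design = design)
  fi <- match_closest(freqs, planted$freqs)
  modes <- c("source_layer", "target_layer", "freq", "connection")
  purrr::map_dfr(gt, function(g) {
    gl <- list(g$source_layer, g$target_layer, g$freq[fi], g$connection)
    score <- vapply(seq_len(model$K), function(j) {
      mean(vapply(seq_along(modes), function(m) {
        cor(gl[[m]], model$loadings[[modes[m]]][, j])
      }, 0))
    }, 0)
    j <- which.max(score)
    cors <- vapply(seq_along(modes), function(m) {
      cor(gl[[m]], model$loadings[[modes[m]]][, j])
    }, 0)
    tibble::tibble(component = g$label, matched = j,
                   source_layer = cors[1], target_layer = cors[2],
                   freq = cors[3], connection = cors[4],
                   min_cor = min(cors))
  })
}

#' Generative end-to-end recovery run
#'
#' Simulates laminar epochs from a planted configuration, fits the
#' time-varying MVAR model, computes iPDC, assembles the group tensor, and
#' decomposes it, returning the fitted model together with the planted
#' recovery scores. One component beyond the planted four is fitted by
#' default: the multivariate estimation noise floor of finite-trial iPDC is
#' itself structured and is best absorbed by its own component.
#'
#' @param planted a `planted_networks` object (e.g. [reduced_config()]).
#' @param n_trials epochs to simulate.
#' @param seed integer seed.
#' @param p tvMVAR model order (defaults to the planted kernel length).
#' @param c filter factor.
#' @param freqs frequency axis for iPDC (Hz).
#' @param K components to fit (default: planted components + 1).
#' @param time_step tensor time resolution in seconds (epochs are estimated
#'   at full resolution; the tensor is subsampled for the decomposition).
#'
#' @return A list with `model` (`parafac_model`), `scores`
#'   (the `recovery_scores()` tibble), `tensor`, and `ipdc`.
#' @export
run_recovery <- function(planted, n_trials = 200, seed = 1, p = NULL,
                         c = 0.98, freqs = seq(2, 100, by = 2), K = NULL,
                         time_step = 0.016) {
  p <- p %||% length(planted$components[[1]]$kernel)
  K <- K %||% (length(planted$components) + 1L)
  epochs <- simulate_epochs(planted, n_trials = n_trials, seed = seed)
  model_ar <- suppressWarnings(fit_tvmvar(epochs, p = p, c = c))
  v <- ipdc(model_ar, freqs = freqs)
  tensor <- build_group_tensor(list(v))
  keep <- seq(p + 2L, length(tensor$time),
              by = max(1L, round(time_step * planted$fs)))
  sub <- conn_tensor(tensor$values[, , keep, , , drop = FALSE], tensor$layers,
                     tensor$time[keep], tensor$freqs, tensor$connections,
                     animals = tensor$animals, condition = tensor$condition)
  fit <- fit_parafac(sub, K = K, seed = seed, n_starts = 2, max_iter = 2000,
                     tol = 1e-9)
  list(model = fit, scores = recovery_scores(planted, fit, freqs, design = FALSE),
       tensor = sub, ipdc = v)
}
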