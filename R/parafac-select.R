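#' Element-wise mean of per-animal connectivity tensors
#'
#' @param tensors list of `conn_tensor` objects with matching axes.
#' @return A `conn_tensor` holding the element-wise mean.
#' @export
mean_tensor <- function(tensors) {
  X <- tensors[[1]]$values
  if (length(tensors) > 1) {
    for (tns in tensors[-1]) X <- X + tns$values
    X <- X / length(tensors)
  }
  conn_tensor(X, tensors[[1]]$layers, tensors[[1]]$time, tensors[[1]]$freqs,
              tensors[[1]]$connections,
              animals = unlist(lapply(tensors, `[[`, "animals")),
              condition = tensors[[1]]$condition)
}

# concatenated standardized non-temporal loadings, one column per component
concat_loadings <- function(model) {
  mats <- model$loadings[c("source_layer", "target_layer", "freq", "connection")]
  do.call(rbind, mats)
}

# maximum absolute between-component correlation of concatenated loadings
max_between_correlation <- function(model) {
  if (model$K < 2) return(0)
  cc <- cor(concat_loadings(model))
  max(abs(cc[upper.tri(cc)]))
}

#' Select the number of PARAFAC components
#'
#' For each of `n_diag_boots` seeded random animal subsets, fits models over
#' the candidate component numbers on the subset-mean tensor and records the
#' Corcondia score, model fit, mean squared error, convergence, and the
#' maximal between-component loading correlation. Fit is expressed on the
#' usual PARAFAC percentage-of-norm scale, `100 (1 - ||X - Xhat|| /
#' ||X||)`. The selected number K* is the largest K whose median Corcondia
#' is at least `corcondia_min`, whose median maximal between-component
#' correlation is below `between_cor_max`, and whose median fit gain over
#' K - 1 is at least `fit_gain_min` (one fit point by default). The full
#' diagnostic table is attached so the decision is auditable.
#'
#' @param tensors list of per-animal `conn_tensor` objects.
#' @param K_range candidate component numbers (non-empty).
#' @param n_diag_boots number of diagnostic bootstraps (>= 1).
#' @param subset_size animals per bootstrap subset.
#' @param seed integer seed.
#' @param corcondia_min,between_cor_max,fit_gain_min decision thresholds
#'   (`fit_gain_min` in fit points, i.e. 0.01 = 1 point).
#' @param n_starts,max_iter,tol passed to [fit_parafac()] (lighter defaults
#'   than a final fit).
#'
#' @return The selected K (integer) with the diagnostic tibble attached as
#'   attribute `"diagnostics"`.
#' @export
select_components <- function(tensors, K_range, n_diag_boots = 10,
                              subset_size = NULL, seed = 1,
                              corcondia_min = 85, between_cor_max = 0.8,
                              fit_gain_min = 0.01, n_starts = 2,
                              max_iter = 1000, tol = 1e-9) {
  if (!length(K_range)) stopf("empty candidate component range")
  if (n_diag_boots < 1) stopf("n_diag_boots must be >= 1")
  K_range <- sort(unique(as.integer(K_range)))
  subset_size <- subset_size %||% max(1L, ceiling(0.75 * length(tensors)))
  if (subset_size > length(tensors)) stopf("subset size exceeds number of animals")
  seeds <- child_seeds(seed, n_diag_boots)
  diag_tbl <- purrr::map_dfr(seq_len(n_diag_boots), function(b) {
    sel <- with_seed(seeds[b], sample(length(tensors), subset_size))
    mt <- mean_tensor(tensors[sel])
    purrr::map_dfr(K_range, function(K) {
      model <- tryCatch(
        fit_parafac(mt, K, seed = seeds[b] + K, n_starts = n_starts,
                    max_iter = max_iter, tol = tol),
        error = function(e) NULL
      )
      if (is.null(model)) {
        return(tibble::tibble(boot = b, K = K, corcondia = -Inf, evar = 0,
                              fit = 0, between_cor = 1, converged = FALSE))
      }
      cc <- model$corcondia %||% NA_real_
      tibble::tibble(boot = b, K = K,
                     corcondia = ifelse(is.finite(cc), cc, -Inf),
                     evar = model$evar,
                     fit = 1 - sqrt(max(1 - model$evar, 0)),
                     between_cor = max_between_correlation(model),
                     converged = model$converged)
    })
  })
  med <- diag_tbl |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(corcondia = median(.data$corcondia),
                     evar = median(.data$evar),
                     fit = median(.data$fit),
                     between_cor = median(.data$between_cor),
                     convergence_rate = mean(.data$converged),
                     .groups = "drop") |>
    dplyr::arrange(.data$K) |>
    dplyr::mutate(fit_gain = .data$fit - dplyr::lag(.data$fit, default = 0),
                  eligible = .data$corcondia >= corcondia_min &
                    .data$between_cor < between_cor_max &
                    .data$fit_gain >= fit_gain_min)
  if (any(med$eligible)) {
    K_star <- max(med$K[med$eligible])
  } else {
    ok <- med$between_cor < between_cor_max
    K_star <- if (any(ok)) med$K[ok][which.max(med$corcondia[ok])] else min(med$K)
    warnf("no candidate met all selection thresholds; falling back to K = %d", K_star)
  }
  structure(as.integer(K_star), diagnostics = diag_tbl, summary = med)
}

#' Bootstrap PARAFAC over animal subsets
#'
#' Fits one model per bootstrap on the mean tensor of a seeded random
#' animal subset (sampling without replacement, as in diagnostic
#' selection). Reproducible given the seed.
#'
#' @param tensors list of per-animal `conn_tensor` objects.
#' @param n_boot number of bootstraps.
#' @param subset_size animals per subset (at most `length(tensors)`).
#' @param K number of components.
#' @param seed integer seed.
#' @param ... further arguments to [fit_parafac()].
#'
#' @return A list of `parafac_model` objects of length `n_boot`.
#' @export
bootstrap_decompose <- function(tensors, n_boot, subset_size, K, seed = 1,
                                ...) {
  if (subset_size > length(tensors)) {
    stopf("subset size (%d) exceeds number of animals (%d)", subset_size,
          length(tensors))
  }
  seeds <- child_seeds(seed, n_boot)
  lapply(seq_len(n_boot), function(b) {
    sel <- with_seed(seeds[b], sample(length(tensors), subset_size))
    fit_parafac(mean_tensor(tensors[sel]), K, seed = seeds[b], ...)
  })
}

#' Align components across bootstrapped models
#'
#' Aligns every model's components to the first model by choosing, over all
#' component permutations, the assignment maximizing the summed correlation
#' of concatenated (source-layer, target-layer, frequency, connection)
#' loadings, and summarizes component consistency: the per-component mean
#' correlation of matched loadings across models (intra) and the mean
#' correlation between different components (inter).
#'
#' @param models list of `parafac_model` objects sharing K and axes.
#'
#' @return A list with `models` (aligned), `intra` (per-component mean
#'   correlation), `inter` (scalar), and `permutations`.
#' @export
match_components <- function(models) {
  K <- models[[1]]$K
  if (!all(vapply(models, `[[`, 0L, "K") == K)) {
    stopf("models have mismatched numbers of components")
  }
  ref <- concat_loadings(models[[1]])
  perms <- permutations_of(K)
  aligned <- vector("list", length(models))
  perm_used <- matrix(0L, length(models), K)
  aligned[[1]] <- models[[1]]
  perm_used[1, ] <- seq_len(K)
  for (i in seq_along(models)[-1]) {
    cc <- cor(ref, concat_loadings(models[[i]])) # ref comp x model comp
    scores <- apply(perms, 1, function(pp) sum(cc[cbind(seq_len(K), pp)]))
    pp <- perms[which.max(scores), ]
    m <- models[[i]]
    m$loadings <- lapply(m$loadings, function(f) f[, pp, drop = FALSE])
    aligned[[i]] <- m
    perm_used[i, ] <- pp
  }
  # consistency: correlations across aligned models
  mats <- lapply(aligned, concat_loadings)
  n_m <- length(mats)
  intra <- rep(0, K); inter <- 0
  if (n_m > 1) {
    intra_acc <- rep(0, K); inter_acc <- 0; n_pairs <- 0
    for (i in seq_len(n_m - 1)) {
      for (j in (i + 1):n_m) {
        cc <- cor(mats[[i]], mats[[j]])
        intra_acc <- intra_acc + diag(cc)
        if (K > 1) inter_acc <- inter_acc + mean(cc[row(cc) != col(cc)])
        n_pairs <- n_pairs + 1
      }
    }
    intra <- intra_acc / n_pairs
    inter <- if (K > 1) inter_acc / n_pairs else NA_real_
  } else {
    intra <- rep(1, K)
    inter <- NA_real_
  }
  list(models = aligned, intra = intra, inter = inter,
       permutations = perm_used)
}

# all permutations of 1..K (K <= 8 here, so explicit enumeration is fine)
permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= K - 1) sub[, pos:(K - 1), drop = FALSE] else matrix(0L, nrow(sub), 0)
    cbind(left, K, right)
  }))
}
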