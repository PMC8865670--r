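#' Permutation test and centroid estimate for one receptive field
#'
#' The observed statistic is the maximum over stimulus positions of the
#' mean response; the null distribution is built by permuting responses
#' across trials and positions. The centroid is the response-weighted mean
#' position over pixels whose mean response exceeds half the maximum
#' (reported only when the RF is significant).
#'
#' @param responses tibble with columns `azimuth`, `elevation`, `trial`,
#'   `response` for one recording site.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level.
#' @param seed integer seed.
#' @param centroid_threshold fraction of the peak mean response a pixel
#'   must exceed to enter the centroid (default 0.5).
#'
#' @return A one-row tibble: `significant`, `p_value`, `azimuth`,
#'   `elevation` (centroid; `NA` when not significant).
#' @export
detect_rf <- function(responses, n_perm = 500, alpha = 0.05, seed = 1,
                      centroid_threshold = 0.5) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  responses <- tibble::as_tibble(responses)
  pos_id <- paste(responses$azimuth, responses$elevation)
  pos <- unique(pos_id)
  idx <- match(pos_id, pos)
  n_pos <- length(pos)
  mean_resp <- vapply(seq_len(n_pos), function(p) mean(responses$response[idx == p]), 0)
  obs <- max(mean_resp)
  counts <- tabulate(idx, n_pos)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      shuf <- sample(responses$response)
      max(vapply(seq_len(n_pos), function(p) mean(shuf[idx == p]), 0))
    }, 0)
  })
  p <- (1 + sum(null_max >= obs)) / (1 + n_perm)
  sig <- p < alpha
  if (sig) {
    az <- as.numeric(vapply(strsplit(pos, " "), `[`, "", 1))
    el <- as.numeric(vapply(strsplit(pos, " "), `[`, "", 2))
    supra <- mean_resp >= centroid_threshold * obs
    wts <- mean_resp[supra]
    cen_az <- sum(az[supra] * wts) / sum(wts)
    cen_el <- sum(el[supra] * wts) / sum(wts)
  } else {
    cen_az <- cen_el <- NA_real_
  }
  tibble::tibble(significant = sig, p_value = p,
                 azimuth = cen_az, elevation = cen_el)
}

#' Euclidean distance between two RF centroids
#'
#' @param c1,c2 length-2 numeric `(azimuth, elevation)` in degrees; `NA`
#'   (missing centroid, e.g. a nonsignificant RF) is an error.
#' @return Distance in degrees.
#' @export
rf_distance <- function(c1, c2) {
  if (anyNA(c1) || anyNA(c2)) stopf("missing centroid: RF distance requires two significant RFs")
  sqrt(sum((as.numeric(c1) - as.numeric(c2))^2))
}

#' Reconstructed between-area connection strength of a component
#'
#' Averages the rank-1 reconstruction of component `k` over source layers,
#' target layers, time, and frequency, leaving one scalar per between-area
#' connection: `e_ck * mean(a) * mean(b) * mean(c_t) * mean(d)` (the
#' Kronecker-product reconstruction collapses to this by multilinearity).
#'
#' @param model a `parafac_model`.
#' @param k component index (1..K).
#'
#' @return A named numeric vector, one value per connection.
#' @export
reconstruct_connection_strength <- function(model, k) {
  if (k < 1 || k > model$K) stopf("component index k = %d out of range 1..%d", k, model$K)
  lo <- model$loadings
  scal <- mean(lo$source_layer[, k]) * mean(lo$target_layer[, k]) *
    mean(lo$time[, k]) * mean(lo$freq[, k])
  setNames(lo$connection[, k] * scal, as.character(model$axes$connection))
}

#' Mixed-effects regression of connection strength on RF distance
#'
#' Fits `strength ~ distance + (1 | bootstrap) + (1 | connection)` by
#' maximum likelihood, reports the fixed distance slope with a
#' Satterthwaite p value, a likelihood-ratio test against the
#' fixed-effects-only model, a naive adjusted R^2 on fitted vs observed,
#' and marginal/conditional variance-partition R^2.
#'
#' @param data tibble with columns `connection`, `bootstrap`, `strength`,
#'   `distance`. Only connections with significant RFs at both ends should
#'   be included (at least 2).
#'
#' @return A list with `fit` (the lmer model), `slope`, `p_value`,
#'   `lrt_p`, `r2_adjusted`, `r2_marginal`, `r2_conditional`, and a
#'   `glance` tibble.
#' @export
regress_rf <- function(data) {
  data <- tibble::as_tibble(data)
  if (length(unique(data$connection)) < 2) {
    stopf("need at least 2 connections with significant RFs at both ends")
  }
  if (length(unique(data$bootstrap)) < 2 && length(unique(data$connection)) < 2) {
    stopf("both grouping factors have a single level")
  }
  fit <- lmerTest::lmer(strength ~ distance + (1 | bootstrap) + (1 | connection),
                        data = data, REML = FALSE)
  coefs <- summary(fit)$coefficients
  slope <- coefs["distance", "Estimate"]
  p_slope <- coefs["distance", "Pr(>|t|)"]
  fixed <- lm(strength ~ distance, data = data)
  lrt_stat <- 2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fixed)))
  lrt_p <- stats::pchisq(max(lrt_stat, 0), df = 2, lower.tail = FALSE)
  # naive adjusted R^2 on fitted vs observed
  r2 <- cor(stats::fitted(fit), data$strength)^2
  n <- nrow(data); k <- 2
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  # variance-partition R^2
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  var_fix <- var(stats::model.matrix(fit) %*% lme4::fixef(fit))[1]
  r2_m <- var_fix / (var_fix + var_re + var_res)
  r2_c <- (var_fix + var_re) / (var_fix + var_re + var_res)
  list(
    fit = fit, slope = slope, p_value = p_slope, lrt_p = lrt_p,
    r2_adjusted = r2_adj, r2_marginal = r2_m, r2_conditional = r2_c,
    glance = tibble::tibble(slope = slope, p_value = p_slope, lrt_p = lrt_p,
                            r2_adjusted = r2_adj, r2_marginal = r2_m,
                            r2_conditional = r2_c)
  )
}

#' Bin spike times into laminar rate series
#'
#' Drops units below the SNR threshold (and, by default, layer L1, which
#' carries too little spiking for rate estimates), pools the remaining
#' units per (area, layer), and counts spikes in uniform bins over the
#' window. The pooled counts conserve the number of in-window spikes of
#' qualifying units exactly.
#'
#' @param spikes tibble with columns `unit`, `area`, `layer`, `time_s`,
#'   `snr` (a `spike_set`).
#' @param binsize bin width in seconds (default 0.004); must divide the
#'   window length.
#' @param window length-2 window in seconds (default `c(0, 1)`).
#' @param snr_min SNR inclusion threshold (units strictly above it are
#'   kept; default 3).
#' @param exclude_layers layers dropped from the analysis (default "L1").
#'
#' @return A tibble (`rate_series`) with columns `area`, `layer`,
#'   `bin_start`, `count`, `n_units`. Sites with no qualifying units are
#'   emitted with zero units and a warning.
#' @export
bin_spikes <- function(spikes, binsize = 0.004, window = c(0, 1),
                       snr_min = 3, exclude_layers = "L1") {
  spikes <- tibble::as_tibble(spikes)
  len <- window[2] - window[1]
  n_bins <- round(len / binsize)
  if (abs(n_bins * binsize - len) > 1e-9) stopf("binsize must divide the window length")
  spikes <- dplyr::filter(spikes, !(.data$layer %in% exclude_layers))
  sites <- dplyr::distinct(spikes, .data$area, .data$layer)
  breaks <- window[1] + binsize * (0:n_bins)
  out <- purrr::map_dfr(seq_len(nrow(sites)), function(s) {
    sub <- dplyr::filter(spikes, .data$area == sites$area[s],
                         .data$layer == sites$layer[s])
    qual <- dplyr::filter(sub, .data$snr > snr_min)
    n_units <- length(unique(qual$unit))
    if (n_units == 0) {
      warnf("no units with SNR > %g at %s %s; emitting empty rate series",
            snr_min, sites$area[s], sites$layer[s])
      counts <- rep(0L, n_bins)
    } else {
      tt <- qual$time_s[qual$time_s >= window[1] & qual$time_s < window[2]]
      counts <- as.integer(table(cut(tt, breaks, right = FALSE,
                                     include.lowest = FALSE)))
    }
    tibble::tibble(area = sites$area[s], layer = sites$layer[s],
                   bin_start = breaks[-length(breaks)], count = counts,
                   n_units = n_units)
  })
  class(out) <- c("rate_series", class(out))
  out
}

#' Correlate network temporal loadings with laminar spiking
#'
#' Computes, per (area, layer) site, the Pearson correlation between each
#' bootstrap's temporal loading (resampled onto the rate bins) and the raw
#' pooled spike counts; reports the mean correlation over bootstraps, and
#' flags significance when the central 95 percent of the bootstrap
#' correlation distribution excludes zero. Sites with constant rate series
#' are flagged and excluded.
#'
#' @param loadings numeric matrix, time x bootstraps (temporal loadings of
#'   one component).
#' @param time time axis of `loadings` (seconds).
#' @param rates a `rate_series` from [bin_spikes()].
#' @param alpha two-tailed significance level (default 0.05).
#'
#' @return A tibble: `area`, `layer`, `r` (mean over bootstraps), `lower`,
#'   `upper`, `significant`, `excluded`.
#' @export
correlate_networks_spikes <- function(loadings, time, rates, alpha = 0.05) {
  loadings <- as.matrix(loadings)
  sites <- dplyr::distinct(rates, .data$area, .data$layer)
  purrr::map_dfr(seq_len(nrow(sites)), function(s) {
    sub <- dplyr::filter(rates, .data$area == sites$area[s],
                         .data$layer == sites$layer[s])
    bin_centers <- sub$bin_start + mean(diff(sub$bin_start)) / 2
    lo <- apply(loadings, 2, function(v) approx(time, v, xout = bin_centers, rule = 2)$y)
    if (sd(sub$count) == 0) {
      return(tibble::tibble(area = sites$area[s], layer = sites$layer[s],
                            r = NA_real_, lower = NA_real_, upper = NA_real_,
                            significant = FALSE, excluded = TRUE))
    }
    rs <- suppressWarnings(as.numeric(cor(lo, sub$count)))
    rs <- rs[is.finite(rs)]
    qs <- quantile(rs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    tibble::tibble(area = sites$area[s], layer = sites$layer[s],
                   r = mean(rs), lower = qs[1], upper = qs[2],
                   significant = qs[1] > 0 | qs[2] < 0, excluded = FALSE)
  })
}
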