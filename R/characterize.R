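#' Laminar significance of source/target loadings
#'
#' Normalizes each bootstrap's layer-loading vector to sum one and flags a
#' layer when the lower bound of the central `1 - alpha` bootstrap interval
#' of its normalized weight exceeds the uniform weight `1 / n_layers`.
#' A one-sample t statistic against the uniform weight is reported
#' alongside.
#'
#' @param loadings numeric matrix, layers x bootstraps (>= 2 bootstraps).
#' @param alpha significance level (default 0.05).
#' @param layers optional layer labels.
#'
#' @return A tibble with columns `layer`, `mean_weight`, `lower`, `upper`,
#'   `t_stat`, `p_value`, `flagged`.
#' @export
laminar_significance <- function(loadings, alpha = 0.05, layers = NULL) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2) stopf("need at least 2 bootstraps")
  layers <- layers %||% rownames(loadings) %||% default_layers(nrow(loadings))
  w <- sweep(loadings, 2, colSums(loadings), "/")
  unif <- 1 / nrow(w)
  purrr::map_dfr(seq_len(nrow(w)), function(l) {
    x <- w[l, ]
    tt <- if (sd(x) > 0) t.test(x, mu = unif, alternative = "greater") else
      list(statistic = c(t = Inf * sign(mean(x) - unif)), p.value = as.numeric(mean(x) <= unif))
    tibble::tibble(
      layer = layers[l],
      mean_weight = mean(x),
      lower = quantile(x, alpha / 2, names = FALSE),
      upper = quantile(x, 1 - alpha / 2, names = FALSE),
      t_stat = unname(tt$statistic),
      p_value = tt$p.value,
      flagged = quantile(x, alpha / 2, names = FALSE) > unif
    )
  })
}

#' Temporal dynamics of a component: percent change and significance
#'
#' Converts temporal loadings to percent change from the pre-stimulus
#' baseline (`100 * (x - xbar_base) / xbar_base`, per bootstrap, then
#' averaged) and tests each post-stimulus time point against the baseline
#' mean with a t test across bootstraps, Bonferroni-corrected over the
#' number of post-stimulus time points. One-sided tests for increases by
#' default; `alternative = "two.sided"` is available.
#'
#' @param c_t numeric matrix, time x bootstraps.
#' @param time time axis in seconds.
#' @param baseline length-2 baseline window in seconds (pre-stimulus).
#' @param alpha family-wise significance level.
#' @param alternative `"greater"` (increases) or `"two.sided"`.
#' @param exclude_burnin number of initial samples excluded from the
#'   baseline (e.g. the tvMVAR burn-in).
#'
#' @return A tibble with columns `time`, `pct_change`, `sd`, `p_value`
#'   (`NA` pre-stimulus), `significant`.
#' @export
temporal_stats <- function(c_t, time, baseline = c(-0.3, 0), alpha = 0.05,
                           alternative = c("greater", "two.sided"),
                           exclude_burnin = 0L) {
  alternative <- match.arg(alternative)
  c_t <- as.matrix(c_t)
  if (ncol(c_t) < 2) stopf("need at least 2 bootstraps")
  base_idx <- which(time >= baseline[1] & time < baseline[2])
  base_idx <- base_idx[base_idx > exclude_burnin]
  if (!length(base_idx)) stopf("baseline window contains no usable samples")
  base_mean <- colMeans(c_t[base_idx, , drop = FALSE])
  if (any(abs(base_mean) < 1e-300)) stopf("zero baseline mean; percent change undefined")
  pct <- 100 * sweep(sweep(c_t, 2, base_mean), 2, base_mean, "/")
  post_idx <- which(time >= 0)
  n_post <- length(post_idx)
  diffs <- sweep(c_t, 2, base_mean) # x_t - baseline mean, per bootstrap
  p <- rep(NA_real_, length(time))
  nb <- ncol(c_t)
  for (t in post_idx) {
    d <- diffs[t, ]
    if (sd(d) == 0) {
      p[t] <- if (alternative == "greater") as.numeric(mean(d) <= 0) else as.numeric(mean(d) == 0)
    } else {
      tt <- mean(d) / (sd(d) / sqrt(nb))
      p[t] <- if (alternative == "greater") pt(tt, nb - 1, lower.tail = FALSE)
      else 2 * pt(abs(tt), nb - 1, lower.tail = FALSE)
    }
  }
  tibble::tibble(
    time = time,
    pct_change = rowMeans(pct),
    sd = apply(pct, 1, sd),
    p_value = p,
    significant = !is.na(p) & p < alpha / n_post
  )
}

#' Amplitude share of each component
#'
#' Shares are each component's averaged temporal loading divided by the sum
#' over components, computed per bootstrap model and summarized as mean and
#' SD over bootstraps. Input models must already be component-aligned (see
#' [match_components()]).
#'
#' @param models a list of aligned `parafac_model` objects (or a single
#'   model).
#'
#' @return A tibble with columns `component`, `share`, `sd`.
#' @export
amplitude_share <- function(models) {
  if (inherits(models, "parafac_model")) models <- list(models)
  shares <- vapply(models, function(m) {
    s <- colMeans(m$loadings$time)
    s / sum(s)
  }, numeric(models[[1]]$K))
  shares <- matrix(shares, nrow = models[[1]]$K)
  tibble::tibble(
    component = seq_len(nrow(shares)),
    share = rowMeans(shares),
    sd = apply(shares, 1, sd)
  )
}

#' Fit candidate spectral models to a frequency loading
#'
#' Fits power-law (`c * f^-beta`), lognormal (`c * exp(-(log f - mu)^2 /
#' (2 sigma^2))`), and exponential (`c * exp(beta * f)`) curves to the
#' frequency loading by nonlinear least squares in linear space, and selects
#' the family with the smallest mean squared error. Families whose fit
#' fails are recorded with infinite MSE.
#'
#' @param d nonnegative frequency loading vector.
#' @param freqs frequencies in Hz (strictly positive).
#'
#' @return A `spectral_fit`: list with per-family `fits` (parameters and
#'   `mse`) and `best` family name.
#' @export
fit_frequency_models <- function(d, freqs) {
  if (any(freqs <= 0)) stopf("frequencies must be strictly positive")
  if (any(d < 0)) stopf("frequency loading must be nonnegative")
  df <- data.frame(f = as.numeric(freqs), y = as.numeric(d))
  fit_one <- function(formula, start) {
    tryCatch({
      fit <- minpack.lm::nlsLM(formula, data = df, start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 500))
      list(pars = as.list(coef(fit)), mse = mean(residuals(fit)^2))
    }, error = function(e) list(pars = NULL, mse = Inf))
  }
  fits <- list(
    powerlaw = fit_one(y ~ c0 * f^(-beta),
                       list(c0 = max(df$y[which.min(df$f)], 1e-6), beta = 1)),
    lognormal = fit_one(y ~ c0 * exp(-(log(f) - mu)^2 / (2 * sigma^2)),
                        list(c0 = max(df$y), mu = log(df$f[which.max(df$y)]),
                             sigma = 1)),
    exponential = fit_one(y ~ c0 * exp(beta * f),
                          list(c0 = max(df$y), beta = -0.05))
  )
  mses <- vapply(fits, `[[`, 0, "mse")
  if (all(!is.finite(mses))) stopf("all three spectral fits failed")
  structure(list(fits = fits, best = names(which.min(mses))),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> best family: %s\n", x$best))
  for (fam in names(x$fits)) {
    cat(sprintf("  %-12s mse %.4g\n", fam, x$fits[[fam]]$mse))
  }
  invisible(x)
}

#' @export
tidy.spectral_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, fam) {
    if (is.null(fit$pars)) {
      return(tibble::tibble(family = fam, term = NA_character_,
                            estimate = NA_real_, mse = fit$mse,
                            best = identical(fam, x$best)))
    }
    tibble::tibble(family = fam, term = names(fit$pars),
                   estimate = unlist(fit$pars), mse = fit$mse,
                   best = identical(fam, x$best))
  })
}

#' @export
glance.spectral_fit <- function(x, ...) {
  tibble::tibble(
    best = x$best,
    mse_powerlaw = x$fits$powerlaw$mse,
    mse_lognormal = x$fits$lognormal$mse,
    mse_exponential = x$fits$exponential$mse
  )
}

#' Modulation spectrum of a temporal loading
#'
#' Removes a linear trend from the post-stimulus window of the temporal
#' loading and returns the discrete Fourier amplitude spectrum; frequency
#' resolution is the inverse window length.
#'
#' @param c_t temporal loading vector (or time x bootstrap matrix, in which
#'   case the spectrum is averaged over bootstraps).
#' @param time time axis in seconds.
#' @param window length-2 analysis window in seconds (post-stimulus).
#'
#' @return A tibble with columns `freq` (Hz) and `amplitude`.
#' @export
modulation_spectrum <- function(c_t, time, window = c(0, 1)) {
  c_t <- as.matrix(c_t)
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 2) stopf("analysis window must contain at least 2 samples")
  m <- length(idx)
  fs <- 1 / mean(diff(time[idx]))
  tt <- time[idx]
  amp <- matrix(0, m, ncol(c_t))
  for (b in seq_len(ncol(c_t))) {
    y <- c_t[idx, b]
    y <- residuals(lm(y ~ tt)) # linear detrend
    amp[, b] <- Mod(fft(y)) / m * 2
  }
  freq <- (seq_len(m) - 1) * fs / m
  keep <- freq <= fs / 2
  tibble::tibble(freq = freq[keep], amplitude = rowMeans(amp)[keep])
}
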