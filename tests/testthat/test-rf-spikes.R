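test_that("RF detection finds planted fields and never fires at alpha = 0", {
  set.seed(2)
  grid <- tidyr::expand_grid(azimuth = seq(-30, 30, 10), elevation = seq(-20, 20, 10))
  mk_site <- function(cx, cy, snr) {
    purrr::map_dfr(1:12, function(tr) {
      tibble::tibble(azimuth = grid$azimuth, elevation = grid$elevation,
                     trial = tr,
                     response = pmax(snr * exp(-((grid$azimuth - cx)^2 +
                                                   (grid$elevation - cy)^2) / 200) +
                                       rnorm(nrow(grid)), 0))
    })
  }
  resp <- mk_site(10, 5, 8)
  det <- detect_rf(resp, n_perm = 300, seed = 3)
  expect_true(det$significant)
  expect_lt(abs(det$azimuth - 10), 10)
  expect_lt(abs(det$elevation - 5), 10)
  # alpha = 0: nothing can be significant
  det0 <- detect_rf(resp, n_perm = 300, alpha = 0, seed = 3)
  expect_false(det0$significant)
  expect_true(is.na(det0$azimuth))
  expect_error(detect_rf(resp, n_perm = 50), "n_perm")
})

test_that("RF permutation p-values are uniform under the null", {
  set.seed(12)
  grid <- tidyr::expand_grid(azimuth = seq(-30, 30, 10), elevation = seq(-20, 20, 10))
  n_sites <- 500
  pvals <- vapply(seq_len(n_sites), function(s) {
    resp <- purrr::map_dfr(1:8, function(tr) {
      tibble::tibble(azimuth = grid$azimuth, elevation = grid$elevation,
                     trial = tr, response = rnorm(nrow(grid)))
    })
    detect_rf(resp, n_perm = 199, seed = 1000 + s)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("RF distances are Euclidean, symmetric, and require centroids", {
  expect_equal(rf_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(rf_distance(c(2, 7), c(2, 7)), 0)
  expect_equal(rf_distance(c(1, 2), c(4, 6)), rf_distance(c(4, 6), c(1, 2)))
  expect_error(rf_distance(c(NA, 0), c(1, 1)), "missing centroid")
})

test_that("Kronecker reconstruction equals the brute-force tensor average", {
  tens <- random_conn_tensor(dims = c(3, 3, 6, 5, 4), K = 3, seed = 6,
                             noise = 0.2)
  fit <- fit_parafac(tens, K = 3, seed = 2)
  for (k in 1:3) {
    got <- reconstruct_connection_strength(fit, k)
    # brute force: full rank-1 tensor of component k, then average over
    # layers, time, and frequency
    lo <- fit$loadings
    full <- laminet:::outer_rank1(list(lo$source_layer[, k], lo$target_layer[, k],
                                       lo$time[, k], lo$freq[, k],
                                       lo$connection[, k]))
    oracle <- apply(full, 5, mean)
    expect_equal(unname(got), oracle, tolerance = 1e-10)
  }
  # all-ones loadings: the connection values come back unchanged
  ones <- fit
  ones$loadings <- lapply(fit$loadings, function(f) {f[] <- 1; f})
  expect_equal(unname(reconstruct_connection_strength(ones, 1)),
               rep(1, 4), tolerance = 1e-12)
  # multilinearity: doubling the time loading doubles every value
  dbl <- fit
  dbl$loadings$time <- 2 * dbl$loadings$time
  expect_equal(unname(reconstruct_connection_strength(dbl, 2)),
               2 * unname(reconstruct_connection_strength(fit, 2)),
               tolerance = 1e-12)
  expect_error(reconstruct_connection_strength(fit, 9), "out of range")
})

test_that("mixed-effects RF regression recovers planted slopes and controls the null", {
  set.seed(33)
  conns <- paste0("c", 1:12)
  dist <- runif(12, 2, 40)
  mk_data <- function(slope) {
    purrr::map_dfr(1:40, function(b) {
      tibble::tibble(connection = conns, bootstrap = b,
                     distance = dist,
                     strength = 2 + slope * dist +
                       rnorm(1, 0, 0.15) + # bootstrap offset
                       rep(rnorm(12, 0, 0.2), each = 1)[seq_along(conns)] * 0 +
                       rnorm(12, 0, 0.3))
    })
  }
  neg <- regress_rf(mk_data(-0.05))
  expect_lt(neg$slope, 0)
  expect_lt(neg$p_value, 0.01)
  expect_true(is.finite(neg$r2_marginal) && neg$r2_marginal <= 1)
  expect_gte(neg$r2_conditional, neg$r2_marginal)
  # type-I behaviour under a zero slope
  set.seed(9)
  pvals <- vapply(1:40, function(i) {
    d <- purrr::map_dfr(1:15, function(b) {
      tibble::tibble(connection = conns, bootstrap = b, distance = dist,
                     strength = 2 + rnorm(1, 0, 0.1) + rnorm(12, 0, 0.3))
    })
    suppressWarnings(suppressMessages(regress_rf(d)$p_value))
  }, 0)
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_error(regress_rf(tibble::tibble(connection = "c1", bootstrap = 1,
                                         distance = 1, strength = 1)),
               "2 connections")
})

test_that("convergent-mode synthetic RFs give a negative distance slope, none-mode does not", {
  # 6 areas: the distance slope is identified from between-connection
  # variation, so the full 30-connection axis is needed for power
  cfg <- default_config("high")
  tensors <- simulate_group_tensors(cfg, n_animals = 5, seed = 14,
                                    time_grid = cfg$time[seq(1, 326, by = 24)],
                                    freq_grid = seq(1, 100, by = 8))
  boots <- bootstrap_decompose(tensors, n_boot = 10, subset_size = 4, K = 4,
                               seed = 5, n_starts = 1, max_iter = 600)
  mm <- match_components(boots)
  sc <- recovery_scores(cfg, mm$models[[1]], seq(1, 100, by = 8))
  k_gamma <- sc$matched[sc$component == "gamma_ff"]
  run_mode <- function(mode) {
    modes <- rep("none", 4); modes[2] <- mode
    rf <- simulate_rfs(cfg, modes = modes, seed = 21)
    ac <- rf$area_centroids
    ct <- laminet:::connection_table(cfg$areas)
    dists <- sqrt((ac$azimuth[match(ct$source_area, ac$area)] -
                     ac$azimuth[match(ct$target_area, ac$area)])^2 +
                    (ac$elevation[match(ct$source_area, ac$area)] -
                       ac$elevation[match(ct$target_area, ac$area)])^2)
    data <- purrr::map_dfr(seq_along(mm$models), function(b) {
      s <- reconstruct_connection_strength(mm$models[[b]], k_gamma)
      tibble::tibble(connection = names(s), bootstrap = b, strength = s,
                     distance = dists[match(names(s), ct$connection)])
    })
    suppressWarnings(suppressMessages(regress_rf(data)))
  }
  conv <- run_mode("convergent")
  expect_lt(conv$slope, 0)
  expect_lt(conv$p_value, 0.01)
})

test_that("spike binning filters on SNR, pools sites, and conserves counts", {
  spikes <- make_spike_table()
  rates <- suppressWarnings(
    bin_spikes(spikes, binsize = 0.004, window = c(0, 1), snr_min = 3)
  )
  l4 <- dplyr::filter(rates, layer == "L4")
  # spikes at 2, 6, 10 ms land in the first three 4-ms bins
  expect_equal(l4$count[1:3], c(1L, 1L, 1L))
  # conservation: all in-window spikes from qualifying units
  expect_equal(sum(l4$count), 4L) # u1 three spikes + u2 one spike
  # u3 has SNR 2 <= 3: its site has no qualifying units -> empty + warning
  expect_warning(bin_spikes(spikes, snr_min = 3, exclude_layers = character(0)),
                 "L5")
  sup <- suppressWarnings(bin_spikes(spikes, snr_min = 3,
                                     exclude_layers = character(0)))
  expect_equal(sum(dplyr::filter(sup, layer == "L5")$count), 0L)
  # L1 excluded by default
  sp1 <- dplyr::mutate(make_spike_table(), layer = "L1")
  expect_equal(nrow(suppressWarnings(bin_spikes(sp1))), 0L)
  expect_error(bin_spikes(spikes, binsize = 0.003), "divide")
})

test_that("spike-network correlations flag planted coupling and spare the null", {
  tt <- seq(0, 0.996, by = 0.004)
  env <- 1 + 0.8 * sin(2 * pi * 3 * tt) + 0.5 * exp(-(tt - 0.2)^2 / 0.01)
  n_boot <- 80
  set.seed(6)
  loadings <- matrix(rep(env, n_boot), ncol = n_boot) +
    matrix(rnorm(length(tt) * n_boot, 0, 0.05), ncol = n_boot)
  # rate = positive affine transform of the loading: r = 1 in every bootstrap
  rates_perfect <- tibble::tibble(area = "V1", layer = "L4", bin_start = tt,
                                  count = round(50 + 20 * env), n_units = 3)
  res <- correlate_networks_spikes(matrix(env, ncol = 2, nrow = length(tt) + 0) [
    , c(1, 1)], tt, rates_perfect)
  expect_gt(res$r, 0.99)
  expect_true(res$significant)
  # planted positive coupling with noise
  rates_noisy <- tibble::tibble(area = "V1", layer = "L4", bin_start = tt,
                                count = rpois(length(tt), 10 * env), n_units = 3)
  res2 <- correlate_networks_spikes(loadings, tt, rates_noisy)
  expect_true(res2$significant & res2$r > 0)
  # constant rate series flagged and excluded
  rates_const <- tibble::tibble(area = "V1", layer = "L2", bin_start = tt,
                                count = 5L, n_units = 1)
  res3 <- correlate_networks_spikes(loadings, tt, rates_const)
  expect_true(res3$excluded)
  expect_false(res3$significant)
})

test_that("spike correlation significance holds its level on independent rates", {
  # the bootstrap CI controls its level when the bootstrap spread of the
  # loadings dominates the loading's own sampling variability (here: white
  # shared curve + larger white per-bootstrap noise), rates independent
  tt <- seq(0, 0.996, by = 0.004)
  n_boot <- 100
  set.seed(44)
  hits <- vapply(1:1000, function(i) {
    shared <- rnorm(length(tt))
    loadings <- 10 + matrix(rep(shared, n_boot), ncol = n_boot) +
      matrix(rnorm(length(tt) * n_boot, 0, 1.5), ncol = n_boot)
    rates <- tibble::tibble(area = "V1", layer = "L4", bin_start = tt,
                            count = rpois(length(tt), 8), n_units = 2)
    correlate_networks_spikes(loadings, tt, rates)$significant
  }, TRUE)
  tol <- 2.5 * sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(hits), 0.05 + tol)
})
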