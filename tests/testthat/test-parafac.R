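test_that("an exact rank-1 tensor is fit perfectly and deterministically", {
  tens <- random_conn_tensor(K = 1, seed = 4)
  fit <- fit_parafac(tens, K = 1, seed = 2)
  expect_gte(fit$evar, 0.999)
  fit_b <- fit_parafac(tens, K = 1, seed = 2)
  expect_identical(fit$loadings, fit_b$loadings)
  expect_error(fit_parafac(tens, K = 0), "K")
  zero <- tens; zero$values[] <- 0
  expect_error(fit_parafac(zero, K = 1), "all-zero")
})

test_that("planted well-separated components are recovered with high congruence", {
  dims <- c(4, 4, 20, 12, 8)
  set.seed(11)
  facs <- lapply(dims, function(nd) matrix(runif(nd * 4, 0, 1)^2 + 0.05, nd, 4))
  X <- laminet:::cp_reconstruct(facs)
  noisy <- X + array(rnorm(length(X), 0, 0.05 * sd(X)), dim = dims)
  tens <- conn_tensor(pmax(noisy, 0), paste0("L", 1:4), 1:20, 1:12, paste0("c", 1:8))
  fit <- fit_parafac(tens, K = 4, seed = 9, n_starts = 3)
  # congruence: cosine of matched loading vectors per planted component
  modes <- c("source_layer", "target_layer", "time", "freq", "connection")
  cong <- vapply(1:4, function(k) {
    scores <- vapply(1:4, function(j) {
      mean(vapply(1:5, function(m) {
        a <- facs[[m]][, k]; b <- fit$loadings[[modes[m]]][, j]
        sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      }, 0))
    }, 0)
    max(scores)
  }, 0)
  expect_true(all(cong > 0.95))
})

test_that("ALS reconstruction error is monotone non-increasing and variance grows with K", {
  tens <- random_conn_tensor(dims = c(3, 3, 10, 8, 6), K = 3, seed = 2,
                             noise = 0.3)
  # monotonicity: run with increasing iteration caps from one start
  errs <- vapply(c(1, 3, 10, 40, 150), function(it) {
    f <- fit_parafac(tens, K = 2, seed = 5, n_starts = 1, max_iter = it)
    1 - f$evar
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
  ev <- vapply(1:4, function(K) {
    fit_parafac(tens, K = K, seed = 5, n_starts = 3)$evar
  }, 0)
  expect_true(all(diff(ev) >= -1e-6))
})

test_that("exit normalization puts unit variance on a, b, d, e without changing the fit", {
  tens <- random_conn_tensor(K = 2, seed = 8, noise = 0.1)
  fit <- fit_parafac(tens, K = 2, seed = 1)
  for (mode in c("source_layer", "target_layer", "freq", "connection")) {
    expect_equal(apply(fit$loadings[[mode]], 2, var), rep(1, 2),
                 tolerance = 1e-8)
  }
  expect_true(all(vapply(fit$loadings, function(f) all(f >= 0), TRUE)))
  # components ordered by descending amplitude share
  expect_true(diff(colMeans(fit$loadings$time)) <= 0)
  # reconstruction from normalized factors matches the reported fit
  Xhat <- laminet:::cp_reconstruct(fit$loadings)
  evar_direct <- 1 - sum((tens$values - Xhat)^2) / sum(tens$values^2)
  expect_equal(evar_direct, fit$evar, tolerance = 1e-6)
})

test_that("corcondia is 100 for K = 1 and exact models, low when overfactored", {
  tens1 <- random_conn_tensor(K = 3, seed = 4, noise = 0.2)
  f1 <- fit_parafac(tens1, K = 1, seed = 2)
  expect_equal(corcondia(f1, tens1), 100, tolerance = 1e-6)
  # exact rank-4 tensor fit with K = 4 scores >= 99
  dims <- c(4, 4, 15, 10, 8)
  set.seed(13)
  facs <- lapply(dims, function(nd) matrix(runif(nd * 4, 0.05, 1), nd, 4))
  tens4 <- conn_tensor(laminet:::cp_reconstruct(facs), paste0("L", 1:4),
                       1:15, 1:10, paste0("c", 1:8))
  f4 <- fit_parafac(tens4, K = 4, seed = 3, n_starts = 3)
  expect_gte(corcondia(f4, tens4), 99)
  # exact rank-2 tensor fit with K = 4 scores below 50
  set.seed(14)
  facs2 <- lapply(dims, function(nd) matrix(runif(nd * 2, 0.05, 1), nd, 2))
  tens2 <- conn_tensor(laminet:::cp_reconstruct(facs2), paste0("L", 1:4),
                       1:15, 1:10, paste0("c", 1:8))
  f24 <- fit_parafac(tens2, K = 4, seed = 3, n_starts = 2)
  expect_lt(corcondia(f24, tens2), 50)
})

test_that("component selection returns 1 for rank-1 tensors and validates inputs", {
  tensors <- lapply(1:4, function(a) random_conn_tensor(dims = c(3, 3, 8, 6, 6),
                                                        K = 1, seed = a * 3))
  # same factors, different seeds -> same underlying rank-1 structure + noise
  base <- random_conn_tensor(dims = c(3, 3, 8, 6, 6), K = 1, seed = 7)
  tensors <- lapply(1:4, function(a) {
    t2 <- base
    set.seed(100 + a)
    t2$values <- pmax(base$values * (1 + 0.05 * rnorm(1)) +
                        array(rnorm(length(base$values), 0, 0.02 * sd(base$values)),
                              dim = dim(base$values)), 0)
    t2
  })
  K <- select_components(tensors, K_range = 1:3, n_diag_boots = 3,
                         subset_size = 3, seed = 5)
  expect_equal(as.integer(K), 1L)
  expect_error(select_components(tensors, integer(0)), "empty")
  expect_error(select_components(tensors, 1:2, n_diag_boots = 0), "n_diag_boots")
  expect_error(select_components(tensors, 1:2, subset_size = 9), "subset")
})

test_that("bootstrap decomposition is reproducible with the expected length", {
  tensors <- lapply(1:3, function(a) random_conn_tensor(K = 2, seed = a,
                                                        noise = 0.1))
  b1 <- bootstrap_decompose(tensors, n_boot = 3, subset_size = 2, K = 2,
                            seed = 11, n_starts = 1, max_iter = 200)
  b2 <- bootstrap_decompose(tensors, n_boot = 3, subset_size = 2, K = 2,
                            seed = 11, n_starts = 1, max_iter = 200)
  expect_length(b1, 3)
  expect_identical(lapply(b1, `[[`, "loadings"), lapply(b2, `[[`, "loadings"))
  expect_error(bootstrap_decompose(tensors, 2, subset_size = 5, K = 2), "subset")
})

test_that("component matching aligns permutations and scores consistency", {
  tens <- random_conn_tensor(K = 3, seed = 21, noise = 0.05)
  m1 <- fit_parafac(tens, K = 3, seed = 2)
  # identical models: intra-consistency 1 for every component
  mm <- match_components(list(m1, m1))
  expect_equal(mm$intra, rep(1, 3), tolerance = 1e-12)
  # permuted copy: permutation recovered, consistency 1
  m2 <- m1
  perm <- c(3, 1, 2)
  m2$loadings <- lapply(m2$loadings, function(f) f[, perm])
  mm2 <- match_components(list(m1, m2))
  expect_equal(mm2$permutations[2, ], order(perm))
  expect_equal(mm2$intra, rep(1, 3), tolerance = 1e-12)
  expect_true(is.na(mm2$inter) || mm2$inter < 1)
  m_bad <- fit_parafac(tens, K = 2, seed = 2)
  expect_error(match_components(list(m1, m_bad)), "mismatch")
})

test_that("bootstrapped planted tensors give intra-consistency above between-component correlation", {
  cfg <- reduced_config("high")
  tg <- cfg$time[seq(1, 326, by = 16)]
  fg <- seq(1, 100, by = 6)
  tensors <- simulate_group_tensors(cfg, n_animals = 6, seed = 19,
                                    time_grid = tg, freq_grid = fg)
  boots <- bootstrap_decompose(tensors, n_boot = 8, subset_size = 4, K = 4,
                               seed = 3, n_starts = 1, max_iter = 600)
  mm <- match_components(boots)
  expect_true(all(mm$intra > 0.81))
  expect_lt(mm$inter, min(mm$intra))
})
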