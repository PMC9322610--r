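test_that("online K-means recovers the exhaustive-search 2-means optimum", {
  # two well-separated clusters of 4 points each
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
             c(10, 10), c(11, 10), c(10, 11), c(11, 11))
  C <- fit_centers(X, h = 2, eta = 0.1, max_epochs = 500, rng_seed = 1)
  got <- apply(X, 1, function(x) which.min(colSums((t(C) - x)^2)))
  # independent oracle: enumerate every 2-partition, score by within-SSE
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^8 - 2)) {
    part <- as.logical(bitwAnd(mask, 2^(0:7)))
    if (!any(part) || all(part)) next
    sse <- sum(scale(X[part, , drop = FALSE], scale = FALSE)^2) +
           sum(scale(X[!part, , drop = FALSE], scale = FALSE)^2)
    if (sse < best_sse) { best_sse <- sse; best <- part }
  }
  expect_true(all(got[best] == got[best][1]) &&
              all(got[!best] == got[!best][1]) &&
              got[best][1] != got[!best][1])
})

test_that("K-means limit cases behave as contracted", {
  set.seed(2)
  X <- matrix(rnorm(12 * 3), 12, 3)
  # h = n: each centre converges onto its own sample
  C <- fit_centers(X, h = 12, eta = 0.5, max_epochs = 300, rng_seed = 3)
  d <- apply(X, 1, function(x) min(colSums((t(C) - x)^2)))
  expect_lt(max(d), 1e-4)
  # h = 1: the single centre stays within the data bounding box
  C1 <- fit_centers(X, h = 1, eta = 0.2, max_epochs = 100, rng_seed = 3)
  expect_true(all(C1 >= apply(X, 2, min) - 1e-9 &
                  C1 <= apply(X, 2, max) + 1e-9))
  expect_error(fit_centers(X, h = 13), "exceeds")
  expect_error(fit_centers(X, h = 2, eta = 1), "strictly between")
  # determinism
  expect_identical(fit_centers(X, 3, rng_seed = 7), fit_centers(X, 3, rng_seed = 7))
})

test_that("width rule gives c_max/sqrt(2h), scales with the centres", {
  C2 <- rbind(c(0, 0), c(3, 4))              # distance 5, h = 2
  expect_equal(compute_widths(C2), rep(5 / 2, 2))
  Csq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))  # unit square, h = 4
  expect_equal(compute_widths(Csq), rep(sqrt(2) / sqrt(8), 4))
  expect_equal(compute_widths(Csq * 3), 3 * compute_widths(Csq))
  expect_equal(compute_widths(C2, rule = "linear"), rep(5 / 4, 2))
  expect_error(compute_widths(rbind(c(1, 1), c(1, 1))), "coincide")
  expect_error(compute_widths(C2[1, , drop = FALSE]), "at least 2")
})

test_that("Gaussian activations match hand-computed values", {
  C <- rbind(c(0, 0), c(3, 4))
  b <- c(5, 5)
  # at a centre: exp(0) = 1; at distance 5 from centre 2 with b = 5:
  # exp(-25/50) = exp(-1/2)
  expect_equal(as.vector(rbf_activations(C, b, c(0, 0))),
               c(1, exp(-1 / 2)))
  # at distance b*sqrt(2): exp(-1)
  expect_equal(as.vector(rbf_activations(C[1, , drop = FALSE], 5,
                                          c(5 * sqrt(2), 0))),
               exp(-1))
  A <- rbf_activations(C, b, matrix(rnorm(20), 10, 2))
  expect_true(all(A > 0 & A <= 1))
  expect_error(rbf_activations(C, b, c(1, 2, 3)), "dimension")
})

test_that("least-squares weights satisfy the normal equations", {
  set.seed(5)
  Phi <- matrix(rnorm(50 * 10), 50, 10)
  Y <- matrix(rnorm(50 * 3), 50, 3)
  W <- fit_weights_lsm(Phi, Y)
  # residual orthogonal to the column space
  expect_lt(max(abs(crossprod(Phi, Phi %*% W - Y))), 1e-8)
  # square nonsingular: exact solve
  Phis <- matrix(rnorm(64), 8, 8)
  Ys <- matrix(rnorm(16), 8, 2)
  Ws <- fit_weights_lsm(Phis, Ys)
  expect_lt(max(abs(Phis %*% Ws - Ys)), 1e-9)
  expect_equal(fit_weights_lsm(Phi, matrix(0, 50, 2)), matrix(0, 10, 2))
  # rank-deficient: minimum-norm among least-squares solutions
  Phir <- cbind(Phi[, 1:3], Phi[, 1:3])
  Wr <- fit_weights_lsm(Phir, Y)
  expect_lt(max(abs(crossprod(Phir, Phir %*% Wr - Y))), 1e-8)
  skip_if_not_installed("pracma")
  expect_equal(Wr, pracma::pinv(Phir) %*% Y, tolerance = 1e-8)
})

test_that("trained network interpolates its own training data when h = N", {
  set.seed(6)
  X <- matrix(rnorm(10 * 5), 10, 5)
  Y <- matrix(runif(10 * 4), 10, 4)
  b <- compute_widths(X)
  Phi <- rbf_activations(X, b, X)
  W <- fit_weights_lsm(Phi, Y)
  expect_lt(max(abs(Phi %*% W - Y)), 1e-6)
})

test_that("end-to-end training is deterministic and predicts sensibly", {
  ds <- small_dataset()
  net <- train_rbfnn(ds, h = 12, rng_seed = 11)
  net2 <- train_rbfnn(ds, h = 12, rng_seed = 11)
  expect_identical(net$weights, net2$weights)
  expect_equal(dim(net$centers), c(12L, 208L))
  expect_true(all(net$widths > 0))
  # prediction shape and clipping
  P <- predict(net, ds$voltages[ds$test_idx, ])
  expect_equal(dim(P), c(12L, ds$grid$n_active))
  expect_true(all(P >= 0 & P <= 1))
  # single frame gives a vector; raw output may exceed [0,1]
  p1 <- predict(net, ds$voltages[1, ])
  expect_length(p1, ds$grid$n_active)
  # continuity: small input perturbation gives small output change
  eps <- 1e-6
  v <- ds$voltages[1, ]
  d <- max(abs(predict(net, v + eps, clip = FALSE) -
               predict(net, v, clip = FALSE)))
  expect_lt(d, 1e-3)
  # untrained network errors
  bad <- net; bad$weights <- NULL
  expect_error(predict(bad, v), "weights")
})
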