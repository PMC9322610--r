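test_that("encircling coefficients follow the linear decay law", {
  set.seed(1)
  c0 <- gwo_coefficients(0, 100, dim = 50)
  expect_equal(c0$a, 2)
  cT <- gwo_coefficients(100, 100, dim = 50)
  expect_equal(cT$a, 0)
  expect_true(all(cT$A == 0))
  for (t in c(0, 25, 50, 99)) {
    cc <- gwo_coefficients(t, 100, dim = 200)
    expect_true(all(abs(cc$A) <= cc$a))
    expect_true(all(cc$C >= 0 & cc$C <= 2))
  }
  expect_error(gwo_coefficients(101, 100), "lie in")
})

test_that("position update fixed points and clamping hold", {
  P <- matrix(rep(c(1, 2, 3), 5), 5, 3, byrow = TRUE)
  leaders <- P[1:3, ]
  # a = 0 forces A = 0: every wolf jumps to the leader mean (all equal here)
  set.seed(2)
  P2 <- eitgwo:::gwo_update_positions(P, leaders, a = 0,
                                      lower = rep(-10, 3), upper = rep(10, 3))
  expect_equal(P2, P)
  # distinct leaders, a = 0: every wolf lands on the leader centroid
  L <- rbind(c(0, 0, 0), c(3, 3, 3), c(6, 0, 3))
  set.seed(3)
  P3 <- eitgwo:::gwo_update_positions(P, L, a = 0,
                                      lower = rep(-10, 3), upper = rep(10, 3))
  expect_equal(P3, matrix(colMeans(L), 5, 3, byrow = TRUE))
  # clamping contract
  set.seed(4)
  P4 <- eitgwo:::gwo_update_positions(P * 100, L, a = 2,
                                      lower = rep(-1, 3), upper = rep(1, 3))
  expect_true(all(P4 >= -1 & P4 <= 1))
})

test_that("fitness equals the RMSE of the stacked network output", {
  set.seed(5)
  Phi <- matrix(rnorm(30 * 6), 30, 6)
  Y <- matrix(runif(30 * 4), 30, 4)
  W <- matrix(rnorm(24), 6, 4)
  expect_equal(fitness_rmse(W, Phi, Y),
               image_rmse(as.vector(Phi %*% W), as.vector(Y)))
  # exact fit gives zero
  Wls <- fit_weights_lsm(Phi[1:6, ], Y[1:6, ])
  expect_lt(fitness_rmse(Wls, Phi[1:6, ], Y[1:6, ]), 1e-10)
  # hand example: errors (1,-1,1,-1) -> RMSE 1
  expect_equal(image_rmse(c(1, 0, 1, 0), c(0, 1, 0, 1)), 1)
  # least squares is optimal for this objective
  Wopt <- fit_weights_lsm(Phi, Y)
  f0 <- fitness_rmse(Wopt, Phi, Y)
  rand <- replicate(100, fitness_rmse(matrix(rnorm(24), 6, 4), Phi, Y))
  expect_true(all(f0 <= rand))
})

test_that("GWO solves the sphere benchmark and beats random search 10x", {
  sphere <- function(x) sum(x^2)
  out <- gwo_minimize(sphere, dim = 10, lower = -10, upper = 10,
                      pop_size = 30, max_iters = 200, rng_seed = 7)
  expect_lt(out$best_fitness, 1e-3)
  # best-so-far trace is monotonically non-increasing
  expect_true(all(diff(out$trace) <= 0))
  # independent random-search baseline with the same evaluation budget
  rs_best <- with_seed(8, {
    min(replicate(out$evaluations, sphere(runif(10, -10, 10))))
  })
  expect_gt(rs_best / out$best_fitness, 10)
  expect_error(gwo_minimize(sphere, 10, -1, 1, pop_size = 3), "at least 4")
})

test_that("GWO is deterministic under a fixed seed", {
  sphere <- function(x) sum(x^2)
  o1 <- gwo_minimize(sphere, 5, -1, 1, pop_size = 8, max_iters = 30, rng_seed = 3)
  o2 <- gwo_minimize(sphere, 5, -1, 1, pop_size = 8, max_iters = 30, rng_seed = 3)
  expect_identical(o1$best, o2$best)
  expect_identical(o1$trace, o2$trace)
})

test_that("LSM-seeded weight optimisation never degrades the training fit", {
  ds <- small_dataset()
  net <- train_rbfnn(ds, h = 8, rng_seed = 13)
  gw <- train_gwo_rbfnn(net, ds, pop_size = 10, max_iters = 25, rng_seed = 13)
  expect_lte(gw$train_rmse, net$train_rmse * (1 + 1e-12))
  expect_true(all(diff(gw$gwo_trace) <= 0))
  expect_equal(gw$method, "gwo-rbfnn")
  # determinism of the full optimisation
  gw2 <- train_gwo_rbfnn(net, ds, pop_size = 10, max_iters = 25, rng_seed = 13)
  expect_identical(gw$weights, gw2$weights)
  # batched Gram-based fitness agrees with the reference implementation
  Xs <- eitgwo:::standardize_input(net, ds$voltages[ds$train_idx, ])
  Phi <- rbf_activations(net$centers, net$widths, Xs)
  Y <- ds$images[ds$train_idx, ]
  expect_equal(gw$train_rmse, fitness_rmse(gw$weights, Phi, Y),
               tolerance = 1e-10)
})

test_that("random-initialised GWO cannot beat the least-squares optimum", {
  ds <- small_dataset()
  net <- train_rbfnn(ds, h = 6, rng_seed = 19)
  gw <- train_gwo_rbfnn(net, ds, pop_size = 8, max_iters = 40, rng_seed = 19,
                        init = "random")
  expect_gte(gw$train_rmse, net$train_rmse - 1e-12)
})
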