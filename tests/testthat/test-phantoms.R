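test_that("phantoms respect containment, count and non-overlap invariants", {
  for (n in 1:3) {
    for (seed in c(1, 7, 99)) {
      ph <- sample_phantom(n, rng_seed = seed)
      inc <- ph$inclusions
      expect_equal(nrow(inc), n)
      # entirely inside the field: centre distance + radius <= field radius
      expect_true(all(sqrt(inc$x^2 + inc$y^2) + inc$diameter / 2 <= 47.5 + 1e-12))
      if (n > 1) {
        d <- as.vector(dist(inc[, c("x", "y")]))
        expect_true(all(d > 10))
      }
    }
  }
  expect_error(sample_phantom(0, 1), "1, 2 or 3")
  expect_error(sample_phantom(4, 1), "1, 2 or 3")
})

test_that("phantom sampling is deterministic and annular mode confines centres", {
  expect_identical(sample_phantom(3, rng_seed = 5), sample_phantom(3, rng_seed = 5))
  ph <- sample_phantom(2, rng_seed = 3, inner_radius_mm = 30)
  r <- sqrt(ph$inclusions$x^2 + ph$inclusions$y^2)
  expect_true(all(r >= 30 & r <= 42.5))
})

test_that("rasterisation assigns target conductivity by centroid membership", {
  m <- coarse_mesh()
  ph <- sample_phantom(1, rng_seed = 2)
  ph$inclusions$x <- 0; ph$inclusions$y <- 0    # centre the target
  sigma <- rasterize(ph, m)
  r <- sqrt(rowSums(m$centroids^2))
  expect_true(all(sigma[r <= 4.9] == 5.5e-8))
  expect_true(all(sigma[r > 5.1] == 5.5e-4))
  # contrast ratio is exactly 1e4
  expect_equal(max(sigma) / min(sigma), 1e4)
})

test_that("target-valued element fraction approximates the area ratio", {
  m <- prod_mesh()
  fr <- vapply(1:20, function(s) {
    sigma <- rasterize(sample_phantom(2, rng_seed = s), m)
    sum(m$areas[sigma == 5.5e-8]) / sum(m$areas)
  }, numeric(1))
  expected <- 2 * pi * 5^2 / (pi * 47.5^2)
  expect_lt(abs(mean(fr) - expected) / expected, 0.25)
})

test_that("dataset generation splits, labels and reproduces deterministically", {
  ds <- small_dataset()
  expect_equal(length(ds$train_idx), 48L)
  expect_equal(length(ds$test_idx), 12L)
  expect_length(intersect(ds$train_idx, ds$test_idx), 0)
  expect_setequal(c(ds$train_idx, ds$test_idx), 1:60)
  expect_true(all(ds$labels %in% 1:3))
  # near-equal thirds by largest remainder
  expect_equal(sort(tabulate(ds$labels, 3)), c(20L, 20L, 20L))
  # no duplicate phantoms under continuous placement (checked exactly on
  # the phantom parameters; coarse rasterisation may still quantise two
  # nearby phantoms onto the same element set)
  params <- sapply(ds$phantoms, function(p)
    paste(round(t(as.matrix(p$inclusions[, c("x", "y")])), 9), collapse = ","))
  expect_equal(anyDuplicated(params), 0L)
  # truth images are binary on the [0,1] scale
  expect_true(all(ds$images %in% c(0, 1)))
  ds2 <- generate_dataset(n_samples = 60, mesh = coarse_mesh(),
                          protocol = std_protocol(), grid = std_grid(),
                          train_fraction = 48 / 60, rng_seed = 42)
  expect_identical(ds$voltages, ds2$voltages)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$train_idx, ds2$train_idx)
})

test_that("1700-sample study split is 1500/1700 with 567/567/566 mix", {
  # split arithmetic only; checked without forward solves
  n <- 1700; mix <- c(1, 1, 1) / 3
  exact <- n * mix
  counts <- floor(exact)
  rem <- n - sum(counts)
  counts[order(exact - counts, decreasing = TRUE)[seq_len(rem)]] <-
    counts[order(exact - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  expect_equal(sort(counts, decreasing = TRUE), c(567, 567, 566))
  expect_equal(round(1500 / 1700 * n), 1500)
})

test_that("noise injection hits the nominal SNR and preserves shape", {
  ds <- small_dataset()
  v <- ds$voltages
  # empirical SNR over 1000 frames within 0.5 dB of nominal
  frames <- v[rep(1:60, length.out = 1000), ]
  for (snr in c(30, 40, 50)) {
    noisy <- add_noise(frames, snr, rng_seed = 17)
    expect_equal(dim(noisy), dim(frames))
    emp <- 10 * log10(sum(frames^2) / sum((noisy - frames)^2))
    expect_lt(abs(emp - snr), 0.5)
  }
  # Inf SNR is the identity
  expect_identical(add_noise(v, Inf, 1), v)
  # vector in, vector out; deterministic under seed
  n1 <- add_noise(v[1, ], 30, rng_seed = 4)
  expect_null(dim(n1))
  expect_identical(n1, add_noise(v[1, ], 30, rng_seed = 4))
  # added noise is unbiased
  big <- add_noise(matrix(1, 2000, 208), 20, rng_seed = 9) - 1
  expect_lt(abs(mean(big)), 5e-3)
})

test_that("dataset container round-trips and exports CSV", {
  ds <- small_dataset()
  f <- tempfile(fileext = ".rds")
  write_dataset(ds, f)
  expect_identical(read_dataset(f)$voltages, ds$voltages)
  unlink(f)
  csv <- tempfile(fileext = ".csv")
  export_sample_csv(ds, 3, csv, "voltages")
  got <- read.table(csv, sep = ",", header = TRUE)
  expect_equal(got$voltage, unname(ds$voltages[3, ]))
  unlink(csv)
})
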