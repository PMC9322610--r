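test_that("protocol enumerates 16 adjacent drives with 13 measurements each", {
  p <- std_protocol()
  expect_equal(nrow(p$frame), 208L)
  expect_equal(p$drive_pairs[, 2], c(2:16, 1))
  # for drive k the measurement pairs are (m, m+1), m = k+2..k+14 (mod 16)
  fr3 <- p$frame[p$frame[, "drive"] == 3, ]
  expect_equal(nrow(fr3), 13L)
  expect_equal(fr3[, "meas"], c(5:16, 1))
  expect_equal(fr3[, "meas_neg"], c(6:16, 1, 2))
  # no measurement touches its drive electrodes
  expect_false(any(p$frame[, "meas"] == p$frame[, "drive"] |
                   p$frame[, "meas_neg"] == p$frame[, "drive"] |
                   p$frame[, "meas"] == p$frame[, "drive_neg"] |
                   p$frame[, "meas_neg"] == p$frame[, "drive_neg"]))
})

test_that("reciprocity holds for homogeneous and inhomogeneous fields", {
  m <- coarse_mesh()
  sig_h <- homog_sigma(m)
  ph <- sample_phantom(2, rng_seed = 11)
  sig_i <- rasterize(ph, m)
  for (sig in list(sig_h, sig_i)) {
    v1 <- pair_voltage(m, sig, c(1, 2), c(9, 10))
    v2 <- pair_voltage(m, sig, c(9, 10), c(1, 2))
    expect_lt(abs(v1 - v2) / abs(v1), 1e-8)
    v3 <- pair_voltage(m, sig, c(4, 5), c(13, 16))
    v4 <- pair_voltage(m, sig, c(13, 16), c(4, 5))
    expect_lt(abs(v3 - v4) / abs(v3), 1e-8)
  }
})

test_that("voltages scale as 1/sigma for a homogeneous field", {
  m <- coarse_mesh()
  p <- std_protocol()
  v1 <- solve_forward(m, homog_sigma(m), p)
  v2 <- solve_forward(m, 2 * homog_sigma(m), p)
  expect_lt(max(abs(v2 - v1 / 2) / abs(v1 / 2)), 1e-10)
})

test_that("net injected current is zero to machine precision", {
  m <- coarse_mesh()
  for (pair in list(c(1, 2), c(7, 8), c(16, 1))) {
    f <- eitgwo:::build_load(m, pair, 5e-4)
    expect_lt(abs(sum(f)), 1e-12 * 5e-4)
  }
})

test_that("degenerate conductivity is rejected with a clear message", {
  m <- coarse_mesh()
  p <- std_protocol()
  expect_error(solve_forward(m, rep(0, nrow(m$elements)), p), "positive")
  expect_error(solve_forward(m, homog_sigma(m)[-1], p), "per mesh element")
})

test_that("boundary potential matches the analytic disc solution within 2%", {
  # narrow electrodes approximate point drives; opposite pair (1, 9).
  # For a homogeneous disc with point source/sink at boundary angles
  # 0 and pi: u(theta) = I/(pi*sigma) * log(|cos(theta/2)|/|sin(theta/2)|)
  m <- build_mesh(47.5, 2, electrode_width_mm = 1)
  sigma0 <- 0.02
  I0 <- 5e-4
  U <- solve_fields(m, rep(sigma0, nrow(m$elements)), rbind(c(1, 9)), I0)
  bn <- m$boundary_nodes
  th <- atan2(m$nodes[bn, 2], m$nodes[bn, 1]) %% (2 * pi)
  analytic <- I0 / (pi * sigma0) * log(abs(cos(th / 2)) / abs(sin(th / 2)))
  # compare potential differences between boundary nodes away from the
  # drive singularities (30 deg to 150 deg)
  sel <- which(th > pi / 6 & th < 5 * pi / 6)
  ref <- sel[1]
  got <- U[bn[sel], 1] - U[bn[ref], 1]
  want <- analytic[sel] - analytic[ref]
  scale <- max(abs(want))
  expect_lt(max(abs(got - want)) / scale, 0.02)
})

test_that("sensitivity matrix matches central finite differences", {
  m <- coarse_mesh()
  p <- std_protocol()
  sigma <- homog_sigma(m)
  J <- compute_sensitivity(m, sigma, p)
  expect_equal(dim(J), c(208L, nrow(m$elements)))
  set.seed(3)
  els <- sample(nrow(m$elements), 8)
  for (e in els) {
    d <- 0.01 * sigma[e]
    sp <- sigma; sp[e] <- sp[e] + d
    sm <- sigma; sm[e] <- sm[e] - d
    fd <- (solve_forward(m, sp, p) - solve_forward(m, sm, p)) / (2 * d)
    ## relative agreement on all non-negligible entries; below ~1e-3 of the
    ## column scale the FD truncation error dominates any relative measure
    big <- abs(J[, e]) > 1e-3 * max(abs(J[, e]))
    expect_lt(max(abs(J[big, e] - fd[big]) / abs(J[big, e])), 1e-3)
  }
})

test_that("sensitivity magnitude decays away from the drive electrodes", {
  m <- coarse_mesh()
  p <- std_protocol()
  J <- compute_sensitivity(m, homog_sigma(m), p)
  # row 1: drive (1,2), measurement (3,4); electrode 1 sits at angle 0
  el1 <- m$nodes[m$electrode_nodes[[1]][1], ]
  d_el <- sqrt((m$centroids[, 1] - el1[1])^2 + (m$centroids[, 2] - el1[2])^2)
  near <- which.min(d_el)
  far <- which.min(rowSums(m$centroids^2))   # disc centre
  expect_gt(abs(J[1, near]), abs(J[1, far]))
})

test_that("sensitivity map is mirror-symmetric about the drive-measure axis", {
  # drive (1,2), measure (9,10): the reflection swapping the two drive
  # electrodes and the two measurement electrodes reverses both current and
  # measurement polarity, leaving the sensitivity unchanged. Compare
  # radially/angularly binned sums on either side of the mirror axis.
  m <- prod_mesh()
  p <- std_protocol()
  J <- compute_sensitivity(m, homog_sigma(m), p)
  row <- which(p$frame[, "drive"] == 1 & p$frame[, "meas"] == 9)
  # reflection about the line at angle pi/16 maps theta -> pi/8 - theta:
  # electrodes 1<->2 (0 <-> 22.5 deg) and 9<->10 (180 <-> 202.5 deg)
  axis_angle <- pi / 16
  th <- atan2(m$centroids[, 2], m$centroids[, 1])
  s <- eitgwo:::ang_diff(th, axis_angle)     # signed angle from the axis
  r <- sqrt(rowSums(m$centroids^2))
  rb <- cut(r, breaks = c(0, 20, 35, 47.5))
  ab <- cut(abs(s), breaks = seq(0.2, pi, length.out = 5))
  keep <- !is.na(ab)
  sums <- tapply(J[row, keep] * sign(s[keep]),
                 list(rb[keep], ab[keep]), sum)
  mags <- tapply(abs(J[row, keep]), list(rb[keep], ab[keep]), sum)
  expect_lt(max(abs(sums) / max(mags)), 0.05)
})

test_that("homogeneous frame is mesh-converged within 1% at production resolution", {
  p <- std_protocol()
  v1 <- solve_forward(prod_mesh(), homog_sigma(prod_mesh()), p)
  m2 <- build_mesh(47.5, 2)
  v2 <- solve_forward(m2, homog_sigma(m2), p)
  expect_lt(max(abs(v2 - v1) / abs(v1)), 0.01)
})
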