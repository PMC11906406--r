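make_dirs <- function(n, seed = 3) {
  set.seed(seed)
  d <- matrix(stats::rnorm(n * 3), n, 3)
  d / sqrt(rowSums(d^2))
}

test_that("sampling schemes validate directions and split off b0 volumes", {
  d <- rbind(c(0, 0, 0), c(0, 0, 0), make_dirs(8))
  sc <- sampling_scheme(d, c(0, 0, rep(1000, 8)))
  expect_identical(sc$b0_indices, 1:2)
  expect_error(sampling_scheme(d * 2, c(0, 0, rep(1000, 8))), "unit")
})

test_that("rotate_scheme rotates directions and rejects non-rotations", {
  sc <- sampling_scheme(make_dirs(10), rep(1000, 10))
  expect_equal(rotate_scheme(sc, diag(3))$directions, sc$directions)
  Rz <- diag(c(-1, -1, 1))
  expect_equal(rotate_scheme(rotate_scheme(sc, Rz), Rz)$directions, sc$directions)
  # pairwise dot products are invariant under any rotation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  d2 <- rotate_scheme(sc, R)$directions
  expect_equal(d2 %*% t(d2), sc$directions %*% t(sc$directions), tolerance = 1e-12)
  expect_error(rotate_scheme(sc, diag(c(1, 1, 2))), "rotation")
  expect_error(rotate_scheme(sc, diag(c(-1, 1, 1))), "rotation") # det -1
})

test_that("Watson weights are row-stochastic, antipodal and uniform at kappa 0", {
  q <- make_dirs(7, seed = 4)
  s <- make_dirs(20, seed = 5)
  W <- watson_weights(q, s, 10)
  expect_equal(rowSums(W), rep(1, 7))
  expect_true(all(W >= 0))
  expect_equal(watson_weights(-q, s, 10), W) # (q.v)^2 symmetry
  expect_equal(watson_weights(q, s, 0), matrix(1 / 20, 7, 20))
  # constant signal interpolates to the constant
  expect_equal(as.numeric(W %*% rep(3.5, 20)), rep(3.5, 7))
})

test_that("resampling concentrates onto the input at large kappa and stays in range", {
  s <- make_dirs(40, seed = 6)
  set.seed(7)
  # smooth antipodally symmetric signal
  A <- crossprod(matrix(stats::rnorm(9), 3, 3)) / 3
  sig <- exp(-rowSums((s %*% A) * s))
  vol <- spherical_volume(array(sig, c(1, 1, 1, 40)), sampling_scheme(s, rep(1000, 40)))
  out <- resample(vol, s, kappa = 500)
  expect_lt(max(abs(out[1, 1, 1, ] - sig) / sig), 0.02)
  # convex combination: output within input range
  out10 <- resample(vol, make_dirs(15, seed = 8), kappa = 10)
  expect_true(all(out10 >= min(sig) - 1e-12 & out10 <= max(sig) + 1e-12))
  # constant per-voxel signal stays constant
  cvol <- spherical_volume(array(2, c(2, 1, 1, 40)), vol$scheme)
  expect_equal(as.numeric(resample(cvol, make_dirs(5, seed = 9))), rep(2, 10))
})

test_that("interpolation commutes with joint rotation of samples and queries", {
  s <- make_dirs(30, seed = 10)
  q <- make_dirs(9, seed = 11)
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  expect_equal(
    watson_weights(q %*% t(R), s %*% t(R), 10),
    watson_weights(q, s, 10),
    tolerance = 1e-12
  )
})

test_that("b0 normalization divides by the voxel-wise b0 mean and guards zeros", {
  d <- rbind(c(0, 0, 0), c(0, 0, 0), make_dirs(4, seed = 12))
  sc <- sampling_scheme(d, c(0, 0, rep(1000, 4)))
  raw <- array(0, c(2, 1, 1, 6))
  raw[1, 1, 1, ] <- c(2, 2, 1, 1, 1, 1) # b0 mean 2 -> 0.5
  raw[2, 1, 1, ] <- 0 # b0 mean 0 -> masked out
  v <- normalize_b0(raw, sc)
  expect_equal(as.numeric(v$values[1, 1, 1, ]), rep(0.5, 4))
  expect_false(v$mask[2, 1, 1])
  expect_true(v$mask[1, 1, 1])
  expect_error(normalize_b0(raw, sampling_scheme(d[3:6, , drop = FALSE], rep(1000, 4))), "b0")
})

test_that("noise-free phantom attenuations equal the closed-form tensor signal", {
  ph <- test_phantom(noise = "none")
  dwi_dirs <- ph$volume$scheme$directions
  b <- ph$volume$scheme$bvalues[1]
  # CSF voxels: isotropic D = 3e-3 I -> attenuation exp(-b d) in every direction
  csf <- which(ph$labels == 1L & ph$volume$mask, arr.ind = TRUE)[1, ]
  vals <- ph$volume$values[csf[1], csf[2], csf[3], ]
  expect_equal(vals, rep(exp(-b * 3e-3), length(vals)), tolerance = 1e-6)
  # a WM voxel matches its circumferential tensor model
  wm <- which(ph$labels == 3L & ph$volume$mask, arr.ind = TRUE)
  wm <- wm[which.max(abs(wm[, 1] - 16.5)), ] # off-axis voxel
  ctr <- (dim(ph$labels)[1] + 1) / 2
  p <- wm - ctr
  tang <- c(-p[2], p[1], 0)
  D <- icoseg:::tensor_from_frame(tang, tissue_models()$WM)
  expect_equal(
    ph$volume$values[wm[1], wm[2], wm[3], ],
    tensor_signal(D, b, dwi_dirs),
    tolerance = 1e-6
  )
})

test_that("FSL bval/bvec files round-trip through read_scheme", {
  sc <- generate_directions(12, seed = 13, n_b0 = 2)
  bval <- tempfile(fileext = ".bval")
  bvec <- tempfile(fileext = ".bvec")
  write_scheme(sc, bval, bvec)
  expect_length(readLines(bvec), 3L) # x, y, z rows
  expect_length(readLines(bval), 1L)
  sc2 <- read_scheme(bval, bvec)
  expect_equal(sc2$directions, sc$directions, tolerance = 1e-12)
  expect_equal(sc2$bvalues, sc$bvalues)
  expect_identical(sc2$b0_indices, sc$b0_indices)
  unlink(c(bval, bvec))
})
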