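test_that("star kernel layout has 11 points permuted cyclically by the stabilizer", {
  lay <- star_kernel_layout(test_ico)
  expect_equal(dim(lay), c(11L, 3L))
  expect_true(all(abs(sqrt(rowSums(lay^2)) - 1) < 1e-12))
  for (k in 2:5) {
    S <- test_group$elements[, , test_group$stabilizer[k]]
    moved <- lay %*% t(S)
    # center fixed
    expect_lt(sqrt(sum((moved[1, ] - lay[1, ])^2)), 1e-9)
    # arms map onto arms of the same ring (set-wise, cyclic)
    for (ring in list(2:6, 7:11)) {
      for (i in ring) {
        d <- min(colSums((t(lay[ring, , drop = FALSE]) - moved[i, ])^2))
        expect_lt(d, 1e-18)
      }
    }
  }
})

test_that("the star-kernel orbit has 42 distinct points closed under the group", {
  orb <- test_orbit
  expect_equal(nrow(orb$points), 42L) # 12 vertices + 30 edge midpoints
  expect_equal(dim(orb$index), c(60L, 11L))
  for (h in c(1L, 13L, 37L, 60L)) {
    perm <- orbit_perm(orb, test_group$elements[, , h])
    expect_identical(sort(perm), 1:42)
  }
})

test_that("lift_s2 implements the discretized lifting correlation", {
  set.seed(20)
  M <- 5
  x <- array(stats::runif(M * 42), c(M, 42, 1))
  # delta kernel at the center sample reads the signal at g.v0
  wd <- array(0, c(1, 1, 11))
  wd[1, 1, 1] <- 1
  out <- lift_s2(x, star_kernel(1, 1, weights = wd, bias = 0), test_group, test_orbit)
  for (g in c(1, 7, 42)) {
    expect_equal(out[, g, 1], x[, test_orbit$index[g, 1], 1])
  }
  # constant input: out = c * sum(w) + bias everywhere
  k <- star_kernel(1, 3)
  xc <- array(2, c(M, 42, 1))
  outc <- lift_s2(xc, k, test_group, test_orbit)
  for (co in 1:3) {
    expect_equal(
      as.numeric(outc[, , co]),
      rep(2 * sum(k$weights[1, co, ]) + k$bias[co], M * 60)
    )
  }
})

test_that("lift_s2 is exactly equivariant under all 60 rotations", {
  set.seed(21)
  M <- 3
  x <- array(stats::runif(M * 42 * 2), c(M, 42, 2))
  k <- star_kernel(2, 3)
  F0 <- lift_s2(x, k, test_group, test_orbit)
  err <- 0
  for (h in 1:60) {
    Rh <- test_group$elements[, , h]
    xr <- x[, orbit_perm(test_orbit, t(Rh)), , drop = FALSE] # f(R^-1 .)
    Fr <- lift_s2(xr, k, test_group, test_orbit)
    perm <- left_translation_perm(test_group, h)
    err <- max(err, max(abs(Fr - F0[, perm, , drop = FALSE])))
  }
  expect_lt(err / max(abs(F0)), 1e-6)
})

test_that("gconv_so3 is a cyclic fiber correlation with exact left equivariance", {
  set.seed(22)
  M <- 4
  F0 <- array(stats::runif(M * 60 * 3), c(M, 60, 3))
  # delta kernel at spin 1 with identity channel map reproduces the input
  wd <- array(0, c(3, 3, 5))
  for (c in 1:3) wd[c, c, 1] <- 1
  expect_equal(gconv_so3(F0, fiber_kernel(3, 3, weights = wd, bias = rep(0, 3)), test_group), F0)
  # constant input gives constant output
  k <- fiber_kernel(3, 2)
  Fc <- array(1.5, c(M, 60, 3))
  outc <- gconv_so3(Fc, k, test_group)
  for (co in 1:2) {
    expect_equal(
      as.numeric(outc[, , co]),
      rep(1.5 * sum(k$weights[, co, ]) + k$bias[co], M * 60)
    )
  }
  # exhaustive left-translation equivariance
  G0 <- gconv_so3(F0, k, test_group)
  err <- 0
  for (h in 1:60) {
    perm <- left_translation_perm(test_group, h)
    Gt <- gconv_so3(F0[, perm, , drop = FALSE], k, test_group)
    err <- max(err, max(abs(Gt - G0[, perm, , drop = FALSE])))
  }
  expect_lt(err / max(abs(G0)), 1e-6)
})

test_that("spatial kernel rotation is trilinear with exact 180-degree flips", {
  set.seed(23)
  k <- spatial_kernel(2, 3)
  expect_identical(rotate_spatial_kernel(k, diag(3))$weights, k$weights)
  # 180 degrees about x: y and z axes flip -> pure index reversal
  kr <- rotate_spatial_kernel(k, diag(c(1, -1, -1)))
  expect_equal(kr$weights, k$weights[, , 1:3, 3:1, 3:1])
  # center weight invariant under arbitrary rotations
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(rotate_spatial_kernel(k, R)$weights[, , 2, 2, 2], k$weights[, , 2, 2, 2])
  # rows of the resampling matrix are partitions of unity while the
  # rotated point stays inside the support
  A <- icoseg:::trilinear_rotation_matrix(R)
  expect_true(all(rowSums(A) <= 1 + 1e-12))
  expect_equal(A[14, 14], 1) # center row picks the center
})

test_that("spatial_conv shrinks 7^3 to 1^3 over three layers and crops with a delta", {
  set.seed(24)
  B <- 2
  F7 <- array(stats::runif(B * 343 * 60 * 2), c(B * 343, 60, 2))
  k22 <- spatial_kernel(2, 2)
  o5 <- spatial_conv(F7, k22, test_group, "none", batch = B, extent = 7)
  expect_equal(dim(o5), c(B * 125, 60, 2))
  o3 <- spatial_conv(o5, k22, test_group, "none", batch = B, extent = 5)
  o1 <- spatial_conv(o3, k22, test_group, "none", batch = B, extent = 3)
  expect_equal(dim(o1), c(B * 1, 60, 2))
  # delta kernel at the center offset = central crop, in every mode
  wd <- array(0, c(2, 2, 3, 3, 3))
  for (c in 1:2) wd[c, c, 2, 2, 2] <- 1
  kd <- spatial_kernel(2, 2, weights = wd, bias = c(0, 0))
  og <- as.matrix(expand.grid(1:5, 1:5, 1:5)) + 1
  vox <- og[, 1] + 7 * (og[, 2] - 1) + 49 * (og[, 3] - 1)
  rows <- as.integer(outer(vox, (seq_len(B) - 1L) * 343L, `+`))
  crop <- F7[rows, , , drop = FALSE]
  expect_equal(
    spatial_conv(F7, kd, test_group, "none", batch = B, extent = 7),
    crop,
    tolerance = 1e-12
  )
  # under rotation tying the trilinear resampling spreads an off-center
  # delta, but the center weight itself is a fixed point of every rotation
  for (g in c(2, 17, 44)) {
    kr <- rotate_spatial_kernel(kd, test_group$elements[, , g])
    expect_equal(kr$weights[, , 2, 2, 2], kd$weights[, , 2, 2, 2])
  }
})

test_that("full-mode spatial convolution commutes with grid-exact rotations", {
  set.seed(25)
  s <- 5
  Fi <- array(stats::runif(s^3 * 60 * 2), c(s^3, 60, 2))
  k <- spatial_kernel(2, 3)
  base <- spatial_conv(Fi, k, test_group, "full", batch = 1, extent = s)
  base_none <- spatial_conv(Fi, k, test_group, "none", batch = 1, extent = s)
  for (h in coordinate_axis_twofold_rotations(test_group)) {
    Rh <- test_group$elements[, , h]
    gp <- left_translation_perm(test_group, h)
    Ft <- Fi[grid_perm(s, Rh), gp, , drop = FALSE]
    out <- spatial_conv(Ft, k, test_group, "full", batch = 1, extent = s)
    ref <- base[grid_perm(s - 2, Rh), gp, , drop = FALSE]
    expect_lt(max(abs(out - ref)) / max(abs(base)), 1e-10)
    # the unrotated-kernel mode visibly breaks the same commutation
    out_none <- spatial_conv(Ft, k, test_group, "none", batch = 1, extent = s)
    ref_none <- base_none[grid_perm(s - 2, Rh), gp, , drop = FALSE]
    expect_gt(max(abs(out_none - ref_none)) / max(abs(base_none)), 0.01)
  }
})

test_that("max projection collapses fibers (sphere) or the whole group (space)", {
  set.seed(26)
  M <- 6
  Fi <- array(stats::runif(M * 60 * 3), c(M, 60, 3))
  # space target equals brute-force max over the 60 slots
  expect_equal(project_max(Fi, "space"), apply(Fi, c(1, 3), max))
  # sphere target is invariant to arbitrary per-fiber spin permutations
  ps <- project_max(Fi, "sphere")
  Fp <- Fi
  for (f in 1:12) {
    slots <- (f - 1L) * 5L + 1:5
    Fp[, slots, ] <- Fp[, sample(slots), , drop = FALSE]
  }
  expect_equal(project_max(Fp, "sphere"), ps)
  # constant map projects to the constant
  expect_equal(
    project_max(array(2.2, c(M, 60, 2)), "space"),
    matrix(2.2, M, 2)
  )
})

test_that("interleaved ReLU pipeline commutes with 180-degree rotations only when rotation-tied", {
  rep <- equiv_check(test_group, seed = 3)
  e <- setNames(rep$max_error, rep$suite)
  expect_lt(e[["se3_pipeline_180"]], 1e-5)
  expect_gt(e[["decoupled_contrast_180"]], 0.01)
  expect_true(all(rep$pass))
})
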