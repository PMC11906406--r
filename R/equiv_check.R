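#' Run the package's equivariance and group-consistency suites
#'
#' Recomputes, on seeded random inputs, the structural guarantees the
#' layer stack is built on: group closure (Cayley residuals), exact
#' left-translation equivariance of the fiber group convolution and the
#' lifting convolution over all 60 elements, invariance of the
#' max-projection, end-to-end commutation of the full SE(3) pipeline with
#' the grid-exact 180-degree rotations, and the deliberate failure of the
#' decoupled (unrotated-kernel) pipeline under the same transform.
#'
#' @param group optional `rotation_group` (built fresh if missing).
#' @param seed RNG seed for the random feature maps.
#' @return A data frame with one row per suite: `suite`, `max_error`,
#'   `tolerance`, `pass` (for the contrast suite, `max_error` is the
#'   observed difference, required to *exceed* the threshold).
#' @export
equiv_check <- function(group = NULL, seed = 1L) {
  if (is.null(group)) group <- build_rotation_group(build_icosahedron())
  orbit <- lift_orbit(group)
  set.seed(seed)
  res <- list()
  add <- function(suite, err, tol, pass) {
    res[[length(res) + 1L]] <<- data.frame(
      suite = suite, max_error = err, tolerance = tol, pass = pass
    )
  }

  # group closure: every product matches its Cayley entry
  E <- group$elements
  worst <- 0
  for (i in 1:60) {
    for (j in 1:60) {
      worst <- max(worst, sqrt(sum((E[, , i] %*% E[, , j] - E[, , group$cayley[i, j]])^2)))
    }
  }
  add("group_closure", worst, 1e-9, worst <= 1e-9)
  fib_ok <- nrow(unique(group$fiber)) == 60 &&
    all(sort(unique(group$fiber[, "vertex"])) == 1:12) &&
    all(sort(unique(group$fiber[, "spin"])) == 1:5)
  add("fiber_structure", as.numeric(!fib_ok), 0, fib_ok)

  # lift equivariance over all 60 rotations
  M <- 4
  x <- array(stats::runif(M * nrow(orbit$points) * 2), c(M, nrow(orbit$points), 2))
  sk <- star_kernel(2, 3)
  F0 <- lift_s2(x, sk, group, orbit)
  err <- 0
  for (h in 1:60) {
    xr <- x[, orbit_perm(orbit, t(E[, , h])), , drop = FALSE]
    Fr <- lift_s2(xr, sk, group, orbit)
    perm <- left_translation_perm(group, h)
    err <- max(err, max(abs(Fr - F0[, perm, , drop = FALSE])) / max(abs(F0)))
  }
  add("lift_equivariance", err, 1e-6, err <= 1e-6)

  # gconv equivariance and projection invariance over all 60 translations
  fk <- fiber_kernel(2, 3)
  F1 <- array(stats::runif(M * 60 * 2), c(M, 60, 2))
  G0 <- gconv_so3(F1, fk, group)
  P0 <- project_max(F1, "space")
  eg <- ep <- 0
  for (h in 1:60) {
    perm <- left_translation_perm(group, h)
    Ft <- F1[, perm, , drop = FALSE]
    eg <- max(eg, max(abs(gconv_so3(Ft, fk, group) - G0[, perm, , drop = FALSE])) / max(abs(G0)))
    ep <- max(ep, max(abs(project_max(Ft, "space") - P0)) / max(abs(P0)))
  }
  add("gconv_equivariance", eg, 1e-6, eg <= 1e-6)
  add("projection_invariance", ep, 1e-6, ep <= 1e-6)

  # end-to-end 180-degree commutation (full SE(3) pipeline, 7^3 patch)
  pipe <- function(x, mode) {
    sk1 <- star_kernel(1, 3, weights = ws$k1, bias = ws$b1)
    spk <- spatial_kernel(3, 3, weights = ws$k2, bias = ws$b2)
    fk1 <- fiber_kernel(3, 2, weights = ws$k3, bias = ws$b3)
    f <- lift_s2(x, sk1, group, orbit)
    f <- f * (f > 0)
    f <- spatial_conv(f, spk, group, mode, batch = 1, extent = 7)
    f <- f * (f > 0)
    f <- gconv_so3(f, fk1, group)
    project_max(f, "space")
  }
  ws <- list(
    k1 = array(stats::rnorm(11 * 3), c(1, 3, 11)), b1 = stats::rnorm(3),
    k2 = array(stats::rnorm(9 * 27), c(3, 3, 3, 3, 3)), b2 = stats::rnorm(3),
    k3 = array(stats::rnorm(3 * 2 * 5), c(3, 2, 5)), b3 = stats::rnorm(2)
  )
  xin <- array(stats::runif(343 * 42), c(343, 42, 1))
  base_full <- pipe(xin, "full")
  base_none <- pipe(xin, "none")
  twofold <- coordinate_axis_twofold_rotations(group)
  e_full <- 0
  d_none <- Inf
  for (h in twofold) {
    Rh <- E[, , h]
    vin <- voxel_rotation_perm(7, Rh) # R = R^-1 for 180-degree rotations
    vout <- voxel_rotation_perm(5, Rh)
    xr <- xin[vin, orbit_perm(orbit, t(Rh)), , drop = FALSE]
    of <- pipe(xr, "full")
    e_full <- max(e_full, max(abs(of - base_full[vout, , drop = FALSE])) / max(abs(base_full)))
    on <- pipe(xr, "none")
    d_none <- min(d_none, max(abs(on - base_none[vout, , drop = FALSE])) / max(abs(base_none)))
  }
  add("se3_pipeline_180", e_full, 1e-5, e_full <= 1e-5)
  add("decoupled_contrast_180", d_none, 0.01, d_none > 0.01)

  do.call(rbind, res)
}
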