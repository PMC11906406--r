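#' @section Feature map convention:
#' Group feature maps are plain 3-d arrays `[M, G, C]` where
#' `M = batch * extent^3` indexes (voxel within patch, then patch), `G = 60`
#' indexes group elements in the (vertex, spin) order of the
#' `rotation_group`, and `C` indexes channels. Voxels are column-major
#' (x fastest). Classical (non-lifted) features use `G = 1`.
#' @name icoseg-features
#' @keywords internal
NULL

#' Star-shaped kernel layout on the sphere
#'
#' The lifting kernel is supported on 11 points around the reference
#' vertex: the vertex itself, the five arc-midpoints of its incident
#' edges, and its five one-ring neighbor vertices. The five stabilizer
#' rotations permute the layout onto itself, cyclically by arm, which is
#' what makes the lifted representation exactly equivariant.
#'
#' @param ico An `icosahedron`.
#' @return Matrix 11 x 3 of unit vectors: row 1 the reference vertex, rows
#'   2-6 the edge arc-midpoints, rows 7-11 the neighbor vertices (arm `a`
#'   uses rows `1 + a` and `6 + a`, matching the neighbor ring order).
#' @export
star_kernel_layout <- function(ico) {
  v0 <- ico$vertices[ico$reference_vertex, ]
  nb <- ico$vertices[ico$neighbors[ico$reference_vertex, ], , drop = FALSE]
  mids <- sweep(nb, 2, v0, `+`)
  mids <- mids / sqrt(rowSums(mids^2))
  rbind(v0, mids, nb, deparse.level = 0)
}

#' Orbit of the star-kernel layout under the rotation group
#'
#' All 60 rotations applied to the 11 layout points, deduplicated at 1e-9
#' point tolerance (42 distinct points: 12 vertices + 30 edge midpoints).
#' The lifting convolution reads its input on exactly this point set, so
#' rotating the underlying spherical function by any group element is an
#' exact permutation of the orbit values.
#'
#' @param group A `rotation_group` (must carry its `icosahedron`).
#' @return A list with `points` (P x 3 matrix), `index` (60 x 11 integer
#'   matrix, `index[g, j]` = orbit row of `R_g p_j`), and `layout`.
#' @export
lift_orbit <- function(group) {
  layout <- star_kernel_layout(group$ico)
  pts <- matrix(0, 0, 3)
  index <- matrix(0L, 60, 11)
  for (g in 1:60) {
    moved <- layout %*% t(group$elements[, , g])
    for (j in 1:11) {
      p <- moved[j, ]
      hit <- 0L
      if (nrow(pts) > 0) {
        d2 <- colSums((t(pts) - p)^2)
        i <- which.min(d2)
        if (d2[i] < 1e-18) hit <- i
      }
      if (hit == 0L) {
        pts <- rbind(pts, p)
        hit <- nrow(pts)
      }
      index[g, j] <- hit
    }
  }
  list(points = pts, index = index, layout = layout)
}

#' Permutation of orbit points induced by a group element
#'
#' Returns `perm` with `orbit$points[perm[i], ] == R %*% orbit$points[i, ]`.
#' Rotating a spherical function f by h (i.e. forming f(h^{-1} .)) sends
#' orbit-sampled values `x` to `x[orbit_perm(orbit, R_h^{-1})]`.
#'
#' @param orbit Result of [lift_orbit()].
#' @param R 3 x 3 rotation matrix.
#' @return Integer permutation of the orbit rows.
#' @export
orbit_perm <- function(orbit, R) {
  moved <- orbit$points %*% t(R)
  n <- nrow(orbit$points)
  perm <- integer(n)
  for (i in 1:n) {
    d2 <- colSums((t(orbit$points) - moved[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > 1e-18) stop("rotation does not preserve the orbit point set")
    perm[i] <- j
  }
  stopifnot(!anyDuplicated(perm))
  perm
}

he_uniform <- function(dim, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

#' Learnable kernels
#'
#' Constructors for the three kernel types. Weights are He-uniform
#' initialized from the current RNG state (seed before calling for
#' reproducibility); biases start at a small positive constant (0.05) so
#' no ReLU path is dead at initialization. Weight layouts:
#' star `[c_in, c_out, 11]`, fiber `[c_in, c_out, 5]` (indexed by
#' stabilizer spin), spatial `[c_in, c_out, 3, 3, 3]` (offset index 1..3
#' maps to spatial offset -1..1 per axis).
#'
#' @param c_in,c_out channel counts.
#' @param weights,bias optional explicit values (checked for shape).
#' @return A list with class `star_kernel` / `fiber_kernel` /
#'   `spatial_kernel`: fields `weights`, `bias`, `c_in`, `c_out`.
#' @name kernels
NULL

new_kernel <- function(cls, c_in, c_out, support_dim, weights, bias) {
  dim_w <- c(c_in, c_out, support_dim)
  if (is.null(weights)) {
    weights <- he_uniform(dim_w, fan_in = c_in * prod(support_dim))
  }
  weights <- array(weights, dim = dim_w)
  # small positive default bias keeps ReLU paths alive at initialization
  if (is.null(bias)) bias <- rep(0.05, c_out)
  stopifnot(length(bias) == c_out, all(is.finite(weights)), all(is.finite(bias)))
  structure(
    list(weights = weights, bias = as.numeric(bias), c_in = c_in, c_out = c_out),
    class = cls
  )
}

#' @rdname kernels
#' @export
star_kernel <- function(c_in, c_out, weights = NULL, bias = NULL) {
  new_kernel("star_kernel", c_in, c_out, 11L, weights, bias)
}

#' @rdname kernels
#' @export
fiber_kernel <- function(c_in, c_out, weights = NULL, bias = NULL) {
  new_kernel("fiber_kernel", c_in, c_out, 5L, weights, bias)
}

#' @rdname kernels
#' @export
spatial_kernel <- function(c_in, c_out, weights = NULL, bias = NULL) {
  new_kernel("spatial_kernel", c_in, c_out, c(3L, 3L, 3L), weights, bias)
}

as_mgc <- function(x) {
  # accept [M, Q] or [M, Q, C]; return [M, Q, C]
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3)
  x
}

#' S2 lifting convolution
#'
#' Lifts per-voxel spherical signals, sampled on the star-kernel orbit, to
#' a function on the 60-element rotation group:
#' `out[x, g, c_out] = bias + sum_{c_in, j} x[x, index[g, j], c_in] * W[c_in, c_out, j]`.
#' Because the orbit is closed under the group, rotating the input
#' spherical function by any group element permutes the orbit samples, and
#' the lift is exactly equivariant (output left-translates).
#'
#' @param x array `[M, Q]` or `[M, Q, c_in]` of signal values at the orbit
#'   points (`Q = nrow(orbit$points)`), e.g. from [resample()] with
#'   `orbit$points` as queries.
#' @param kernel A `star_kernel`.
#' @param group A `rotation_group`.
#' @param orbit Result of [lift_orbit()] (computed if missing).
#' @return Group feature map array `[M, 60, c_out]`.
#' @export
lift_s2 <- function(x, kernel, group, orbit = lift_orbit(group)) {
  x <- as_mgc(x)
  stopifnot(dim(x)[2] == nrow(orbit$points), dim(x)[3] == kernel$c_in)
  cpp_lift_fwd(x, orbit$index, kernel$weights, kernel$bias)
}

#' SO(3) group convolution on fibers
#'
#' Correlates a group feature map with a kernel supported on the five
#' stabilizer rotations (one fiber):
#' `out[x, g, c_out] = bias + sum_{c_in, k} F[x, g * sigma_k^{-1}, c_in] * W[c_in, c_out, k]`
#' — a cyclic correlation inside each left coset, looked up through the
#' Cayley table, hence exactly equivariant under all 60 left translations.
#'
#' @param F_in group feature map `[M, 60, c_in]`.
#' @param kernel A `fiber_kernel`.
#' @param group A `rotation_group`.
#' @return Group feature map `[M, 60, c_out]`.
#' @export
gconv_so3 <- function(F_in, kernel, group) {
  F_in <- as_mgc(F_in)
  stopifnot(dim(F_in)[2] == 60, dim(F_in)[3] == kernel$c_in)
  cpp_gconv_fwd(F_in, fiber_perms(group), kernel$weights, kernel$bias)
}

# 60 x 5 table of g * sigma_k^{-1} lookups through the Cayley table
fiber_perms <- function(group) {
  vapply(1:5, function(k) {
    group$cayley[, group$inverse[group$stabilizer[k]]]
  }, integer(60))
}

#' Trilinear resampling matrix for rotating a 3x3x3 kernel
#'
#' `A[y, z]` is the trilinear weight of source grid point z in evaluating
#' the rotated kernel `w'(y) = w(R^{-1} y)` at target grid point y, with
#' value 0 outside the 3^3 support. Grid points are the 27 integer offsets
#' in `{-1,0,1}^3`, column-major (x fastest).
#'
#' @param R 3 x 3 rotation matrix.
#' @return 27 x 27 matrix.
#' @keywords internal
trilinear_rotation_matrix <- function(R) {
  key <- paste(round(R, 9), collapse = ",")
  hit <- .trilinear_cache[[key]]
  if (!is.null(hit)) return(hit)
  A <- trilinear_rotation_matrix_impl(R)
  .trilinear_cache[[key]] <- A
  A
}

.trilinear_cache <- new.env(parent = emptyenv())

trilinear_rotation_matrix_impl <- function(R) {
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  A <- matrix(0, 27, 27)
  src <- offs %*% R # row y: R^T y = R^{-1} y
  for (y in 1:27) {
    p <- src[y, ]
    f <- floor(p)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      corner <- f + c(cx, cy, cz)
      wgt <- prod(1 - abs(p - corner))
      if (wgt <= 0) next
      if (any(corner < -1 | corner > 1)) next # zero outside the support
      z <- 1 + (corner[1] + 1) + 3 * (corner[2] + 1) + 9 * (corner[3] + 1)
      A[y, z] <- A[y, z] + wgt
    }
  }
  A
}

#' Rotate a spatial kernel
#'
#' Resamples the 3x3x3 kernel grid under a rotation by trilinear
#' interpolation (`w'(y) = w(R^{-1} y)`, zero outside the support). For
#' 180-degree coordinate-axis rotations the rotated grid points are grid
#' points, so the result is an exact index flip. The bias is unchanged.
#'
#' @param kernel A `spatial_kernel`.
#' @param R 3 x 3 rotation matrix.
#' @return The rotated `spatial_kernel`.
#' @export
rotate_spatial_kernel <- function(kernel, R) {
  A <- trilinear_rotation_matrix(R)
  w <- array(kernel$weights, dim = c(kernel$c_in * kernel$c_out, 27))
  w_rot <- w %*% t(A)
  spatial_kernel(
    kernel$c_in, kernel$c_out,
    weights = array(w_rot, dim = dim(kernel$weights)),
    bias = kernel$bias
  )
}

# flatten [c_in, c_out, 3,3,3] weights to the [27*c_in, c_out] im2col form
# (row index t + 27*(c_in - 1), t the column-major offset index)
spatial_weight_mat <- function(weights, c_in, c_out) {
  w <- array(weights, dim = c(c_in, c_out, 27))
  w <- aperm(w, c(3, 1, 2))
  dim(w) <- c(27 * c_in, c_out)
  w
}

# index machinery for valid 3^3 correlation on a cubic patch:
# rows[r', t] = input row feeding output row r' through offset t
spatial_conv_rows <- function(extent, batch) {
  s_out <- extent - 2L
  v_in <- extent^3
  v_out <- s_out^3
  og <- as.matrix(expand.grid(x = 1:s_out, y = 1:s_out, z = 1:s_out))
  offs <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))
  rows <- matrix(0L, v_out * batch, 27)
  for (t in 1:27) {
    ip <- sweep(og, 2, offs[t, ], `+`)
    vox <- ip[, 1] + extent * (ip[, 2] - 1) + extent^2 * (ip[, 3] - 1)
    rows[, t] <- as.integer(outer(vox, (seq_len(batch) - 1L) * v_in, `+`))
  }
  rows
}

# rotation index per group slot for the three orientation modes
spatial_mode_rotations <- function(group, mode) {
  switch(mode,
    none = rep(NA_integer_, 60),
    full = 1:60,
    partial = {
      # spin-1 coset representative of each element's fiber; with the
      # (vertex, spin) element ordering that is slot (vertex-1)*5 + 1
      (group$fiber[, "vertex"] - 1L) * 5L + 1L
    },
    stop("unknown orientation mode: ", mode)
  )
}

#' Rotation-tied spatial convolution
#'
#' Valid (no padding), stride-1 3x3x3 correlation applied independently to
#' every group slot of a group feature map. The `orientation_mode` decides
#' how the kernel is tied to the group coordinate:
#' \describe{
#'   \item{none}{the unrotated kernel for every slot (T3 x SO(3) action;
#'     spatial and spherical parts decoupled).}
#'   \item{full}{slot g uses the kernel rotated by R_g (SE(3) action), so
#'     spatial offsets co-rotate with the spherical responses.}
#'   \item{partial}{slot g uses the kernel rotated by the spin-1 coset
#'     representative of g's fiber (SE(3)*: one rotation per vertex).}
#' }
#' Output spatial extent shrinks by 2 per axis.
#'
#' @param F_in feature map `[M, G, c_in]`, `M = batch * extent^3`; `G` is
#'   60 for lifted features or 1 for classical volumes.
#' @param kernel A `spatial_kernel`.
#' @param group A `rotation_group` (ignored for mode `"none"` with G = 1).
#' @param orientation_mode one of `"none"`, `"partial"`, `"full"`.
#' @param batch number of patches stacked in `F_in`.
#' @param extent input spatial side length (>= 3).
#' @return Feature map `[batch * (extent-2)^3, G, c_out]`.
#' @export
spatial_conv <- function(F_in, kernel, group = NULL,
                         orientation_mode = c("none", "partial", "full"),
                         batch, extent) {
  orientation_mode <- match.arg(orientation_mode)
  F_in <- as_mgc(F_in)
  G <- dim(F_in)[2]
  stopifnot(extent >= 3, dim(F_in)[1] == batch * extent^3, dim(F_in)[3] == kernel$c_in)
  if (orientation_mode != "none") stopifnot(G == 60, !is.null(group))
  rows <- spatial_conv_rows(extent, batch)
  wm <- spatial_wm_stack(kernel, group, orientation_mode, G)
  cpp_spatial_fwd(F_in, rows, wm$Wm, wm$rotidx, kernel$bias)
}

# stack of im2col weight matrices (one per distinct kernel rotation) and
# the per-slot index into it
spatial_wm_stack <- function(kernel, group, orientation_mode, G) {
  c_in <- kernel$c_in
  c_out <- kernel$c_out
  if (orientation_mode == "none") {
    Wm <- array(spatial_weight_mat(kernel$weights, c_in, c_out),
                dim = c(27 * c_in, c_out, 1))
    list(Wm = Wm, rotidx = rep(1L, G), rotations = NA_integer_)
  } else {
    rot_for_slot <- spatial_mode_rotations(group, orientation_mode)
    urot <- unique(rot_for_slot)
    Wm <- array(0, dim = c(27 * c_in, c_out, length(urot)))
    for (i in seq_along(urot)) {
      kr <- rotate_spatial_kernel(kernel, group$elements[, , urot[i]])
      Wm[, , i] <- spatial_weight_mat(kr$weights, c_in, c_out)
    }
    list(Wm = Wm, rotidx = match(rot_for_slot, urot), rotations = urot)
  }
}

#' Max projection of a group feature map
#'
#' Collapses the group coordinate by a component-wise maximum with no
#' learned weights. `target = "space"` maximizes over all 60 group slots,
#' yielding per-voxel features invariant to left translation;
#' `target = "sphere"` maximizes over the 5 spins within each of the 12
#' fibers, yielding per-vertex features on the sphere (used by the
#' SO(3)-only network).
#'
#' @param F_in feature map `[M, 60, C]`.
#' @param target `"space"` or `"sphere"`.
#' @return `[M, C]` for `"space"`, `[M, 12, C]` for `"sphere"`.
#' @export
project_max <- function(F_in, target = c("space", "sphere")) {
  target <- match.arg(target)
  F_in <- as_mgc(F_in)
  M <- dim(F_in)[1]
  C <- dim(F_in)[3]
  if (target == "space") {
    out <- matrix(F_in[, 1, ], M, C)
    for (g in 2:60) out <- pmax(out, matrix(F_in[, g, ], M, C))
    out
  } else {
    out <- array(0, dim = c(M, 12, C))
    for (f in 1:12) {
      slots <- (f - 1L) * 5L + 1:5
      m <- matrix(F_in[, slots[1], ], M, C)
      for (s in slots[-1]) m <- pmax(m, matrix(F_in[, s, ], M, C))
      out[, f, ] <- m
    }
    out
  }
}
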