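#' Construct the regular icosahedron used to discretize the sphere
#'
#' Vertices are the twelve normalized cyclic coordinate permutations of
#' \eqn{(0, \pm 1, \pm\phi)} with \eqn{\phi} the golden ratio. This embedding
#' is chosen deliberately: it places three of the solid's two-fold symmetry
#' axes on the coordinate axes, so three 180-degree voxel-grid rotations are
#' exact members of the rotation group and end-to-end equivariance can be
#' tested without any interpolation.
#'
#' The reference ("north") vertex is the one with the lexicographically
#' largest coordinate triple; vertices are reordered so it comes first.
#' Neighbor rings are ordered counter-clockwise as seen from outside the
#' sphere (right-handed about the outward vertex direction).
#'
#' @return An object of class `icosahedron` with components
#'   \describe{
#'     \item{vertices}{12 x 3 matrix of unit vectors.}
#'     \item{neighbors}{12 x 5 integer matrix; row `i` lists the one-ring of
#'       vertex `i` in counter-clockwise order.}
#'     \item{reference_vertex}{index of the distinguished vertex (always 1).}
#'   }
#' @examples
#' ico <- build_icosahedron()
#' nrow(ico$vertices)
#' @export
build_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    c(0,  1,  phi), c(0,  1, -phi), c(0, -1,  phi), c(0, -1, -phi),
    c( 1,  phi, 0), c( 1, -phi, 0), c(-1,  phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c(-phi, 0,  1), c( phi, 0, -1), c(-phi, 0, -1)
  )
  v <- base / sqrt(rowSums(base^2))

  # reference vertex: lexicographically largest triple; reorder so it is
  # first and the rest follow in decreasing lexicographic order (gives a
  # stable, embedding-determined vertex indexing)
  key <- order(-v[, 1], -v[, 2], -v[, 3])
  v <- v[key, , drop = FALSE]

  # one-ring: the 5 vertices at angular distance arccos(1/sqrt(5))
  dots <- v %*% t(v)
  neighbors <- matrix(0L, 12, 5)
  for (i in 1:12) {
    nb <- which(abs(dots[i, ] - 1 / sqrt(5)) < 1e-9)
    stopifnot(length(nb) == 5L)
    # order counter-clockwise seen from outside: sort by angle in the
    # tangent plane at v_i, right-handed about the outward normal v_i
    n0 <- v[nb[1], ] - dots[i, nb[1]] * v[i, ]
    e1 <- n0 / sqrt(sum(n0^2))
    e2 <- c(
      v[i, 2] * e1[3] - v[i, 3] * e1[2],
      v[i, 3] * e1[1] - v[i, 1] * e1[3],
      v[i, 1] * e1[2] - v[i, 2] * e1[1]
    )
    ang <- atan2(v[nb, , drop = FALSE] %*% e2, v[nb, , drop = FALSE] %*% e1)
    neighbors[i, ] <- nb[order(ang)]
  }

  structure(
    list(vertices = v, neighbors = neighbors, reference_vertex = 1L),
    class = "icosahedron"
  )
}

#' Rotation matrix about an axis (Rodrigues form)
#' @param axis unit 3-vector.
#' @param theta angle in radians; positive = right-handed about `axis`.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
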