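#' Generate the 60-element icosahedral rotation group
#'
#' Closes two generators — a 2\eqn{\pi}/5 rotation about the reference vertex
#' and a 2\eqn{\pi}/3 rotation about an adjacent face center — under matrix
#' composition, deduplicating at 1e-6 Frobenius tolerance. The resulting
#' elements are indexed by their coset (fiber) structure: each element maps
#' the reference vertex v0 to one of the 12 vertices, and within the coset
#' of elements sharing that target vertex it differs from the coset
#' representative by one of the five stabilizer rotations ("spins").
#' Elements are ordered lexicographically by (vertex index, spin index), so
#' element 1 is the identity (vertex 1 = reference vertex, spin 1).
#'
#' @param ico An `icosahedron`, from [build_icosahedron()].
#' @return An object of class `rotation_group`:
#'   \describe{
#'     \item{elements}{3 x 3 x 60 array of rotation matrices.}
#'     \item{cayley}{60 x 60 integer table, `cayley[i, j]` = index of the
#'       matrix product of elements i and j.}
#'     \item{inverse}{integer vector, `inverse[i]` = index of the inverse.}
#'     \item{fiber}{60 x 2 integer matrix of (vertex, spin), both 1-based.}
#'     \item{vertex_perm}{60 x 12 integer matrix; row g is the permutation
#'       `i -> index of g.v_i` of the vertices.}
#'     \item{stabilizer}{indices of the five elements fixing v0, ordered so
#'       entry k+1 is the rotation by angle 2k*pi/5 (a cyclic subgroup).}
#'     \item{identity_index}{always 1.}
#'     \item{ico}{the generating icosahedron.}
#'   }
#' @export
build_rotation_group <- function(ico) {
  stopifnot(inherits(ico, "icosahedron"))
  v <- ico$vertices
  v0 <- v[ico$reference_vertex, ]
  n1 <- v[ico$neighbors[ico$reference_vertex, 1], ]
  n2 <- v[ico$neighbors[ico$reference_vertex, 2], ]
  face_center <- (v0 + n1 + n2)
  g5 <- rotation_about_axis(v0, 2 * pi / 5)
  g3 <- rotation_about_axis(face_center, 2 * pi / 3)

  # breadth-first closure with 1e-6 Frobenius deduplication
  elems <- list(diag(3), g5, g3)
  frontier <- elems
  while (length(frontier) > 0) {
    fresh <- list()
    for (f in frontier) {
      for (gen in list(g5, g3)) {
        cand <- gen %*% f
        known <- any(vapply(
          c(elems, fresh),
          function(e) sqrt(sum((e - cand)^2)) < 1e-6,
          logical(1)
        ))
        if (!known) fresh[[length(fresh) + 1L]] <- cand
      }
    }
    elems <- c(elems, fresh)
    frontier <- fresh
    if (length(elems) > 60) {
      stop("group closure exceeded 60 elements; icosahedron geometry is broken")
    }
  }
  if (length(elems) != 60) {
    stop(
      "group closure terminated at ", length(elems),
      " elements (expected 60); icosahedron geometry is broken"
    )
  }

  E <- array(unlist(elems), dim = c(3, 3, 60))

  # stabilizer rotations sigma_k = 2*k*pi/5 about v0, k = 0..4
  sigma <- lapply(0:4, function(k) rotation_about_axis(v0, 2 * k * pi / 5))

  match_element <- function(M) {
    d <- apply(E, 3, function(e) sqrt(sum((e - M)^2)))
    i <- which.min(d)
    if (d[i] > 1e-9) stop("no matching group element within 1e-9")
    i
  }

  # fiber decomposition: vertex hit by g.v0, then spin relative to the
  # coset representative (the coset element with lexicographically largest
  # rounded row-major entries -- this makes the identity its own coset's
  # representative)
  tv <- t(apply(E, 3, function(e) as.numeric(e %*% v0)))
  vert <- apply(tv, 1, function(p) {
    i <- which.min(colSums((t(v) - p)^2))
    if (sqrt(sum((v[i, ] - p)^2)) > 1e-9) stop("g.v0 is not a vertex")
    i
  })

  flat <- t(apply(E, 3, function(e) round(as.numeric(t(e)), 9)))
  rep_of_vertex <- integer(12)
  for (w in 1:12) {
    members <- which(vert == w)
    o <- do.call(order, c(lapply(1:9, function(j) -flat[members, j]), list()))
    rep_of_vertex[w] <- members[o[1]]
  }

  spin <- integer(60)
  for (g in 1:60) {
    r <- rep_of_vertex[vert[g]]
    h <- t(E[, , r]) %*% E[, , g] # rep^{-1} g, must be a stabilizer rotation
    k <- which(vapply(sigma, function(s) sqrt(sum((s - h)^2)) < 1e-9, logical(1)))
    if (length(k) != 1L) stop("coset decomposition failed")
    spin[g] <- k
  }

  ord <- order(vert, spin)
  E <- E[, , ord, drop = FALSE]
  fiber <- cbind(vertex = vert[ord], spin = spin[ord])

  # Cayley table via nearest-neighbour matching on flattened matrices;
  # |R|_F^2 = 3 for rotations, so nearest = largest inner product
  Eflat <- t(apply(E, 3, as.numeric)) # 60 x 9
  prod_idx <- matrix(0L, 60, 60)
  worst <- 0
  for (i in 1:60) {
    P <- t(apply(E, 3, function(e) as.numeric(E[, , i] %*% e))) # 60 x 9, row j = E_i E_j
    sim <- P %*% t(Eflat)
    k <- max.col(sim)
    err <- sqrt(pmax(0, 6 - 2 * sim[cbind(1:60, k)]))
    worst <- max(worst, max(err))
    prod_idx[i, ] <- k
  }
  if (worst > 1e-9) stop("Cayley closure residual ", worst, " exceeds 1e-9")

  identity_index <- which(fiber[, "vertex"] == ico$reference_vertex & fiber[, "spin"] == 1L)
  stopifnot(identity_index == 1L)
  inverse <- apply(prod_idx, 1, function(r) which(r == identity_index))

  vertex_perm <- matrix(0L, 60, 12)
  for (g in 1:60) {
    tvg <- v %*% t(E[, , g]) # row i = g.v_i
    for (i in 1:12) {
      j <- which.min(colSums((t(v) - tvg[i, ])^2))
      if (sqrt(sum((v[j, ] - tvg[i, ])^2)) > 1e-9) stop("vertex permutation failed")
      vertex_perm[g, i] <- j
    }
  }

  stabilizer <- vapply(sigma, match_element_in(E), integer(1))

  structure(
    list(
      elements = E, cayley = prod_idx, inverse = inverse, fiber = fiber,
      vertex_perm = vertex_perm, stabilizer = stabilizer,
      identity_index = 1L, ico = ico
    ),
    class = "rotation_group"
  )
}

# closure returning a matcher against a fixed element array
match_element_in <- function(E) {
  function(M) {
    d <- apply(E, 3, function(e) sqrt(sum((e - M)^2)))
    i <- which.min(d)
    if (d[i] > 1e-9) stop("no matching group element within 1e-9")
    as.integer(i)
  }
}

#' Find the index of the group element equal to a rotation matrix
#'
#' @param group A `rotation_group`.
#' @param R 3 x 3 rotation matrix.
#' @param tol match tolerance (Frobenius).
#' @return Element index, or `NA_integer_` if no element matches.
#' @export
group_element_index <- function(group, R, tol = 1e-9) {
  d <- apply(group$elements, 3, function(e) sqrt(sum((e - R)^2)))
  i <- which.min(d)
  if (d[i] > tol) return(NA_integer_)
  as.integer(i)
}

#' Left-translate a group-indexed value vector
#'
#' Implements the regular representation \eqn{(L_g f)(h) = f(g^{-1} h)} as a
#' pure index permutation through the Cayley table.
#'
#' @param group A `rotation_group`.
#' @param g_index index of the translating element.
#' @param values numeric vector of length 60, or a matrix/array whose
#'   *first* dimension has length 60 (one slot per group element).
#' @return Translated values, same shape.
#' @export
left_translate <- function(group, g_index, values) {
  perm <- group$cayley[group$inverse[g_index], ]
  if (is.null(dim(values))) {
    stopifnot(length(values) == 60L)
    values[perm]
  } else {
    stopifnot(dim(values)[1] == 60L)
    do.call(`[`, c(
      list(values, perm),
      rep(list(quote(expr = )), length(dim(values)) - 1L),
      list(drop = FALSE)
    ))
  }
}

#' Permutation of group slots implementing one left translation
#'
#' `perm` such that `translated[h] = values[perm[h]]`.
#' @param group A `rotation_group`.
#' @param g_index translating element index.
#' @return Integer vector of length 60.
#' @export
left_translation_perm <- function(group, g_index) {
  group$cayley[group$inverse[g_index], ]
}

#' Group elements that are 180-degree rotations about coordinate axes
#'
#' In the standard (0, +/-1, +/-phi) embedding the three two-fold symmetry
#' axes of the icosahedron lie on the coordinate axes, so the three diagonal
#' sign matrices with determinant +1 are exact group elements. These are the
#' rotations used for interpolation-free end-to-end equivariance checks:
#' they act on a voxel grid as exact index flips.
#'
#' @param group A `rotation_group`.
#' @return Integer vector of element indices (empty if the embedding was
#'   changed and no coordinate-axis two-fold rotation is a group element).
#' @export
coordinate_axis_twofold_rotations <- function(group) {
  targets <- list(diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  idx <- vapply(targets, function(R) {
    i <- group_element_index(group, R)
    if (is.na(i)) 0L else i
  }, integer(1))
  idx[idx > 0L]
}

#' Export group tables to JSON
#'
#' Serializes element matrices (row-major), Cayley table, inverses and
#' fibers so a generated group can be cached as a plain-text fixture.
#' Indices are written 1-based as stored.
#'
#' @param group A `rotation_group`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_group_json <- function(group, path) {
  obj <- list(
    elements = t(apply(group$elements, 3, function(e) as.numeric(t(e)))),
    cayley = group$cayley,
    inverse = group$inverse,
    fiber = group$fiber,
    vertex_perm = group$vertex_perm,
    stabilizer = group$stabilizer
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read group tables from JSON written by [write_group_json()]
#'
#' @param path file path.
#' @param ico optional `icosahedron` to attach.
#' @return A `rotation_group` (without `ico` unless supplied).
#' @export
read_group_json <- function(path, ico = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  E <- array(0, dim = c(3, 3, 60))
  for (g in 1:60) E[, , g] <- matrix(obj$elements[g, ], 3, 3, byrow = TRUE)
  structure(
    list(
      elements = E,
      cayley = matrix(as.integer(obj$cayley), 60, 60),
      inverse = as.integer(obj$inverse),
      fiber = cbind(vertex = as.integer(obj$fiber[, 1]), spin = as.integer(obj$fiber[, 2])),
      vertex_perm = matrix(as.integer(obj$vertex_perm), 60, 12),
      stabilizer = as.integer(obj$stabilizer),
      identity_index = 1L,
      ico = ico
    ),
    class = "rotation_group"
  )
}
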