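test_that("icosahedron geometry is the standard unit embedding", {
  ico <- test_ico
  expect_equal(nrow(ico$vertices), 12L)
  expect_true(all(abs(sqrt(rowSums(ico$vertices^2)) - 1) <= 1e-12))
  # antipodal closure
  for (i in 1:12) {
    d <- colSums((t(ico$vertices) + ico$vertices[i, ])^2)
    expect_true(min(d) < 1e-18)
  }
  # every vertex has exactly 5 neighbors at angular distance acos(1/sqrt(5))
  dots <- ico$vertices %*% t(ico$vertices)
  for (i in 1:12) {
    nb <- ico$neighbors[i, ]
    expect_length(nb, 5L)
    expect_true(all(abs(dots[i, nb] - 1 / sqrt(5)) < 1e-12))
  }
  # all 30 edge arc-lengths equal (exhaustive pairwise check)
  edge <- acos(pmin(1, pmax(-1, dots[upper.tri(dots)])))
  edges <- sort(edge)[1:30]
  expect_lt(max(edges) - min(edges), 1e-12)
  # reference vertex is the lexicographically largest triple
  v <- ico$vertices
  key <- order(-v[, 1], -v[, 2], -v[, 3])
  expect_identical(key[1], ico$reference_vertex)
})

test_that("rotation group closes at exactly 60 elements with exact tables", {
  g <- test_group
  expect_equal(dim(g$elements)[3], 60L)
  expect_equal(g$identity_index, 1L)
  expect_equal(g$elements[, , 1], diag(3), tolerance = 1e-12)
  # brute-force Cayley verification over all 3600 pairs
  worst <- 0
  for (i in 1:60) {
    for (j in 1:60) {
      P <- g$elements[, , i] %*% g$elements[, , j]
      worst <- max(worst, sqrt(sum((P - g$elements[, , g$cayley[i, j]])^2)))
    }
  }
  expect_lt(worst, 1e-9)
  # rows and columns of the Cayley table are permutations
  expect_true(all(apply(g$cayley, 1, function(r) identical(sort(r), 1:60))))
  expect_true(all(apply(g$cayley, 2, function(r) identical(sort(r), 1:60))))
  # inverses
  for (i in 1:60) expect_equal(g$cayley[i, g$inverse[i]], 1L)
  # associativity spot-check through the index tables
  set.seed(1)
  ok <- TRUE
  for (rep in 1:1000) {
    ijk <- sample.int(60, 3, replace = TRUE)
    ok <- ok && identical(
      g$cayley[g$cayley[ijk[1], ijk[2]], ijk[3]],
      g$cayley[ijk[1], g$cayley[ijk[2], ijk[3]]]
    )
  }
  expect_true(ok)
})

test_that("fiber decomposition is a bijection onto 12 vertices x 5 spins", {
  g <- test_group
  expect_equal(nrow(unique(g$fiber)), 60L)
  expect_identical(sort(unique(g$fiber[, "vertex"])), 1:12)
  expect_identical(sort(unique(g$fiber[, "spin"])), 1:5)
  expect_identical(g$fiber[1, ], c(vertex = test_ico$reference_vertex, spin = 1L))
  # element with fiber (v, s) maps v0 to vertex v; all coset members agree
  v0 <- test_ico$vertices[test_ico$reference_vertex, ]
  for (e in 1:60) {
    tv <- as.numeric(g$elements[, , e] %*% v0)
    expect_lt(sqrt(sum((tv - test_ico$vertices[g$fiber[e, "vertex"], ])^2)), 1e-9)
  }
})

test_that("stabilizer is the cyclic group of five 2k*pi/5 rotations about v0", {
  g <- test_group
  s <- g$stabilizer
  expect_length(s, 5L)
  expect_true(all(g$fiber[s, "vertex"] == test_ico$reference_vertex))
  # rotation k is rotation 1 applied k times, and the cycle closes
  for (k in 1:4) expect_identical(g$cayley[s[2], s[k]], s[k + 1])
  expect_identical(g$cayley[s[2], s[5]], s[1])
})

test_that("vertex permutations form a homomorphism into S12", {
  g <- test_group
  for (i in 1:60) expect_identical(sort(g$vertex_perm[i, ]), 1:12)
  # perm(i o j) = perm_i o perm_j (acting on the left), all 3600 pairs
  mismatches <- 0L
  for (i in 1:60) {
    for (j in 1:60) {
      if (!identical(
        g$vertex_perm[g$cayley[i, j], ],
        g$vertex_perm[i, g$vertex_perm[j, ]]
      )) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("left translation is the regular representation index permutation", {
  g <- test_group
  v <- stats::rnorm(60)
  expect_identical(left_translate(g, 1L, v), v)
  set.seed(2)
  for (gi in sample.int(60, 8)) {
    expect_equal(left_translate(g, g$inverse[gi], left_translate(g, gi, v)), v)
    # one-hot at h maps to one-hot at g*h
    for (h in sample.int(60, 3)) {
      oh <- numeric(60)
      oh[h] <- 1
      expect_equal(which(left_translate(g, gi, oh) == 1), g$cayley[gi, h])
    }
  }
  # matrix-valued translation permutes the first dimension
  m <- matrix(stats::rnorm(120), 60, 2)
  lt <- left_translate(g, 5L, m)
  expect_equal(lt[, 1], left_translate(g, 5L, m[, 1]))
})

test_that("the three coordinate-axis 180-degree rotations are group elements", {
  tf <- coordinate_axis_twofold_rotations(test_group)
  expect_length(tf, 3L)
  for (h in tf) {
    expect_identical(test_group$inverse[h], h) # involution
    p <- test_group$vertex_perm[h, ]
    expect_identical(p[p], 1:12) # vertex permutation is an involution
  }
})

test_that("group tables survive a JSON round trip", {
  path <- tempfile(fileext = ".json")
  write_group_json(test_group, path)
  g2 <- read_group_json(path, ico = test_ico)
  expect_equal(g2$elements, test_group$elements, tolerance = 1e-12)
  expect_identical(g2$cayley, test_group$cayley)
  expect_identical(g2$inverse, test_group$inverse)
  expect_identical(unname(g2$fiber), unname(test_group$fiber))
  unlink(path)
})
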