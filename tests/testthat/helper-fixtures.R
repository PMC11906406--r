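# Shared fixtures, built once per test session. The group tables are
# deterministic; the phantom is the package's default study condition at a
# fixed seed.

test_ico <- build_icosahedron()
test_group <- build_rotation_group(test_ico)
test_orbit <- lift_orbit(test_group)

.phantom_cache <- new.env()

test_phantom <- function(noise = "rician") {
  key <- paste0("ph_", noise)
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(
      phantom_config(seed = 11L, noise = noise)
    )
  }
  .phantom_cache[[key]]
}

# voxel permutation of a cubic patch under a grid-exact rotation, for
# equivariance oracles (R must map the centered grid to itself)
grid_perm <- function(s, R) {
  pos <- as.matrix(expand.grid(1:s, 1:s, 1:s))
  ctr <- (s + 1) / 2
  src <- sweep(sweep(pos, 2, ctr) %*% R, 2, ctr, `+`)
  idx <- round(src)
  stopifnot(max(abs(src - idx)) < 1e-9)
  as.integer(idx[, 1] + s * (idx[, 2] - 1) + s^2 * (idx[, 3] - 1))
}
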