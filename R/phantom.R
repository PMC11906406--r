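#' Approximately uniform gradient directions by electrostatic repulsion
#'
#' Seeded electrostatic repulsion (500 iterations) of n points on the
#' sphere, with each point also repelled by all antipodes so the set is
#' well spread for antipodally symmetric signals. Optionally prepends
#' unweighted (b0) entries with zero direction vectors.
#'
#' @param n number of diffusion-weighted directions (>= 6).
#' @param seed RNG seed.
#' @param bvalue shell b-value in s/mm^2 (default 1000).
#' @param n_b0 number of b0 volumes to prepend (default 5).
#' @param iterations repulsion iterations (default 500).
#' @return A `sampling_scheme`.
#' @export
generate_directions <- function(n, seed = 1L, bvalue = 1000, n_b0 = 5L,
                                iterations = 500L) {
  stopifnot(n >= 6)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 3), n, 3)
  x <- x / sqrt(rowSums(x^2))
  step <- 0.01
  for (it in seq_len(iterations)) {
    G <- x %*% t(x)
    w1 <- (pmax(2 - 2 * G, 1e-12))^(-1.5) # 1/|x_i - x_j|^3
    diag(w1) <- 0
    w2 <- (pmax(2 + 2 * G, 1e-12))^(-1.5) # antipode repulsion
    f <- (rowSums(w1) + rowSums(w2)) * x - w1 %*% x + w2 %*% x
    f <- f - rowSums(f * x) * x # tangential component only
    f <- f / max(1, sqrt(max(rowSums(f^2)))) # cap the largest step
    x <- x + step * f
    x <- x / sqrt(rowSums(x^2))
  }
  dirs <- rbind(matrix(0, n_b0, 3), x)
  bvals <- c(rep(0, n_b0), rep(bvalue, n))
  sampling_scheme(dirs, bvals)
}

#' Mono-exponential diffusion tensor signal
#'
#' `S(v) = S0 * exp(-b * v' D v)` — the standard tensor model, producing
#' antipodally symmetric spherical signals.
#'
#' @param D symmetric positive-definite 3 x 3 diffusivity tensor
#'   (mm^2/s).
#' @param b diffusion weighting (s/mm^2).
#' @param directions N x 3 unit vectors.
#' @param S0 unweighted signal scale.
#' @return Numeric vector of N signal values.
#' @export
tensor_signal <- function(D, b, directions, S0 = 1) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-12 || any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("D must be symmetric positive-definite")
  }
  q <- rowSums((directions %*% D) * directions)
  S0 * exp(-b * q)
}

#' Default tissue diffusion models
#'
#' Literature-typical diffusivity eigenvalues (mm^2/s) giving the
#' qualitative class contrast of brain tissue: CSF isotropic and fast,
#' WM strongly anisotropic and spatially coherent, GM near-isotropic and
#' slow, subcortical a 50/50 two-tensor mixture of the WM and GM models.
#'
#' @return Named list with per-class eigenvalue triples.
#' @export
tissue_models <- function() {
  list(
    CSF = c(3.0e-3, 3.0e-3, 3.0e-3),
    WM = c(1.7e-3, 0.3e-3, 0.3e-3),
    GM = c(0.9e-3, 0.7e-3, 0.7e-3),
    subcortical = NULL # mixture, handled in generate_phantom
  )
}

#' Configuration for the synthetic DWI phantom
#'
#' @param grid_size cubic grid side (>= 9 so 7^3 patches exist;
#'   default 32).
#' @param n_directions diffusion-weighted directions (default 90).
#' @param bvalue shell b-value (default 1000 s/mm^2).
#' @param n_b0 number of b0 volumes (default 5).
#' @param noise `"rician"` (default), `"gaussian"` or `"none"`.
#' @param sigma noise standard deviation relative to S0 (default 0.02).
#' @param seed RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_size = 32L, n_directions = 90L,
                           bvalue = 1000, n_b0 = 5L,
                           noise = c("rician", "gaussian", "none"),
                           sigma = 0.02, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(grid_size >= 9, n_directions >= 6)
  structure(
    list(
      grid_size = as.integer(grid_size), n_directions = as.integer(n_directions),
      bvalue = bvalue, n_b0 = as.integer(n_b0), noise = noise,
      sigma = sigma, seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

# local orthonormal frame with the given principal direction first
tensor_from_frame <- function(e1, ev) {
  e1 <- e1 / sqrt(sum(e1^2))
  up <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- up - sum(up * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(
    e1[2] * e2[3] - e1[3] * e2[2],
    e1[3] * e2[1] - e1[1] * e2[3],
    e1[1] * e2[2] - e1[2] * e2[1]
  )
  Rm <- cbind(e1, e2, e3)
  Rm %*% diag(ev) %*% t(Rm)
}

#' Generate a synthetic DWI phantom with four tissue classes
#'
#' Rasterizes a concentric geometry onto the grid — a CSF core plus two
#' CSF blobs, a subcortical ring, a WM interior whose principal fiber
#' direction rotates smoothly (circumferentially) with position, and a GM
#' shell — and simulates the per-voxel diffusion tensor signal at the
#' scheme's directions, with optional Gaussian or Rician noise. Every
#' step is seeded and reproducible.
#'
#' @param config A `phantom_config`.
#' @param scheme optional `sampling_scheme` to acquire at (defaults to
#'   seeded repulsion directions); used e.g. to generate the same anatomy
#'   under a rotated gradient table.
#' @return List with `raw` (X x Y x Z x N array including b0 volumes),
#'   `scheme`, `labels` (integer array, 0 outside, 1..4 = CSF,
#'   subcortical, WM, GM), `mask`, and `volume` (the b0-normalized
#'   `spherical_volume`).
#' @export
generate_phantom <- function(config = phantom_config(), scheme = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid_size
  if (is.null(scheme)) {
    scheme <- generate_directions(
      config$n_directions, seed = config$seed,
      bvalue = config$bvalue, n_b0 = config$n_b0
    )
  }
  ctr <- (g + 1) / 2
  coords <- as.matrix(expand.grid(x = 1:g, y = 1:g, z = 1:g))
  rel <- sweep(coords, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  scale <- g / 32 # radii defined for the default grid, scaled otherwise
  r_mask <- 14 * scale
  r_gm <- 11 * scale
  r_sub_out <- 8 * scale
  r_sub_in <- 5.5 * scale
  r_csf <- 3.5 * scale
  blob_r <- 2 * scale
  blob1 <- c(0, 6.75, 0) * scale
  blob2 <- -blob1

  lab <- integer(g^3)
  inmask <- r <= r_mask
  lab[inmask & r > r_gm] <- 4L
  lab[r <= r_gm] <- 3L
  lab[r > r_sub_in & r <= r_sub_out] <- 2L
  lab[r <= r_csf] <- 1L
  db1 <- sqrt(rowSums(sweep(rel, 2, blob1)^2))
  db2 <- sqrt(rowSums(sweep(rel, 2, blob2)^2))
  lab[db1 <= blob_r | db2 <= blob_r] <- 1L
  for (cl in 1:4) {
    if (!any(lab == cl)) stop("degenerate phantom geometry: class ", cl, " is empty")
  }

  tm <- tissue_models()
  dirs <- scheme$directions
  dwi <- setdiff(seq_len(nrow(dirs)), scheme$b0_indices)
  N <- nrow(dirs)
  vox <- which(lab > 0L)
  raw <- array(0, dim = c(g, g, g, N))
  flat <- matrix(0, g^3, N)
  S0 <- 1
  D_csf <- diag(tm$CSF)
  D_gm_iso <- NULL
  sig_cache_csf <- tensor_signal(D_csf, config$bvalue, dirs[dwi, , drop = FALSE], S0)
  for (v in vox) {
    cl <- lab[v]
    p <- rel[v, ]
    tang <- c(-p[2], p[1], 0)
    if (sum(tang^2) < 1e-12) tang <- c(1, 0, 0)
    sig <- switch(cl,
      sig_cache_csf, # 1 CSF (isotropic, position-independent)
      { # 2 subcortical: 50/50 two-tensor WM/GM mixture
        Dw <- tensor_from_frame(tang, tm$WM)
        Dg <- tensor_from_frame(tang, tm$GM)
        0.5 * tensor_signal(Dw, config$bvalue, dirs[dwi, , drop = FALSE], S0) +
          0.5 * tensor_signal(Dg, config$bvalue, dirs[dwi, , drop = FALSE], S0)
      },
      { # 3 WM: coherent circumferential fibers
        Dw <- tensor_from_frame(tang, tm$WM)
        tensor_signal(Dw, config$bvalue, dirs[dwi, , drop = FALSE], S0)
      },
      { # 4 GM: near-isotropic, slow
        Dg <- tensor_from_frame(tang, tm$GM)
        tensor_signal(Dg, config$bvalue, dirs[dwi, , drop = FALSE], S0)
      }
    )
    flat[v, dwi] <- sig
    flat[v, scheme$b0_indices] <- S0
  }
  if (config$noise != "none") {
    set.seed(config$seed + 1L)
    sel <- lab > 0L
    nsel <- sum(sel)
    e1 <- matrix(stats::rnorm(nsel * N, sd = config$sigma), nsel, N)
    if (config$noise == "gaussian") {
      flat[sel, ] <- flat[sel, ] + e1
    } else {
      e2 <- matrix(stats::rnorm(nsel * N, sd = config$sigma), nsel, N)
      flat[sel, ] <- sqrt((flat[sel, ] + e1)^2 + e2^2)
    }
  }
  raw <- array(flat, dim = c(g, g, g, N))
  labels <- array(lab, dim = c(g, g, g))
  mask <- array(lab > 0L, dim = c(g, g, g))
  volume <- normalize_b0(raw, scheme, mask)
  list(raw = raw, scheme = scheme, labels = labels, mask = mask, volume = volume)
}

#' Write a phantom to NIfTI and FSL gradient files
#'
#' Writes the 4-d image (float32), uint8 label and mask volumes, and
#' bval/bvec text files. A round-trip read reproduces the data to
#' float32 precision.
#'
#' @param phantom result of [generate_phantom()] (or any list with `raw`,
#'   `labels`, `mask`, `scheme`).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"phantom"`).
#' @return Named character vector of the five paths written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dwi = file.path(dir, paste0(prefix, "_dwi.nii.gz")),
    labels = file.path(dir, paste0(prefix, "_labels.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    bval = file.path(dir, paste0(prefix, ".bval")),
    bvec = file.path(dir, paste0(prefix, ".bvec"))
  )
  RNifti::writeNifti(RNifti::asNifti(phantom$raw, datatype = "float"), paths["dwi"])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom$labels), dim = dim(phantom$labels)), datatype = "uint8"), paths["labels"])
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(phantom$mask), dim = dim(phantom$mask)), datatype = "uint8"), paths["mask"])
  write_scheme(phantom$scheme, paths["bval"], paths["bvec"])
  paths
}

#' Read a phantom (or any DWI dataset in the same layout) back
#'
#' @param paths named vector as returned by [write_phantom()], or a
#'   directory containing files written with the default prefix.
#' @param prefix file name prefix when `paths` is a directory.
#' @return List with `raw`, `scheme`, `labels`, `mask`, `volume` (b0
#'   normalized).
#' @export
read_phantom <- function(paths, prefix = "phantom") {
  if (length(paths) == 1 && dir.exists(paths)) {
    dir <- paths
    paths <- c(
      dwi = file.path(dir, paste0(prefix, "_dwi.nii.gz")),
      labels = file.path(dir, paste0(prefix, "_labels.nii.gz")),
      mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
      bval = file.path(dir, paste0(prefix, ".bval")),
      bvec = file.path(dir, paste0(prefix, ".bvec"))
    )
  }
  raw <- array(as.numeric(RNifti::readNifti(paths["dwi"])), dim = dim(RNifti::readNifti(paths["dwi"])))
  labels <- array(as.integer(RNifti::readNifti(paths["labels"])), dim = dim(raw)[1:3])
  mask <- array(as.integer(RNifti::readNifti(paths["mask"])) > 0, dim = dim(raw)[1:3])
  scheme <- read_scheme(paths["bval"], paths["bvec"])
  list(
    raw = raw, scheme = scheme, labels = labels, mask = mask,
    volume = normalize_b0(raw, scheme, mask)
  )
}
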