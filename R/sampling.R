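#' Diffusion sampling scheme (gradient table)
#'
#' Bundles the N gradient directions (b-vectors) and b-values of a DWI
#' acquisition. Directions with b-value at or below `b0_max` are treated as
#' unweighted (b0) volumes; all other directions must be unit vectors.
#'
#' @param directions N x 3 matrix of gradient directions (rows may be zero
#'   for b0 volumes).
#' @param bvalues numeric vector of length N, in s/mm^2.
#' @param b0_max b-values at or below this threshold count as b0
#'   (default 50, the usual guard for scanner-reported near-zero shells).
#' @return An object of class `sampling_scheme` with fields `directions`,
#'   `bvalues`, `b0_indices`.
#' @export
sampling_scheme <- function(directions, bvalues, b0_max = 50) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, nrow(directions) == length(bvalues), nrow(directions) >= 1)
  b0 <- which(bvalues <= b0_max)
  dwi <- setdiff(seq_len(nrow(directions)), b0)
  if (length(dwi) > 0) {
    nrm <- sqrt(rowSums(directions[dwi, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("non-b0 directions must be unit vectors (max |norm - 1| = ",
           format(max(abs(nrm - 1))), ")")
    }
  }
  structure(
    list(directions = directions, bvalues = as.numeric(bvalues), b0_indices = b0),
    class = "sampling_scheme"
  )
}

#' Rotate a sampling scheme
#'
#' Applies one rotation to every gradient direction; b-values are
#' unchanged. Used when a voxel grid is rotated: the directional signals
#' in each voxel rotate with the grid.
#'
#' @param scheme A `sampling_scheme`.
#' @param R 3 x 3 rotation matrix (orthonormal, det +1).
#' @return The rotated `sampling_scheme`.
#' @export
rotate_scheme <- function(scheme, R) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  R <- as.matrix(R)
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("R is not a proper rotation matrix")
  }
  sampling_scheme(scheme$directions %*% t(R), scheme$bvalues)
}

#' Row-stochastic Watson interpolation weights
#'
#' Builds the Q x N matrix that interpolates values measured at N sample
#' directions to Q query directions with the antipodally symmetric Watson
#' kernel \eqn{w(q, v) \propto \exp(\kappa (q \cdot v)^2)}. Each row is
#' normalized to sum to one (Nadaraya-Watson smoothing), so interpolated
#' values are convex combinations of the measurements and the kappa = 0
#' limit is the uniform average.
#'
#' @param query_dirs Q x 3 unit vectors.
#' @param sample_dirs N x 3 unit vectors.
#' @param kappa concentration parameter (>= 0); the package default for
#'   network input interpolation is 10.
#' @return Q x N row-stochastic weight matrix.
#' @export
watson_weights <- function(query_dirs, sample_dirs, kappa) {
  query_dirs <- as.matrix(query_dirs)
  sample_dirs <- as.matrix(sample_dirs)
  stopifnot(kappa >= 0, ncol(query_dirs) == 3, ncol(sample_dirs) == 3)
  d2 <- (query_dirs %*% t(sample_dirs))^2
  w <- exp(kappa * (d2 - 1)) # shift by kappa for overflow safety; cancels in the ratio
  rs <- rowSums(w)
  if (any(rs <= 0)) stop("zero row sum in Watson weights")
  w / rs
}

#' A volume of per-voxel spherical signals
#'
#' @param values 4-d array X x Y x Z x N of non-negative signal values
#'   (typically b0-normalized attenuations).
#' @param scheme the `sampling_scheme` describing the N directions.
#' @param mask logical X x Y x Z array of voxels carrying signal.
#' @return An object of class `spherical_volume`.
#' @export
spherical_volume <- function(values, scheme, mask = NULL) {
  stopifnot(length(dim(values)) == 4, dim(values)[4] == nrow(scheme$directions))
  if (is.null(mask)) mask <- array(TRUE, dim(values)[1:3])
  stopifnot(all(dim(mask) == dim(values)[1:3]))
  if (!all(is.finite(values[rep(mask, dim(values)[4])]))) {
    stop("non-finite signal values inside the mask")
  }
  structure(
    list(values = values, scheme = scheme, mask = mask),
    class = "spherical_volume"
  )
}

#' Normalize diffusion-weighted volumes by the voxel-wise mean b0
#'
#' Divides each voxel's diffusion-weighted (b > 0) signals by that voxel's
#' average unweighted (b0) signal, yielding attenuations in [0, ~1].
#' Voxels whose mean b0 does not exceed `epsilon` are removed from the
#' mask (no meaningful attenuation can be formed there).
#'
#' @param raw 4-d array X x Y x Z x N of raw signals, N matching `scheme`.
#' @param scheme `sampling_scheme` with at least one b0 index.
#' @param mask optional logical array; defaults to all voxels.
#' @param epsilon positivity guard on the mean b0 (default 1e-6).
#' @return A `spherical_volume` holding only the diffusion-weighted
#'   directions, with the updated mask.
#' @export
normalize_b0 <- function(raw, scheme, mask = NULL, epsilon = 1e-6) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (length(scheme$b0_indices) == 0) stop("scheme has no b0 volumes")
  dims <- dim(raw)
  stopifnot(length(dims) == 4, dims[4] == nrow(scheme$directions))
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  b0 <- raw[, , , scheme$b0_indices, drop = FALSE]
  mb0 <- apply(b0, 1:3, mean)
  keep <- mask & (mb0 > epsilon)
  dwi_idx <- setdiff(seq_len(dims[4]), scheme$b0_indices)
  values <- raw[, , , dwi_idx, drop = FALSE]
  denom <- ifelse(mb0 > epsilon, mb0, 1)
  values <- values / as.vector(denom) # recycles over the 4th dimension
  values[!is.finite(values)] <- 0
  sub_scheme <- sampling_scheme(
    scheme$directions[dwi_idx, , drop = FALSE],
    scheme$bvalues[dwi_idx]
  )
  spherical_volume(values, sub_scheme, keep)
}

#' Resample per-voxel spherical signals at new directions
#'
#' Watson-kernel interpolation of every voxel's signal from the volume's
#' measured directions onto `query_dirs`. One interpolation matrix is
#' precomputed per (scheme, query set) pair and applied to all voxels.
#'
#' @param volume A `spherical_volume`.
#' @param query_dirs Q x 3 unit vectors.
#' @param kappa Watson concentration (default 10).
#' @return 4-d array X x Y x Z x Q of interpolated values.
#' @export
resample <- function(volume, query_dirs, kappa = 10) {
  stopifnot(inherits(volume, "spherical_volume"))
  W <- watson_weights(query_dirs, volume$scheme$directions, kappa)
  dims <- dim(volume$values)
  flat <- matrix(volume$values, prod(dims[1:3]), dims[4])
  out <- flat %*% t(W)
  array(out, dim = c(dims[1:3], nrow(W)))
}

#' Read FSL-convention bval/bvec files into a sampling scheme
#'
#' @param bval_path path to the bval file (one whitespace-separated row).
#' @param bvec_path path to the bvec file (three rows: x, y, z).
#' @param b0_max passed to [sampling_scheme()].
#' @return A `sampling_scheme`.
#' @export
read_scheme <- function(bval_path, bvec_path, b0_max = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- utils::read.table(bvec_path)
  stopifnot(nrow(rows) == 3)
  dirs <- unname(t(as.matrix(rows)))
  sampling_scheme(dirs, bvals, b0_max = b0_max)
}

#' Write a sampling scheme as FSL-convention bval/bvec files
#'
#' @param scheme A `sampling_scheme`.
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  cat(paste(format(scheme$bvalues, trim = TRUE, scientific = FALSE), collapse = " "),
      "\n", sep = "", file = bval_path)
  dirs <- t(scheme$directions)
  lines <- apply(dirs, 1, function(r) paste(formatC(r, digits = 15, format = "g"), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}
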