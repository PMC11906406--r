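#' Tissue class labels
#'
#' Class codes used throughout: 1 = CSF, 2 = subcortical, 3 = WM, 4 = GM.
#' @return Character vector of the four class names.
#' @export
tissue_classes <- function() c("CSF", "subcortical", "WM", "GM")

#' Extract labeled patches from a spherical volume
#'
#' Collects cubic windows of `patch_size^3` voxels whose center voxel is
#' inside the mask and carries a label; the patch label is the
#' center-voxel label. Centers whose window would overrun the volume are
#' skipped. With `n_per_class` set, a seeded subsample of that many
#' centers per class is drawn (fewer if a class has fewer valid centers).
#'
#' @param volume A `spherical_volume`.
#' @param labels integer array (same grid) with classes 1..4, 0/NA = none.
#' @param patch_size odd window side (7 for spatial networks, 1 for the
#'   single-voxel SO(3) baseline).
#' @param n_per_class optional per-class subsample size (balanced
#'   sampling).
#' @param n_total optional total subsample size drawn uniformly over valid
#'   centers, preserving the volume's natural class frequencies (the
#'   regime the focal-loss class weights are designed for).
#' @param seed RNG seed for the subsample.
#' @param scan scan identifier stored with the patches.
#' @param exclude optional matrix of center coordinates to exclude (e.g.
#'   the centers of an already-extracted training set).
#' @return An object of class `patch_dataset`: `values` `[B, V, N]`,
#'   `labels` (1..4), `centers` (B x 3), `patch_size`, `scheme`, `scan`,
#'   `rotations` (octahedral rotation index per patch; 0 = none).
#' @export
extract_patches <- function(volume, labels, patch_size, n_per_class = NULL,
                            n_total = NULL, seed = 1L, scan = 1L,
                            exclude = NULL) {
  stopifnot(inherits(volume, "spherical_volume"), patch_size %% 2 == 1)
  dims <- dim(volume$mask)
  h <- (patch_size - 1L) / 2L
  lab <- labels
  lab[!volume$mask] <- 0L
  lab[is.na(lab)] <- 0L
  cand <- which(lab > 0L, arr.ind = TRUE)
  fits <- cand[, 1] > h & cand[, 1] <= dims[1] - h &
    cand[, 2] > h & cand[, 2] <= dims[2] - h &
    cand[, 3] > h & cand[, 3] <= dims[3] - h
  cand <- cand[fits, , drop = FALSE]
  if (!is.null(exclude) && nrow(cand) > 0) {
    ckey <- apply(cand, 1, paste, collapse = ",")
    ekey <- apply(exclude, 1, paste, collapse = ",")
    cand <- cand[!(ckey %in% ekey), , drop = FALSE]
  }
  if (nrow(cand) == 0) stop("no valid patch centers inside the mask")
  y <- lab[cand]
  if (!is.null(n_total)) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(cand), min(n_total, nrow(cand))))
    cand <- cand[keep, , drop = FALSE]
    y <- y[keep]
  } else if (!is.null(n_per_class)) {
    set.seed(seed)
    keep <- unlist(lapply(sort(unique(y)), function(cl) {
      i <- which(y == cl)
      i[sample.int(length(i), min(n_per_class, length(i)))]
    }))
    keep <- sort(keep)
    cand <- cand[keep, , drop = FALSE]
    y <- y[keep]
  }
  B <- nrow(cand)
  V <- patch_size^3
  N <- dim(volume$values)[4]
  vals <- array(0, dim = c(B, V, N))
  for (b in seq_len(B)) {
    cx <- cand[b, ]
    blk <- volume$values[
      (cx[1] - h):(cx[1] + h), (cx[2] - h):(cx[2] + h),
      (cx[3] - h):(cx[3] + h), , drop = FALSE
    ]
    vals[b, , ] <- matrix(blk, V, N)
  }
  structure(
    list(
      values = vals, labels = as.integer(y), centers = unname(cand),
      patch_size = as.integer(patch_size), scheme = volume$scheme,
      scan = rep(as.integer(scan), B), rotations = integer(B)
    ),
    class = "patch_dataset"
  )
}

#' The 24 proper rotations of the cube
#'
#' All signed permutation matrices with determinant +1: the octahedral
#' rotation group, which maps the voxel grid to itself exactly and is
#' therefore used for interpolation-free rotation augmentation.
#'
#' @return 3 x 3 x 24 array of rotation matrices (entries in -1, 0, 1);
#'   element 1 is the identity.
#' @export
octahedral_group <- function() {
  perms <- rbind(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
  out <- array(0, dim = c(3, 3, 24))
  k <- 0L
  for (p in seq_len(6)) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- matrix(0, 3, 3)
      R[1, perms[p, 1]] <- s1
      R[2, perms[p, 2]] <- s2
      R[3, perms[p, 3]] <- s3
      if (abs(det(R) - 1) < 1e-12) {
        k <- k + 1L
        out[, , k] <- R
      }
    }
  }
  stopifnot(k == 24L)
  # put the identity first for convenience
  id <- which(apply(out, 3, function(R) all(R == diag(3))))
  if (id != 1L) out[, , c(1L, id)] <- out[, , c(id, 1L)]
  out
}

# voxel permutation for a grid-exact rotation: rotated[x] = original[R^-1 x]
# (centered coordinates); perm[i] gives the source voxel of target voxel i
voxel_rotation_perm <- function(patch_size, R) {
  s <- patch_size
  pos <- as.matrix(expand.grid(x = 1:s, y = 1:s, z = 1:s))
  ctr <- (s + 1) / 2
  src <- sweep(sweep(pos, 2, ctr) %*% R, 2, ctr, `+`) # rows: R^-1 (x - c) + c
  idx <- round(src)
  if (max(abs(src - idx)) > 1e-9) stop("rotation is not grid-exact")
  as.integer(idx[, 1] + s * (idx[, 2] - 1) + s^2 * (idx[, 3] - 1))
}

#' Rotate one patch by an octahedral rotation
#'
#' The voxel grid is permuted exactly (octahedral rotations map the cubic
#' grid to itself); the per-voxel directional signals are re-expressed on
#' the unrotated direction set by Watson interpolation from the rotated
#' gradient scheme, mirroring how a physically rotated acquisition would
#' be resampled.
#'
#' @param values patch array `[V, N]` (voxels x directions).
#' @param scheme `sampling_scheme` of the N directions.
#' @param R 3 x 3 matrix from [octahedral_group()].
#' @param patch_size cubic side, `V = patch_size^3`.
#' @param kappa Watson concentration (default 10).
#' @return Rotated patch `[V, N]` on the original directions.
#' @export
octahedral_augment <- function(values, scheme, R, patch_size, kappa = 10) {
  if (max(abs(abs(R) %*% rep(1, 3) - 1)) > 1e-12 || abs(det(R) - 1) > 1e-9) {
    stop("R is not an octahedral (signed-permutation, det +1) rotation")
  }
  perm <- voxel_rotation_perm(patch_size, R)
  rot <- rotate_scheme(scheme, R)
  W <- watson_weights(scheme$directions, rot$directions, kappa)
  values[perm, , drop = FALSE] %*% t(W)
}

#' Annotate a dataset with one random octahedral rotation per patch
#'
#' Draws an independent uniform element of the octahedral group for every
#' patch (seeded, reproducible) and records it in the dataset's
#' `rotations` field; labels are unchanged. Input preparation applies the
#' grid permutation exactly and interpolates the directional signals at
#' the discretization-appropriate query set from the rotated scheme.
#'
#' @param dataset A `patch_dataset`.
#' @param seed RNG seed.
#' @return The dataset with `rotations` filled (indices into
#'   [octahedral_group()]).
#' @export
build_rotated_testset <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "patch_dataset"))
  set.seed(seed)
  dataset$rotations <- sample.int(24L, length(dataset$labels), replace = TRUE)
  dataset
}

# prepare network inputs for a subset of patches, honoring per-patch
# octahedral rotations; interpolation matrices are cached per rotation
prepare_patch_inputs <- function(network, dataset, idx = NULL, kappa = 10,
                                 center = 0.5, scale = 0.3) {
  if (is.null(idx)) idx <- seq_along(dataset$labels)
  B <- length(idx)
  V <- dataset$patch_size^3
  N <- dim(dataset$values)[3]
  oct <- octahedral_group()
  classical <- network$spec$variant %in% c("classical", "rotavg_classical")
  qpts <- if (classical) dataset$scheme$directions else network$orbit$points
  Q <- nrow(qpts)
  x <- matrix(0, V * B, Q)
  rots <- dataset$rotations[idx]
  for (r in unique(rots)) {
    sel <- which(rots == r)
    if (r == 0L || r == 1L) {
      Wr <- if (classical) NULL else
        watson_weights(qpts, dataset$scheme$directions, kappa)
      vperm <- seq_len(V)
    } else {
      Rm <- oct[, , r]
      Wr <- watson_weights(qpts, dataset$scheme$directions %*% t(Rm), kappa)
      vperm <- voxel_rotation_perm(dataset$patch_size, Rm)
    }
    for (b in sel) {
      pv <- dataset$values[idx[b], vperm, , drop = FALSE]
      dim(pv) <- c(V, N)
      rows <- (b - 1L) * V + seq_len(V)
      x[rows, ] <- if (is.null(Wr)) pv else pv %*% t(Wr)
    }
  }
  # rows are already voxel-within-patch fastest: row = v + (b-1)*V
  if (!is.null(center)) x <- (x - center) / scale
  if (classical) {
    array(x, dim = c(V * B, 1L, Q))
  } else {
    array(x, dim = c(V * B, Q, 1L))
  }
}

#' Multiclass focal loss
#'
#' \eqn{-\alpha_y (1 - p_y)^\gamma \log p_y}, averaged over the batch,
#' with \eqn{p_y} clamped at 1e-8 before the logarithm. With gamma = 0 it
#' reduces to alpha-weighted cross-entropy. Defaults follow the training
#' setup for the four-class tissue task: gamma = 2 and
#' alpha = (0.35, 0.35, 0.15, 0.15) for CSF, subcortical, WM, GM.
#'
#' @param probs `B x K` matrix of class probabilities (rows sum to 1), or
#'   a single probability vector.
#' @param labels integer class labels in 1..K, length B.
#' @param gamma focusing exponent.
#' @param alpha per-class weights, length K.
#' @return Scalar mean loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2,
                       alpha = c(0.35, 0.35, 0.15, 0.15)) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  stopifnot(nrow(probs) == length(labels), ncol(probs) == length(alpha))
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probs must be non-negative and sum to 1 per row")
  }
  py <- pmax(probs[cbind(seq_along(labels), labels)], 1e-8)
  mean(-alpha[labels] * (1 - py)^gamma * log(py))
}

# softmax focal loss and its gradient w.r.t. the logits (mean over batch)
focal_loss_logits <- function(logits, labels, gamma = 2,
                              alpha = c(0.35, 0.35, 0.15, 0.15)) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  B <- nrow(p)
  iy <- cbind(seq_len(B), labels)
  u <- pmax(p[iy], 1e-8)
  loss <- mean(-alpha[labels] * (1 - u)^gamma * log(u))
  # dL/du for one sample
  dLdu <- -alpha[labels] * ((1 - u)^gamma / u - gamma * (1 - u)^(gamma - 1) * log(u))
  # du/dz_k = u (1[k==y] - p_k)
  g <- -p * (dLdu * u)
  g[iy] <- g[iy] + dLdu * u
  list(loss = loss, grad = g / B, probs = p)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
    v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
    t = 0L
  )
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

#' Train a network with seeded mini-batch Adam on focal loss
#'
#' Deterministic given the seed (single-threaded BLAS assumed). The
#' optimizer is Adam at the stated learning rate; batches are sampled
#' without replacement each epoch. With `augment = TRUE` every patch is
#' rotated by a fresh random octahedral element each epoch (on-the-fly
#' augmentation); otherwise the dataset's recorded rotations are used.
#'
#' @param network An `icoseg_network`.
#' @param dataset A `patch_dataset` whose `patch_size` matches the
#'   network.
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size (default 100).
#' @param lr learning rate (default 0.001).
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param augment apply on-the-fly octahedral rotation augmentation.
#' @param gamma,alpha focal loss parameters.
#' @param kappa Watson concentration for input interpolation.
#' @param verbose print per-epoch loss to stderr.
#' @return List with `network` (trained) and `history` (per-epoch mean
#'   loss).
#' @export
train_network <- function(network, dataset, epochs, batch_size = 100,
                          lr = 0.001, seed = 1L, augment = FALSE,
                          gamma = 2, alpha = c(0.35, 0.35, 0.15, 0.15),
                          kappa = 10, verbose = FALSE) {
  stopifnot(inherits(network, "icoseg_network"), inherits(dataset, "patch_dataset"))
  stopifnot(dataset$patch_size == network$spec$patch_size)
  set.seed(seed)
  params <- network_params(network)
  opt <- adam_init(params)
  B_all <- length(dataset$labels)
  history <- numeric(epochs)
  # static inputs can be prepared once
  static_x <- if (!augment) prepare_patch_inputs(network, dataset, kappa = kappa) else NULL
  V <- as.integer(dataset$patch_size^3)
  for (ep in seq_len(epochs)) {
    if (augment) {
      ds_ep <- dataset
      ds_ep$rotations <- sample.int(24L, B_all, replace = TRUE)
      x_ep <- prepare_patch_inputs(network, ds_ep, kappa = kappa)
    } else {
      x_ep <- static_x
    }
    ord <- sample.int(B_all)
    losses <- c()
    for (start in seq(1L, B_all, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, B_all)]
      nb <- length(idx)
      rows <- as.vector(vapply(idx, function(b) (b - 1L) * V + seq_len(V), integer(V)))
      xb <- x_ep[rows, , , drop = FALSE]
      st <- network_forward(network, xb, nb, keep_cache = TRUE)
      fl <- focal_loss_logits(st$logits, dataset$labels[idx], gamma, alpha)
      if (!is.finite(fl$loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep)
      }
      grads <- network_backward(network, st, fl$grad, nb)
      upd <- adam_step(opt, params, grads[names(params)], lr)
      opt <- upd$state
      params <- upd$params
      network <- set_network_params(network, params)
      losses <- c(losses, fl$loss)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
  }
  list(network = network, history = history)
}

#' Predict class labels for a patch dataset
#'
#' @param network trained `icoseg_network`.
#' @param dataset A `patch_dataset` (its `rotations` field is honored).
#' @param batch_size forward-pass batch size.
#' @param kappa Watson concentration.
#' @return Integer vector of predicted labels (1..4).
#' @export
predict_patches <- function(network, dataset, batch_size = 200, kappa = 10) {
  B_all <- length(dataset$labels)
  V <- dataset$patch_size^3
  out <- integer(B_all)
  for (start in seq(1L, B_all, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B_all)
    x <- prepare_patch_inputs(network, dataset, idx, kappa = kappa)
    lg <- network_forward(network, x, length(idx))$logits
    out[idx] <- max.col(lg, ties.method = "first")
  }
  out
}

#' Segmentation metrics with per-scan aggregation
#'
#' Per class: recall-style accuracy (#correct / #class samples) and Dice
#' (2TP / (2TP + FP + FN)); plus overall accuracy
#' (#correct / #samples). Metrics are computed per scan and summarized as
#' mean and standard deviation across scans. A class absent from a scan
#' yields NA for that scan and is excluded from (and flagged in) the
#' summary.
#'
#' @param predictions integer labels 1..K.
#' @param labels integer reference labels 1..K.
#' @param scans scan identifier per sample (default: one scan).
#' @param num_classes K (default 4).
#' @return An object of class `eval_report`: `per_scan` data frame
#'   (scan, class, n_ref, accuracy, dice), `overall` data frame
#'   (scan, accuracy), `summary` data frame with mean/sd columns, and
#'   `overall_mean`, `overall_sd`.
#' @export
evaluate_predictions <- function(predictions, labels, scans = NULL,
                                 num_classes = 4L) {
  stopifnot(length(predictions) == length(labels))
  if (is.null(scans)) scans <- rep(1L, length(labels))
  scan_ids <- sort(unique(scans))
  per <- list()
  overall <- data.frame(scan = scan_ids, accuracy = NA_real_)
  for (si in seq_along(scan_ids)) {
    s <- scan_ids[si]
    i <- scans == s
    p <- predictions[i]
    y <- labels[i]
    overall$accuracy[si] <- mean(p == y)
    for (cl in seq_len(num_classes)) {
      tp <- sum(p == cl & y == cl)
      fp <- sum(p == cl & y != cl)
      fn <- sum(p != cl & y == cl)
      nref <- sum(y == cl)
      per[[length(per) + 1L]] <- data.frame(
        scan = s, class = tissue_classes()[cl], n_ref = nref,
        accuracy = if (nref > 0) tp / nref else NA_real_,
        dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
      )
    }
  }
  per <- do.call(rbind, per)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  summ <- do.call(rbind, lapply(seq_len(num_classes), function(cl) {
    rows <- per[per$class == tissue_classes()[cl] & !is.na(per$accuracy), ]
    data.frame(
      class = tissue_classes()[cl],
      accuracy_mean = mean(rows$accuracy), accuracy_sd = sd0(rows$accuracy),
      dice_mean = mean(rows$dice, na.rm = TRUE), dice_sd = sd0(rows$dice[!is.na(rows$dice)]),
      n_scans = nrow(rows)
    )
  }))
  structure(
    list(
      per_scan = per, overall = overall, summary = summ,
      overall_mean = mean(overall$accuracy), overall_sd = sd0(overall$accuracy)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Segmentation evaluation across", nrow(x$overall), "scan(s)\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("overall accuracy: %.4f +/- %.4f\n", x$overall_mean, x$overall_sd))
  invisible(x)
}

#' Performance-drop map
#'
#' Maps the ratio `x = c_reference / c_perturbed` of a performance metric
#' before and after a perturbation to a drop score with decay rate
#' `alpha` (default 20). Two readings of the mapping are provided:
#' `exp_decay` gives `exp(-alpha * x)` (smaller when the drop is larger);
#' `logistic` gives `1 / (1 + exp(-alpha * (x - 1)))` (0.5 at no drop).
#'
#' @param c_reference,c_perturbed metric values in (0, 1].
#' @param alpha decay rate.
#' @param formula `"exp_decay"` or `"logistic"`.
#' @return Scalar drop score with attribute `"formula"`.
#' @export
performance_drop_map <- function(c_reference, c_perturbed, alpha = 20,
                                 formula = c("exp_decay", "logistic")) {
  formula <- match.arg(formula)
  stopifnot(c_reference > 0, c_reference <= 1, c_perturbed <= 1)
  if (c_perturbed <= 0) stop("zero or negative perturbed metric")
  x <- c_reference / c_perturbed
  val <- switch(formula,
    exp_decay = exp(-alpha * x),
    logistic = 1 / (1 + exp(-alpha * (x - 1)))
  )
  structure(val, formula = formula)
}
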