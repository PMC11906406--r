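tiny_volume <- function(g = 9L, n = 12L, seed = 40) {
  sc <- generate_directions(n, seed = seed, n_b0 = 1)
  set.seed(seed)
  raw <- array(stats::runif(g^3 * (n + 1), 0.5, 1), c(g, g, g, n + 1))
  vol <- normalize_b0(raw, sc)
  labels <- array(sample.int(4L, g^3, replace = TRUE), c(g, g, g))
  list(volume = vol, labels = labels)
}

test_that("patch extraction collects interior centers with matching labels", {
  tv <- tiny_volume()
  ds <- extract_patches(tv$volume, tv$labels, 7)
  expect_equal(length(ds$labels), 27L) # 3^3 interior centers of a 9^3 grid
  expect_equal(dim(ds$values), c(27L, 343L, 12L))
  # stored label equals the label at the stored center coordinate
  for (b in seq_along(ds$labels)) {
    expect_identical(ds$labels[b], tv$labels[ds$centers[b, 1], ds$centers[b, 2], ds$centers[b, 3]])
  }
  # single-voxel patches
  ds1 <- extract_patches(tv$volume, tv$labels, 1)
  expect_equal(dim(ds1$values)[2], 1L)
  expect_equal(length(ds1$labels), sum(tv$volume$mask & tv$labels > 0))
  # per-class subsample is deterministic
  dsa <- extract_patches(tv$volume, tv$labels, 7, n_per_class = 3, seed = 5)
  dsb <- extract_patches(tv$volume, tv$labels, 7, n_per_class = 3, seed = 5)
  expect_identical(dsa$centers, dsb$centers)
})

test_that("the octahedral group has 24 integer rotations closed under product", {
  oct <- octahedral_group()
  expect_equal(dim(oct), c(3L, 3L, 24L))
  expect_true(all(oct %in% c(-1, 0, 1)))
  expect_equal(oct[, , 1], diag(3))
  flat <- apply(oct, 3, paste, collapse = ",")
  expect_equal(length(unique(flat)), 24L)
  for (i in c(1, 5, 12, 24)) {
    expect_equal(det(oct[, , i]), 1)
    for (j in c(2, 9, 17)) {
      expect_true(paste(oct[, , i] %*% oct[, , j], collapse = ",") %in% flat)
    }
  }
})

test_that("octahedral augmentation permutes the grid and re-expresses signals", {
  tv <- tiny_volume()
  ds <- extract_patches(tv$volume, tv$labels, 7, n_per_class = 2, seed = 1)
  pv <- matrix(ds$values[1, , ], 343, 12)
  oct <- octahedral_group()
  # identity rotation: only the idempotent Watson resampling acts, which
  # is near-identity at large kappa
  out_id <- octahedral_augment(pv, ds$scheme, diag(3), 7, kappa = 500)
  expect_lt(max(abs(out_id - pv)), 0.05 * max(pv))
  # a 180-degree rotation applied twice restores the grid permutation
  R <- diag(c(-1, -1, 1))
  p1 <- icoseg:::voxel_rotation_perm(7, R)
  expect_identical(p1[p1], seq_len(343L))
  # isotropic (direction-constant) signals are invariant under any rotation
  iso <- matrix(rep(stats::runif(343), 12), 343, 12)
  for (r in c(3, 10, 20)) {
    out <- octahedral_augment(iso, ds$scheme, oct[, , r], 7)
    vp <- icoseg:::voxel_rotation_perm(7, oct[, , r])
    expect_equal(out, iso[vp, ], tolerance = 1e-9)
  }
  # signal range is preserved (convex interpolation) and labels untouched
  out <- octahedral_augment(pv, ds$scheme, oct[, , 7], 7)
  expect_true(min(out) >= min(pv) - 1e-9 && max(out) <= max(pv) + 1e-9)
  expect_error(octahedral_augment(pv, ds$scheme, diag(c(1, 1, 2)), 7), "octahedral")
})

test_that("rotated test sets are seeded, label-preserving and uniform over 24 elements", {
  tv <- tiny_volume()
  ds <- extract_patches(tv$volume, tv$labels, 7)
  r1 <- build_rotated_testset(ds, seed = 9)
  r2 <- build_rotated_testset(ds, seed = 9)
  expect_identical(r1$rotations, r2$rotations)
  expect_identical(r1$labels, ds$labels)
  # chi-square uniformity over many draws
  big <- ds
  big$labels <- rep(1L, 10000L)
  big$rotations <- integer(10000L)
  big <- build_rotated_testset(big, seed = 10)
  tab <- tabulate(big$rotations, nbins = 24L)
  chi <- sum((tab - 10000 / 24)^2 / (10000 / 24))
  expect_lt(chi, stats::qchisq(1 - 2e-4, df = 23)) # ~3.5 sigma bound
})

test_that("focal loss matches hand-computed oracles", {
  # perfect prediction -> zero loss
  expect_equal(focal_loss(c(0, 0, 1, 0), 3L), 0)
  # gamma 0 reduces to alpha-weighted cross-entropy
  p <- matrix(c(0.7, 0.1, 0.1, 0.1), 1)
  expect_equal(focal_loss(p, 1L, gamma = 0), -0.35 * log(0.7))
  # hand evaluation: p_y = 0.5 for WM (class 3)
  expect_equal(
    focal_loss(matrix(c(0.2, 0.2, 0.5, 0.1), 1), 3L),
    0.15 * 0.25 * log(2),
    tolerance = 1e-12
  )
  expect_equal(0.15 * 0.25 * log(2), 0.02599, tolerance = 1e-3)
  # batch averaging
  pm <- rbind(c(1, 0, 0, 0), c(0.2, 0.2, 0.5, 0.1))
  expect_equal(focal_loss(pm, c(1L, 3L)), 0.15 * 0.25 * log(2) / 2)
  expect_error(focal_loss(matrix(c(0.5, 0.2, 0.2, 0.2), 1), 1L), "sum to 1")
})

test_that("softmax focal gradient matches finite differences", {
  set.seed(41)
  z <- matrix(stats::rnorm(12), 3, 4)
  y <- c(2L, 4L, 1L)
  fl <- icoseg:::focal_loss_logits(z, y)
  for (i in seq_along(z)) {
    eps <- 1e-6
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (icoseg:::focal_loss_logits(zp, y)$loss - icoseg:::focal_loss_logits(zm, y)$loss) / (2 * eps)
    expect_equal(fl$grad[i], num, tolerance = 1e-5)
  }
})

test_that("evaluation metrics match confusion-matrix oracles", {
  # perfect predictions
  rep0 <- evaluate_predictions(c(1, 2, 3, 4, 2), c(1, 2, 3, 4, 2))
  expect_true(all(rep0$summary$accuracy_mean == 1))
  expect_true(all(rep0$summary$dice_mean == 1))
  expect_equal(rep0$overall_mean, 1)
  # constructed confusion: class 1 with TP=3, FP=1, FN=1 -> Dice 0.75
  y <- c(1, 1, 1, 1, 2, 2, 2)
  p <- c(1, 1, 1, 2, 1, 2, 2)
  rep1 <- evaluate_predictions(p, y)
  expect_equal(rep1$per_scan$dice[rep1$per_scan$class == "CSF"], 0.75)
  expect_equal(rep1$per_scan$accuracy[rep1$per_scan$class == "CSF"], 3 / 4)
  # all-one-class predictor on balanced labels -> overall accuracy 0.25
  yb <- rep(1:4, each = 10)
  rep2 <- evaluate_predictions(rep(2L, 40), yb)
  expect_equal(rep2$overall_mean, 0.25)
  # random vectors vs direct per-sample counting, across scans
  set.seed(42)
  yr <- sample.int(4L, 200, replace = TRUE)
  pr <- sample.int(4L, 200, replace = TRUE)
  scans <- rep(1:2, each = 100)
  repr <- evaluate_predictions(pr, yr, scans)
  for (s in 1:2) {
    i <- scans == s
    for (cl in 1:4) {
      tp <- sum(pr[i] == cl & yr[i] == cl)
      fp <- sum(pr[i] == cl & yr[i] != cl)
      fn <- sum(pr[i] != cl & yr[i] == cl)
      row <- repr$per_scan[repr$per_scan$scan == s & repr$per_scan$class == tissue_classes()[cl], ]
      expect_equal(row$dice, 2 * tp / (2 * tp + fp + fn))
      expect_equal(row$accuracy, tp / sum(yr[i] == cl))
    }
    expect_equal(repr$overall$accuracy[s], mean(pr[i] == yr[i]))
  }
  # a class absent from a scan is excluded from the summary and flagged
  rep3 <- evaluate_predictions(c(1, 1, 2), c(1, 1, 2))
  expect_equal(rep3$summary$n_scans[rep3$summary$class == "WM"], 0L)
})

test_that("performance drop map implements both readings of the decay", {
  expect_equal(as.numeric(performance_drop_map(0.8, 0.8)), exp(-20))
  # larger drop (larger ratio) -> smaller exp_decay score
  expect_lt(
    as.numeric(performance_drop_map(0.9, 0.6)),
    as.numeric(performance_drop_map(0.9, 0.8))
  )
  expect_equal(as.numeric(performance_drop_map(0.7, 0.7, formula = "logistic")), 0.5)
  expect_error(performance_drop_map(0.5, 0))
})

test_that("training is deterministic, records history, and aborts on divergence", {
  tv <- tiny_volume()
  ds <- extract_patches(tv$volume, tv$labels, 1, n_per_class = 6, seed = 3)
  spec <- architecture_spec("baseline_so3", c(1, 3))
  run <- function() {
    net <- build_network(spec, test_group, seed = 7)
    train_network(net, ds, epochs = 2, batch_size = 10, seed = 8)
  }
  t1 <- run()
  t2 <- run()
  expect_length(t1$history, 2L)
  expect_true(all(is.finite(t1$history)))
  expect_identical(
    icoseg:::network_params(t1$network),
    icoseg:::network_params(t2$network)
  )
  # divergence guard trips on a poisoned network
  net_bad <- build_network(spec, test_group, seed = 7)
  net_bad$fc$W[] <- NaN
  expect_error(
    train_network(net_bad, ds, epochs = 1, batch_size = 10, seed = 8),
    "diverged"
  )
})
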