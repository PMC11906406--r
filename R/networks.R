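#' Declarative description of one network variant
#'
#' The ablation family covers six architectures distinguished by the group
#' action they respect:
#' \describe{
#'   \item{classical}{plain 3D CNN on the raw N-direction measurement
#'     vector (Type 1); `widths[1]` is the input channel count (the number
#'     of gradient directions), followed by three conv widths.}
#'   \item{baseline_so3}{single-voxel SO(3) network: lift, one fiber group
#'     convolution, projection to the sphere, fully connected head on
#'     12 x C vertex features. `widths` = (lift width, gconv width).}
#'   \item{decoupled, partial_se3, full_se3}{interleaved separable
#'     sublayers on 7^3 patches. `widths` alternates S2 / R3 sublayer
#'     output widths starting with the S2 lift; an odd length ends with an
#'     S2 sublayer on the final 1^3 grid. The three variants differ only in
#'     how the spatial kernel is tied to the group slot (`none`,
#'     `partial`, `full`), which adds no parameters.}
#'   \item{rotavg_classical}{the classical stack replicated over 12 or 60
#'     rotated kernel copies with shared weights; branch logits are
#'     averaged.}
#' }
#'
#' @param variant one of `"classical"`, `"baseline_so3"`, `"decoupled"`,
#'   `"partial_se3"`, `"full_se3"`, `"rotavg_classical"`.
#' @param widths integer vector of sublayer widths (see above).
#' @param num_classes number of output classes (default 4).
#' @param rotavg_copies 12 or 60 (rotation-averaged classical only).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(variant, widths, num_classes = 4L,
                              rotavg_copies = 12L) {
  variant <- match.arg(variant, c(
    "classical", "baseline_so3", "decoupled", "partial_se3",
    "full_se3", "rotavg_classical"
  ))
  widths <- as.integer(widths)
  stopifnot(all(widths >= 1), num_classes >= 2)
  if (variant %in% c("classical", "rotavg_classical")) {
    stopifnot(length(widths) >= 2)
    patch_size <- 2L * (length(widths) - 1L) + 1L
  } else if (variant == "baseline_so3") {
    stopifnot(length(widths) == 2)
    patch_size <- 1L
  } else {
    stopifnot(length(widths) >= 2)
    patch_size <- 2L * (length(widths) %/% 2L) + 1L
  }
  if (variant == "rotavg_classical") stopifnot(rotavg_copies %in% c(12L, 60L))
  structure(
    list(
      variant = variant, widths = widths,
      num_classes = as.integer(num_classes), patch_size = patch_size,
      rotavg_copies = if (variant == "rotavg_classical") as.integer(rotavg_copies) else NULL
    ),
    class = "architecture_spec"
  )
}

#' Named architecture presets
#'
#' The capacity pairs of the ablation family, by their usual labels:
#' `classical-` (90-5-5-5), `classical+` (90-120-120-90),
#' `baseline-` (1-5), `baseline+` (10-20),
#' `decoupled-`/`partial-`/`full-` (5-5-5-5-5-5-5),
#' `decoupled+`/`partial+`/`full+` (10-20-20-40-40-20-10),
#' `full-compare` (10-10-20-40-20-10, the three-spatial-sublayer
#' configuration used for the state-of-the-art comparison), and
#' `rotavg-12` / `rotavg-60` (shared-weight rotation-averaged 90-5-5-5).
#'
#' @param name preset name.
#' @param n_directions input channel count for classical variants
#'   (default 90).
#' @return An `architecture_spec`.
#' @export
architecture_preset <- function(name, n_directions = 90L) {
  low <- c(5, 5, 5, 5, 5, 5, 5)
  high <- c(10, 20, 20, 40, 40, 20, 10)
  switch(name,
    "classical-" = architecture_spec("classical", c(n_directions, 5, 5, 5)),
    "classical+" = architecture_spec("classical", c(n_directions, 120, 120, 90)),
    "baseline-" = architecture_spec("baseline_so3", c(1, 5)),
    "baseline+" = architecture_spec("baseline_so3", c(10, 20)),
    "decoupled-" = architecture_spec("decoupled", low),
    "decoupled+" = architecture_spec("decoupled", high),
    "partial-" = architecture_spec("partial_se3", low),
    "partial+" = architecture_spec("partial_se3", high),
    "full-" = architecture_spec("full_se3", low),
    "full+" = architecture_spec("full_se3", high),
    "full-compare" = architecture_spec("full_se3", c(10, 10, 20, 40, 20, 10)),
    "rotavg-12" = architecture_spec("rotavg_classical", c(n_directions, 5, 5, 5), rotavg_copies = 12L),
    "rotavg-60" = architecture_spec("rotavg_classical", c(n_directions, 5, 5, 5), rotavg_copies = 60L),
    stop("unknown preset: ", name)
  )
}

# sublayer plan for the separable spatial variants: alternate S2 / R3
# starting with the lift
spatial_sublayer_plan <- function(widths) {
  types <- ifelse(seq_along(widths) %% 2L == 1L, "s2", "r3")
  types[1] <- "lift"
  types
}

#' Count the trainable parameters of an architecture
#'
#' Exact count of independent scalars. Every convolutional sublayer
#' (S2 lift: 11 support points; SO(3) fiber: 5; spatial: 27) carries one
#' bias per output channel, and the fully connected head carries biases.
#' Rotated kernel copies share weights and are counted once, so the
#' rotation-averaged classical CNN has exactly the classical count and the
#' decoupled / partial / full variants of equal widths have equal counts.
#'
#' @param spec An `architecture_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  w <- spec$widths
  nc <- spec$num_classes
  n <- switch(spec$variant,
    classical = ,
    rotavg_classical = {
      convs <- sum(w[-length(w)] * w[-1] * 27 + w[-1])
      convs + w[length(w)] * nc + nc
    },
    baseline_so3 = {
      (1 * w[1] * 11 + w[1]) + (w[1] * w[2] * 5 + w[2]) + (12 * w[2] * nc + nc)
    },
    {
      types <- spatial_sublayer_plan(w)
      cin <- c(1L, w[-length(w)])
      support <- ifelse(types == "lift", 11L, ifelse(types == "s2", 5L, 27L))
      sum(cin * w * support + w) + w[length(w)] * nc + nc
    }
  )
  as.integer(n)
}

#' Build a network from an architecture spec
#'
#' Instantiates every kernel (He-uniform initialization over fan-in
#' `channels x kernel support`) and precomputes the group structures the
#' forward pass needs (lift orbit, Watson interpolation is applied by
#' [prepare_network_input()]).
#'
#' @param spec An `architecture_spec`.
#' @param group A `rotation_group`.
#' @param seed optional integer seed for weight initialization.
#' @return An object of class `icoseg_network`.
#' @export
build_network <- function(spec, group, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"), inherits(group, "rotation_group"))
  if (!is.null(seed)) set.seed(seed)
  orbit <- lift_orbit(group)
  w <- spec$widths
  nc <- spec$num_classes
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  if (spec$variant %in% c("classical", "rotavg_classical")) {
    extent <- spec$patch_size
    for (i in 2:length(w)) {
      add(list(
        type = "spatial", kernel = spatial_kernel(w[i - 1], w[i]),
        mode = "none", extent_in = extent
      ))
      add(list(type = "relu"))
      extent <- extent - 2L
    }
    stopifnot(extent == 1L)
    fc_in <- w[length(w)]
  } else if (spec$variant == "baseline_so3") {
    add(list(type = "lift", kernel = star_kernel(1, w[1])))
    add(list(type = "relu"))
    add(list(type = "gconv", kernel = fiber_kernel(w[1], w[2])))
    add(list(type = "relu"))
    add(list(type = "project", target = "sphere"))
    fc_in <- 12L * w[2]
  } else {
    mode <- switch(spec$variant,
      decoupled = "none", partial_se3 = "partial", full_se3 = "full"
    )
    types <- spatial_sublayer_plan(w)
    extent <- spec$patch_size
    cin <- 1L
    for (i in seq_along(w)) {
      if (types[i] == "lift") {
        add(list(type = "lift", kernel = star_kernel(cin, w[i])))
      } else if (types[i] == "s2") {
        add(list(type = "gconv", kernel = fiber_kernel(cin, w[i])))
      } else {
        add(list(
          type = "spatial", kernel = spatial_kernel(cin, w[i]),
          mode = mode, extent_in = extent
        ))
        extent <- extent - 2L
      }
      add(list(type = "relu"))
      cin <- w[i]
    }
    stopifnot(extent == 1L)
    add(list(type = "project", target = "space"))
    fc_in <- w[length(w)]
  }

  fc <- list(
    W = he_uniform(c(fc_in, nc), fan_in = fc_in),
    b = numeric(nc)
  )
  structure(
    list(spec = spec, group = group, orbit = orbit, layers = layers, fc = fc),
    class = "icoseg_network"
  )
}

#' Prepare raw patch signals as network input
#'
#' Classical (Type 1) variants consume the raw per-voxel measurement
#' vector as channels. Group variants consume the Type 2 (Watson
#' interpolated) representation sampled on the star-kernel orbit.
#'
#' @param network An `icoseg_network`.
#' @param values array `[B, V, N]` of per-voxel signals (V = patch voxels,
#'   N = number of measured directions).
#' @param scheme the `sampling_scheme` of the N directions.
#' @param kappa Watson concentration for Type 2 interpolation (default 10).
#' @param center,scale affine input standardization applied as
#'   `(x - center) / scale`; the defaults place b0-normalized attenuations
#'   (which live in (0, 1)) roughly at zero mean and unit-order scale,
#'   which conditions ReLU optimization. `center = NULL` disables.
#' @return Input array in the network's expected layout.
#' @export
prepare_network_input <- function(network, values, scheme, kappa = 10,
                                  center = 0.5, scale = 0.3) {
  stopifnot(length(dim(values)) == 3)
  B <- dim(values)[1]
  V <- dim(values)[2]
  if (network$spec$variant %in% c("classical", "rotavg_classical")) {
    x <- aperm(values, c(2, 1, 3)) # [V, B, N] -> rows voxel-major within batch
    dim(x) <- c(V * B, 1L, dim(values)[3])
  } else {
    W <- watson_weights(network$orbit$points, scheme$directions, kappa)
    flat <- matrix(aperm(values, c(2, 1, 3)), V * B, dim(values)[3])
    x <- flat %*% t(W)
    dim(x) <- c(V * B, nrow(network$orbit$points), 1L)
  }
  if (!is.null(center)) x <- (x - center) / scale
  x
}

layer_forward <- function(layer, x, batch, net, keep) {
  cache <- NULL
  out <- switch(layer$type,
    lift = {
      if (keep) cache <- list(x = x)
      lift_s2(x, layer$kernel, net$group, net$orbit)
    },
    gconv = {
      if (keep) cache <- list(x = x)
      gconv_so3(x, layer$kernel, net$group)
    },
    spatial = {
      if (keep) cache <- list(x = x)
      spatial_conv(x, layer$kernel, net$group, layer$mode,
                   batch = batch, extent = layer$extent_in)
    },
    relu = {
      y <- cpp_relu(as_mgc(x))
      if (keep) cache <- list(y = y) # reference only; doubles as the mask
      y
    },
    project = {
      pr <- project_max_with_arg(x, layer$target)
      if (keep) cache <- list(arg = pr$arg, dim_in = dim(as_mgc(x)))
      pr$value
    },
    stop("unknown layer type")
  )
  list(out = out, cache = cache)
}

# projection that also returns argmax slots (for backprop)
project_max_with_arg <- function(F_in, target) {
  F_in <- as_mgc(F_in)
  M <- dim(F_in)[1]
  C <- dim(F_in)[3]
  if (target == "space") {
    val <- matrix(F_in[, 1, ], M, C)
    arg <- matrix(1L, M, C)
    for (g in 2:60) {
      fg <- matrix(F_in[, g, ], M, C)
      upd <- fg > val
      val[upd] <- fg[upd]
      arg[upd] <- g
    }
    list(value = val, arg = arg)
  } else {
    val <- array(0, c(M, 12, C))
    arg <- array(1L, c(M, 12, C))
    for (f in 1:12) {
      slots <- (f - 1L) * 5L + 1:5
      v <- matrix(F_in[, slots[1], ], M, C)
      a <- matrix(slots[1], M, C)
      for (s in slots[-1]) {
        fs <- matrix(F_in[, s, ], M, C)
        upd <- fs > v
        v[upd] <- fs[upd]
        a[upd] <- s
      }
      val[, f, ] <- v
      arg[, f, ] <- a
    }
    list(value = val, arg = arg)
  }
}

#' Forward pass of a built network
#'
#' @param network An `icoseg_network`.
#' @param x prepared input from [prepare_network_input()].
#' @param batch number of patches in `x`.
#' @param keep_cache retain intermediate values for a backward pass.
#' @return List with `logits` (`batch x num_classes`) and, if requested,
#'   `caches`.
#' @export
network_forward <- function(network, x, batch, keep_cache = FALSE) {
  if (network$spec$variant == "rotavg_classical") {
    return(rotavg_forward(network, x, batch, keep_cache))
  }
  caches <- vector("list", length(network$layers))
  for (i in seq_along(network$layers)) {
    st <- layer_forward(network$layers[[i]], x, batch, network, keep_cache)
    x <- st$out
    caches[[i]] <- st$cache
  }
  feats <- matrix(x, batch, length(x) / batch)
  logits <- sweep(feats %*% network$fc$W, 2, network$fc$b, `+`)
  if (keep_cache) {
    list(logits = logits, caches = caches, features = feats)
  } else {
    list(logits = logits)
  }
}

# rotation indices used by the averaged-copy classical network:
# 60 = all elements, 12 = the spin-1 coset representative at each vertex
rotavg_rotations <- function(network) {
  copies <- network$spec$rotavg_copies
  if (!is.null(network$rotation_override)) return(network$rotation_override)
  if (copies == 60L) 1:60 else (0:11) * 5L + 1L
}

rotavg_forward <- function(network, x, batch, keep_cache = FALSE) {
  rots <- rotavg_rotations(network)
  logits <- NULL
  caches <- if (keep_cache) vector("list", length(rots)) else NULL
  for (ri in seq_along(rots)) {
    r <- rots[ri]
    net_r <- network
    net_r$spec$variant <- "classical"
    for (i in seq_along(net_r$layers)) {
      if (net_r$layers[[i]]$type == "spatial") {
        net_r$layers[[i]]$kernel <- rotate_spatial_kernel(
          net_r$layers[[i]]$kernel, network$group$elements[, , r]
        )
      }
    }
    st <- network_forward(net_r, x, batch, keep_cache)
    logits <- if (is.null(logits)) st$logits else logits + st$logits
    if (keep_cache) caches[[ri]] <- st
  }
  logits <- logits / length(rots)
  if (keep_cache) list(logits = logits, caches = caches, rots = rots) else list(logits = logits)
}

#' Class scores for a batch of raw patches
#'
#' Convenience wrapper: prepares the input representation for the
#' network's discretization type and runs the forward pass.
#'
#' @param network An `icoseg_network`.
#' @param values array `[B, V, N]` of per-voxel raw signals.
#' @param scheme `sampling_scheme` of the N directions.
#' @param kappa Watson concentration (default 10).
#' @return `B x num_classes` matrix of class scores (logits).
#' @export
network_scores <- function(network, values, scheme, kappa = 10) {
  x <- prepare_network_input(network, values, scheme, kappa)
  network_forward(network, x, dim(values)[1])$logits
}

#' Enumerate the learnable scalars of a built network
#'
#' Walks the concrete layer list and counts every weight and bias once.
#' Used as the independent oracle for [count_parameters()].
#'
#' @param network An `icoseg_network`.
#' @return Integer count.
#' @export
enumerate_parameters <- function(network) {
  n <- 0L
  for (l in network$layers) {
    if (!is.null(l$kernel)) {
      n <- n + length(l$kernel$weights) + length(l$kernel$bias)
    }
  }
  n + length(network$fc$W) + length(network$fc$b)
}

# ---- parameter access (flat list) for the optimizer -------------------

network_params <- function(network) {
  ps <- list()
  for (i in seq_along(network$layers)) {
    k <- network$layers[[i]]$kernel
    if (!is.null(k)) {
      ps[[paste0("layer", i, ".weights")]] <- k$weights
      ps[[paste0("layer", i, ".bias")]] <- k$bias
    }
  }
  ps[["fc.W"]] <- network$fc$W
  ps[["fc.b"]] <- network$fc$b
  ps
}

set_network_params <- function(network, ps) {
  for (i in seq_along(network$layers)) {
    k <- network$layers[[i]]$kernel
    if (!is.null(k)) {
      network$layers[[i]]$kernel$weights <- array(
        ps[[paste0("layer", i, ".weights")]], dim = dim(k$weights)
      )
      network$layers[[i]]$kernel$bias <- as.numeric(ps[[paste0("layer", i, ".bias")]])
    }
  }
  network$fc$W <- matrix(ps[["fc.W"]], nrow(network$fc$W), ncol(network$fc$W))
  network$fc$b <- as.numeric(ps[["fc.b"]])
  network
}
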