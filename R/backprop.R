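# Reverse-mode gradients for the layer stack. Each backward function
# receives the gradient of the scalar loss w.r.t. the layer output and
# returns gradients w.r.t. the layer input (NULL for first layers, where
# it is never needed) and w.r.t. the kernel weights/bias. The heavy
# gather/scatter loops live in src/ops.cpp.

lift_backward <- function(layer, cache, gout, net) {
  k <- layer$kernel
  x <- as_mgc(cache$x)
  gout <- array(gout, dim = c(dim(x)[1], 60, k$c_out))
  bk <- cpp_lift_bwd(x, net$orbit$index, gout)
  list(gx = NULL, gw = array(bk$gw, dim = dim(k$weights)), gb = as.numeric(bk$gb))
}

gconv_backward <- function(layer, cache, gout, net, want_gx = TRUE) {
  k <- layer$kernel
  F_in <- as_mgc(cache$x)
  gout <- array(gout, dim = c(dim(F_in)[1], 60, k$c_out))
  bk <- cpp_gconv_bwd(F_in, fiber_perms(net$group), k$weights, gout, want_gx)
  list(
    gx = if (want_gx) bk$gx else NULL,
    gw = array(bk$gw, dim = dim(k$weights)),
    gb = as.numeric(bk$gb)
  )
}

# invert the im2col flattening back to [c_in, c_out, 3, 3, 3]
unflatten_wm <- function(wm, c_in, c_out) {
  array(aperm(array(wm, dim = c(27, c_in, c_out)), c(2, 3, 1)),
        dim = c(c_in, c_out, 3, 3, 3))
}

spatial_backward <- function(layer, cache, gout, net, batch, want_gx = TRUE) {
  k <- layer$kernel
  F_in <- as_mgc(cache$x)
  extent <- layer$extent_in
  G <- dim(F_in)[2]
  rows <- spatial_conv_rows(extent, batch)
  gout <- array(gout, dim = c(nrow(rows), G, k$c_out))
  wm <- spatial_wm_stack(k, net$group, layer$mode, G)
  bk <- cpp_spatial_bwd(F_in, rows, wm$Wm, wm$rotidx, gout, want_gx)
  if (layer$mode == "none") {
    gw <- unflatten_wm(bk$gWm[, , 1], k$c_in, k$c_out)
  } else {
    # pull rotated-kernel gradients back to the base kernel: the rotation
    # acts blockwise per input channel as W_r = A_r W, so gW += t(A_r) gW_r
    gwm <- matrix(0, 27 * k$c_in, k$c_out)
    for (i in seq_along(wm$rotations)) {
      At <- t(trilinear_rotation_matrix(net$group$elements[, , wm$rotations[i]]))
      gi <- matrix(bk$gWm[, , i], 27 * k$c_in, k$c_out)
      for (ci in seq_len(k$c_in)) {
        blk <- (ci - 1L) * 27L + 1:27
        gwm[blk, ] <- gwm[blk, ] + At %*% gi[blk, ]
      }
    }
    gw <- unflatten_wm(gwm, k$c_in, k$c_out)
  }
  list(gx = if (want_gx) bk$gx else NULL, gw = gw, gb = as.numeric(bk$gb))
}

project_backward <- function(layer, cache, gout) {
  dim_in <- cache$dim_in
  M <- dim_in[1]
  C <- dim_in[3]
  gx <- array(0, dim = dim_in)
  if (layer$target == "space") {
    gout <- matrix(gout, M, C)
    for (c in seq_len(C)) {
      gx[cbind(seq_len(M), cache$arg[, c], c)] <- gout[, c]
    }
  } else {
    gout <- array(gout, dim = c(M, 12, C))
    for (c in seq_len(C)) {
      for (f in 1:12) {
        gx[cbind(seq_len(M), cache$arg[, f, c], c)] <-
          gx[cbind(seq_len(M), cache$arg[, f, c], c)] + gout[, f, c]
      }
    }
  }
  gx
}

# full backward pass; glogits is d loss / d logits [batch, num_classes]
network_backward <- function(network, state, glogits, batch) {
  if (network$spec$variant == "rotavg_classical") {
    return(rotavg_backward(network, state, glogits, batch))
  }
  grads <- list()
  grads[["fc.W"]] <- crossprod(state$features, glogits)
  grads[["fc.b"]] <- colSums(glogits)
  gx <- glogits %*% t(network$fc$W)
  nl <- length(network$layers)
  for (i in rev(seq_len(nl))) {
    l <- network$layers[[i]]
    cache <- state$caches[[i]]
    want_gx <- i > 1L
    if (l$type == "relu") {
      gx <- cpp_relu_bwd(cache$y, gx)
    } else if (l$type == "project") {
      gx <- project_backward(l, cache, gx)
    } else {
      bk <- switch(l$type,
        lift = lift_backward(l, cache, gx, network),
        gconv = gconv_backward(l, cache, gx, network, want_gx),
        spatial = spatial_backward(l, cache, gx, network, batch, want_gx)
      )
      grads[[paste0("layer", i, ".weights")]] <- bk$gw
      grads[[paste0("layer", i, ".bias")]] <- bk$gb
      gx <- bk$gx
    }
  }
  grads
}

rotavg_backward <- function(network, state, glogits, batch) {
  rots <- state$rots
  gl <- glogits / length(rots)
  total <- NULL
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
    g_r <- network_backward(net_r, state$caches[[ri]], gl, batch)
    # unrotate spatial weight gradients (shared base weights):
    # flattened over channel pairs, W_r = W t(A_r), hence gW = gW_r A_r
    A <- trilinear_rotation_matrix(network$group$elements[, , r])
    for (i in seq_along(network$layers)) {
      l <- network$layers[[i]]
      if (l$type == "spatial") {
        nm <- paste0("layer", i, ".weights")
        gw <- array(g_r[[nm]], dim = c(l$kernel$c_in * l$kernel$c_out, 27))
        g_r[[nm]] <- array(gw %*% A, dim = dim(l$kernel$weights))
      }
    }
    total <- if (is.null(total)) g_r else mapply(`+`, total, g_r, SIMPLIFY = FALSE)
  }
  total
}
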