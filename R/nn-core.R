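# Minimal feed-forward network machinery: dense and strided-3x3-conv layers,
# ReLU / LeakyReLU / sigmoid activations, reverse-mode gradients, Adam.
# Layers are environments so optimiser state can live next to the weights;
# parameter snapshots (net_params / net_set_params) are plain lists of arrays.
#
# Layout conventions:
#   dense input  : B x n_in matrix (rows = samples)
#   conv input   : (H*W*B) x C matrix, pixel index column-major within an
#                  image and fastest; images stacked along rows
#   conv weights : (k^2 * C_in) x C_out, kernel-offset index fastest

act_apply <- function(z, act, alpha = 0.01) {
  switch(act,
    relu    = pmax(z, 0),
    lrelu   = ifelse(z > 0, z, alpha * z),
    sigmoid = 1 / (1 + exp(-z)),
    linear  = z,
    stop("unknown activation: ", act)
  )
}

# derivative wrt pre-activation; `out` is the post-activation value
act_deriv <- function(pre, out, act, alpha = 0.01) {
  switch(act,
    relu    = (pre > 0) * 1,
    lrelu   = ifelse(pre > 0, 1, alpha),
    sigmoid = out * (1 - out),
    linear  = 1,
    stop("unknown activation: ", act)
  )
}

new_dense_layer <- function(n_in, n_out, act, alpha = 0.01) {
  sd0 <- if (act %in% c("relu", "lrelu")) sqrt(2 / n_in) else sqrt(1 / n_in)
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$W <- matrix(rnorm(n_in * n_out, sd = sd0), n_in, n_out)
  e$b <- numeric(n_out)
  e$act <- act
  e$alpha <- alpha
  e
}

# Source-pixel indices for each (kernel offset, output position); NA = padding.
conv_index_map <- function(H, W, k, stride, pad) {
  Hout <- (H + 2 * pad - k) %/% stride + 1
  Wout <- (W + 2 * pad - k) %/% stride + 1
  oi <- rep(seq_len(Hout), times = Wout)          # output row, fastest
  oj <- rep(seq_len(Wout), each = Hout)
  idx <- matrix(NA_integer_, k * k, Hout * Wout)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      sh <- (oi - 1L) * stride + a - pad
      sw <- (oj - 1L) * stride + b - pad
      lin <- (sw - 1L) * H + sh
      lin[sh < 1L | sh > H | sw < 1L | sw > W] <- NA_integer_
      idx[(b - 1L) * k + a, ] <- lin
    }
  }
  list(idx = idx, Hout = Hout, Wout = Wout)
}

new_conv_layer <- function(Hin, Win, Cin, Cout, k = 3L, stride = 2L, pad = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$k <- k; e$stride <- stride; e$pad <- pad
  e$Cin <- Cin; e$Cout <- Cout
  e$Hin <- Hin; e$Win <- Win
  m <- conv_index_map(Hin, Win, k, stride, pad)
  e$idx <- m$idx
  e$Hout <- m$Hout; e$Wout <- m$Wout
  e$W <- matrix(rnorm(k * k * Cin * Cout, sd = sqrt(2 / (k * k * Cin))),
                k * k * Cin, Cout)
  e$b <- numeric(Cout)
  e$act <- "relu"
  e$idx_cache <- list()   # per-batch-size expanded index vectors
  e
}

new_gap_layer <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "gap"
  e
}

# Expanded gather indices for a whole batch. For a fixed kernel offset the
# output-position -> input-pixel map is injective, so the backward scatter is a
# plain indexed add; padding positions are tracked separately and zeroed.
conv_batch_idx <- function(layer, B) {
  key <- as.character(B)
  cached <- layer$idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  HW <- layer$Hin * layer$Win
  k2 <- layer$k^2
  out <- vector("list", k2)
  offs <- (seq_len(B) - 1L) * HW
  for (j in seq_len(k2)) {
    base <- layer$idx[j, ]
    napos <- is.na(base)
    m <- outer(ifelse(napos, 1L, base), offs, `+`)   # P x B
    pad <- which(rep(napos, times = B))
    safe <- as.integer(m)
    out[[j]] <- list(safe = safe, pad = pad,
                     tgt = safe[if (length(pad)) -pad else TRUE],
                     valid = if (length(pad)) seq_along(safe)[-pad]
                             else seq_along(safe))
  }
  layer$idx_cache[[key]] <- out
  out
}

conv_patches <- function(layer, X, B) {
  idxf <- conv_batch_idx(layer, B)
  k2 <- layer$k^2
  P <- matrix(0, layer$Hout * layer$Wout * B, k2 * layer$Cin)
  cols <- seq(0L, by = k2, length.out = layer$Cin)
  for (j in seq_len(k2)) {
    G <- X[idxf[[j]]$safe, , drop = FALSE]
    if (length(idxf[[j]]$pad)) G[idxf[[j]]$pad, ] <- 0
    P[, j + cols] <- G
  }
  P
}

layer_forward <- function(layer, X, B) {
  if (layer$type == "dense") {
    pre <- X %*% layer$W
    pre <- pre + rep(layer$b, each = nrow(pre))
    out <- act_apply(pre, layer$act, layer$alpha)
    list(out = out, cache = list(X = X, pre = pre, out = out))
  } else if (layer$type == "conv") {
    P <- conv_patches(layer, X, B)
    pre <- P %*% layer$W
    pre <- pre + rep(layer$b, each = nrow(pre))
    out <- act_apply(pre, layer$act)
    list(out = out, cache = list(P = P, pre = pre, out = out))
  } else { # gap
    HW <- nrow(X) / B
    grp <- rep(seq_len(B), each = HW)
    out <- rowsum(X, grp, reorder = FALSE) / HW
    list(out = out, cache = list(HW = HW, B = B))
  }
}

layer_backward <- function(layer, cache, dOut, B, need_dX = TRUE) {
  if (layer$type == "dense") {
    dPre <- dOut * act_deriv(cache$pre, cache$out, layer$act, layer$alpha)
    list(dW = crossprod(cache$X, dPre), db = colSums(dPre),
         dX = if (need_dX) tcrossprod(dPre, layer$W) else NULL)
  } else if (layer$type == "conv") {
    dPre <- dOut * act_deriv(cache$pre, cache$out, layer$act)
    dW <- crossprod(cache$P, dPre)
    db <- colSums(dPre)
    if (!need_dX) return(list(dW = dW, db = db, dX = NULL))
    dP <- tcrossprod(dPre, layer$W)
    HW <- layer$Hin * layer$Win
    dX <- matrix(0, HW * B, layer$Cin)
    idxf <- conv_batch_idx(layer, B)
    k2 <- layer$k^2
    cols <- seq(0L, by = k2, length.out = layer$Cin)
    for (j in seq_len(k2)) {
      ix <- idxf[[j]]
      dX[ix$tgt, ] <- dX[ix$tgt, , drop = FALSE] +
        dP[ix$valid, j + cols, drop = FALSE]
    }
    list(dW = dW, db = db, dX = dX)
  } else { # gap
    grp <- rep(seq_len(B), each = cache$HW)
    list(dX = dOut[grp, , drop = FALSE] / cache$HW)
  }
}

net_forward <- function(net, X, B = nrow(X), keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], X, B)
    X <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

# dOut is the gradient of the loss wrt the net output. Set need_input_grad
# FALSE when the gradient wrt the net input is not consumed (saves the
# dominant scatter at the first conv layer).
net_backward <- function(net, caches, dOut, B, need_input_grad = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    g <- layer_backward(net$layers[[i]], caches[[i]], dOut, B,
                        need_dX = need_input_grad || i > 1L)
    grads[[i]] <- g[c("dW", "db")]
    dOut <- g$dX
  }
  list(grads = grads, dX = dOut)
}

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps; e$t <- 0L
  e
}

adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "gap") next
    g <- grads[[i]]
    if (is.null(ly$mW)) {
      ly$mW <- ly$W * 0; ly$vW <- ly$W * 0
      ly$mb <- ly$b * 0; ly$vb <- ly$b * 0
    }
    ly$mW <- b1 * ly$mW + (1 - b1) * g$dW
    ly$vW <- b2 * ly$vW + (1 - b2) * g$dW^2
    ly$W <- ly$W - opt$lr * (ly$mW / corr1) / (sqrt(ly$vW / corr2) + opt$eps)
    ly$mb <- b1 * ly$mb + (1 - b1) * g$db
    ly$vb <- b2 * ly$vb + (1 - b2) * g$db^2
    ly$b <- ly$b - opt$lr * (ly$mb / corr1) / (sqrt(ly$vb / corr2) + opt$eps)
  }
  invisible(net)
}

net_params <- function(net) {
  lapply(net$layers, function(ly) {
    if (ly$type == "gap") list() else list(W = ly$W, b = ly$b)
  })
}

net_set_params <- function(net, params) {
  stopifnot(length(params) == length(net$layers))
  for (i in seq_along(params)) {
    if (net$layers[[i]]$type == "gap") next
    stopifnot(identical(dim(net$layers[[i]]$W), dim(params[[i]]$W)))
    net$layers[[i]]$W <- params[[i]]$W
    net$layers[[i]]$b <- params[[i]]$b
  }
  invisible(net)
}

# Deep copy of weights and structure; optimiser state is not copied.
net_clone <- function(net) {
  layers <- lapply(net$layers, function(ly) {
    e <- new.env(parent = emptyenv())
    for (nm in setdiff(ls(ly), c("mW", "vW", "mb", "vb"))) {
      assign(nm, get(nm, envir = ly), envir = e)
    }
    e
  })
  out <- net
  out$layers <- layers
  out
}
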