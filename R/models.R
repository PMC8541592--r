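#' Build the feature extractor, regressor head and discriminator
#'
#' The feature extractor is a 4-block strided-convolution network with
#' global average pooling emitting length-`feature_dim` vectors. The
#' regressor stacks three dense layers `F -> F/2 -> F/4 -> 1` with ReLU,
#' ReLU and a linear output (an unbounded real count); the discriminator
#' uses the same widths with LeakyReLU(0.01) activations and a sigmoid
#' output strictly inside `(0,1)`. With `feature_dim = 2048` the head
#' widths are `2048 -> 1024 -> 512 -> 1`; other feature dims scale the
#' widths proportionally.
#'
#' @param config List with elements `backbone` (only `"smallcnn"` is
#'   available), `feature_dim` (default 128), `image_size` (default 64) and
#'   `seed` (default 1).
#' @return List with elements `feature_extractor`, `regressor`,
#'   `discriminator`.
#' @examples
#' m <- build_models(list(feature_dim = 128, image_size = 32, seed = 1))
#' @export
build_models <- function(config = list()) {
  backbone <- config$backbone %||% "smallcnn"
  F_dim <- as.integer(config$feature_dim %||% 128L)
  size <- as.integer(config$image_size %||% 64L)
  seed <- as.integer(config$seed %||% 1L)
  if (!identical(backbone, "smallcnn")) {
    stop("unknown backbone '", backbone, "': only 'smallcnn' is available")
  }
  if (size < 16L) stop("image_size must be >= 16 for the 4-block backbone")
  with_seed_(seed, {
    fe <- build_feature_extractor(size, F_dim)
    reg <- build_head(F_dim, acts = c("relu", "relu", "linear"))
    disc <- build_head(F_dim, acts = c("lrelu", "lrelu", "sigmoid"))
    list(feature_extractor = fe, regressor = reg, discriminator = disc)
  })
}

build_feature_extractor <- function(size, F_dim) {
  ch <- c(3L, 8L, 16L, 32L, F_dim)
  layers <- list()
  h <- size
  for (i in 1:4) {
    layers[[i]] <- new_conv_layer(h, h, ch[i], ch[i + 1])
    h <- layers[[i]]$Hout
  }
  layers[[5]] <- new_gap_layer()
  structure(list(layers = layers,
                 meta = list(kind = "smallcnn", image_size = size,
                             feature_dim = F_dim)),
            class = c("feature_extractor", "countda_net"))
}

head_widths <- function(F_dim) {
  c(F_dim, max(1L, round(F_dim / 2)), max(1L, round(F_dim / 4)), 1L)
}

build_head <- function(F_dim, acts) {
  w <- head_widths(F_dim)
  layers <- lapply(1:3, function(i) new_dense_layer(w[i], w[i + 1], acts[i]))
  cls <- if (acts[3] == "sigmoid") "discriminator" else "regressor_head"
  structure(list(layers = layers,
                 meta = list(feature_dim = F_dim, widths = w, acts = acts)),
            class = c(cls, "countda_net"))
}

#' Extract feature vectors from a batch of images
#'
#' @param fe A `feature_extractor` from [build_models()].
#' @param images `H x W x 3 x B` array (preprocessed, `[-1,1]`) or a
#'   `count_dataset`.
#' @param chunk Images are processed in chunks of this size.
#' @return `B x F` matrix of finite features (a feature batch).
#' @export
extract_features <- function(fe, images, chunk = 64L) {
  stopifnot(inherits(fe, "feature_extractor"))
  if (inherits(images, "count_dataset")) images <- images$images
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  dsize <- dim(images)
  if (dsize[1] != fe$meta$image_size || dsize[2] != fe$meta$image_size) {
    stop("image size ", dsize[1], "x", dsize[2],
         " does not match the configured extractor size ",
         fe$meta$image_size)
  }
  n <- dsize[4]
  out <- matrix(0, n, fe$meta$feature_dim)
  ds <- list(images = images)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    X <- dataset_batch(ds, idx)
    out[idx, ] <- net_forward(fe, X, length(idx), keep_cache = FALSE)$out
  }
  if (!all(is.finite(out))) stop("non-finite features produced")
  out
}

#' Discriminator probabilities for a feature batch
#'
#' @param d A `discriminator` from [build_models()].
#' @param feats `B x F` feature matrix.
#' @return Vector of `B` probabilities strictly in `(0,1)`.
#' @export
discriminate <- function(d, feats) {
  stopifnot(inherits(d, "discriminator"))
  feats <- as.matrix(feats)
  if (ncol(feats) != d$meta$feature_dim) {
    stop("feature width ", ncol(feats), " does not match discriminator ",
         d$meta$feature_dim)
  }
  p <- net_forward(d, feats, keep_cache = FALSE)$out
  as.numeric(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' Save / load model checkpoints
#'
#' Checkpoints store the network parameters and metadata by stage name
#' (`pretrained`, `adapted`, `finetuned`).
#'
#' @param models Named list of networks (and auxiliary objects such as the
#'   label normalizer).
#' @param dir Checkpoint directory.
#' @param stage Stage name.
#' @return `save_checkpoint` returns the file path; `load_checkpoint` the
#'   restored list.
#' @export
save_checkpoint <- function(models, dir, stage) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(stage, ".rds"))
  ser <- lapply(models, function(m) {
    if (inherits(m, "countda_net")) {
      list(net = TRUE, params = net_params(m), meta = m$meta,
           class = class(m),
           spec = lapply(m$layers, layer_spec))
    } else list(net = FALSE, value = m)
  })
  saveRDS(ser, path)
  path
}

layer_spec <- function(ly) {
  if (ly$type == "dense") {
    list(type = "dense", n_in = nrow(ly$W), n_out = ncol(ly$W),
         act = ly$act, alpha = ly$alpha)
  } else if (ly$type == "conv") {
    list(type = "conv", Hin = ly$Hin, Win = ly$Win, Cin = ly$Cin,
         Cout = ly$Cout, k = ly$k, stride = ly$stride, pad = ly$pad)
  } else list(type = "gap")
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir, stage) {
  path <- file.path(dir, paste0(stage, ".rds"))
  if (!file.exists(path)) {
    stop("missing checkpoint for stage '", stage, "' (expected ", path, ")")
  }
  ser <- readRDS(path)
  lapply(ser, function(s) {
    if (!isTRUE(s$net)) return(s$value)
    layers <- lapply(s$spec, function(sp) {
      switch(sp$type,
        dense = new_dense_layer(sp$n_in, sp$n_out, sp$act, sp$alpha),
        conv = new_conv_layer(sp$Hin, sp$Win, sp$Cin, sp$Cout, sp$k,
                              sp$stride, sp$pad),
        gap = new_gap_layer())
    })
    net <- structure(list(layers = layers, meta = s$meta), class = s$class)
    net_set_params(net, s$params)
    net
  })
}
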