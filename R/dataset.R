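#' Generate a synthetic counting dataset on disk
#'
#' Renders `n` scenes from `spec` with counts drawn uniformly from the
#' spec's count range, writes them as 8-bit RGB PNGs under
#' `out_dir/images/`, and writes a `manifest.csv` with columns
#' `id,path,count,split`. Split sizes follow largest-remainder
#' apportionment of `n * split_fracs` (remainder ties broken in split
#' order); assignment of images to splits is a seeded permutation. The full
#' dataset is bit-identical under regeneration from the same
#' `(spec, n, seed)`.
#'
#' @param spec A [scene_spec()]; `spec$seed` drives all sampling.
#' @param n Number of images, `>= 1`.
#' @param split_fracs Non-negative fractions for `(train, val, test)`
#'   summing to 1.
#' @param out_dir Output directory (created if needed).
#' @param domain Domain tag recorded in sample ids.
#' @return The manifest as a `data.frame` (invisibly written to
#'   `out_dir/manifest.csv`), with the scene spec saved alongside as
#'   `spec.yaml`.
#' @export
generate_dataset <- function(spec, n, split_fracs = c(train = 0.55,
                                                      val = 0.20,
                                                      test = 0.25),
                             out_dir, domain = "source") {
  stopifnot(inherits(spec, "scene_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (length(split_fracs) != 3L || any(split_fracs < 0) ||
      abs(sum(split_fracs) - 1) > 1e-8) {
    stop("split_fracs must be 3 non-negative fractions summing to 1")
  }
  names(split_fracs) <- c("train", "val", "test")
  img_dir <- file.path(out_dir, "images")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory: ", out_dir)

  sizes <- apportion_splits(n, split_fracs)
  draws <- with_seed_(spec$seed, list(
    counts = sample(seq(spec$count_range[1], spec$count_range[2]),
                    n, replace = TRUE),
    perm = sample.int(n)
  ))
  split <- character(n)
  split[draws$perm] <- rep(names(sizes), times = sizes)

  ids <- sprintf("%s_%05d", domain, seq_len(n))
  paths <- file.path("images", paste0(ids, ".png"))
  for (i in seq_len(n)) {
    s <- render_scene(spec, draws$counts[i],
                      seed = scene_seed(spec$seed, i),
                      domain = domain, id = ids[i])
    png::writePNG(s$image, file.path(out_dir, paths[i]))
  }
  manifest <- data.frame(id = ids, path = paths, count = draws$counts,
                         split = split, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write_scene_spec(spec, file.path(out_dir, "spec.yaml"))
  invisible(manifest)
}

# keep derived per-scene seeds inside 32-bit integer range
scene_seed <- function(seed, i) {
  as.integer((as.double(seed) * 2654435L + 7919 * i) %% 2147483647)
}

# Largest-remainder apportionment; ties on the fractional remainder are
# broken in the order the splits are given.
apportion_splits <- function(n, fracs) {
  quota <- n * fracs
  base <- floor(quota)
  rem <- quota - base
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(-rem, seq_along(rem))
    take <- order_rem[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

#' Read a dataset manifest
#'
#' @param dir Dataset directory containing `manifest.csv` (or a direct path
#'   to a manifest CSV).
#' @return `data.frame` with columns `id`, `path`, `count`, `split`.
#' @export
read_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  if (!file.exists(path)) stop("no manifest found at ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "path", "count", "split")
  if (!all(required %in% names(m))) {
    stop("manifest must have columns ", paste(required, collapse = ","))
  }
  if (anyDuplicated(m$id)) stop("manifest ids are not unique")
  m
}

#' Load and preprocess a dataset split into memory
#'
#' Applies the training-time preprocessing: resize to `size`, per-image
#' per-channel histogram equalisation, then an affine map of intensities to
#' `[-1, 1]`.
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param split One of `"train"`, `"val"`, `"test"`, or `NULL` for all rows.
#' @param size Side length images are resized to.
#' @param equalize Logical; apply per-image histogram equalisation.
#' @return A `count_dataset`: list with `images` (`size x size x 3 x n`
#'   array in `[-1,1]`), `counts`, `ids`, `split`.
#' @export
load_dataset <- function(dir, split = NULL, size = 64L, equalize = TRUE) {
  m <- read_manifest(dir)
  if (!is.null(split)) m <- m[m$split %in% split, , drop = FALSE]
  if (nrow(m) == 0L) stop("no images in requested split")
  arr <- array(0, dim = c(size, size, 3, nrow(m)))
  for (i in seq_len(nrow(m))) {
    img <- png::readPNG(file.path(dir, m$path[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    arr[, , , i] <- preprocess_image(img[, , 1:3], size, equalize)
  }
  structure(list(images = arr, counts = m$count, ids = m$id,
                 split = m$split),
            class = "count_dataset")
}

#' Preprocess a single image for the counting networks
#'
#' @param img H x W x 3 array in `[0,1]`.
#' @param size Target side length.
#' @param equalize Logical; per-channel histogram equalisation.
#' @return `size x size x 3` array in `[-1, 1]`.
#' @export
preprocess_image <- function(img, size = 64L, equalize = TRUE) {
  if (dim(img)[1] != size || dim(img)[2] != size) {
    img <- as.array(EBImage::resize(EBImage::Image(img, colormode = "Color"),
                                    w = size, h = size))
  }
  if (equalize) {
    for (ch in 1:3) {
      v <- img[, , ch]
      if (diff(range(v)) > 1e-8) {
        img[, , ch] <- as.array(EBImage::equalize(EBImage::Image(v),
                                                  range = c(0, 1),
                                                  levels = 256))
      }
    }
  }
  img * 2 - 1
}

# Stack dataset images idx into the conv-net input layout:
# (H*W*B) x 3 matrix, pixel index fastest, images along rows.
dataset_batch <- function(ds, idx) {
  x <- ds$images[, , , idx, drop = FALSE]
  H <- dim(x)[1]; W <- dim(x)[2]; B <- length(idx)
  dim(x) <- c(H * W, 3, B)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(H * W * B, 3)
  x
}

# Training-time augmentation on a (H,W,3,B) array in [-1,1]:
# random horizontal/vertical flips and multiplicative colour jitter.
# Uses the current RNG stream.
augment_images <- function(x) {
  B <- dim(x)[4]
  for (i in seq_len(B)) {
    if (runif(1) < 0.5) x[, , , i] <- x[dim(x)[1]:1, , , i]
    if (runif(1) < 0.5) x[, , , i] <- x[, dim(x)[2]:1, , i]
    sc <- runif(3, 0.85, 1.15)
    for (ch in 1:3) {
      x[, , ch, i] <- pmin(pmax(x[, , ch, i] * sc[ch], -1), 1)
    }
  }
  x
}

#' Subset a loaded dataset by index
#'
#' @param ds A `count_dataset`.
#' @param idx Integer indices.
#' @return A `count_dataset` with the selected images.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "count_dataset"))
  structure(list(images = ds$images[, , , idx, drop = FALSE],
                 counts = ds$counts[idx], ids = ds$ids[idx],
                 split = ds$split[idx]),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat("count_dataset:", length(x$counts), "images,",
      dim(x$images)[1], "x", dim(x$images)[2],
      "| counts in [", min(x$counts), ",", max(x$counts), "]\n")
  invisible(x)
}
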