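#' Render one synthetic cell scene
#'
#' Draws exactly `count` Gaussian-profile discs ("cells") with the
#' appearance defined by `spec` onto a noisy dark background. Blob centres
#' are placed by rejection sampling so that footprints (halo included) do
#' not overlap; placement failure after the retry budget raises a "scene too
#' crowded" error rather than silently dropping blobs. Identical
#' `(spec, count, seed)` triples yield bit-identical images.
#'
#' @param spec A [scene_spec()].
#' @param count Integer number of blobs, within `spec$count_range`.
#' @param seed Integer seed for this scene.
#' @param domain Domain tag, `"source"` or `"target"`.
#' @param id Sample identifier string.
#' @return A `labeled_image_sample`: list with `image` (H x W x 3 array in
#'   `[0,1]`), `count`, `domain`, `id`, and `mask`, the noise-free binary
#'   foreground mask whose connected components equal `count` when overlap
#'   is disallowed.
#' @examples
#' sp <- scene_spec(image_size = 64, count_range = c(3, 8),
#'                  blob_radius_range = c(3, 5))
#' s <- render_scene(sp, count = 5, seed = 1)
#' s$count
#' @export
render_scene <- function(spec, count, seed, domain = "source",
                         id = sprintf("%s_%06d", domain, seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  count <- as.integer(count)
  if (count < spec$count_range[1] || count > spec$count_range[2]) {
    stop("count ", count, " outside spec count_range [",
         spec$count_range[1], ", ", spec$count_range[2], "]")
  }
  n <- spec$image_size
  with_seed_(seed, {
    img <- array(0.06, dim = c(n, n, 3))
    mask <- matrix(FALSE, n, n)
    if (count > 0L) {
      radii <- runif(count, spec$blob_radius_range[1],
                     spec$blob_radius_range[2])
      colors <- matrix(spec$blob_color, count, 3, byrow = TRUE) +
        matrix(rnorm(count * 3, sd = spec$color_jitter_sd), count, 3)
      colors <- pmin(pmax(colors, 0.05), 1)
      centers <- place_blobs(n, radii, blob_extent_factor(spec$halo),
                             spec$allow_overlap)
      for (i in seq_len(count)) {
        drawn <- draw_blob(img, mask, centers[i, ], radii[i], colors[i, ],
                           spec$halo)
        img <- drawn$img
        mask <- drawn$mask
      }
    }
    if (spec$background_noise_std > 0) {
      img <- img + array(rnorm(length(img), sd = spec$background_noise_std),
                         dim = dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, count = count, domain = domain, id = id,
                   mask = mask),
              class = "labeled_image_sample")
  })
}

# Rejection-sample non-overlapping centres; footprint radius = r * extent.
place_blobs <- function(n, radii, extent, allow_overlap,
                        max_attempts_per_blob = 300L) {
  k <- length(radii)
  centers <- matrix(NA_real_, k, 2)
  fr <- radii * extent                    # footprint radii
  for (i in seq_len(k)) {
    placed <- FALSE
    for (att in seq_len(max_attempts_per_blob)) {
      cand <- runif(2, min = fr[i] + 1, max = n - fr[i])
      if (allow_overlap || i == 1L) {
        ok <- TRUE
      } else {
        prev <- seq_len(i - 1L)
        d <- sqrt((centers[prev, 1] - cand[1])^2 +
                  (centers[prev, 2] - cand[2])^2)
        ok <- all(d >= fr[prev] + fr[i] + 2)   # 2px gap keeps masks disjoint
      }
      if (ok) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("scene too crowded: failed to place blob ", i, " of ", k,
           " after ", max_attempts_per_blob, " attempts")
    }
  }
  centers
}

# Additively compose one blob (and optional halo ring) into the image.
# Disc profile is a Gaussian truncated at d = r, so the rendered support
# coincides exactly with the foreground mask.
draw_blob <- function(img, mask, center, r, color, halo) {
  n <- nrow(mask)
  rr <- r * blob_extent_factor(halo)
  h0 <- max(1L, floor(center[1] - rr)); h1 <- min(n, ceiling(center[1] + rr))
  w0 <- max(1L, floor(center[2] - rr)); w1 <- min(n, ceiling(center[2] + rr))
  hs <- h0:h1; ws <- w0:w1
  d <- sqrt(outer((hs - center[1])^2, (ws - center[2])^2, `+`))
  core <- exp(-0.5 * (d / (r / 2))^2) * (d <= r)
  add <- core
  if (halo) {
    ring <- 0.45 * exp(-0.5 * ((d - 1.25 * r) / (0.15 * r))^2) *
      (d > r & d <= 1.5 * r)
    add <- add + ring
  }
  for (ch in 1:3) {
    img[hs, ws, ch] <- img[hs, ws, ch] + add * color[ch]
  }
  mask[hs, ws] <- mask[hs, ws] | (d <= r)
  list(img = img, mask = mask)
}

#' @export
print.labeled_image_sample <- function(x, ...) {
  cat("labeled_image_sample", x$id, "| count:", x$count,
      "| domain:", x$domain, "| size:", dim(x$image)[1], "x",
      dim(x$image)[2], "\n")
  invisible(x)
}
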