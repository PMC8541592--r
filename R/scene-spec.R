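#' Specification of a synthetic cell-scene domain
#'
#' A `scene_spec` fixes every parameter of the synthetic renderer for one
#' image domain: geometry (image size, blob radii), appearance (blob colour,
#' per-channel colour jitter, optional cytoplasm-like halo ring, background
#' noise) and the closed integer count range from which per-image labels are
#' drawn. Covariate shift between two domains is expressed through the
#' appearance fields; label gap through `count_range`.
#'
#' The constructor checks a packing bound: `hi` blobs of maximal radius
#' (halo included) must fit into the usable image area at random-sequential
#' packing density, so that non-overlapping placement cannot be structurally
#' impossible.
#'
#' @param image_size Side length in pixels of the square image.
#' @param count_range Integer vector `c(lo, hi)`, the closed label range.
#' @param blob_radius_range Numeric `c(min, max)` blob radius in pixels.
#' @param blob_color Mean RGB triple in `[0,1]`.
#' @param color_jitter_sd Per-channel s.d. of the per-blob colour jitter.
#' @param halo Logical; render a cytoplasm-like ring around each blob.
#' @param background_noise_std S.d. of additive Gaussian pixel noise.
#' @param seed Integer seed governing dataset-level sampling.
#' @param allow_overlap Logical; permit overlapping blobs (disables the
#'   label-fidelity guarantee that mask components equal the count).
#' @return An object of class `scene_spec`.
#' @examples
#' sp <- scene_spec(image_size = 64, count_range = c(3, 8),
#'                  blob_radius_range = c(3, 5))
#' @export
scene_spec <- function(image_size = 256,
                       count_range = c(20L, 50L),
                       blob_radius_range = c(6, 9),
                       blob_color = c(0.25, 0.35, 0.90),
                       color_jitter_sd = 0.05,
                       halo = FALSE,
                       background_noise_std = 0.02,
                       seed = 1L,
                       allow_overlap = FALSE) {
  spec <- structure(list(
    image_size = as.integer(image_size),
    count_range = as.integer(count_range),
    blob_radius_range = as.numeric(blob_radius_range),
    blob_color = as.numeric(blob_color),
    color_jitter_sd = as.numeric(color_jitter_sd),
    halo = isTRUE(halo),
    background_noise_std = as.numeric(background_noise_std),
    seed = as.integer(seed),
    allow_overlap = isTRUE(allow_overlap)
  ), class = "scene_spec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  cr <- spec$count_range
  rr <- spec$blob_radius_range
  if (length(cr) != 2L || anyNA(cr) || cr[1] < 0L || cr[2] < cr[1]) {
    stop("count_range must be c(lo, hi) with 0 <= lo <= hi")
  }
  if (length(rr) != 2L || anyNA(rr) || rr[1] <= 0 || rr[2] < rr[1]) {
    stop("blob_radius_range must be positive and ordered")
  }
  if (length(spec$blob_color) != 3L ||
      any(spec$blob_color < 0 | spec$blob_color > 1)) {
    stop("blob_color must be an RGB triple in [0,1]")
  }
  if (spec$color_jitter_sd < 0 || spec$background_noise_std < 0) {
    stop("jitter and noise standard deviations must be non-negative")
  }
  if (spec$image_size < 16L) stop("image_size must be at least 16 pixels")
  if (!spec$allow_overlap) {
    r_eff <- rr[2] * blob_extent_factor(spec$halo)
    usable <- (spec$image_size - 2 * r_eff)^2
    # 0.45 < random-sequential-adsorption jamming density (~0.547) for disks
    if (usable <= 0 || cr[2] * pi * r_eff^2 > 0.45 * usable) {
      stop("scene too crowded: ", cr[2], " blobs of radius ", rr[2],
           " cannot be packed without overlap into a ", spec$image_size,
           "px image")
    }
  }
  spec
}

# halo ring extends the occupied footprint of a blob
blob_extent_factor <- function(halo) if (halo) 1.5 else 1.0

#' Derive a covariate- and/or label-shifted target domain from a source spec
#'
#' Builds a (source, target) pair of scene specifications where the target
#' differs from the source only in the requested parameters. Appearance
#' deltas (`blob_color`, `color_jitter_sd`, `halo`, `background_noise_std`)
#' induce covariate shift; `count_range` and `blob_radius_range` deltas
#' induce label gap (smaller blobs let a higher count fit the same frame).
#'
#' @param source_spec A [scene_spec()].
#' @param appearance_shift Named list of appearance-field replacements.
#' @param label_gap_shift Named list of `count_range` / `blob_radius_range`
#'   replacements.
#' @return `list(source = source_spec, target = <shifted scene_spec>)`.
#' @examples
#' s <- scene_spec(image_size = 64, count_range = c(3, 8),
#'                 blob_radius_range = c(3, 5))
#' pair <- make_shifted_pair(s,
#'   appearance_shift = list(blob_color = c(0.9, 0.25, 0.2), halo = TRUE),
#'   label_gap_shift = list(count_range = c(6, 12),
#'                          blob_radius_range = c(2, 3.5)))
#' @export
make_shifted_pair <- function(source_spec,
                              appearance_shift = list(),
                              label_gap_shift = list()) {
  stopifnot(inherits(source_spec, "scene_spec"))
  appearance_keys <- c("blob_color", "color_jitter_sd", "halo",
                       "background_noise_std")
  label_keys <- c("count_range", "blob_radius_range")
  bad_a <- setdiff(names(appearance_shift), appearance_keys)
  bad_l <- setdiff(names(label_gap_shift), label_keys)
  if (length(bad_a)) stop("unknown appearance_shift fields: ",
                          paste(bad_a, collapse = ", "))
  if (length(bad_l)) stop("unknown label_gap_shift fields: ",
                          paste(bad_l, collapse = ", "))
  target <- unclass(source_spec)
  target <- modifyList(target, c(appearance_shift, label_gap_shift))
  target <- structure(target, class = "scene_spec")
  target$count_range <- as.integer(target$count_range)
  list(source = source_spec, target = validate_scene_spec(target))
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("scene_spec:", x$image_size, "x", x$image_size,
      "| counts [", x$count_range[1], ",", x$count_range[2], "]",
      "| radius [", x$blob_radius_range[1], ",", x$blob_radius_range[2], "]",
      "| halo:", x$halo, "\n")
  invisible(x)
}

#' Read or write a scene specification as YAML
#'
#' @param spec A [scene_spec()].
#' @param path File path.
#' @return `read_scene_spec` returns a `scene_spec`; `write_scene_spec`
#'   returns `path` invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("count_range")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("scene spec YAML is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  do.call(scene_spec, raw[intersect(names(raw), names(formals(scene_spec)))])
}
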