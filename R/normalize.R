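#' Min-max label normalisation
#'
#' Maps labels from the source range `[a, b]` onto `[0, 1]` via
#' `(y - a) / (b - a)`. The regressor is pretrained against normalised
#' labels so that the same network can later be remapped onto a different
#' target range by fine-tuning alone, which is what mitigates the label
#' gap between domains.
#'
#' @param labels Numeric labels.
#' @param a,b Range endpoints with `b > a` (typically the minimum and
#'   maximum source training label).
#' @param clamp If `TRUE`, labels outside `[a, b]` are clamped (with a
#'   warning) instead of raising an error.
#' @return Normalised labels in `[0, 1]`.
#' @examples
#' normalize_labels(35, 20, 50)  # 0.5
#' @export
normalize_labels <- function(labels, a, b, clamp = FALSE) {
  if (b <= a) stop("invalid label range: b (", b, ") must exceed a (", a, ")")
  labels <- as.numeric(labels)
  out_of_range <- labels < a | labels > b
  if (any(out_of_range)) {
    if (!clamp) {
      stop(sum(out_of_range), " label(s) outside [", a, ", ", b, "]")
    }
    warning(sum(out_of_range), " label(s) clamped into [", a, ", ", b, "]")
    labels <- pmin(pmax(labels, a), b)
  }
  (labels - a) / (b - a)
}

#' Fit a label normalizer from training labels
#'
#' @param labels Numeric source training labels.
#' @return Object of class `label_normalizer` with fields `a` (min) and
#'   `b` (max).
#' @export
label_normalizer <- function(labels) {
  if (length(labels) == 0L) stop("cannot fit a normalizer on empty labels")
  a <- min(labels); b <- max(labels)
  if (b <= a) {
    stop("degenerate labels: all equal to ", a,
         " (label range must be non-trivial)")
  }
  structure(list(a = a, b = b), class = "label_normalizer")
}

#' Invert the label normalisation
#'
#' @param values Values on the normalised `[0,1]` scale.
#' @param normalizer A [label_normalizer()].
#' @return Values mapped back to `[a, b]`.
#' @export
denormalize_labels <- function(values, normalizer) {
  stopifnot(inherits(normalizer, "label_normalizer"))
  values * (normalizer$b - normalizer$a) + normalizer$a
}

#' @export
print.label_normalizer <- function(x, ...) {
  cat("label_normalizer: [", x$a, ",", x$b, "] -> [0, 1]\n")
  invisible(x)
}
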