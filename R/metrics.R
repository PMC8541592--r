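#' Counting evaluation metrics
#'
#' Computes the standard holistic-counting metrics from integer ground
#' truth and real-valued predictions. With the per-image error
#' `e_i = y_i - round(yhat_i)` (rounding half away from zero):
#' absolute difference in count `|DiC| = mean(|e|)`, signed difference in
#' count `DiC = mean(e)`, `MSE = mean(e^2)`, and percentage agreement, the
#' percentage of images with `e_i = 0`. Standard deviations are population
#' (divide by n) standard deviations.
#'
#' @param y_true Integer counts.
#' @param y_pred Real-valued predictions (rounded internally; predictions
#'   are produced as reals and only the metrics round them).
#' @return A `count_metrics` list: `abs_dic_mean`, `abs_dic_std`,
#'   `dic_mean`, `dic_std`, `mse`, `pct_agree` (0-100), `n`.
#' @examples
#' compute_metrics(c(5, 7), c(5.4, 6.6))  # perfect after rounding
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true)
  y_pred <- as.numeric(y_pred)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  }
  if (anyNA(y_true) || anyNA(y_pred)) stop("NA values in metrics input")
  eps <- y_true - round_half_away(y_pred)
  n <- length(eps)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  structure(list(
    abs_dic_mean = mean(abs(eps)),
    abs_dic_std = pop_sd(abs(eps)),
    dic_mean = mean(eps),
    dic_std = pop_sd(eps),
    mse = mean(eps^2),
    pct_agree = 100 * mean(eps == 0),
    n = n
  ), class = "count_metrics")
}

# round() in R rounds half to even; counting uses half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf(
    "|DiC| %.2f(%.2f)  DiC %.2f(%.2f)  MSE %.2f  %% %.1f  (n=%d)\n",
    x$abs_dic_mean, x$abs_dic_std, x$dic_mean, x$dic_std, x$mse,
    x$pct_agree, x$n))
  invisible(x)
}

#' Bind per-condition metric reports into a table
#'
#' @param reports Named list of `count_metrics` objects (names become the
#'   `condition` column).
#' @return `data.frame` with one row per condition.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(condition = nm, abs_dic_mean = r$abs_dic_mean,
               abs_dic_std = r$abs_dic_std, dic_mean = r$dic_mean,
               dic_std = r$dic_std, mse = r$mse, pct_agree = r$pct_agree,
               n = r$n, stringsAsFactors = FALSE)
  }))
}

#' Write / read a metrics report CSV
#'
#' @param tab `data.frame` from [metrics_table()].
#' @param path CSV path.
#' @return `write_metrics_csv` returns `path` invisibly; `read_metrics_csv`
#'   the `data.frame`.
#' @export
write_metrics_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
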