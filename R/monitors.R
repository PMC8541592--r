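#' Kernel specification for the MMD monitor
#'
#' @param family Kernel family; only `"rbf"` is implemented.
#' @param bandwidth Positive fixed bandwidth (the `sigma` of
#'   `exp(-||x-y||^2 / (2 sigma^2))`), or `NULL` to use the median
#'   heuristic: the median of the pooled pairwise Euclidean distances.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = "rbf", bandwidth = NULL) {
  if (!identical(family, "rbf")) stop("unknown kernel family: ", family)
  if (!is.null(bandwidth) && bandwidth <= 0) {
    stop("fixed bandwidth must be > 0")
  }
  structure(list(family = family, bandwidth = bandwidth),
            class = "kernel_spec")
}

#' Squared maximum mean discrepancy between two feature batches
#'
#' Biased empirical estimator of the squared RKHS distance between the mean
#' embeddings of two samples,
#' `(1/M^2) sum k(x_i, x_j) + (1/N^2) sum k(y_i, y_j) - (2/MN) sum k(x_i, y_j)`,
#' clipped at zero against negative round-off. Used as an unsupervised
#' proxy for residual covariate shift between source and target features.
#'
#' @param X `M x F` matrix (rows are samples).
#' @param Y `N x F` matrix.
#' @param kernel A [kernel_spec()].
#' @return Non-negative scalar MMD^2.
#' @examples
#' X <- matrix(rnorm(40), 10)
#' mmd2(X, X)  # 0
#' @export
mmd2 <- function(X, Y, kernel = kernel_spec()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop("feature width mismatch: ", ncol(X), " vs ", ncol(Y))
  }
  M <- nrow(X); N <- nrow(Y)
  if (M < 1L || N < 1L) stop("both batches must be non-empty")
  Z <- rbind(X, Y)
  sq <- rowSums(Z^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Z)
  D2[D2 < 0] <- 0
  sigma <- kernel$bandwidth
  if (is.null(sigma)) {
    d <- sqrt(D2[upper.tri(D2)])
    sigma <- median(d[d > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  K <- exp(-D2 / (2 * sigma^2))
  ix <- seq_len(M); iy <- M + seq_len(N)
  val <- sum(K[ix, ix]) / M^2 + sum(K[iy, iy]) / N^2 -
    2 * sum(K[ix, iy]) / (M * N)
  max(val, 0)
}

#' Deviation of the discriminator from GAN global optimality
#'
#' At the adversarial optimum the discriminator outputs 1/2 on every
#' feature, so `|mean(D(z)) - 1/2|` over features pooled from both domains
#' measures the distance from optimality; it lies in `[0, 1/2]`.
#'
#' @param outputs Discriminator probabilities in `(0,1)`, pooled over
#'   source and target features.
#' @return Scalar in `[0, 1/2]`.
#' @export
ggo <- function(outputs) {
  outputs <- as.numeric(outputs)
  if (length(outputs) == 0L) stop("ggo needs at least one output")
  if (anyNA(outputs) || any(outputs < 0 | outputs > 1)) {
    stop("discriminator outputs must lie in [0,1]")
  }
  abs(mean(outputs) - 0.5)
}

#' Joint patience-based stopping state for adversarial adaptation
#'
#' Tracks the best (smallest) MMD and GGO values seen so far and, for each,
#' the number of epochs since it last strictly improved. Training stops
#' when the monitored signals have all been stale for `patience` epochs.
#' `mode` selects the joint rule (`"both"`, the default) or the
#' single-signal ablations (`"mmd"`, `"ggo"`).
#'
#' @param patience Integer `>= 1`; default 10.
#' @param mode `"both"`, `"mmd"` or `"ggo"`.
#' @param tol Improvements smaller than `tol` count as ties and do not
#'   reset the counters.
#' @return Object of class `stopping_state`.
#' @export
stopping_state <- function(patience = 10L, mode = c("both", "mmd", "ggo"),
                           tol = 1e-6) {
  mode <- match.arg(mode)
  patience <- as.integer(patience)
  if (patience < 1L) stop("patience must be >= 1")
  structure(list(patience = patience, mode = mode, tol = tol,
                 epoch = 0L,
                 best_mmd = Inf, best_ggo = Inf,
                 since_mmd = 0L, since_ggo = 0L,
                 best_epoch = 0L),
            class = "stopping_state")
}

#' Record pre-training monitor values as the improvement baseline
#'
#' Sets the best-so-far monitor values from an epoch-0 (pre-adaptation)
#' measurement without counting an epoch: subsequent epochs must then
#' strictly improve on the initial state for the counters to reset, so a
#' run that never beats its starting point stops after exactly `patience`
#' epochs and restores the initial snapshot.
#'
#' @param state A [stopping_state()].
#' @param mmd0,ggo0 Finite monitor values measured before training.
#' @return The updated state.
#' @export
set_monitor_baseline <- function(state, mmd0, ggo0) {
  stopifnot(inherits(state, "stopping_state"))
  if (!is.finite(mmd0) || !is.finite(ggo0)) {
    stop("non-finite baseline monitor value (mmd2=", mmd0,
         ", ggo=", ggo0, ")")
  }
  state$best_mmd <- mmd0
  state$best_ggo <- ggo0
  state
}

#' Advance the stopping state by one epoch of monitor values
#'
#' A strict improvement (decrease by more than `tol`) of a monitor resets
#' its no-improvement counter and records the new best; otherwise the
#' counter increments. `should_stop` is `TRUE` once every monitored signal
#' has been stale for at least `patience` epochs. `best_epoch` indexes the
#' snapshot to restore: the epoch with the best MMD (ties resolved by the
#' best GGO; in `"ggo"` mode the best-GGO epoch).
#'
#' @param state A [stopping_state()].
#' @param epoch_mmd,epoch_ggo Finite monitor values for this epoch.
#' @return `list(state = <updated state>, should_stop = <logical>)`.
#' @export
update_monitor <- function(state, epoch_mmd, epoch_ggo) {
  stopifnot(inherits(state, "stopping_state"))
  if (!is.finite(epoch_mmd) || !is.finite(epoch_ggo)) {
    stop("non-finite monitor value at epoch ", state$epoch + 1L,
         " (mmd2=", epoch_mmd, ", ggo=", epoch_ggo, ")")
  }
  state$epoch <- state$epoch + 1L
  mmd_improved <- epoch_mmd < state$best_mmd - state$tol
  ggo_improved <- epoch_ggo < state$best_ggo - state$tol
  if (mmd_improved) {
    state$best_mmd <- epoch_mmd
    state$since_mmd <- 0L
    if (state$mode != "ggo") state$best_epoch <- state$epoch
  } else {
    state$since_mmd <- state$since_mmd + 1L
  }
  if (ggo_improved) {
    state$best_ggo <- epoch_ggo
    state$since_ggo <- 0L
    if (state$mode == "ggo" ||
        (state$mode == "both" && !mmd_improved &&
         abs(epoch_mmd - state$best_mmd) <= state$tol)) {
      state$best_epoch <- state$epoch
    }
  } else {
    state$since_ggo <- state$since_ggo + 1L
  }
  should_stop <- switch(state$mode,
    both = state$since_mmd >= state$patience &&
           state$since_ggo >= state$patience,
    mmd = state$since_mmd >= state$patience,
    ggo = state$since_ggo >= state$patience)
  list(state = state, should_stop = should_stop)
}

#' @export
print.stopping_state <- function(x, ...) {
  cat("stopping_state[", x$mode, "] epoch", x$epoch,
      "| best mmd2", signif(x$best_mmd, 4), "(stale", x$since_mmd, ")",
      "| best ggo", signif(x$best_ggo, 4), "(stale", x$since_ggo, ")",
      "| best epoch", x$best_epoch, "\n")
  invisible(x)
}
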