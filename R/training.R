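#' Configuration for one training stage
#'
#' @param lr_head Adam learning rate for the dense heads (regressor,
#'   discriminator).
#' @param lr_fe Learning rate for the feature extractor during
#'   pretraining.
#' @param lr_phi Learning rate for the target feature extractor during
#'   adversarial adaptation (kept lower than the heads so the generator
#'   does not outrun the discriminator).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs (0 = no-op training).
#' @param lambda Weight of the output-variance regulariser in the
#'   generator objective; `>= 0`, 0 disables it.
#' @param patience Early-stopping patience in epochs.
#' @param augment Apply flip + colour-jitter augmentation (training only).
#' @param monitor_n Maximum feature vectors per domain fed to the MMD/GGO
#'   monitors each epoch.
#' @param seed Integer seed for all stage randomness.
#' @return List of class `stage_config`.
#' @export
stage_config <- function(lr_head = 1e-4, lr_fe = 1e-4, lr_phi = 1e-5,
                         batch_size = 32L, max_epochs = 50L, lambda = 0.1,
                         patience = 10L, augment = TRUE, monitor_n = 256L,
                         seed = 1L) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (patience < 1L) stop("patience must be >= 1")
  structure(list(lr_head = lr_head, lr_fe = lr_fe, lr_phi = lr_phi,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lambda = lambda,
                 patience = as.integer(patience), augment = isTRUE(augment),
                 monitor_n = as.integer(monitor_n), seed = as.integer(seed)),
            class = "stage_config")
}

mse_loss <- function(yhat, y) mean((yhat - y)^2)

# joint forward/backward/update of extractor + regressor on one batch
supervised_step <- function(fe, reg, X, y, B, opt_fe, opt_reg) {
  ffe <- net_forward(fe, X, B)
  freg <- net_forward(reg, ffe$out)
  yhat <- as.numeric(freg$out)
  loss <- mse_loss(yhat, y)
  dY <- matrix(2 * (yhat - y) / B, B, 1)
  bk_reg <- net_backward(reg, freg$caches, dY, B)
  bk_fe <- net_backward(fe, ffe$caches, bk_reg$dX, B,
                        need_input_grad = FALSE)
  adam_step(reg, bk_reg$grads, opt_reg)
  adam_step(fe, bk_fe$grads, opt_fe)
  loss
}

#' Stage A: supervised pretraining on the source domain
#'
#' Fits the label normalizer on the source training labels, then trains
#' the feature extractor and regressor jointly with an MSE loss against
#' normalised labels. Validation MSE is monitored each epoch for early
#' stopping; the checkpoint with the best validation MSE is returned.
#'
#' @param fe,regressor Networks from [build_models()] (trained in place;
#'   the returned networks carry the best-epoch weights).
#' @param source_train,source_val `count_dataset`s.
#' @param cfg A [stage_config()].
#' @return List with `feature_extractor`, `regressor`, `normalizer`, and
#'   `history` (per-epoch train/validation MSE on the normalised scale).
#' @export
pretrain <- function(fe, regressor, source_train, source_val, cfg) {
  stopifnot(inherits(source_train, "count_dataset"))
  n <- length(source_train$counts)
  if (n == 0L) stop("empty training set")
  normalizer <- label_normalizer(source_train$counts)
  y_train <- normalize_labels(source_train$counts, normalizer$a,
                              normalizer$b)
  y_val <- normalize_labels(source_val$counts, normalizer$a, normalizer$b,
                            clamp = TRUE)
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  if (cfg$max_epochs == 0L) {
    return(list(feature_extractor = fe, regressor = regressor,
                normalizer = normalizer, history = history))
  }
  opt_fe <- adam_new(lr = cfg$lr_fe)
  opt_reg <- adam_new(lr = cfg$lr_head)
  best_val <- Inf
  best <- list(fe = net_params(fe), reg = net_params(regressor))
  stale <- 0L
  with_seed_(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      imgs <- source_train$images
      if (cfg$augment) imgs <- augment_images(imgs)
      ds <- list(images = imgs)
      B <- min(cfg$batch_size, n)
      losses <- c()
      for (start in seq(1L, n - B + 1L, by = B)) {
        idx <- perm[start:(start + B - 1L)]
        X <- dataset_batch(ds, idx)
        loss <- supervised_step(fe, regressor, X, y_train[idx], B,
                                opt_fe, opt_reg)
        if (!is.finite(loss)) {
          stop("NaN/Inf pretraining loss at epoch ", epoch,
               " (lr too high or degenerate inputs)")
        }
        losses <- c(losses, loss)
      }
      val_pred <- predict_counts(fe, regressor, source_val)
      val_mse <- mse_loss(val_pred, y_val)
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), val_mse)
      if (val_mse < best_val - 1e-9) {
        best_val <- val_mse
        best <- list(fe = net_params(fe), reg = net_params(regressor))
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
  })
  net_set_params(fe, best$fe)
  net_set_params(regressor, best$reg)
  list(feature_extractor = fe, regressor = regressor,
       normalizer = normalizer, history = history)
}

#' Population variance of regressor outputs
#'
#' The quantity the adaptation stage maximises (scaled by `lambda`) to
#' prevent posterior collapse: if all target predictions coincide the
#' variance is zero.
#'
#' @param predictions Numeric vector of length `>= 2`.
#' @return Population variance (`mean((x - mean(x))^2)`).
#' @export
variance_penalty <- function(predictions) {
  predictions <- as.numeric(predictions)
  if (length(predictions) < 2L) {
    stop("variance_penalty needs at least 2 predictions")
  }
  mean((predictions - mean(predictions))^2)
}

resolve_features <- function(net, batch, keep_cache = FALSE) {
  if (is.matrix(batch)) {
    return(list(out = batch, caches = NULL, is_feat = TRUE))
  }
  if (inherits(batch, "count_dataset")) batch <- batch$images
  if (length(dim(batch)) == 3L) batch <- array(batch, c(dim(batch), 1L))
  B <- dim(batch)[4]
  X <- dataset_batch(list(images = batch), seq_len(B))
  r <- net_forward(net, X, B, keep_cache = keep_cache)
  list(out = r$out, caches = r$caches, X = X, B = B, is_feat = FALSE)
}

#' One discriminator update of the adversarial stage
#'
#' Cross-entropy of real-vs-1 on source features and fake-vs-0 on target
#' features: `mean(-log D(phi_S(s))) + mean(-log(1 - D(phi_T(t))))`.
#' Gradients touch only the discriminator parameters; pass `opt = NULL`
#' to compute the loss without updating.
#'
#' @param d Discriminator.
#' @param phi_S,phi_T Source / target feature extractors (ignored when the
#'   batches are already feature matrices).
#' @param source_batch,target_batch Image arrays (`H x W x 3 x B`) or
#'   `B x F` feature matrices.
#' @param opt Adam state from `adam_new`, or `NULL` for loss-only.
#' @return Scalar loss.
#' @export
discriminator_step <- function(d, phi_S, phi_T, source_batch, target_batch,
                               opt = NULL) {
  fs <- resolve_features(phi_S, source_batch)$out
  ft <- resolve_features(phi_T, target_batch)$out
  Ms <- nrow(fs); Mt <- nrow(ft)
  if (Ms == 0L || Mt == 0L) stop("empty batch in discriminator_step")
  rs <- net_forward(d, fs)
  rt <- net_forward(d, ft)
  ps <- pmin(pmax(as.numeric(rs$out), 1e-12), 1 - 1e-12)
  pt <- pmin(pmax(as.numeric(rt$out), 1e-12), 1 - 1e-12)
  loss <- mean(-log(ps)) + mean(-log(1 - pt))
  if (!is.null(opt)) {
    bs <- net_backward(d, rs$caches, matrix(-1 / (Ms * ps), Ms, 1), Ms,
                       need_input_grad = FALSE)
    bt <- net_backward(d, rt$caches, matrix(1 / (Mt * (1 - pt)), Mt, 1), Mt,
                       need_input_grad = FALSE)
    grads <- Map(function(g1, g2) {
      if (is.null(g1$dW)) return(g1)
      list(dW = g1$dW + g2$dW, db = g1$db + g2$db)
    }, bs$grads, bt$grads)
    adam_step(d, grads, opt)
  }
  loss
}

#' One generator update of the adversarial stage
#'
#' The target extractor is trained to fool the discriminator
#' (`mean(-log D(phi_T(t)))`, i.e. fake-vs-1 cross-entropy) minus `lambda`
#' times the population variance of the frozen regressor's outputs on the
#' same features. Gradients touch only the target-extractor parameters.
#'
#' @param d Discriminator (frozen here).
#' @param phi_T Target feature extractor, or `NULL` when `target_batch` is
#'   a feature matrix (loss-only mode).
#' @param regressor Frozen regressor providing the variance term.
#' @param target_batch Image array or `B x F` feature matrix.
#' @param lambda Variance-regulariser weight; needs batch size `>= 2` when
#'   positive.
#' @param opt Adam state for `phi_T`, or `NULL` for loss-only.
#' @return Scalar loss `CE - lambda * variance`.
#' @export
generator_step <- function(d, phi_T, regressor, target_batch, lambda = 0.1,
                           opt = NULL) {
  rt <- resolve_features(phi_T, target_batch, keep_cache = TRUE)
  feats <- rt$out
  B <- nrow(feats)
  if (B == 0L) stop("empty batch in generator_step")
  if (lambda > 0 && B < 2L) {
    stop("variance regulariser (lambda > 0) requires batch size >= 2")
  }
  fd <- net_forward(d, feats)
  p <- pmin(pmax(as.numeric(fd$out), 1e-12), 1 - 1e-12)
  loss <- mean(-log(p))
  yhat <- NULL
  if (lambda > 0) {
    fr <- net_forward(regressor, feats)
    yhat <- as.numeric(fr$out)
    loss <- loss - lambda * variance_penalty(yhat)
  }
  if (!is.null(opt) && !rt$is_feat) {
    bd <- net_backward(d, fd$caches, matrix(-1 / (B * p), B, 1), B)
    dFeats <- bd$dX
    if (lambda > 0) {
      dVar <- matrix(-lambda * 2 * (yhat - mean(yhat)) / B, B, 1)
      br <- net_backward(regressor, fr$caches, dVar, B)
      dFeats <- dFeats + br$dX
    }
    bphi <- net_backward(phi_T, rt$caches, dFeats, B,
                         need_input_grad = FALSE)
    adam_step(phi_T, bphi$grads, opt)
  }
  loss
}

#' Stage B: adversarial feature alignment
#'
#' Clones the frozen source extractor into a target extractor `phi_T` and
#' alternates one discriminator update with one generator update per batch
#' pair. After every epoch the squared MMD between held-out source features
#' (from `phi_S`) and target features (from `phi_T`) and the discriminator
#' optimality deviation (GGO) are recorded; training stops when the joint
#' patience rule of `monitors` fires or `max_epochs` is reached, and the
#' `phi_T` snapshot from the best monitored epoch is restored.
#'
#' @param phi_S Frozen source feature extractor.
#' @param regressor Frozen regressor (used by the variance regulariser).
#' @param target_train,source_train `count_dataset`s (labels unused: this
#'   stage is unsupervised).
#' @param discriminator Discriminator network (trained in place).
#' @param cfg A [stage_config()]; `cfg$lambda` weighs the variance
#'   regulariser.
#' @param monitors A [stopping_state()].
#' @param source_monitor,target_monitor Held-out `count_dataset`s for the
#'   monitor statistics (default: the training sets).
#' @param kernel [kernel_spec()] for the MMD.
#' @param keep_snapshots Keep all per-epoch `phi_T` parameter snapshots in
#'   the result (used by the stopping-rule ablations).
#' @return List with `phi_T` (restored to the best epoch), `discriminator`,
#'   `trace` (per-epoch monitor CSV-ready data.frame), `best_epoch`, and
#'   optionally `snapshots`.
#' @export
adapt <- function(phi_S, regressor, target_train, source_train,
                  discriminator, cfg, monitors = stopping_state(cfg$patience),
                  source_monitor = NULL, target_monitor = NULL,
                  kernel = kernel_spec(), keep_snapshots = FALSE) {
  stopifnot(inherits(target_train, "count_dataset"))
  nt <- length(target_train$counts)
  ns <- length(source_train$counts)
  if (nt == 0L) stop("empty target training set")
  source_monitor <- source_monitor %||% source_train
  target_monitor <- target_monitor %||% target_train
  phi_T <- net_clone(phi_S)
  if (cfg$max_epochs == 0L) {
    return(list(phi_T = phi_T, discriminator = discriminator,
                trace = empty_trace(), best_epoch = 0L,
                snapshots = list(`0` = net_params(phi_T))))
  }
  opt_d <- adam_new(lr = cfg$lr_head)
  opt_phi <- adam_new(lr = cfg$lr_phi)
  theta_S_before <- net_params(phi_S)
  reg_before <- net_params(regressor)
  B <- min(cfg$batch_size, ns, nt)
  if (cfg$lambda > 0 && B < 2L) stop("batch size must be >= 2 when lambda > 0")
  nb <- max(1L, min(ns %/% B, nt %/% B))
  trace <- empty_trace()
  snapshots <- list(`0` = net_params(phi_T))

  mon <- function() {
    fs <- monitor_features(phi_S, source_monitor, cfg$monitor_n)
    ft <- monitor_features(phi_T, target_monitor, cfg$monitor_n)
    pooled <- discriminate(discriminator, rbind(fs, ft))
    c(mmd2(fs, ft, kernel), ggo(pooled))
  }

  with_seed_(cfg$seed, {
    m0 <- mon()
    monitors <- set_monitor_baseline(monitors, m0[1], m0[2])
    trace[1L, ] <- list(0L, m0[1], m0[2], 0L, 0L, FALSE)
    for (epoch in seq_len(cfg$max_epochs)) {
      perm_s <- sample.int(ns)
      perm_t <- sample.int(nt)
      simgs <- source_train$images
      timgs <- target_train$images
      if (cfg$augment) {
        simgs <- augment_images(simgs)
        timgs <- augment_images(timgs)
      }
      sds <- list(images = simgs); tds <- list(images = timgs)
      for (bi in seq_len(nb)) {
        is_ <- perm_s[((bi - 1L) * B + 1L):(bi * B)]
        it_ <- perm_t[((bi - 1L) * B + 1L):(bi * B)]
        sb <- array(sds$images[, , , is_], c(dim(simgs)[1:3], B))
        tb <- array(tds$images[, , , it_], c(dim(timgs)[1:3], B))
        dl <- discriminator_step(discriminator, phi_S, phi_T, sb, tb, opt_d)
        gl <- generator_step(discriminator, phi_T, regressor, tb,
                             cfg$lambda, opt_phi)
        if (!is.finite(dl) || !is.finite(gl)) {
          stop("NaN/Inf adversarial loss at epoch ", epoch, " batch ", bi,
               " (d=", dl, ", g=", gl, ")")
        }
      }
      m <- mon()
      upd <- update_monitor(monitors, m[1], m[2])
      monitors <- upd$state
      snapshots[[as.character(epoch)]] <- net_params(phi_T)
      trace[nrow(trace) + 1L, ] <- list(epoch, m[1], m[2],
                                        monitors$since_mmd,
                                        monitors$since_ggo, upd$should_stop)
      if (upd$should_stop) break
    }
  })
  stopifnot(identical(theta_S_before, net_params(phi_S)),
            identical(reg_before, net_params(regressor)))
  best_epoch <- monitors$best_epoch
  net_set_params(phi_T, snapshots[[as.character(best_epoch)]])
  out <- list(phi_T = phi_T, discriminator = discriminator, trace = trace,
              best_epoch = best_epoch, monitors = monitors)
  if (keep_snapshots) out$snapshots <- snapshots
  out
}

empty_trace <- function() {
  data.frame(epoch = integer(), mmd2 = numeric(), ggo = numeric(),
             since_mmd = integer(), since_ggo = integer(),
             stopped = logical())
}

monitor_features <- function(net, ds, monitor_n) {
  n <- length(ds$counts)
  idx <- seq_len(min(n, monitor_n))
  x <- ds$images[, , , idx, drop = FALSE]
  X <- dataset_batch(list(images = x), seq_along(idx))
  net_forward(net, X, length(idx), keep_cache = FALSE)$out
}

#' Stage C: semi-supervised fine-tuning of the regressor
#'
#' Freezes the adapted target extractor and retrains only the regressor on
#' a handful of labelled target images against their raw (unnormalised)
#' counts. Because the extractor stays fixed, this step is what remaps the
#' network's `[0,1]`-scale outputs onto the target label range; subsequent
#' predictions need no explicit denormalisation.
#'
#' @param phi_T Adapted (frozen) target feature extractor.
#' @param regressor Regressor to fine-tune; the input object is not
#'   modified.
#' @param labelled_subset `count_dataset` with `k >= 1` labelled target
#'   images.
#' @param cfg A [stage_config()]; `max_epochs = 0` returns an unchanged
#'   copy.
#' @return The fine-tuned regressor.
#' @export
finetune <- function(phi_T, regressor, labelled_subset, cfg) {
  stopifnot(inherits(labelled_subset, "count_dataset"))
  k <- length(labelled_subset$counts)
  if (k == 0L) stop("empty fine-tuning subset")
  reg <- net_clone(regressor)
  if (cfg$max_epochs == 0L) return(reg)
  feats <- extract_features(phi_T, labelled_subset)
  y <- as.numeric(labelled_subset$counts)
  opt <- adam_new(lr = cfg$lr_head)
  with_seed_(cfg$seed, {
    B <- min(cfg$batch_size, k)
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(k)
      for (start in seq(1L, k - B + 1L, by = B)) {
        idx <- perm[start:(start + B - 1L)]
        fr <- net_forward(reg, feats[idx, , drop = FALSE])
        yhat <- as.numeric(fr$out)
        dY <- matrix(2 * (yhat - y[idx]) / length(idx), length(idx), 1)
        bk <- net_backward(reg, fr$caches, dY, length(idx),
                           need_input_grad = FALSE)
        adam_step(reg, bk$grads, opt)
      }
    }
  })
  reg
}

#' Predict counts for a batch of images
#'
#' @param phi Feature extractor.
#' @param regressor Regressor head.
#' @param images `H x W x 3 x B` array or `count_dataset` (preprocessed as
#'   in training).
#' @return Numeric vector of real-valued count predictions (rounding is
#'   left to the metrics).
#' @export
predict_counts <- function(phi, regressor, images) {
  feats <- extract_features(phi, images)
  as.numeric(net_forward(regressor, feats, keep_cache = FALSE)$out)
}
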