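# Shared toy study conditions: a miniature source -> shifted-target cell
# counting problem (64px scenes, ~300 images per domain, F = 128 backbone).
# Heavy intermediate results are memoised across test files.

toy_cache <- new.env()

toy_source_spec <- function() {
  scene_spec(image_size = 64, count_range = c(3L, 8L),
             blob_radius_range = c(3, 5),
             blob_color = c(0.25, 0.35, 0.90), seed = 11L)
}

# T3-style shift: red, smaller, halo'd blobs with an overlapping-but-larger
# count range.
toy_pair <- function() {
  make_shifted_pair(
    toy_source_spec(),
    appearance_shift = list(blob_color = c(0.90, 0.25, 0.20), halo = TRUE),
    label_gap_shift = list(count_range = c(6L, 12L),
                           blob_radius_range = c(2, 3.5)))
}

toy_data_dir <- function(n = 300L) {
  key <- paste0("dir_", n)
  if (is.null(toy_cache[[key]])) {
    d <- file.path(tempdir(), paste0("countda_toy_", n))
    pair <- toy_pair()
    tgt <- pair$target
    tgt$seed <- 12L
    generate_dataset(pair$source, n, out_dir = file.path(d, "source"),
                     domain = "source")
    generate_dataset(tgt, n, out_dir = file.path(d, "target"),
                     domain = "target")
    toy_cache[[key]] <- d
  }
  toy_cache[[key]]
}

toy_datasets <- function(n = 300L) {
  key <- paste0("ds_", n)
  if (is.null(toy_cache[[key]])) {
    d <- toy_data_dir(n)
    toy_cache[[key]] <- list(
      s_train = load_dataset(file.path(d, "source"), "train", 64),
      s_val = load_dataset(file.path(d, "source"), "val", 64),
      t_train = load_dataset(file.path(d, "target"), "train", 64),
      t_val = load_dataset(file.path(d, "target"), "val", 64),
      t_test = load_dataset(file.path(d, "target"), "test", 64))
  }
  toy_cache[[key]]
}

toy_model_config <- function(seed) {
  list(feature_dim = 128L, image_size = 64L, seed = seed)
}
toy_pretrain_cfg <- function(seed) {
  stage_config(lr_head = 1e-3, lr_fe = 1e-3, max_epochs = 30L,
               patience = 8L, seed = seed)
}
toy_adapt_cfg <- function(seed, lambda = 0.1) {
  stage_config(lr_head = 1e-3, lr_phi = 1e-5, max_epochs = 25L,
               lambda = lambda, patience = 10L, seed = seed)
}
toy_finetune_cfg <- function(seed) {
  stage_config(lr_head = 1e-2, max_epochs = 200L, augment = FALSE,
               seed = seed)
}

toy_stage_a <- function(seed) {
  key <- paste0("stage_a_", seed)
  if (is.null(toy_cache[[key]])) {
    ds <- toy_datasets()
    models <- build_models(toy_model_config(seed))
    toy_cache[[key]] <- pretrain(models$feature_extractor, models$regressor,
                                 ds$s_train, ds$s_val,
                                 toy_pretrain_cfg(seed))
  }
  toy_cache[[key]]
}

toy_adaptation <- function(seed, lambda = 0.1) {
  key <- paste0("adapt_", seed, "_", lambda)
  if (is.null(toy_cache[[key]])) {
    ds <- toy_datasets()
    a <- toy_stage_a(seed)
    disc <- build_models(toy_model_config(seed))$discriminator
    toy_cache[[key]] <- adapt(a$feature_extractor, a$regressor, ds$t_train,
                              ds$s_train, disc,
                              toy_adapt_cfg(seed, lambda),
                              source_monitor = ds$s_val,
                              target_monitor = ds$t_val,
                              keep_snapshots = TRUE)
  }
  toy_cache[[key]]
}

toy_finetuned_mse <- function(seed, phi_T, k = 50L) {
  ds <- toy_datasets()
  a <- toy_stage_a(seed)
  sub <- countda:::draw_label_subset(ds$t_train, k, seed)
  reg <- finetune(phi_T, a$regressor, sub, toy_finetune_cfg(seed))
  compute_metrics(ds$t_test$counts,
                  predict_counts(phi_T, reg, ds$t_test))$mse
}

toy_bounds <- function(seed) {
  key <- paste0("bounds_", seed)
  if (is.null(toy_cache[[key]])) {
    ds <- toy_datasets()
    a <- toy_stage_a(seed)
    ad <- toy_adaptation(seed)
    mc <- toy_model_config(seed)
    mc$seed <- seed + 1000L
    toy_cache[[key]] <- evaluate_bounds(a, ad$phi_T, ds$t_train, ds$t_val,
                                        ds$t_test, k = 50L,
                                        cfg_finetune = toy_finetune_cfg(seed),
                                        lb_cfg = toy_pretrain_cfg(seed),
                                        model_config = mc)
  }
  toy_cache[[key]]
}

# Independent O((M+N)^2) double-loop oracle for the biased MMD^2 estimator
# with a fixed-bandwidth RBF kernel.
mmd2_oracle <- function(X, Y, sigma) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  M <- nrow(X); N <- nrow(Y)
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) {
    sxx <- sxx + k(X[i, ], X[j, ])
  }
  for (i in seq_len(N)) for (j in seq_len(N)) {
    syy <- syy + k(Y[i, ], Y[j, ])
  }
  for (i in seq_len(M)) for (j in seq_len(N)) {
    sxy <- sxy + k(X[i, ], Y[j, ])
  }
  sxx / M^2 + syy / N^2 - 2 * sxy / (M * N)
}

# Small image-domain fixtures for unit tests that need a quick train.
tiny_dataset <- function(n, counts_range = c(2L, 5L), size = 32L, seed = 5L) {
  sp <- scene_spec(image_size = size, count_range = counts_range,
                   blob_radius_range = c(2, 3.5), seed = seed)
  counts <- countda:::with_seed_(seed, sample(seq(counts_range[1],
                                                  counts_range[2]),
                                              n, replace = TRUE))
  imgs <- array(0, c(size, size, 3, n))
  for (i in seq_len(n)) {
    s <- render_scene(sp, counts[i], seed = seed * 1000L + i)
    imgs[, , , i] <- preprocess_image(s$image, size)
  }
  structure(list(images = imgs, counts = counts,
                 ids = sprintf("tiny_%03d", seq_len(n)),
                 split = rep("train", n)),
            class = "count_dataset")
}
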