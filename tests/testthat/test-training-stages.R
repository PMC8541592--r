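# Label normalisation, the three training stages, and the adversarial steps.

test_that("label normalisation is the affine [a,b] -> [0,1] map", {
  expect_equal(normalize_labels(35, 20, 50), 0.5)
  expect_equal(normalize_labels(20, 20, 50), 0)
  expect_equal(normalize_labels(50, 20, 50), 1)
  expect_equal(normalize_labels(c(6, 9, 12), 6, 12), c(0, 0.5, 1))
  expect_error(normalize_labels(1, 5, 5), "range")
  expect_error(normalize_labels(60, 20, 50), "outside")
  expect_warning(v <- normalize_labels(60, 20, 50, clamp = TRUE), "clamped")
  expect_equal(v, 1)
  nrm <- label_normalizer(c(3, 5, 8))
  expect_equal(denormalize_labels(normalize_labels(c(3, 5, 8), nrm$a, nrm$b),
                                  nrm), c(3, 5, 8))
  expect_error(label_normalizer(rep(4, 10)), "degenerate")
})

test_that("adversarial losses take their analytic values at D = 1/2", {
  m <- build_models(list(feature_dim = 16L, image_size = 32L, seed = 1))
  m$discriminator$layers[[3]]$W[] <- 0
  m$discriminator$layers[[3]]$b[] <- 0
  fs <- countda:::with_seed_(1, matrix(rnorm(3 * 16), 3, 16))
  ft <- countda:::with_seed_(2, matrix(rnorm(5 * 16), 5, 16))
  expect_equal(discriminator_step(m$discriminator, NULL, NULL, fs, ft),
               2 * log(2), tolerance = 1e-6)
  expect_equal(generator_step(m$discriminator, NULL, m$regressor, ft,
                              lambda = 0),
               log(2), tolerance = 1e-6)
})

test_that("step losses match a hand arithmetic oracle on fixed tiny weights", {
  # one-layer 'heads': D(x) = sigmoid(w . x + b), R(x) = v . x
  d <- structure(list(layers = list(countda:::new_dense_layer(2, 1, "sigmoid")),
                      meta = list(feature_dim = 2L)),
                 class = c("discriminator", "countda_net"))
  d$layers[[1]]$W <- matrix(c(0.3, -0.2), 2, 1)
  d$layers[[1]]$b <- 0.1
  r <- structure(list(layers = list(countda:::new_dense_layer(2, 1, "linear")),
                      meta = list(feature_dim = 2L)),
                 class = c("regressor_head", "countda_net"))
  r$layers[[1]]$W <- matrix(c(1, 2), 2, 1)
  r$layers[[1]]$b <- 0
  fs <- rbind(c(1, 0), c(0, 1))
  ft <- rbind(c(1, 1), c(-1, 0.5))
  sig <- function(z) 1 / (1 + exp(-z))
  ps <- sig(c(0.3 + 0.1, -0.2 + 0.1))
  pt <- sig(c(0.3 - 0.2 + 0.1, -0.3 - 0.1 + 0.1))
  expect_equal(discriminator_step(d, NULL, NULL, fs, ft),
               mean(-log(ps)) + mean(-log(1 - pt)), tolerance = 1e-12)
  yhat <- c(1 + 2, -1 + 1)          # R outputs on ft
  lam <- 0.3
  expect_equal(generator_step(d, NULL, r, ft, lambda = lam),
               mean(-log(pt)) - lam * mean((yhat - mean(yhat))^2),
               tolerance = 1e-12)
})

test_that("variance penalty is the population variance", {
  expect_equal(variance_penalty(rep(0.7, 5)), 0)
  expect_equal(variance_penalty(c(0, 1)), 0.25)
  x <- countda:::with_seed_(3, rnorm(10))
  # two-pass oracle: mean first, then mean squared deviation
  mu <- sum(x) / 10
  expect_equal(variance_penalty(x), sum((x - mu)^2) / 10, tolerance = 1e-12)
  expect_error(variance_penalty(1), "at least 2")
  # lambda = 0 vs lambda > 0 coincide when R's outputs are constant
  d <- build_models(list(feature_dim = 8L, image_size = 32L, seed = 2))
  d$regressor$layers[[3]]$W[] <- 0
  d$regressor$layers[[3]]$b[] <- 0.4
  ft <- countda:::with_seed_(4, matrix(rnorm(4 * 8), 4, 8))
  expect_equal(generator_step(d$discriminator, NULL, d$regressor, ft, 0),
               generator_step(d$discriminator, NULL, d$regressor, ft, 0.9))
})

test_that("adversarial updates touch only their own parameter sets", {
  m <- build_models(list(feature_dim = 16L, image_size = 32L, seed = 5))
  phi_S <- m$feature_extractor
  phi_T <- countda:::net_clone(phi_S)
  imgs_s <- countda:::with_seed_(6, array(runif(32 * 32 * 3 * 4) * 2 - 1,
                                          c(32, 32, 3, 4)))
  imgs_t <- countda:::with_seed_(7, array(runif(32 * 32 * 3 * 4) * 2 - 1,
                                          c(32, 32, 3, 4)))
  p <- countda:::net_params
  before <- list(s = p(phi_S), t = p(phi_T), d = p(m$discriminator),
                 r = p(m$regressor))
  opt <- countda:::adam_new(1e-3)
  discriminator_step(m$discriminator, phi_S, phi_T, imgs_s, imgs_t, opt)
  expect_identical(p(phi_S), before$s)      # Psi-updates leave Theta alone
  expect_identical(p(phi_T), before$t)
  expect_false(identical(p(m$discriminator), before$d))
  before$d <- p(m$discriminator)
  opt2 <- countda:::adam_new(1e-3)
  generator_step(m$discriminator, phi_T, m$regressor, imgs_t, 0.1, opt2)
  expect_identical(p(phi_S), before$s)      # Theta_T-updates leave the rest
  expect_identical(p(m$discriminator), before$d)
  expect_identical(p(m$regressor), before$r)
  expect_false(identical(p(phi_T), before$t))
  expect_error(generator_step(m$discriminator, phi_T, m$regressor,
                              imgs_t[, , , 1, drop = FALSE], 0.1, opt2),
               "batch size")
  expect_error(discriminator_step(m$discriminator, phi_S, phi_T,
                                  matrix(0, 0, 16), imgs_t), "empty")
})

test_that("pretraining beats the constant-mean predictor on toy source data", {
  ds <- toy_datasets()
  a <- toy_stage_a(0)
  pred <- denormalize_labels(
    predict_counts(a$feature_extractor, a$regressor, ds$s_val),
    a$normalizer)
  model_mse <- mean((ds$s_val$counts - pred)^2)
  baseline_mse <- mean((ds$s_val$counts - mean(ds$s_train$counts))^2)
  expect_lt(model_mse, baseline_mse)
  # stage-A predictions on source validation sit near the normalised scale
  raw <- predict_counts(a$feature_extractor, a$regressor, ds$s_val)
  expect_true(all(raw > -0.2 & raw < 1.2))
})

test_that("no-op stages return their inputs untouched", {
  ds <- tiny_dataset(12)
  m <- build_models(list(feature_dim = 32L, image_size = 32L, seed = 8))
  cfg0 <- stage_config(max_epochs = 0, seed = 1)
  p <- countda:::net_params
  init <- list(fe = p(m$feature_extractor), reg = p(m$regressor))
  a <- pretrain(m$feature_extractor, m$regressor, ds, ds, cfg0)
  expect_identical(p(a$feature_extractor), init$fe)
  expect_identical(p(a$regressor), init$reg)
  expect_s3_class(a$normalizer, "label_normalizer")  # still fitted
  ad <- adapt(m$feature_extractor, m$regressor, ds, ds, m$discriminator,
              cfg0)
  expect_identical(p(ad$phi_T), init$fe)             # phi_T equals phi_S
  reg2 <- finetune(m$feature_extractor, m$regressor, ds, cfg0)
  expect_identical(p(reg2), init$reg)
  # degenerate inputs
  empty <- subset_dataset(ds, integer(0))
  expect_error(pretrain(m$feature_extractor, m$regressor, empty, ds,
                        stage_config(seed = 1)), "empty")
  const <- ds; const$counts <- rep(4L, length(const$counts))
  expect_error(pretrain(m$feature_extractor, m$regressor, const, ds,
                        stage_config(seed = 1)), "degenerate")
  expect_error(finetune(m$feature_extractor, m$regressor, empty, cfg0),
               "empty")
})

test_that("adaptation leaves the trained discriminator near chance on held-out features", {
  ds <- toy_datasets()
  a <- toy_stage_a(0)
  # balanced adversarial rates; subset of the toy data for speed
  sub_s <- subset_dataset(ds$s_train, 1:96)
  sub_t <- subset_dataset(ds$t_train, 1:96)
  disc <- build_models(toy_model_config(31L))$discriminator
  ad <- adapt(a$feature_extractor, a$regressor, sub_t, sub_s, disc,
              stage_config(lr_head = 5e-4, lr_phi = 1e-4, max_epochs = 10,
                           lambda = 0.1, seed = 0),
              source_monitor = ds$s_val, target_monitor = ds$t_val)
  fs <- extract_features(a$feature_extractor, ds$s_val)
  acc_of <- function(d, ft) {
    p <- discriminate(d, rbind(fs, ft))
    mean(c(p[seq_len(nrow(fs))] > 0.5, p[-seq_len(nrow(fs))] <= 0.5))
  }
  # pre-adaptation reference: a discriminator trained with phi_T frozen at
  # phi_S separates the two domains well
  ft_pre <- extract_features(a$feature_extractor, ds$t_val)
  probe <- build_models(toy_model_config(32L))$discriminator
  opt <- countda:::adam_new(1e-3)
  fs_tr <- extract_features(a$feature_extractor, sub_s)
  ft_tr <- extract_features(a$feature_extractor, sub_t)
  for (i in 1:150) discriminator_step(probe, NULL, NULL, fs_tr, ft_tr, opt)
  pre_acc <- acc_of(probe, ft_pre)
  post_acc <- acc_of(ad$discriminator, extract_features(ad$phi_T, ds$t_val))
  expect_lt(abs(post_acc - 0.5), abs(pre_acc - 0.5))
})

test_that("identity adaptation is benign: small initial MMD, no catastrophic forgetting", {
  ds <- tiny_dataset(80, seed = 6)
  val <- tiny_dataset(30, seed = 61)
  m <- build_models(list(feature_dim = 64L, image_size = 32L, seed = 9))
  a <- pretrain(m$feature_extractor, m$regressor, ds, val,
                stage_config(lr_head = 1e-3, lr_fe = 1e-3, max_epochs = 12,
                             seed = 9))
  y_val <- normalize_labels(val$counts, a$normalizer$a, a$normalizer$b,
                            clamp = TRUE)
  mse_before <- mean((predict_counts(a$feature_extractor, a$regressor, val) -
                        y_val)^2)
  ad <- adapt(a$feature_extractor, a$regressor, ds, ds, m$discriminator,
              stage_config(lr_head = 1e-3, lr_phi = 1e-5, max_epochs = 5,
                           lambda = 0.1, seed = 9),
              source_monitor = val, target_monitor = val)
  # target = source: the monitor sees no shift from the very start
  expect_lt(ad$trace$mmd2[1], 0.05)
  mse_after <- mean((predict_counts(ad$phi_T, a$regressor, val) - y_val)^2)
  expect_lt(mse_after, 2 * mse_before + 0.02)
})

test_that("fine-tuning restores the target label scale from few labels", {
  ds <- toy_datasets()
  a <- toy_stage_a(0)
  ad <- toy_adaptation(0)
  sub10 <- countda:::draw_label_subset(ds$t_train, 10L, 0)
  reg10 <- finetune(ad$phi_T, a$regressor, sub10, toy_finetune_cfg(0))
  pred <- predict_counts(ad$phi_T, reg10, ds$t_test)
  # mean prediction inside the target range expanded by 20%
  expect_gt(mean(pred), 6 * 0.8)
  expect_lt(mean(pred), 12 * 1.2)
  # limiting case: k = full training set equals finetune-on-all exactly
  n <- length(ds$t_train$counts)
  rega <- finetune(ad$phi_T, a$regressor,
                   countda:::draw_label_subset(ds$t_train, n, 0),
                   stage_config(lr_head = 1e-2, max_epochs = 20,
                                augment = FALSE, seed = 0))
  regb <- finetune(ad$phi_T, a$regressor, ds$t_train,
                   stage_config(lr_head = 1e-2, max_epochs = 20,
                                augment = FALSE, seed = 0))
  expect_equal(predict_counts(ad$phi_T, rega, ds$t_test),
               predict_counts(ad$phi_T, regb, ds$t_test),
               tolerance = 1e-9)
  # prediction shape and determinism contracts
  three <- subset_dataset(ds$t_test, 1:3)
  expect_length(predict_counts(ad$phi_T, reg10, three), 3)
  dup <- subset_dataset(ds$t_test, c(1, 1))
  pd <- predict_counts(ad$phi_T, reg10, dup)
  expect_equal(pd[1], pd[2])
})
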