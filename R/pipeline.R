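#' Upper-bound / adapted / lower-bound comparison on the target test split
#'
#' Evaluates three conditions on the target test set:
#' \describe{
#'   \item{UB}{the pretrained source model applied to the target without
#'     any adaptation, its normalised outputs mapped back through the
#'     source label range;}
#'   \item{Ours}{the adapted target extractor with the regressor
#'     fine-tuned on `k` labelled target images (predictions are already
#'     on the target scale);}
#'   \item{LB}{a fresh model trained fully supervised on the target
#'     training split (trained on demand).}
#' }
#'
#' @param stage_a Result of [pretrain()] (gives UB and the regressor to
#'   fine-tune).
#' @param phi_T Adapted target extractor from [adapt()].
#' @param target_train,target_val,target_test `count_dataset`s.
#' @param k Number of labelled target images for fine-tuning (drawn
#'   seeded from the target training split).
#' @param cfg_finetune [stage_config()] for stage C.
#' @param lb_cfg [stage_config()] for the lower-bound training.
#' @param model_config Model configuration for the lower-bound networks.
#' @param out_csv Optional path; the comparison table is written there.
#' @return List with `reports` (named `count_metrics`), `table`
#'   (data.frame), `finetuned_regressor`, and `lb_models`.
#' @export
evaluate_bounds <- function(stage_a, phi_T, target_train, target_val,
                            target_test, k = 50L, cfg_finetune,
                            lb_cfg, model_config, out_csv = NULL) {
  if (length(target_test$counts) == 0L) stop("empty target test split")

  ub_pred <- denormalize_labels(
    predict_counts(stage_a$feature_extractor, stage_a$regressor,
                   target_test),
    stage_a$normalizer)
  ub <- compute_metrics(target_test$counts, ub_pred)

  subset <- draw_label_subset(target_train, k, cfg_finetune$seed)
  reg_ft <- finetune(phi_T, stage_a$regressor, subset, cfg_finetune)
  ours_pred <- predict_counts(phi_T, reg_ft, target_test)
  ours <- compute_metrics(target_test$counts, ours_pred)

  lb_models <- build_models(model_config)
  lb_fit <- pretrain(lb_models$feature_extractor, lb_models$regressor,
                     target_train, target_val, lb_cfg)
  lb_pred <- denormalize_labels(
    predict_counts(lb_fit$feature_extractor, lb_fit$regressor, target_test),
    lb_fit$normalizer)
  lb <- compute_metrics(target_test$counts, lb_pred)

  reports <- list(UB = ub, Ours = ours, LB = lb)
  tab <- metrics_table(reports)
  if (!is.null(out_csv)) write_metrics_csv(tab, out_csv)
  list(reports = reports, table = tab, finetuned_regressor = reg_ft,
       lb_models = lb_fit)
}

# Seeded draw of k labelled images from a dataset.
draw_label_subset <- function(ds, k, seed) {
  n <- length(ds$counts)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the ", n, " available labels")
  idx <- if (k == n) seq_len(n) else with_seed_(seed, sample.int(n, k))
  subset_dataset(ds, idx)
}

#' Run the full three-stage pipeline on a source/target dataset pair
#'
#' Loads both domains from disk, pretrains on the source, adapts the
#' target extractor adversarially, fine-tunes the regressor on `k`
#' labelled target images, and evaluates UB / Ours / LB on the target test
#' split. All randomness derives from the `seed` fields of the stage
#' configurations.
#'
#' @param source_dir,target_dir Dataset directories written by
#'   [generate_dataset()].
#' @param model_config List for [build_models()] (`image_size` also sets
#'   the preprocessing size).
#' @param cfg_pretrain,cfg_adapt,cfg_finetune [stage_config()]s per stage.
#' @param k Fine-tuning label budget.
#' @param stop_mode Stopping-rule mode: `"both"`, `"mmd"` or `"ggo"`.
#' @param lb_cfg Config for the lower-bound run (default: `cfg_pretrain`).
#' @param keep_snapshots Keep per-epoch extractor snapshots in the result.
#' @param out_dir Optional run directory: resolved settings, monitor trace
#'   and metrics CSV are written there.
#' @return List with stage outputs (`stage_a`, `adaptation`), `bounds`
#'   (from [evaluate_bounds()]), and the loaded datasets.
#' @export
run_experiment <- function(source_dir, target_dir, model_config,
                           cfg_pretrain, cfg_adapt, cfg_finetune,
                           k = 50L, stop_mode = "both", lb_cfg = cfg_pretrain,
                           keep_snapshots = FALSE, out_dir = NULL) {
  size <- model_config$image_size %||% 64L
  s_train <- load_dataset(source_dir, "train", size)
  s_val <- load_dataset(source_dir, "val", size)
  t_train <- load_dataset(target_dir, "train", size)
  t_val <- load_dataset(target_dir, "val", size)
  t_test <- load_dataset(target_dir, "test", size)

  models <- build_models(model_config)
  stage_a <- pretrain(models$feature_extractor, models$regressor,
                      s_train, s_val, cfg_pretrain)
  adaptation <- adapt(stage_a$feature_extractor, stage_a$regressor,
                      t_train, s_train, models$discriminator, cfg_adapt,
                      monitors = stopping_state(cfg_adapt$patience,
                                                mode = stop_mode),
                      source_monitor = s_val, target_monitor = t_val,
                      keep_snapshots = keep_snapshots)
  mc_lb <- model_config
  mc_lb$seed <- (model_config$seed %||% 1L) + 1000L
  bounds <- evaluate_bounds(stage_a, adaptation$phi_T, t_train, t_val,
                            t_test, k = k, cfg_finetune = cfg_finetune,
                            lb_cfg = lb_cfg, model_config = mc_lb)
  out <- list(stage_a = stage_a, adaptation = adaptation, bounds = bounds,
              datasets = list(source_train = s_train, source_val = s_val,
                              target_train = t_train, target_val = t_val,
                              target_test = t_test))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(bounds$table, file.path(out_dir, "metrics.csv"))
    write.csv(adaptation$trace, file.path(out_dir, "training_log.csv"),
              row.names = FALSE)
    yaml::write_yaml(list(
      model = model_config,
      pretrain = unclass(cfg_pretrain), adapt = unclass(cfg_adapt),
      finetune = unclass(cfg_finetune), k = k, stop_mode = stop_mode
    ), file.path(out_dir, "resolved_config.yaml"))
  }
  out
}

#' Label-budget sweep of the fine-tuning stage
#'
#' Re-runs stage C from the same adapted extractor for each label budget
#' `k`, drawing the labelled subset with several seeds, and reports the
#' mean target-test MSE per budget.
#'
#' @param phi_T Adapted target extractor.
#' @param regressor Pretrained regressor (fine-tuned afresh per run).
#' @param target_train,target_test `count_dataset`s.
#' @param k_values Positive label budgets, each `<=` the target training
#'   size.
#' @param cfg [stage_config()] for fine-tuning.
#' @param seeds Integer seeds for the subset draws (>= 1).
#' @return `data.frame` with columns `k`, `mse_mean`, `mse_sd`, and the
#'   per-seed MSEs as attribute `"per_seed"`.
#' @export
label_budget_sweep <- function(phi_T, regressor, target_train, target_test,
                               k_values, cfg, seeds = 0:2) {
  n <- length(target_train$counts)
  k_values <- as.integer(k_values)
  if (any(k_values < 1L)) stop("k values must be positive")
  if (any(k_values > n)) {
    stop("k = ", max(k_values), " exceeds the ", n, " available labels")
  }
  per_seed <- expand.grid(k = k_values, seed = seeds)
  per_seed$mse <- NA_real_
  for (i in seq_len(nrow(per_seed))) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(per_seed$seed[i])
    subset <- draw_label_subset(target_train, per_seed$k[i], cfg_i$seed)
    reg_ft <- finetune(phi_T, regressor, subset, cfg_i)
    pred <- predict_counts(phi_T, reg_ft, target_test)
    per_seed$mse[i] <- compute_metrics(target_test$counts, pred)$mse
  }
  agg <- aggregate(mse ~ k, per_seed, mean)
  sds <- aggregate(mse ~ k, per_seed, sd)
  out <- data.frame(k = agg$k, mse_mean = agg$mse, mse_sd = sds$mse)
  attr(out, "per_seed") <- per_seed
  out
}

#' Replay recorded stopping-rule ablations from one adaptation run
#'
#' The monitors are passive observers until they trigger a stop, so a
#' single adaptation run with `keep_snapshots = TRUE` contains every
#' single-signal ablation as a prefix: this helper re-applies a stopping
#' rule to the recorded monitor trace and returns the extractor restored
#' to that rule's best epoch.
#'
#' @param adaptation Result of [adapt()] with `keep_snapshots = TRUE`.
#' @param mode `"both"`, `"mmd"` or `"ggo"`.
#' @param patience Patience of the replayed rule.
#' @return List with `phi_T` (restored snapshot), `best_epoch`,
#'   `stop_epoch`.
#' @export
replay_stopping_rule <- function(adaptation, mode, patience = 10L) {
  if (is.null(adaptation$snapshots)) {
    stop("adaptation was run without keep_snapshots = TRUE")
  }
  tr <- adaptation$trace
  base <- tr[tr$epoch == 0L, , drop = FALSE]
  tr <- tr[tr$epoch > 0L, , drop = FALSE]
  state <- stopping_state(patience, mode = mode)
  if (nrow(base)) state <- set_monitor_baseline(state, base$mmd2, base$ggo)
  stop_epoch <- NA_integer_
  for (i in seq_len(nrow(tr))) {
    upd <- update_monitor(state, tr$mmd2[i], tr$ggo[i])
    state <- upd$state
    if (upd$should_stop) {
      stop_epoch <- tr$epoch[i]
      break
    }
  }
  phi <- net_clone(adaptation$phi_T)
  net_set_params(phi, adaptation$snapshots[[as.character(state$best_epoch)]])
  list(phi_T = phi, best_epoch = state$best_epoch, stop_epoch = stop_epoch)
}
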