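# Pipeline stages: simulate | standardize | train | fuse | predict |
# evaluate, plus run_all() chaining them. Every stage is a pure function of
# the run configuration; artifacts (TSV profiles, model checkpoints, the
# fitness-history CSV, predictions, metrics JSON) land under the configured
# output directory, and later stages fail with a dependency error when an
# artifact they need has not been produced yet.

artifact_paths <- function(config) {
  out <- config$outdir
  list(outdir = out,
       data_dir = file.path(out, "data"),
       profile_dir = file.path(out, "profiles"),
       model_dir = file.path(out, "models"),
       base_model = function(ord) file.path(out, "models",
                                            sprintf("base_%d.json", ord)),
       stacker = file.path(out, "models", "stacker.json"),
       history = file.path(out, "pso_history.csv"),
       base_validation = file.path(out, "base_validation_metrics.json"),
       predictions = file.path(out, "predictions.tsv"),
       metrics = file.path(out, "metrics.json"),
       resolved_config = file.path(out, "config_resolved.yaml"))
}

require_artifact <- function(path, producing_stage) {
  if (!file.exists(path))
    err_dependency("missing artifact '%s'; run the '%s' stage first",
                   path, producing_stage)
  path
}

resolve_task <- function(config) {
  tk <- config$task$task_kind
  task_spec(task_kind = tk,
            n_classes = config$task$n_classes %||% 1L,
            epochs = config$task$epochs %||% 50L,
            batch_size = config$task$batch_size %||% 128L,
            learning_rate = config$task$learning_rate %||% 1e-3,
            split = config$task$split %||% c(0.8, 0.1, 0.1),
            seed = derive_seed(config$seed, 7))
}

resolve_inputs <- function(config) {
  if (!is.null(config$data)) {
    d <- config$data
    mats_a <- lapply(d$features_a, load_feature_matrix)
    ids_a <- rownames(mats_a[[1]])
    set_a <- feature_set(ids_a, mats_a)
    same_set <- isTRUE(d$same_set)
    if (same_set) {
      set_b <- set_a
    } else {
      mats_b <- lapply(d$features_b, load_feature_matrix)
      set_b <- feature_set(rownames(mats_b[[1]]), mats_b)
    }
    pairs <- load_pair_labels(d$pairs, set_a$entity_ids, set_b$entity_ids,
                              task_kind = config$task$task_kind,
                              strict = !isTRUE(d$lenient))
    list(feature_sets = list(set_a = set_a, set_b = set_b), pairs = pairs,
         same_set = same_set)
  } else if (!is.null(config$synthetic)) {
    syn <- do.call(synthetic_task_config,
                   merge_config(config$synthetic,
                                list(seed = derive_seed(config$seed, 5))))
    st <- simulate_task(syn)
    list(feature_sets = st$feature_sets, pairs = st$pairs,
         same_set = syn$same_set)
  } else {
    err_invalid_config("run config needs either 'data' file paths or a 'synthetic' block")
  }
}

# Entity representations per feature type: raw similarity rows by default,
# optionally their leading principal components.
resolve_representations <- function(config, feature_sets) {
  reps_of <- function(fs) {
    profiles <- standardize_features(fs)
    if (identical(config$representation, "pca")) {
      nc <- config$pca_components
      if (is.null(nc) || nc < 1)
        err_invalid_config("representation 'pca' requires pca_components >= 1")
      lapply(profiles, function(p) pca_reduce(p, nc)$scores)
    } else {
      lapply(profiles, function(p) p$matrix)
    }
  }
  rep_a <- reps_of(feature_sets$set_a)
  rep_b <- if (identical(feature_sets$set_b, feature_sets$set_a)) rep_a
           else reps_of(feature_sets$set_b)
  list(a = rep_a, b = rep_b)
}

# Everything deterministic the stages share: data, task, combinations,
# representations, per-combination input matrices, labels, split indices.
prepare_pipeline <- function(config) {
  inp <- resolve_inputs(config)
  task <- resolve_task(config)
  pairs <- inp$pairs
  if (inp$same_set) {
    cn <- canonicalize_pairs(pairs$idx_a, pairs$idx_b)
    pairs$idx_a <- cn$idx_a
    pairs$idx_b <- cn$idx_b
  }
  reps <- resolve_representations(config, inp$feature_sets)
  combos <- enumerate_feature_pairs(names(reps$a), names(reps$b))
  inputs <- lapply(seq_len(nrow(combos)), function(i)
    cbind(reps$a[[combos$index_a[i]]][pairs$idx_a, , drop = FALSE],
          reps$b[[combos$index_b[i]]][pairs$idx_b, , drop = FALSE]))
  labels <- pairs$label
  stratify <- isTRUE(config$stratify_split) && !is.matrix(labels)
  splits <- split_dataset(labels, task$split,
                          seed = derive_seed(config$seed, 11),
                          stratify = stratify)
  list(config = config, task = task, feature_sets = inp$feature_sets,
       same_set = inp$same_set, pairs = pairs, reps = reps, combos = combos,
       inputs = inputs, labels = labels, splits = splits)
}

take_rows <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

# Training rows; for same-set tasks with the symmetric-augmentation switch
# on, each pair is additionally presented in swapped order.
training_views <- function(prep) {
  idx <- prep$splits$train
  inputs <- lapply(prep$inputs, function(m) m[idx, , drop = FALSE])
  labels <- take_rows(prep$labels, idx)
  if (prep$same_set && isTRUE(prep$config$augment_symmetric)) {
    swapped <- lapply(seq_len(nrow(prep$combos)), function(i)
      cbind(prep$reps$a[[prep$combos$index_a[i]]][prep$pairs$idx_b[idx], , drop = FALSE],
            prep$reps$b[[prep$combos$index_b[i]]][prep$pairs$idx_a[idx], , drop = FALSE]))
    inputs <- Map(rbind, inputs, swapped)
    labels <- if (is.matrix(labels)) rbind(labels, labels) else c(labels, labels)
  }
  list(inputs = inputs, labels = labels)
}

#' Stage: write the synthetic input files
#'
#' Materializes the configured synthetic task under `<outdir>/data/` in the
#' same TSV formats the readers consume. Only valid for synthetic runs.
#'
#' @param config Run configuration (see [default_run_config()]).
#' @return The written directory, invisibly.
#' @export
stage_simulate <- function(config) {
  if (is.null(config$synthetic))
    err_invalid_config("'simulate' requires a synthetic block in the config")
  ap <- artifact_paths(config)
  syn <- do.call(synthetic_task_config,
                 merge_config(config$synthetic,
                              list(seed = derive_seed(config$seed, 5))))
  simulate_task(syn, outdir = ap$data_dir)
  psf_log(config, "simulate: wrote synthetic task to %s", ap$data_dir)
  invisible(ap$data_dir)
}

#' Stage: standardize features into similarity profiles
#'
#' Computes every feature type's Jaccard similarity matrix and exports each
#' as TSV under `<outdir>/profiles/`.
#'
#' @param config Run configuration.
#' @return The profile directory, invisibly.
#' @export
stage_standardize <- function(config) {
  ap <- artifact_paths(config)
  dir.create(ap$profile_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- resolve_inputs(config)
  for (side in c("a", "b")) {
    fs <- if (side == "a") inp$feature_sets$set_a else inp$feature_sets$set_b
    if (side == "b" && inp$same_set) next
    for (p in standardize_features(fs))
      write_similarity_tsv(p, file.path(ap$profile_dir,
                                        sprintf("%s.tsv", p$feature_type)),
                           ids = fs$entity_ids)
  }
  psf_log(config, "standardize: wrote profiles to %s", ap$profile_dir)
  invisible(ap$profile_dir)
}

#' Stage: preliminary training and swarm refinement
#'
#' Initializes one base network per feature-type combination, trains each
#' independently on the training split, then refines all of them jointly by
#' particle swarm optimization with validation loss as fitness. Saves the
#' refined checkpoints, the fitness-history CSV and the per-model validation
#' metrics.
#'
#' @param config Run configuration.
#' @return Invisibly, a list with `models`, `swarm` and the prepared state.
#' @export
stage_train <- function(config) {
  ap <- artifact_paths(config)
  dir.create(ap$model_dir, recursive = TRUE, showWarnings = FALSE)
  prep <- prepare_pipeline(config)
  task <- prep$task
  tv <- training_views(prep)
  val_inputs <- lapply(prep$inputs, function(m)
    m[prep$splits$validation, , drop = FALSE])
  val_labels <- take_rows(prep$labels, prep$splits$validation)

  hidden <- config$architecture$hidden_dims %||% c(512L, 256L, 128L)
  models <- lapply(seq_len(nrow(prep$combos)), function(i) {
    arch <- network_architecture(ncol(prep$inputs[[i]]), hidden,
                                 task$n_classes,
                                 output_activation = activation_for(task$task_kind))
    m <- init_model(arch, seed = derive_seed(config$seed, 100, i),
                    combination = prep$combos[i, ])
    train_model(m, tv$inputs[[i]], tv$labels, task,
                seed = derive_seed(config$seed, 150, i))
  })
  psf_log(config, "train: preliminary training of %d base models done",
          length(models))

  swcfg <- swarm_config(
    inertia = config$swarm$inertia %||% 0.7,
    cognitive = config$swarm$cognitive %||% 1.5,
    social = config$swarm$social %||% 1.5,
    iterations = config$swarm$iterations %||% 10L,
    retrain_epochs = config$swarm$retrain_epochs %||% 5L,
    velocity_clamp = config$swarm$velocity_clamp,
    convergence_tol = config$swarm$convergence_tol,
    seed = derive_seed(config$seed, 300))
  swarm <- run_swarm(models, tv$inputs, tv$labels, val_inputs, val_labels,
                     task, swcfg)
  psf_log(config, "train: swarm refined global best fitness %.6g -> %.6g",
          min(swarm$initial_fitness), swarm$global_best_fitness)

  for (i in seq_along(swarm$models))
    save_model(swarm$models[[i]], ap$base_model(prep$combos$ordinal[i]))
  write_fitness_history(swarm, ap$history)

  if (task$task_kind != "regression") {
    base_val <- do.call(rbind, lapply(seq_along(swarm$models), function(i) {
      scores <- predict(swarm$models[[i]], val_inputs[[i]])
      rep <- compute_metrics(val_labels,
                             if (task$n_classes == 1) scores[, 1] else scores,
                             task_kind = task$task_kind,
                             split = "validation", seed = config$seed)
      data.frame(ordinal = prep$combos$ordinal[i],
                 index_a = prep$combos$index_a[i],
                 index_b = prep$combos$index_b[i],
                 auroc = rep$auroc, auprc = rep$auprc,
                 fitness = swarm$personal_best_fitness[i])
    }))
    writeLines(jsonlite::toJSON(base_val, digits = NA, na = "null",
                                dataframe = "rows"), ap$base_validation)
  }
  invisible(list(models = swarm$models, swarm = swarm, prep = prep))
}

load_base_models <- function(config, n_combos) {
  ap <- artifact_paths(config)
  lapply(seq_len(n_combos) - 1L, function(ord)
    load_model(require_artifact(ap$base_model(ord), "train")))
}

#' Stage: train the stacking network
#'
#' Loads the frozen base checkpoints, concatenates their training-split
#' outputs and trains the stacking network on them (plain backpropagation;
#' the swarm is not involved).
#'
#' @param config Run configuration.
#' @return The trained stacker, invisibly.
#' @export
stage_fuse <- function(config) {
  ap <- artifact_paths(config)
  prep <- prepare_pipeline(config)
  models <- load_base_models(config, nrow(prep$combos))
  tv <- training_views(prep)
  stacked <- collect_base_outputs(models, tv$inputs)
  stacker <- train_stacker(stacked, tv$labels, prep$task,
                           hidden_dims = config$stacker$hidden_dims %||% c(64L, 32L),
                           epochs = config$stacker$epochs %||% 50L,
                           seed = derive_seed(config$seed, 400))
  save_model(stacker, ap$stacker)
  psf_log(config, "fuse: stacker trained on %d stacked columns", ncol(stacked))
  invisible(stacker)
}

#' Stage: predict on the test split
#'
#' Applies the configured integration strategy (`"stack"`, `"average"`,
#' `"vote"` or `"weighted"`) to the frozen base outputs on the test split
#' and writes `predictions.tsv`: entity ids, per-class scores, the
#' predicted label and the true label.
#'
#' @param config Run configuration.
#' @return The predictions data frame, invisibly.
#' @export
stage_predict <- function(config) {
  ap <- artifact_paths(config)
  prep <- prepare_pipeline(config)
  task <- prep$task
  models <- load_base_models(config, nrow(prep$combos))
  idx <- prep$splits$test
  test_inputs <- lapply(prep$inputs, function(m) m[idx, , drop = FALSE])
  stacked <- collect_base_outputs(models, test_inputs)
  d <- task$n_classes
  strategy <- config$integration %||% "stack"

  if (strategy == "stack") {
    stacker <- load_model(require_artifact(ap$stacker, "fuse"))
    scores <- predict(stacker, unclass_stacked(stacked))
  } else if (strategy == "average") {
    scores <- average_outputs(stacked, d)
  } else if (strategy == "weighted") {
    w <- config$integration_weights %||% rep(1, nrow(prep$combos))
    scores <- weighted_sum(stacked, w, d)
  } else if (strategy == "vote") {
    scores <- average_outputs(stacked, d)   # ranking scores for metrics
  } else {
    err_invalid_config("unknown integration strategy '%s'", strategy)
  }

  predicted <- if (strategy == "vote") {
    majority_vote(stacked, d, task$task_kind)
  } else if (task$task_kind == "multiclass") {
    max.col(scores, ties.method = "first")
  } else if (task$task_kind == "regression") {
    scores[, 1]
  } else if (d == 1) {
    as.integer(scores[, 1] >= 0.5)
  } else {
    NULL   # multilabel: thresholded below
  }

  out <- data.frame(id_a = prep$pairs$id_a[idx], id_b = prep$pairs$id_b[idx],
                    stringsAsFactors = FALSE)
  score_cols <- if (d == 1) "score" else sprintf("score_%d", seq_len(d))
  for (j in seq_len(d)) out[[score_cols[j]]] <- scores[, j]
  out$predicted <- if (task$task_kind == "multilabel")
    apply(matrix(as.integer(scores >= 0.5), ncol = d), 1, paste, collapse = ",")
  else predicted
  truth <- take_rows(prep$labels, idx)
  out$label <- if (is.matrix(truth)) apply(truth, 1, paste, collapse = ",")
               else truth
  utils::write.table(out, ap$predictions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  psf_log(config, "predict: wrote %d test predictions (%s integration)",
          nrow(out), strategy)
  invisible(out)
}

#' Stage: evaluate the test predictions
#'
#' Reads `predictions.tsv` and computes the six metrics, writing
#' `metrics.json` with a provenance echo.
#'
#' @param config Run configuration.
#' @return The [compute_metrics()] report, invisibly.
#' @export
stage_evaluate <- function(config) {
  ap <- artifact_paths(config)
  preds <- utils::read.delim(require_artifact(ap$predictions, "predict"),
                             colClasses = "character")
  task <- resolve_task(config)
  d <- task$n_classes
  scores <- if (d == 1) as.numeric(preds$score)
            else sapply(sprintf("score_%d", seq_len(d)),
                        function(cl) as.numeric(preds[[cl]]))
  truth <- if (task$task_kind == "multilabel")
    do.call(rbind, lapply(strsplit(preds$label, ","), as.numeric))
  else as.numeric(preds$label)
  report <- compute_metrics(truth, scores,
                            task_kind = task$task_kind,
                            split = "test", seed = config$seed)
  write_metrics_json(report, ap$metrics)
  psf_log(config, "evaluate: ACC %.4f AUROC %s F %.4f", report$acc,
          ifelse(is.na(report$auroc), "NA", sprintf("%.4f", report$auroc)),
          report$f_score)
  invisible(report)
}

#' Run the whole pipeline
#'
#' Chains simulate (for synthetic configs), standardize, train, fuse,
#' predict and evaluate; every artifact lands under `config$outdir`, the
#' resolved configuration (including the master seed) is written alongside,
#' and two runs with the same configuration produce identical artifacts.
#'
#' @param config Run configuration list, or a path to a YAML/JSON config
#'   file.
#' @return Invisibly, a list with `models`, `swarm`, `stacker`,
#'   `predictions`, `metrics` and the resolved `config`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  config <- merge_config(default_run_config(), config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  save_run_config(config, artifact_paths(config)$resolved_config)
  psf_log(config, "run-all: outdir %s, master seed %d", config$outdir,
          config$seed)
  if (!is.null(config$synthetic)) stage_simulate(config)
  stage_standardize(config)
  tr <- stage_train(config)
  stacker <- if (identical(config$integration %||% "stack", "stack"))
    stage_fuse(config) else NULL
  preds <- stage_predict(config)
  metrics <- stage_evaluate(config)
  invisible(list(config = config, models = tr$models, swarm = tr$swarm,
                 stacker = stacker, predictions = preds, metrics = metrics))
}
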