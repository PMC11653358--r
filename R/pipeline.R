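# End-to-end orchestration: split/augment -> train the fused network ->
# extract depth-concatenation features -> CFO selection -> shallow-classifier
# k-fold evaluation -> tabular reports. Every stage is seeded and every
# artifact (config, architecture manifest, audit, features, mask, reports)
# can be written to a run directory for exact re-runs.

#' Assemble a run configuration
#'
#' Defaults follow the tuned training settings (initial learning rate
#' 1.4e-4, momentum 0.7002, mini-batch 64), a 70/30 stratified split and
#' 10-fold cross-validation; all knobs are overridable. Either `data_path`
#' (a class-per-folder image directory) or the synthetic-phantom settings
#' drive the data stage.
#'
#' @param data_path Optional image folder; when `NULL`, phantoms are used.
#' @param n_classes,per_class,noise_sd Phantom settings (see
#'   [phantom_config()]).
#' @param split_fraction Training fraction (default 0.7).
#' @param augment_target Per-class target after augmentation of the
#'   training partition (`NULL` = no augmentation). Augmentation runs after
#'   the split, on the training partition only.
#' @param width_scale Channel width multiplier for desk-scale training.
#' @param lr,momentum,batch_size,epochs Training hyperparameters.
#' @param cfo_pop,cfo_budget,lambda Feature-selection settings.
#' @param classifiers Shallow variants to evaluate.
#' @param k Cross-validation folds.
#' @param classifier_epochs Training epochs per shallow classifier fit.
#' @param seed Master seed for the run.
#' @param out_dir Optional output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(data_path = NULL, n_classes = 5L, per_class = 40L,
                       noise_sd = 0.05, split_fraction = 0.7,
                       augment_target = NULL, width_scale = 1.0,
                       lr = 1.4e-4, momentum = 0.7002, batch_size = 64L,
                       epochs = 10L, cfo_pop = 20L, cfo_budget = 600L,
                       lambda = 0.05,
                       classifiers = c("NNN", "MNN", "SWNN", "BNN", "TNN"),
                       k = 10L, classifier_epochs = 200L, seed = 1L,
                       out_dir = NULL) {
  cfg <- list(data_path = data_path, n_classes = as.integer(n_classes),
              per_class = as.integer(per_class), noise_sd = noise_sd,
              split_fraction = split_fraction, augment_target = augment_target,
              width_scale = width_scale, lr = lr, momentum = momentum,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              cfo_pop = as.integer(cfo_pop), cfo_budget = as.integer(cfo_budget),
              lambda = lambda, classifiers = classifiers, k = as.integer(k),
              classifier_epochs = as.integer(classifier_epochs),
              seed = as.integer(seed), out_dir = out_dir)
  num <- c("split_fraction", "width_scale", "lr", "momentum", "batch_size",
           "epochs", "k", "lambda")
  for (f in num) if (any(unlist(cfg[f]) <= 0)) stop("config field ", f, " must be positive")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @export
config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

load_stage <- function(cfg) {
  ds <- if (!is.null(cfg$data_path)) {
    load_image_folder(cfg$data_path)
  } else {
    generate_phantoms(phantom_config(n_classes = cfg$n_classes,
                                     per_class = cfg$per_class,
                                     noise_sd = cfg$noise_sd, seed = cfg$seed))
  }
  split <- split_dataset(ds, cfg$split_fraction, seed = cfg$seed)
  if (!is.null(cfg$augment_target)) {
    split$train <- augment(split$train, cfg$augment_target, seed = cfg$seed)
  }
  split
}

#' Train the fused network on the configured data
#'
#' Runs split (and optional training-set augmentation), builds the fused
#' architecture at the configured width scale, and trains it with
#' SGD + momentum. Writes `arch.json`, `audit.json`, `loss.csv` and a
#' weights checkpoint to `out_dir` when set.
#'
#' @param cfg A [run_config()].
#' @return An `nf_run`: the trained network, the data split, the audit and
#'   the loss history.
#' @export
run_training <- function(cfg) {
  split <- withCallersStage("data", load_stage(cfg))
  n_classes <- nlevels(split$train$label)
  graph <- withCallersStage("build",
    build_fused_network(num_classes = n_classes, width_scale = cfg$width_scale))
  net <- instantiate_network(graph, seed = cfg$seed)
  net <- withCallersStage("train",
    train_network(net, dataset_array(split$train), split$train$label,
                  epochs = cfg$epochs, lr = cfg$lr, momentum = cfg$momentum,
                  batch_size = cfg$batch_size, seed = cfg$seed))
  audit <- architecture_audit(graph)
  run <- structure(list(cfg = cfg, net = net, split = split, audit = audit,
                        history = net$history, loss0 = net$loss0),
                   class = "nf_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    config_to_yaml(cfg, file.path(cfg$out_dir, "run.yaml"))
    graph_to_json(graph, file.path(cfg$out_dir, "arch.json"))
    audit_to_json(audit, file.path(cfg$out_dir, "audit.json"))
    utils::write.csv(net$history, file.path(cfg$out_dir, "loss.csv"),
                     row.names = FALSE)
    saveRDS(net, file.path(cfg$out_dir, "checkpoint.rds"))
  }
  run
}

withCallersStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.nf_run <- function(x, ...) {
  cat(sprintf("<nf_run> %s | %d train / %d test | final loss %.4f (start %.4f)\n",
              x$net$graph$name, nrow(x$split$train), nrow(x$split$test),
              utils::tail(x$history$loss, 1), x$loss0))
  invisible(x)
}

#' Extract deep features at the fusion layer
#'
#' Forward-passes a partition through the trained network and taps the
#' requested layer (default the fusion depth-concatenation node: 512-wide
#' at full width). Returns a tibble of feature columns plus `label`.
#'
#' @param run An [run_training()] result (or a checkpoint path to a saved
#'   network).
#' @param partition `"test"` (default) or `"train"`.
#' @param tap Layer id to tap (`"fusion_cat"`, `"d_attention"`,
#'   `"i_attention"`, ...).
#' @return Tibble with one row per sample.
#' @export
run_extract <- function(run, partition = c("test", "train"), tap = "fusion_cat") {
  partition <- match.arg(partition)
  net <- if (is.character(run)) {
    if (!file.exists(run)) stop("checkpoint not found: ", run)
    readRDS(run)
  } else run$net
  ds <- run$split[[partition]]
  feats <- forward(net, dataset_array(ds), tap = tap)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- tibble::as_tibble(feats)
  out$label <- ds$label
  if (!is.null(run$cfg$out_dir)) {
    utils::write.csv(out, file.path(run$cfg$out_dir,
                                    sprintf("features_%s_%s.csv", tap, partition)),
                     row.names = FALSE)
  }
  out
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(colnames(features), "label"), drop = FALSE])
}

classify_features <- function(features, cfg, label = "fused", selection = FALSE) {
  X <- feature_matrix(features)
  y <- features$label
  purrr::map_dfr(cfg$classifiers, function(v) {
    spec <- classifier_spec(v, input_dim = ncol(X), n_classes = nlevels(y),
                            seed = cfg$seed)
    res <- kfold_evaluate(X, y, spec, k = cfg$k, seed = cfg$seed,
                          epochs = cfg$classifier_epochs)
    r <- res$report
    tibble::tibble(feature_source = label, classifier = v,
                   selection = selection, n_features = ncol(X),
                   Accuracy = r$accuracy, Sensitivity = r$sensitivity,
                   Precision = r$precision, F1 = r$f1, FNR = r$fnr,
                   Time = r$elapsed_s)
  })
}

#' Select features with CFO and evaluate the shallow classifiers
#'
#' Applies CFO wrapper selection to the feature table, then evaluates every
#' configured classifier variant with stratified k-fold cross-validation on
#' the full and on the selected features. Writes `report.csv`, `mask.json`
#' and `confusion.json` to the run directory when set.
#'
#' @param cfg A [run_config()].
#' @param features Feature tibble from [run_extract()].
#' @return List: `mask` (the [select_features()] result) and `report`
#'   (tibble with columns Accuracy, Sensitivity, Precision, F1, FNR, Time).
#' @export
run_select_and_classify <- function(cfg, features) {
  mask <- withCallersStage("select",
    select_features(features, lambda = cfg$lambda,
                    params = cfo_params(M = cfg$cfo_pop,
                                        max_evals = cfg$cfo_budget,
                                        seed = cfg$seed)))
  X <- feature_matrix(features)
  sel <- tibble::as_tibble(X[, mask$mask, drop = FALSE])
  sel$label <- features$label
  report <- dplyr::bind_rows(
    classify_features(features, cfg, label = "fused", selection = FALSE),
    classify_features(sel, cfg, label = "fused+CFO", selection = TRUE)
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(cfg$out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(list(selected = mask$selected, fitness = mask$fitness,
                              selected_count = mask$selected_count),
                         file.path(cfg$out_dir, "mask.json"), auto_unbox = TRUE)
  }
  list(mask = mask, report = report)
}

#' Feature-source ablation grid
#'
#' Evaluates every configured classifier on four feature sources — the
#' inception branch's attention output, the dense branch's attention
#' output, the fused concatenation, and the fused features after CFO
#' selection — reproducing the 4-experiments-by-variants report grid.
#'
#' @param run An [run_training()] result.
#' @param cfg Optional config override (defaults to the run's).
#' @return Report tibble (one row per source x classifier).
#' @export
ablation_study <- function(run, cfg = run$cfg) {
  fused <- run_extract(run, tap = "fusion_cat")
  rows <- dplyr::bind_rows(
    classify_features(run_extract(run, tap = "i_attention"), cfg, "inception"),
    classify_features(run_extract(run, tap = "d_attention"), cfg, "dense"),
    classify_features(fused, cfg, "fused")
  )
  sel <- run_select_and_classify(cfg, fused)
  dplyr::bind_rows(rows, dplyr::filter(sel$report, .data$selection))
}

#' Random-search hyperparameter tuner
#'
#' Pluggable tuner over `{lr, momentum, batch_size}`: samples `budget`
#' settings from the space (log-uniform for `lr`, uniform for `momentum`,
#' uniform choice for `batch_size`) and returns the best-scoring one. The
#' shipped defaults of [run_config()] are the tuned values; this interface
#' exists to re-derive settings on new data with any scoring function.
#'
#' @param space List with `lr = c(lo, hi)`, `momentum = c(lo, hi)`,
#'   `batch_size = <choices>`.
#' @param budget Number of sampled settings (>= 1).
#' @param seed RNG seed.
#' @param scorer `function(settings)` returning a score to maximize;
#'   default trains a small phantom run and scores test accuracy.
#' @return List: best `settings`, its `score`, and the full `trials` tibble.
#' @export
tune_hyperparameters <- function(space, budget, seed = 1L, scorer = NULL) {
  if (budget < 1L) stop("tuner budget must be >= 1")
  stopifnot(all(c("lr", "momentum", "batch_size") %in% names(space)))
  set.seed(seed)
  settings <- purrr::map(seq_len(budget), function(i) {
    list(lr = exp(stats::runif(1, log(space$lr[1]), log(space$lr[2]))),
         momentum = stats::runif(1, space$momentum[1], space$momentum[2]),
         batch_size = as.integer(sample(rep(space$batch_size, 2L), 1L)))
  })
  scorer <- scorer %||% function(s) {
    cfg <- run_config(n_classes = 3L, per_class = 8L, width_scale = 0.125,
                      epochs = 2L, lr = s$lr, momentum = s$momentum,
                      batch_size = s$batch_size, seed = seed)
    run <- run_training(cfg)
    probs <- forward(run$net, dataset_array(run$split$test))
    mean(max.col(probs) == as.integer(run$split$test$label))
  }
  scores <- vapply(settings, function(s) scorer(s), numeric(1))
  best <- which.max(scores)
  list(settings = settings[[best]], score = scores[best],
       trials = tibble::tibble(
         lr = vapply(settings, `[[`, numeric(1), "lr"),
         momentum = vapply(settings, `[[`, numeric(1), "momentum"),
         batch_size = vapply(settings, `[[`, integer(1), "batch_size"),
         score = scores))
}
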