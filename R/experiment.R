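#' Repeat-experiment evaluation of the prognosis pipeline
#'
#' For each repeat: a stratified random split of the tumor samples into
#' training and test halves, p-value-threshold selection by stratified
#' k-fold cross-validation on the training half, classifier training on the
#' full training half restricted to the selected genes, and metric
#' evaluation on the test half. The per-patient feature matrix is computed
#' once (it does not depend on the split). Running two experiments with the
#' same `seed` yields identical splits, which pairs ablation variants.
#'
#' @param cohort A `cohort`.
#' @param network A `gene_network`.
#' @param n_repeats Number of repeated splits. Default 10.
#' @param train_fraction Training share of the stratified split. Default 0.5.
#' @param grid Candidate p-value thresholds for gene selection.
#' @param cv_folds Folds for threshold choice. Default 5.
#' @param config Classifier configuration, see [dnn_config()].
#' @param network_variant,feature_mode Ablation hooks, see
#'   [compute_features()].
#' @param penalty Mutation penalty factor. Default 0.85.
#' @param seed Master seed; every repeat derives its own seeds from it.
#' @param features Optional precomputed [compute_features()] tibble to
#'   reuse across experiments.
#' @return A `driver_experiment` object; `tidy()` gives the per-repeat
#'   metrics, `glance()` their means.
#' @export
run_experiment <- function(cohort, network, n_repeats = 10,
                           train_fraction = 0.5,
                           grid = c(0.1, 0.05, 0.01, 0.005), cv_folds = 5,
                           config = dnn_config(),
                           network_variant = "patient",
                           feature_mode = "win_rate",
                           penalty = 0.85, seed = 1, features = NULL) {
  stopifnot(inherits(cohort, "cohort"), n_repeats >= 1,
            train_fraction > 0, train_fraction < 1)
  if (is.null(features)) {
    features <- compute_features(cohort, network,
                                 network_variant = network_variant,
                                 feature_mode = feature_mode,
                                 penalty = penalty, seed = seed)
  }
  fm <- features_matrix(features)
  samples <- rownames(fm)
  labels <- cohort$labels[samples]

  metrics <- vector("list", n_repeats)
  selections <- vector("list", n_repeats)
  train_sets <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rep_seed <- seed * 1000L + r
    split <- stratified_split(labels, train_fraction, rep_seed)
    tr <- samples[split]
    te <- samples[!split]
    sel <- choose_threshold(fm[tr, , drop = FALSE],
                            cohort$tumor_expr[, tr, drop = FALSE],
                            labels[tr], grid = grid, k = cv_folds,
                            config = config, seed = rep_seed)
    cfg <- config
    cfg$seed <- config$seed + rep_seed
    model <- train_dnn(fm[tr, sel$selected_genes, drop = FALSE], labels[tr], cfg)
    probs <- predict(model, fm[te, sel$selected_genes, drop = FALSE])
    metrics[[r]] <- dplyr::bind_cols(
      tibble::tibble(repeat_id = r, chosen_threshold = sel$chosen_threshold,
                     n_selected = length(sel$selected_genes)),
      evaluate_predictions(probs, labels[te])
    )
    selections[[r]] <- sel
    train_sets[[r]] <- tr
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics), selections = selections,
         train_samples = train_sets, features = features, labels = labels,
         params = list(n_repeats = n_repeats, train_fraction = train_fraction,
                       grid = grid, cv_folds = cv_folds, seed = seed,
                       network_variant = network_variant,
                       feature_mode = feature_mode, penalty = penalty)),
    class = "driver_experiment"
  )
}

#' @exportS3Method base::print
print.driver_experiment <- function(x, ...) {
  cat("<driver_experiment> ", x$params$n_repeats, " repeats; ",
      x$params$network_variant, " network, ", x$params$feature_mode,
      " features; mean AUC ", round(mean(x$metrics$auc), 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.driver_experiment <- function(x, ...) {
  x$metrics
}

#' @export
glance.driver_experiment <- function(x, ...) {
  dplyr::summarise(
    x$metrics,
    n_repeats = dplyr::n(),
    sd_auc = stats::sd(.data$auc),
    dplyr::across(c("auc", "pr_auc", "balanced_accuracy", "f1", "mcc"),
                  mean)
  )
}

#' Write per-repeat metrics as TSV
#'
#' @param experiment A `driver_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(experiment, path) {
  readr::write_tsv(tidy(experiment), path)
  invisible(path)
}

# Stratified train/test split: TRUE = training. Per class, round() of the
# class size goes to training.
stratified_split <- function(labels, train_fraction, seed) {
  take <- logical(length(labels))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    n_tr <- max(1, round(length(idx) * train_fraction))
    take[sample(idx, n_tr)] <- TRUE
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  take
}
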