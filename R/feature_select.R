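#' Per-gene Welch t-test between prognosis groups
#'
#' Two-sided two-sample (unequal-variance) t-test of each gene's expression
#' between the good- and bad-prognosis samples. Genes that are constant in
#' both groups get p = 1 by convention.
#'
#' @param expr_good,expr_bad Gene-by-sample numeric matrices over the same
#'   genes, at least 2 samples each.
#' @return Named per-gene p-value vector.
#' @export
per_gene_test <- function(expr_good, expr_bad) {
  if (ncol(expr_good) < 2 || ncol(expr_bad) < 2) {
    stop("each prognosis group needs at least 2 samples", call. = FALSE)
  }
  stopifnot(nrow(expr_good) == nrow(expr_bad))
  p <- vapply(seq_len(nrow(expr_good)), function(i) {
    tryCatch(t.test(expr_good[i, ], expr_bad[i, ])$p.value,
             error = function(e) 1)
  }, numeric(1))
  p[is.na(p)] <- 1
  setNames(p, rownames(expr_good))
}

#' Choose the gene-selection p-value threshold by cross-validation
#'
#' Runs stratified k-fold cross-validation on the training set: within each
#' fold, per-gene t-test p-values are computed on the fold's training
#' samples only (no held-out label ever influences selection), genes below
#' each candidate threshold are selected, a classifier is trained on the
#' win-rate features of those genes and scored by AUC on the held-out fold.
#' The threshold with the highest mean fold AUC wins; ties go to the
#' smaller (stricter) threshold. The returned gene set is re-derived on the
#' full training set at the chosen threshold.
#'
#' @param features Samples-by-genes feature tibble or matrix (training
#'   samples only), as from [compute_features()].
#' @param expr_tumor Gene-by-sample expression matrix for the same training
#'   samples.
#' @param labels Named factor (`good`/`bad`) over the training samples.
#' @param grid Candidate p-value thresholds. Default `c(0.1, 0.05, 0.01, 0.005)`.
#' @param k Number of folds. Default 5.
#' @param config Classifier configuration, see [dnn_config()].
#' @param seed Integer seed governing fold assignment and fold-model training.
#' @return A `feature_selection` object: `p_values` (full training set),
#'   `chosen_threshold`, `selected_genes`, `fold_auc` (tibble of threshold,
#'   mean_auc).
#' @export
choose_threshold <- function(features, expr_tumor, labels,
                             grid = c(0.1, 0.05, 0.01, 0.005), k = 5,
                             config = dnn_config(), seed = 1) {
  stopifnot(length(grid) > 0, k >= 2)
  fm <- if (is.matrix(features)) features else features_matrix(features)
  samples <- rownames(fm)
  labels <- droplevels(labels[samples])
  if (nlevels(labels) != 2) stop("training labels must contain both classes", call. = FALSE)
  if (min(table(labels)) < k) {
    stop("fewer samples than folds in one class; cannot stratify", call. = FALSE)
  }
  folds <- stratified_folds(labels, k, seed)

  grid <- sort(unique(grid))
  fold_aucs <- matrix(NA_real_, nrow = k, ncol = length(grid))
  for (fold in seq_len(k)) {
    tr <- samples[folds != fold]
    te <- samples[folds == fold]
    p <- per_gene_test(expr_tumor[, intersect(tr, samples[labels == "good"]), drop = FALSE],
                       expr_tumor[, intersect(tr, samples[labels == "bad"]), drop = FALSE])
    for (gi in seq_along(grid)) {
      sel <- names(p)[p < grid[gi]]
      if (length(sel) == 0) {
        fold_aucs[fold, gi] <- 0.5  # nothing selected: uninformative fold
        next
      }
      cfg <- config
      cfg$seed <- config$seed + 1000L * fold + seed
      model <- train_dnn(fm[tr, sel, drop = FALSE], labels[tr], cfg)
      probs <- predict(model, fm[te, sel, drop = FALSE])
      fold_aucs[fold, gi] <- roc_auc(probs, labels[te])
    }
  }
  mean_auc <- colMeans(fold_aucs)
  best <- grid[which.max(mean_auc)]  # which.max takes the first (smallest) tie

  p_full <- per_gene_test(expr_tumor[, samples[labels == "good"], drop = FALSE],
                          expr_tumor[, samples[labels == "bad"], drop = FALSE])
  selected <- names(p_full)[p_full < best]
  if (length(selected) == 0) {
    # degenerate null case: keep the classifier viable with the best gene
    selected <- names(which.min(p_full))
    message("no gene below chosen threshold ", best,
            "; falling back to the smallest-p gene")
  }
  structure(
    list(p_values = p_full, chosen_threshold = best, selected_genes = selected,
         fold_auc = tibble::tibble(threshold = grid, mean_auc = mean_auc)),
    class = "feature_selection"
  )
}

#' @exportS3Method base::print
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> threshold ", x$chosen_threshold, "; ",
      length(x$selected_genes), " genes selected of ",
      length(x$p_values), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.feature_selection <- function(x, ...) {
  tibble::tibble(gene = names(x$p_values), p_value = unname(x$p_values),
                 selected = names(x$p_values) %in% x$selected_genes)
}

#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(chosen_threshold = x$chosen_threshold,
                 n_selected = length(x$selected_genes),
                 best_mean_auc = max(x$fold_auc$mean_auc))
}

#' Write a selection result (gene, p-value, selected flag) as TSV
#'
#' @param selection A `feature_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(selection, path) {
  readr::write_tsv(tidy(selection), path)
  invisible(path)
}

# Stratified fold ids in [1, k], balanced within each class.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (cls in levels(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  folds
}
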