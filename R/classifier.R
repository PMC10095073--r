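#' Configuration for the feed-forward prognosis classifier
#'
#' Three hidden layers with ReLU activations, a sigmoid output unit,
#' binary cross-entropy loss and Adam at learning rate 0.001 with
#' mini-batches of 2 for up to 200 epochs. Training terminates early once
#' the mean per-epoch loss has been below `early_stop_loss` on more than
#' `early_stop_count` epochs (cumulative by default).
#'
#' @param hidden Integer widths of the 3 hidden layers, or `NULL` to derive
#'   a geometric taper from the input width p (p/2, p/4, p/8, floored at
#'   64, 32 and 16 units).
#' @param learning_rate Adam learning rate. Default 0.001.
#' @param batch_size Mini-batch size. Default 2.
#' @param max_epochs Epoch cap. Default 200.
#' @param early_stop_loss Loss level counting toward early stopping.
#'   Default 1e-4.
#' @param early_stop_count Number of low-loss epochs after which training
#'   stops. Default 20.
#' @param early_stop_mode `"cumulative"` (default) or `"consecutive"`.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(hidden = NULL, learning_rate = 0.001, batch_size = 2,
                       max_epochs = 200, early_stop_loss = 1e-4,
                       early_stop_count = 20,
                       early_stop_mode = c("cumulative", "consecutive"),
                       seed = 1L) {
  early_stop_mode <- match.arg(early_stop_mode)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  if (!is.null(hidden)) stopifnot(length(hidden) == 3, all(hidden >= 1))
  structure(list(hidden = hidden, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_loss = early_stop_loss,
                 early_stop_count = as.integer(early_stop_count),
                 early_stop_mode = early_stop_mode,
                 seed = as.integer(seed)),
            class = "dnn_config")
}

# Geometric taper from the input width with generous floors: narrow ReLU
# layers die easily on small samples, and 64-32-16 keeps small-batch Adam
# training stable for the feature-set sizes the selection step produces.
default_hidden <- function(p) {
  pmax(ceiling(p / c(2, 4, 8)), c(64L, 32L, 16L))
}

#' Train the feed-forward prognosis classifier
#'
#' @param features Samples-by-genes numeric matrix or feature tibble
#'   (training samples); column order defines the model's gene order.
#' @param labels Factor (`good`/`bad`) named by sample or aligned with the
#'   rows of `features`; `bad` is the positive class.
#' @param config A [dnn_config()].
#' @return A `prognosis_dnn` model object.
#' @export
train_dnn <- function(features, labels, config = dnn_config()) {
  fm <- if (is.matrix(features)) features else features_matrix(features)
  if (!is.null(names(labels)) && !is.null(rownames(fm))) {
    labels <- labels[rownames(fm)]
  }
  labels <- droplevels(factor(labels, levels = c("good", "bad")))
  if (nlevels(labels) < 2) stop("training set has a single class", call. = FALSE)
  if (min(table(labels)) < 2) stop("need at least 2 samples per class", call. = FALSE)
  if (ncol(fm) < 1) stop("need at least one feature", call. = FALSE)
  y <- as.numeric(labels == "bad")
  hidden <- config$hidden %||% default_hidden(ncol(fm))
  fit <- .mlp_train(t(fm), y, as.integer(hidden),
                    config$learning_rate, config$batch_size,
                    config$max_epochs, config$early_stop_loss,
                    config$early_stop_count,
                    config$early_stop_mode == "consecutive",
                    config$seed)
  structure(
    list(weights = fit$weights, biases = fit$biases, genes = colnames(fm),
         hidden = hidden, config = config, loss = fit$loss,
         epochs = fit$epochs),
    class = "prognosis_dnn"
  )
}

#' @exportS3Method base::print
print.prognosis_dnn <- function(x, ...) {
  cat("<prognosis_dnn> ", length(x$genes), " -> ",
      paste(x$hidden, collapse = " -> "), " -> 1; trained ", x$epochs,
      " epochs (final loss ", signif(x$loss[length(x$loss)], 4), ")\n",
      sep = "")
  invisible(x)
}

#' Predict the probability of bad prognosis
#'
#' @param object A `prognosis_dnn`.
#' @param newdata Samples-by-genes matrix or feature tibble; must contain
#'   every gene the model was trained on.
#' @param ... Unused.
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
predict.prognosis_dnn <- function(object, newdata, ...) {
  fm <- if (is.matrix(newdata)) newdata else features_matrix(newdata)
  missing <- setdiff(object$genes, colnames(fm))
  if (length(missing) > 0) {
    stop("features missing model genes: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  a <- t(fm[, object$genes, drop = FALSE])
  L <- length(object$weights)
  for (l in seq_len(L)) {
    z <- object$weights[[l]] %*% a + as.numeric(object$biases[[l]])
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  setNames(as.numeric(a), rownames(fm))
}

#' @export
glance.prognosis_dnn <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), epochs = x$epochs,
                 final_loss = x$loss[length(x$loss)])
}

#' Classification metrics for prognosis predictions
#'
#' AUC and PR-AUC are computed from the raw probabilities; balanced
#' accuracy, F1 and Matthews correlation from calls at `threshold`. The
#' positive class is `bad`.
#'
#' @param probs Predicted probabilities of bad prognosis.
#' @param labels Factor (`good`/`bad`), aligned with `probs` (by name when
#'   both are named).
#' @param threshold Call threshold. Default 0.5.
#' @return One-row tibble: `auc`, `pr_auc`, `balanced_accuracy`, `f1`, `mcc`.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5) {
  if (!is.null(names(probs)) && !is.null(names(labels))) {
    labels <- labels[names(probs)]
  }
  labels <- factor(labels, levels = c("good", "bad"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  y <- labels == "bad"
  call_bad <- probs >= threshold
  tp <- sum(call_bad & y); fp <- sum(call_bad & !y)
  fn <- sum(!call_bad & y); tn <- sum(!call_bad & !y)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  tibble::tibble(
    auc = roc_auc(probs, labels),
    pr_auc = pr_auc(probs, labels),
    balanced_accuracy = (sens + spec) / 2,
    f1 = f1,
    mcc = mcc
  )
}

# Rank-based (Mann-Whitney) ROC AUC with midrank tie handling.
roc_auc <- function(probs, labels) {
  y <- labels == "bad"
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(probs, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision: sum over descending unique score thresholds of
# precision * incremental recall.
pr_auc <- function(probs, labels) {
  y <- as.numeric(labels == "bad")
  n_pos <- sum(y)
  if (n_pos == 0 || n_pos == length(y)) return(NA_real_)
  ord <- order(probs, decreasing = TRUE)
  ps <- probs[ord]; ys <- y[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- c(ps[-1] != ps[-length(ps)], TRUE)  # last index of each tie block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * prec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
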