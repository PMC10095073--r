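toy_separable <- function(n = 20, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("s", 1:n), c("fa", "fb")))
  x[1:(n / 2), 1] <- x[1:(n / 2), 1] + 5
  lab <- setNames(factor(rep(c("bad", "good"), each = n / 2),
                         levels = c("good", "bad")), rownames(x))
  list(x = x, labels = lab)
}

test_that("the classifier fits linearly separable data perfectly", {
  toy <- toy_separable()
  model <- train_dnn(toy$x, toy$labels, dnn_config(seed = 7))
  probs <- predict(model, toy$x)
  expect_equal(mean((probs >= 0.5) == (toy$labels == "bad")), 1)
  expect_lte(model$epochs, 200)
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_separable()
  m1 <- train_dnn(toy$x, toy$labels, dnn_config(seed = 3))
  m2 <- train_dnn(toy$x, toy$labels, dnn_config(seed = 3))
  expect_identical(predict(m1, toy$x), predict(m2, toy$x))
  m3 <- train_dnn(toy$x, toy$labels, dnn_config(seed = 4))
  expect_false(identical(predict(m1, toy$x), predict(m3, toy$x)))
})

test_that("early stopping kicks in after enough low-loss epochs", {
  toy <- toy_separable()
  cfg <- dnn_config(learning_rate = 0.05, early_stop_loss = 0.01,
                    early_stop_count = 5, seed = 2)
  model <- train_dnn(toy$x, toy$labels, cfg)
  expect_lt(model$epochs, 200)
  expect_gt(sum(model$loss < 0.01), 5)
})

test_that("prediction is batch-invariant and validates columns", {
  toy <- toy_separable()
  model <- train_dnn(toy$x, toy$labels, dnn_config(seed = 5))
  all_p <- predict(model, toy$x)
  one_p <- predict(model, toy$x[3, , drop = FALSE])
  expect_equal(one_p, all_p[3])

  zero_row <- matrix(0, 1, 2, dimnames = list("z", colnames(toy$x)))
  pz <- predict(model, zero_row)
  expect_true(pz >= 0 && pz <= 1)

  bad_cols <- matrix(0, 1, 1, dimnames = list("z", "other"))
  expect_error(predict(model, bad_cols), "missing model genes")
})

test_that("degenerate training sets are rejected", {
  toy <- toy_separable()
  one_class <- setNames(factor(rep("bad", 20), levels = c("good", "bad")),
                        rownames(toy$x))
  expect_error(train_dnn(toy$x, one_class), "single class")
})

test_that("metrics reproduce hand-computed values", {
  probs <- c(0.9, 0.8, 0.3, 0.1)
  labels <- factor(c("bad", "bad", "good", "good"), levels = c("good", "bad"))
  m <- evaluate_predictions(probs, labels)
  expect_equal(m$auc, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$pr_auc, 1)
  expect_equal(m$balanced_accuracy, 1)

  # one error at threshold 0.5: probs (.9,.4,.6,.1), TP=1 FN=1 FP=1 TN=1
  m2 <- evaluate_predictions(c(0.9, 0.4, 0.6, 0.1),
                             factor(c("bad", "bad", "good", "good"),
                                    levels = c("good", "bad")))
  expect_equal(m2$balanced_accuracy, 0.5)
  expect_equal(m2$f1, 0.5)
  expect_equal(m2$mcc, 0)
  expect_equal(m2$auc, 0.75)  # 3 of 4 pairs ordered correctly
  # average precision by hand: hits at ranks 1 and 3
  expect_equal(m2$pr_auc, 0.5 * 1 + 0.5 * (2 / 3))

  expect_error(evaluate_predictions(probs, factor(rep("bad", 4),
                                                  levels = c("good", "bad"))),
               "single class")
})

test_that("label-independent probabilities give chance-level AUC", {
  set.seed(44)
  probs <- runif(4000)
  labels <- factor(sample(c("good", "bad"), 4000, TRUE),
                   levels = c("good", "bad"))
  expect_equal(evaluate_predictions(probs, labels)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC agrees with pROC to high precision on random inputs", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    probs <- round(runif(n), sample(c(1, 3), 1))  # force some ties
    labels <- factor(sample(c("good", "bad"), n, TRUE, prob = c(0.6, 0.4)),
                     levels = c("good", "bad"))
    if (nlevels(droplevels(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, levels = c("good", "bad"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(evaluate_predictions(probs, labels)$auc, ref,
                 tolerance = 1e-9)
  }
})

test_that("experiments are reproducible and sized by n_repeats", {
  st <- small_study()
  feats <- suppressWarnings(compute_features(st$cohort, st$network))
  ex1 <- run_experiment(st$cohort, st$network, n_repeats = 1, seed = 5,
                        features = feats, cv_folds = 3)
  expect_equal(nrow(tidy(ex1)), 1)

  ex2 <- run_experiment(st$cohort, st$network, n_repeats = 2, seed = 5,
                        features = feats, cv_folds = 3)
  ex3 <- run_experiment(st$cohort, st$network, n_repeats = 2, seed = 5,
                        features = feats, cv_folds = 3)
  expect_identical(tidy(ex2), tidy(ex3))
  expect_identical(ex2$train_samples, ex3$train_samples)
  expect_true(all(c("auc", "pr_auc", "balanced_accuracy", "f1", "mcc")
                  %in% names(tidy(ex2))))
  expect_equal(glance(ex2)$n_repeats, 2)
})
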