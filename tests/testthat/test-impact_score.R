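test_that("damping follows the in-degree closed form", {
  expect_equal(damping_vector(3), 0.5)
  expect_equal(damping_vector(0), 0)
  expect_equal(damping_vector(6), 2 / 3)
  expect_equal(damping_vector(c(a = 1, b = 2)), c(a = 0.25, b = 0.4))
  expect_error(damping_vector(-1))
})

test_that("initial scores are absolute expression differences", {
  expect_equal(initial_scores(5, 8, normalize = FALSE), 3)
  expect_equal(initial_scores(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(initial_scores(c(10, 0), c(0, 10), normalize = FALSE), c(10, 10))
  expect_equal(initial_scores(c(10, 0), c(0, 10)), c(0.5, 0.5))
  expect_equal(initial_scores(c(5, 1, 4), c(1, 5, 2), mode = "rank",
                              normalize = FALSE),
               abs(c(3, 1, 2) - c(1, 3, 2)))
})

test_that("propagation degenerates correctly and hits the known fixed point", {
  # d = 0 everywhere: S = f immediately
  W <- Matrix::Matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p <- propagate(W, c(1, 2, 3), c(0, 0, 0))
  expect_equal(unname(p$s), c(1, 2, 3))
  expect_true(p$converged)
  expect_equal(p$iterations, 1)

  # 2-gene chain g1 -> g2, d = (0, 1/4), f = (1, 0): fixed point (1, 1/4)
  W2 <- Matrix::sparseMatrix(i = 2, j = 1, x = 1, dims = c(2, 2),
                             dimnames = list(c("g1", "g2"), c("g1", "g2")))
  p2 <- propagate(W2, c(1, 0), c(0, 0.25), tol = 1e-12)
  expect_equal(unname(p2$s), c(1, 0.25), tolerance = 1e-9)
  expect_equal(unname(p2$s), propagate_solve(W2, c(1, 0), c(0, 0.25)),
               tolerance = 1e-9)
})

test_that("propagation matches the direct linear solve on random networks", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    net <- generate_network(synthetic_spec(n_genes = n, n_edges = 4 * n,
                                           n_planted_genes = 3, seed = i))
    Wn <- normalize_W(compute_phi(runif(n, 0, 10), net))
    d <- unname(damping_vector(incoming_degree(net)))
    f <- runif(n)
    got <- propagate(Wn, f, d, tol = 1e-12)
    expect_true(got$converged)
    expect_lt(max(abs(unname(got$s) - propagate_solve(Wn, f, d))), 1e-8)
  }
})

test_that("propagation is linear in the initial scores", {
  set.seed(5)
  net <- generate_network(synthetic_spec(n_genes = 30, n_edges = 120,
                                         n_planted_genes = 3, seed = 9))
  Wn <- normalize_W(compute_phi(runif(30, 0, 5), net))
  d <- unname(damping_vector(incoming_degree(net)))
  f <- runif(30)
  s1 <- propagate(Wn, f, d, tol = 1e-12)$s
  s3 <- propagate(Wn, 3 * f, d, tol = 1e-12)$s
  expect_equal(unname(s3), 3 * unname(s1), tolerance = 1e-6)
})

test_that("the mutation penalty spares mutated genes only", {
  s <- c(g1 = 0.4, g2 = 0.4)
  out <- apply_penalty(s, mutated = "g1", p = 0.85)
  expect_equal(unname(out), c(0.4, 0.34))
  expect_equal(apply_penalty(s, "g1", p = 1), s)
  expect_error(apply_penalty(s, "g1", p = 0))
})

test_that("win rates follow the two comparison sets with ties at 0.5", {
  s <- c(g1 = 0.9, g2 = 0.5, g3 = 0.2, g4 = 0.7, g5 = 0.1)
  v <- win_rate(s, mutated = c("g1", "g5"))
  expect_equal(v[["g1"]], 1)    # mutated, beats all 4 others
  expect_equal(v[["g5"]], 0)    # mutated, beats none
  expect_equal(v[["g2"]], 0.5)  # non-mutated: beats g5, loses to g1

  all_tied <- win_rate(setNames(rep(1, 4), paste0("g", 1:4)), "g1")
  expect_true(all(all_tied == 0.5))

  top <- win_rate(c(a = 5, b = 1, c = 2), mutated = "a")
  expect_equal(top[["a"]], 1)

  expect_warning(v0 <- win_rate(s, mutated = character()), "no mutated")
  expect_equal(unname(v0), unname(rank(s) - 1) / 4)
})

test_that("win rates match the brute-force pairwise oracle", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    s <- setNames(sample(round(runif(n, 0, 5), 1)), paste0("g", seq_len(n)))
    mut <- paste0("g", sample(n, sample(1:max(1, n %/% 3), 1)))
    expect_equal(unname(win_rate(s, mut)), win_rate_brute(s, mut))
  }
})

test_that("win rates are invariant under increasing score transforms", {
  set.seed(8)
  s <- setNames(runif(20), paste0("g", 1:20))
  mut <- paste0("g", c(2, 5, 11))
  expect_equal(win_rate(s, mut), win_rate(exp(4 * s), mut))
})

test_that("the per-patient impact chain produces valid win rates", {
  st <- small_study()
  coh <- st$cohort
  net <- align_network(st$network, coh$genes)
  smp <- colnames(coh$tumor_expr)[3]
  imp <- suppressWarnings(
    patient_impact(net, coh$tumor_expr[, smp], rowMeans(coh$normal_expr),
                   coh$mutations[[smp]])
  )
  expect_equal(nrow(imp), length(coh$genes))
  expect_true(all(imp$v >= 0 & imp$v <= 1))
  expect_true(all(is.finite(imp$s)))
  # penalty: non-mutated genes scaled by 0.85
  expect_equal(imp$s_pen, imp$s * ifelse(imp$mutated, 1, 0.85))
})

test_that("cohort features are one row per tumor sample with correct modes", {
  st <- small_study()
  feats <- suppressWarnings(compute_features(st$cohort, st$network))
  fm <- features_matrix(feats)
  expect_equal(rownames(fm), colnames(st$cohort$tumor_expr))
  expect_equal(colnames(fm), st$cohort$genes)
  expect_true(all(fm >= 0 & fm <= 1))

  raw <- suppressWarnings(
    compute_features(st$cohort, st$network, feature_mode = "raw_score"))
  expect_false(isTRUE(all.equal(features_matrix(raw), fm)))
})
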