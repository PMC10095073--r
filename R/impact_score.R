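#' Per-gene damping factor from incoming degree
#'
#' `d = Asum / (Asum + 3)` where `Asum` is the gene's incoming-edge count.
#' Well-connected genes rely more on propagated influence; isolated genes
#' (d = 0) keep their initial score.
#'
#' @param in_degree Nonnegative per-gene incoming-edge counts, as from
#'   [incoming_degree()].
#' @return Per-gene damping values in \[0, 1), names preserved.
#' @export
#' @examples
#' damping_vector(c(0, 3, 6))  # 0, 0.5, 2/3
damping_vector <- function(in_degree) {
  stopifnot(all(in_degree >= 0))
  in_degree / (in_degree + 3)
}

#' Initial propagation scores from differential expression
#'
#' The seed vector f is the absolute difference between the tumor sample's
#' expression and the mean normal expression, optionally (by default)
#' divided by its sum so per-patient scores share a common scale. A
#' rank-based alternative uses the rank difference R instead.
#'
#' @param tumor_col Per-gene tumor expression.
#' @param normal_mean Per-gene mean normal expression, same order.
#' @param mode `"expression"` (absolute expression difference, default) or
#'   `"rank"` (absolute rank difference).
#' @param normalize Divide by the vector sum (when positive). Default `TRUE`.
#' @return Per-gene nonnegative numeric vector.
#' @export
initial_scores <- function(tumor_col, normal_mean,
                           mode = c("expression", "rank"), normalize = TRUE) {
  mode <- match.arg(mode)
  if (length(tumor_col) != length(normal_mean)) {
    stop("tumor and normal vectors differ in length", call. = FALSE)
  }
  f <- if (mode == "expression") {
    abs(tumor_col - normal_mean)
  } else {
    compute_rank_diff(tumor_col, normal_mean)$r
  }
  if (normalize && sum(f) > 0) f <- f / sum(f)
  f
}

#' Damped network propagation of driver-impact scores
#'
#' Iterates `S <- (1 - d) * f + d * (W_norm %*% S)` from `S = f` until the
#' largest absolute per-gene change falls below `tol`. With column-stochastic
#' `W_norm` and all damping values below 1 the iteration is a contraction and
#' converges to the unique fixed point
#' `S = (I - diag(d) W_norm)^(-1) diag(1 - d) f`.
#'
#' @param W_norm Column-normalised patient weight matrix.
#' @param f Initial per-gene scores.
#' @param d Per-gene damping in \[0, 1).
#' @param tol Convergence threshold on the max-abs change. Default 1e-6.
#' @param max_iter Iteration cap. Default 1000.
#' @return An `impact_scores` object: list with `s` (named per-gene scores),
#'   `converged`, `iterations`.
#' @export
propagate <- function(W_norm, f, d, tol = 1e-6, max_iter = 1000) {
  stopifnot(tol > 0, length(f) == length(d), nrow(W_norm) == length(f),
            all(d >= 0), all(d < 1))
  s <- as.numeric(f)
  for (it in seq_len(max_iter)) {
    s_new <- (1 - d) * f + d * as.numeric(W_norm %*% s)
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta <= tol) {
      return(structure(list(s = setNames(s, rownames(W_norm)),
                            converged = TRUE, iterations = it),
                       class = "impact_scores"))
    }
  }
  message("propagation did not converge in ", max_iter, " iterations")
  structure(list(s = setNames(s, rownames(W_norm)), converged = FALSE,
                 iterations = max_iter),
            class = "impact_scores")
}

#' @exportS3Method base::print
print.impact_scores <- function(x, ...) {
  cat("<impact_scores> ", length(x$s), " genes; ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Down-weight scores of genes without somatic mutation
#'
#' Genes carrying a somatic mutation in the patient keep their propagated
#' score; all other genes are multiplied by the penalty `p` (default 0.85).
#'
#' @param s Per-gene scores (named, or in the order of `genes`).
#' @param mutated Character vector of mutated gene symbols.
#' @param p Penalty factor in (0, 1]. Default 0.85.
#' @return Penalised scores, same names/order.
#' @export
apply_penalty <- function(s, mutated, p = 0.85) {
  stopifnot(p > 0, p <= 1)
  genes <- names(s)
  if (is.null(genes)) stop("scores must be named by gene", call. = FALSE)
  is_mut <- genes %in% mutated
  s * ifelse(is_mut, 1, p)
}

#' Win-rate normalisation of penalised scores
#'
#' Converts a patient's score vector into win rates in \[0, 1\]. A mutated
#' gene is compared against all other genes; a non-mutated gene is compared
#' against the mutated genes only. Each comparison won counts 1, each tie
#' 0.5, divided by the number of comparisons. If the patient has no mutated
#' gene at all, every gene falls back to the all-genes comparison with a
#' warning.
#'
#' @param s Named per-gene (penalised) scores.
#' @param mutated Character vector of mutated gene symbols.
#' @return Named per-gene win rates in \[0, 1\].
#' @export
win_rate <- function(s, mutated) {
  genes <- names(s)
  if (is.null(genes)) stop("scores must be named by gene", call. = FALSE)
  n <- length(s)
  if (n < 2) stop("need at least 2 genes", call. = FALSE)
  is_mut <- genes %in% mutated
  v <- numeric(n)

  # wins + 0.5 * ties against all other genes equals midrank - 1
  mid <- rank(s, ties.method = "average")
  v_all <- (mid - 1) / (n - 1)

  if (!any(is_mut)) {
    warning("patient has no mutated gene; win rates computed against all genes",
            call. = FALSE)
    return(setNames(v_all, genes))
  }
  v[is_mut] <- v_all[is_mut]

  if (any(!is_mut)) {
    sm <- sort(s[is_mut])
    m <- length(sm)
    x <- s[!is_mut]
    n_le <- findInterval(x, sm)
    n_lt <- findInterval(x, sm, left.open = TRUE)
    v[!is_mut] <- (n_lt + 0.5 * (n_le - n_lt)) / m
  }
  setNames(v, genes)
}

#' Driver-impact scores and win rates for one patient
#'
#' Runs the full per-patient scoring chain: patient-specific network,
#' damped propagation of expression differences, mutation penalty, win-rate
#' normalisation.
#'
#' @param network A `gene_network` over the cohort's gene universe.
#' @param tumor_col,normal_mean Per-gene expression vectors.
#' @param mutated The patient's mutated genes.
#' @param penalty Mutation penalty factor. Default 0.85.
#' @param initial_score_mode Passed to [initial_scores()].
#' @param tol,max_iter Passed to [propagate()].
#' @return A tibble with columns `gene`, `f`, `s` (propagated), `s_pen`
#'   (penalised), `v` (win rate), `mutated`.
#' @export
patient_impact <- function(network, tumor_col, normal_mean,
                           mutated = character(), penalty = 0.85,
                           initial_score_mode = "expression",
                           tol = 1e-6, max_iter = 1000) {
  pn <- patient_network(network, tumor_col, normal_mean, mutated)
  d <- damping_vector(incoming_degree(network))
  f <- initial_scores(align_gene_vector(tumor_col, network$genes),
                      align_gene_vector(normal_mean, network$genes),
                      mode = initial_score_mode)
  prop <- propagate(pn$W_norm, f, unname(d), tol = tol, max_iter = max_iter)
  s <- setNames(prop$s, network$genes)
  s_pen <- apply_penalty(s, pn$mutated, p = penalty)
  v <- win_rate(s_pen, pn$mutated)
  tibble::tibble(gene = network$genes, f = unname(f), s = unname(s),
                 s_pen = unname(s_pen), v = unname(v),
                 mutated = network$genes %in% pn$mutated)
}

#' Per-patient driver feature matrix for a cohort
#'
#' Computes, for every tumor sample, the per-gene feature used by the
#' prognosis classifier. The default is the win rate of the penalised
#' propagated score on the patient-specific weighted network. Ablation
#' variants replace the network weighting (`unweighted`: binary adjacency;
#' `random_weight`: i.i.d. uniform edge weights drawn once per call) or the
#' feature (`score_no_winrate`: penalised score; `raw_score`: propagated
#' score without penalty or win rate). The win-rate feature is invariant to
#' the per-patient sum-normalisation of f, so the default path normalises
#' for numerical stability; the two score-feature ablations propagate f on
#' the raw expression scale, which is what feeding scores directly to the
#' classifier means.
#'
#' @param cohort A `cohort`.
#' @param network A `gene_network`; re-aligned to the cohort's genes
#'   automatically.
#' @param network_variant `"patient"`, `"unweighted"` or `"random_weight"`.
#' @param feature_mode `"win_rate"`, `"score_no_winrate"` or `"raw_score"`.
#' @param penalty Mutation penalty factor. Default 0.85.
#' @param initial_score_mode Passed to [initial_scores()].
#' @param tol,max_iter Passed to [propagate()].
#' @param seed Seed for the `random_weight` variant's edge weights.
#' @return A `driver_features` tibble: one row per tumor sample, first
#'   column `sample`, then one column per gene.
#' @export
compute_features <- function(cohort, network,
                             network_variant = c("patient", "unweighted", "random_weight"),
                             feature_mode = c("win_rate", "score_no_winrate", "raw_score"),
                             penalty = 0.85, initial_score_mode = "expression",
                             tol = 1e-6, max_iter = 1000, seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  network_variant <- match.arg(network_variant)
  feature_mode <- match.arg(feature_mode)
  net <- align_network(network, cohort$genes)
  genes <- net$genes
  n <- length(genes)
  e <- net$edges
  d <- unname(damping_vector(incoming_degree(net)))
  normal_mean <- rowMeans(cohort$normal_expr)
  n_rank <- rank(normal_mean, ties.method = "average")

  fixed_W_norm <- NULL
  if (network_variant == "unweighted") {
    fixed_W_norm <- normalize_W(adjacency_matrix(net))
  } else if (network_variant == "random_weight") {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    wts <- runif(nrow(e))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    fixed_W_norm <- normalize_W(
      Matrix::sparseMatrix(i = e$to, j = e$from, x = wts, dims = c(n, n),
                           dimnames = list(genes, genes)))
  }

  samples <- colnames(cohort$tumor_expr)
  feats <- matrix(NA_real_, nrow = length(samples), ncol = n,
                  dimnames = list(samples, genes))
  for (smp in samples) {
    tumor_col <- cohort$tumor_expr[, smp]
    mutated <- cohort$mutations[[smp]]
    if (is.null(fixed_W_norm)) {
      t_rank <- rank(tumor_col, ties.method = "average")
      r <- abs(t_rank - n_rank)
      phi <- phi_edge_weight(r[e$to], r[e$from])
      is_mut <- genes %in% mutated
      a <- 1 + as.numeric(is_mut[e$from] | is_mut[e$to])
      W <- Matrix::sparseMatrix(i = e$to, j = e$from, x = a * phi,
                                dims = c(n, n), dimnames = list(genes, genes))
      W_norm <- normalize_W(W)
    } else {
      W_norm <- fixed_W_norm
    }
    f <- initial_scores(tumor_col, normal_mean, mode = initial_score_mode,
                        normalize = feature_mode == "win_rate")
    s <- propagate(W_norm, unname(f), d, tol = tol, max_iter = max_iter)$s
    s <- setNames(as.numeric(s), genes)
    feats[smp, ] <- switch(
      feature_mode,
      raw_score = s,
      score_no_winrate = apply_penalty(s, mutated, p = penalty),
      win_rate = win_rate(apply_penalty(s, mutated, p = penalty), mutated)
    )
  }
  out <- tibble::as_tibble(feats, rownames = "sample")
  class(out) <- c("driver_features", class(out))
  attr(out, "feature_mode") <- feature_mode
  attr(out, "network_variant") <- network_variant
  out
}

#' Extract the samples-by-genes matrix from a feature tibble
#'
#' @param features A `driver_features` tibble (or any tibble whose first
#'   column is `sample`).
#' @return Numeric matrix with samples as rownames.
#' @export
features_matrix <- function(features) {
  m <- as.matrix(features[, setdiff(names(features), "sample"), drop = FALSE])
  rownames(m) <- features$sample
  storage.mode(m) <- "double"
  m
}

#' Write a feature matrix as TSV (samples x genes)
#'
#' @param features A `driver_features` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  readr::write_tsv(tibble::as_tibble(features), path)
  invisible(path)
}
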