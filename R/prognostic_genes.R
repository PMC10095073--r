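#' Prognostic genes by top-k rank frequency across repeats
#'
#' For each repeat of an experiment, genes are ranked by their final score
#' — the mean win-rate feature across that repeat's training samples (or
#' the bad-minus-good difference of those means with
#' `final_score = "mean_v_diff"`) — and the top `k` are flagged. Genes
#' flagged in at least `min_count` repeats are the prognostic set.
#'
#' @param experiment A `driver_experiment` from [run_experiment()].
#' @param k Rank cutoff per repeat. Default 30.
#' @param min_count Minimum number of repeats in the top k. Default 3.
#' @param final_score `"mean_v"` (default) or `"mean_v_diff"`.
#' @return A `gene_frequency` tibble: `gene`, `count`, `selected`, sorted
#'   by decreasing count.
#' @export
rank_frequency <- function(experiment, k = 30, min_count = 3,
                           final_score = c("mean_v", "mean_v_diff")) {
  stopifnot(inherits(experiment, "driver_experiment"), k >= 1, min_count >= 1)
  final_score <- match.arg(final_score)
  fm <- features_matrix(experiment$features)
  labels <- experiment$labels
  counts <- setNames(integer(ncol(fm)), colnames(fm))
  for (tr in experiment$train_samples) {
    score <- if (final_score == "mean_v") {
      colMeans(fm[tr, , drop = FALSE])
    } else {
      bad <- tr[labels[tr] == "bad"]
      good <- tr[labels[tr] == "good"]
      colMeans(fm[bad, , drop = FALSE]) - colMeans(fm[good, , drop = FALSE])
    }
    top <- names(sort(score, decreasing = TRUE))[seq_len(min(k, length(score)))]
    counts[top] <- counts[top] + 1L
  }
  out <- tibble::tibble(gene = names(counts), count = unname(counts),
                        selected = unname(counts) >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene)
  attr(out, "k") <- k
  attr(out, "min_count") <- min_count
  attr(out, "n_repeats") <- length(experiment$train_samples)
  class(out) <- c("gene_frequency", class(out))
  out
}

#' Average edge density of a gene subset across patient networks
#'
#' For every tumor sample's patient-specific weighted network, counts the
#' nonzero W entries within the subgraph induced by `genes` and divides by
#' the number of subset genes; the per-patient values are averaged over the
#' cohort. The same statistic over the full gene universe is returned as
#' the whole-network baseline. A tight, co-dysregulated prognostic module
#' shows a subset density well above baseline.
#'
#' @param cohort A `cohort`.
#' @param network A `gene_network`.
#' @param genes Character vector of subset genes (at least 2 in the
#'   cohort's universe).
#' @return One-row tibble: `subset_density`, `baseline_density`,
#'   `n_subset_genes`, `n_samples`.
#' @export
edge_density <- function(cohort, network, genes) {
  stopifnot(inherits(cohort, "cohort"))
  genes <- intersect(genes, cohort$genes)
  if (length(genes) < 2) {
    stop("need at least 2 subset genes present in the cohort", call. = FALSE)
  }
  net <- align_network(network, cohort$genes)
  e <- net$edges
  n <- length(net$genes)
  in_sub <- net$genes %in% genes
  sub_edge <- in_sub[e$from] & in_sub[e$to]
  normal_mean <- rowMeans(cohort$normal_expr)
  n_rank <- rank(normal_mean, ties.method = "average")

  subset_dens <- baseline_dens <- numeric(ncol(cohort$tumor_expr))
  for (i in seq_len(ncol(cohort$tumor_expr))) {
    t_rank <- rank(cohort$tumor_expr[, i], ties.method = "average")
    r <- abs(t_rank - n_rank)
    # W = A * Phi is nonzero exactly where Phi > 0 (A is 1 or 2 on edges)
    w_pos <- phi_edge_weight(r[e$to], r[e$from]) > 0
    subset_dens[i] <- sum(w_pos & sub_edge) / length(genes)
    baseline_dens[i] <- sum(w_pos) / n
  }
  tibble::tibble(subset_density = mean(subset_dens),
                 baseline_density = mean(baseline_dens),
                 n_subset_genes = length(genes),
                 n_samples = ncol(cohort$tumor_expr))
}

#' Induced subgraph edge list for a gene subset
#'
#' @param network A `gene_network`.
#' @param genes Subset gene symbols.
#' @return Tibble of oriented edges with both endpoints in `genes`.
#' @export
induced_subgraph_edges <- function(network, genes) {
  tidy(network) |>
    dplyr::filter(.data$source %in% genes, .data$target %in% genes)
}
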