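#' Rank difference between a tumor sample and the normal reference
#'
#' Ranks the tumor sample's expression and the mean normal expression
#' ascending (the largest value gets rank n, ties get average ranks) and
#' takes the absolute rank difference R per gene. R is scale-free: any
#' strictly increasing transform of either vector leaves it unchanged.
#'
#' @param tumor_col Per-gene expression of one tumor sample (named or in
#'   gene order).
#' @param normal_mean Per-gene mean expression over the normal samples,
#'   same length and order.
#' @return A tibble with columns `gene`, `t_rank`, `n_rank`, `r`.
#' @export
#' @examples
#' compute_rank_diff(c(a = 5, b = 2, c = 9), c(a = 1, b = 8, c = 3))
compute_rank_diff <- function(tumor_col, normal_mean) {
  if (length(tumor_col) != length(normal_mean)) {
    stop("tumor and normal vectors differ in length", call. = FALSE)
  }
  if (length(tumor_col) < 2) stop("need at least 2 genes to rank", call. = FALSE)
  genes <- names(tumor_col)
  if (is.null(genes)) genes <- paste0("g", seq_along(tumor_col))
  t_rank <- unname(rank(tumor_col, ties.method = "average"))
  n_rank <- unname(rank(normal_mean, ties.method = "average"))
  tibble::tibble(gene = genes, t_rank = t_rank, n_rank = n_rank,
                 r = abs(t_rank - n_rank))
}

#' Edge significance weight Phi
#'
#' For an edge between genes with rank differences `r_i` and `r_j`, the
#' weight is `(r_i + r_j) * min(r_i, r_j)`: the min factor rewards edges
#' whose *both* endpoints are dysregulated, so two moderately shifted genes
#' outweigh one extreme plus one unchanged gene even at equal rank-difference
#' sum.
#'
#' @param r_i,r_j Nonnegative rank-difference values (vectorised).
#' @return Numeric vector of edge weights.
#' @export
#' @examples
#' phi_edge_weight(6, 1)  # 7
#' phi_edge_weight(3, 4)  # 21
phi_edge_weight <- function(r_i, r_j) {
  (r_i + r_j) * pmin(r_i, r_j)
}

#' Phi matrix over a network's oriented edges
#'
#' @param r Per-gene rank-difference vector in network gene order (or named
#'   by gene).
#' @param network A `gene_network`.
#' @return Sparse matrix with `phi_edge_weight()` values at the network's
#'   oriented edge positions (row = target, column = source).
#' @export
compute_phi <- function(r, network) {
  stopifnot(inherits(network, "gene_network"))
  r <- align_gene_vector(r, network$genes, default = 0)
  e <- network$edges
  vals <- phi_edge_weight(r[e$to], r[e$from])
  n <- length(network$genes)
  Matrix::sparseMatrix(i = e$to, j = e$from, x = vals, dims = c(n, n),
                       dimnames = list(network$genes, network$genes))
}

#' Mutation-aware adjacency A
#'
#' A is 2 on edges with at least one somatically mutated endpoint, 1 on
#' other edges, 0 off the edge set.
#'
#' @param network A `gene_network`.
#' @param mutated Character vector of mutated gene symbols for the patient;
#'   symbols outside the network's universe are ignored.
#' @return Sparse matrix of 1/2 values at edge positions.
#' @export
build_A <- function(network, mutated) {
  stopifnot(inherits(network, "gene_network"))
  mut_idx <- match(intersect(mutated, network$genes), network$genes)
  is_mut <- logical(length(network$genes))
  is_mut[mut_idx] <- TRUE
  e <- network$edges
  vals <- 1 + as.numeric(is_mut[e$from] | is_mut[e$to])
  n <- length(network$genes)
  Matrix::sparseMatrix(i = e$to, j = e$from, x = vals, dims = c(n, n),
                       dimnames = list(network$genes, network$genes))
}

#' Patient network weights W = A (x) Phi
#'
#' @param A,Phi Matrices of identical shape (as from [build_A()] and
#'   [compute_phi()]).
#' @return Their elementwise product.
#' @export
build_W <- function(A, Phi) {
  if (!all(dim(A) == dim(Phi))) stop("A and Phi shapes differ", call. = FALSE)
  A * Phi
}

#' Column-normalise a weight matrix
#'
#' Divides every column with nonzero sum by that sum, so each source gene
#' distributes unit influence across its outgoing edges; all-zero columns
#' (genes with no out-edges, or whose edges all have zero weight) stay zero.
#' Column-stochastic W keeps the damped propagation a contraction.
#'
#' @param W Nonnegative sparse or dense matrix, columns = source genes.
#' @return The normalised matrix.
#' @export
normalize_W <- function(W) {
  cs <- Matrix::colSums(W)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  W %*% Matrix::Diagonal(x = scale, n = length(scale))
}

#' Build the full patient-specific network for one tumor sample
#'
#' Combines the rank-difference weights and the mutation-aware adjacency
#' into the patient's weighted network and its column-normalised propagation
#' operator.
#'
#' @param network A `gene_network` over the cohort's gene universe.
#' @param tumor_col Per-gene expression of the tumor sample (network gene
#'   order, or named).
#' @param normal_mean Per-gene mean normal expression, same order.
#' @param mutated Character vector of the patient's mutated genes.
#' @return A `patient_network` object with elements `genes`, `rank_diff`
#'   (tibble), `A`, `phi`, `W`, `W_norm` (sparse matrices).
#' @export
patient_network <- function(network, tumor_col, normal_mean, mutated = character()) {
  stopifnot(inherits(network, "gene_network"))
  tumor_col <- align_gene_vector(tumor_col, network$genes)
  normal_mean <- align_gene_vector(normal_mean, network$genes)
  rd <- compute_rank_diff(setNames(tumor_col, network$genes), normal_mean)
  Phi <- compute_phi(rd$r, network)
  A <- build_A(network, mutated)
  W <- build_W(A, Phi)
  structure(
    list(genes = network$genes, rank_diff = rd, A = A, phi = Phi, W = W,
         W_norm = normalize_W(W), mutated = intersect(mutated, network$genes)),
    class = "patient_network"
  )
}

#' @exportS3Method base::print
print.patient_network <- function(x, ...) {
  cat("<patient_network> ", length(x$genes), " genes, ",
      length(x$W@x), " weighted edges (",
      sum(x$W@x > 0), " nonzero), ", length(x$mutated),
      " mutated genes\n", sep = "")
  invisible(x)
}

#' @export
tidy.patient_network <- function(x, ...) {
  tr <- Matrix::mat2triplet(x$A)
  idx <- cbind(tr$i, tr$j)
  tibble::tibble(
    source = x$genes[tr$j],
    target = x$genes[tr$i],
    a = tr$x,
    phi = x$phi[idx],
    w = x$W[idx]
  ) |> dplyr::arrange(.data$source, .data$target)
}

#' Write a patient network's edges (source, target, A, Phi, W) as TSV
#'
#' @param pn A `patient_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_network_tsv <- function(pn, path) {
  readr::write_tsv(tidy(pn), path)
  invisible(path)
}

# Reorder a per-gene vector onto `genes`; named vectors are matched by name,
# unnamed vectors must already be in order. Missing genes get `default`.
align_gene_vector <- function(x, genes, default = NA_real_) {
  if (!is.null(names(x))) {
    out <- setNames(rep(default, length(genes)), genes)
    hit <- intersect(names(x), genes)
    out[hit] <- x[hit]
    if (anyNA(out)) stop("vector missing values for some network genes", call. = FALSE)
    unname(out)
  } else {
    if (length(x) != length(genes)) {
      stop("unnamed per-gene vector has wrong length", call. = FALSE)
    }
    as.numeric(x)
  }
}
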