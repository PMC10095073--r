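#' Read a gene-network edge list from TSV
#'
#' Reads a two- or three-column tab-separated edge list (source, target,
#' optional directedness flag). Exact duplicate (source, target, directed)
#' triples are collapsed.
#'
#' @param path Path to a TSV file.
#' @param directed_default Logical; directedness assumed for rows without a
#'   third column. Functional-interaction networks are typically undirected
#'   (`FALSE`), regulatory networks directed (`TRUE`).
#' @param header Logical; whether the first line is a header to skip.
#' @param source_name Free-text label stored on the result.
#'
#' @return A tibble with columns `source`, `target`, `directed` and attribute
#'   `source_name`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("TP53\tMDM2\tTRUE", "BRCA1\tBARD1\tFALSE"), tf)
#' read_edge_list(tf)
read_edge_list <- function(path, directed_default = TRUE, header = FALSE,
                           source_name = basename(path)) {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines_kept <- which(nzchar(trimws(lines)))
  if (length(lines_kept) == 0) {
    out <- tibble::tibble(source = character(), target = character(),
                          directed = logical())
    attr(out, "source_name") <- source_name
    return(out)
  }
  parts <- strsplit(lines[lines_kept], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0) {
    stop("malformed edge-list row at line ",
         lines_kept[bad[1]] + as.integer(header),
         " of ", path, " (expected 2-3 tab-separated fields, got ",
         nf[bad[1]], ")", call. = FALSE)
  }
  src <- trimws(vapply(parts, `[`, "", 1L))
  tgt <- trimws(vapply(parts, `[`, "", 2L))
  dir_raw <- vapply(parts, function(p) if (length(p) >= 3) trimws(p[3]) else NA_character_, "")
  directed <- dplyr::case_when(
    is.na(dir_raw) ~ directed_default,
    tolower(dir_raw) %in% c("true", "t", "1", "directed", "yes") ~ TRUE,
    tolower(dir_raw) %in% c("false", "f", "0", "undirected", "no") ~ FALSE,
    TRUE ~ NA
  )
  if (anyNA(directed)) {
    stop("unrecognised directedness flag '",
         dir_raw[which(is.na(directed))[1]], "' in ", path, call. = FALSE)
  }
  if (any(!nzchar(src)) || any(!nzchar(tgt))) {
    stop("empty gene symbol in ", path, call. = FALSE)
  }
  out <- tibble::tibble(source = src, target = tgt, directed = directed)
  n_read <- nrow(out)
  out <- dplyr::distinct(out)
  n_dup <- n_read - nrow(out)
  message("read ", n_read, " edges from ", source_name,
          " (", n_dup, " duplicate", if (n_dup == 1) "" else "s", " dropped)")
  attr(out, "source_name") <- source_name
  out
}

#' Integrate edge lists into an oriented gene network
#'
#' Unions one or more edge lists into a single directed network over the
#' union of their node sets. Directed input edges are reversed (an edge
#' u -> v becomes v -> u) so that downstream propagation flows from a gene's
#' targets back to the gene, scoring regulators by the dysregulation of what
#' they control. Undirected edges contribute both orientations. Self-loops
#' are dropped with a warning and duplicate oriented edges are collapsed.
#'
#' @param ... Edge-list tibbles as returned by [read_edge_list()] (columns
#'   `source`, `target`, `directed`), or a single list of them.
#'
#' @return A `gene_network` object: the ordered gene universe plus the
#'   oriented edge set.
#' @export
#' @examples
#' el <- tibble::tibble(source = "A", target = "B", directed = TRUE)
#' net <- integrate_networks(el)
#' tidy(net)  # single oriented edge B -> A
integrate_networks <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  if (length(lists) == 0 || all(vapply(lists, nrow, 0L) == 0)) {
    stop("empty network: no edges in any input edge list", call. = FALSE)
  }
  all_edges <- dplyr::bind_rows(lists)
  n_loops <- sum(all_edges$source == all_edges$target)
  if (n_loops > 0) {
    warning("dropping ", n_loops, " self-loop edge",
            if (n_loops == 1) "" else "s", call. = FALSE)
    all_edges <- dplyr::filter(all_edges, .data$source != .data$target)
  }
  if (nrow(all_edges) == 0) stop("empty network after self-loop removal", call. = FALSE)
  directed <- dplyr::filter(all_edges, .data$directed)
  undirected <- dplyr::filter(all_edges, !.data$directed)
  oriented <- dplyr::bind_rows(
    # reverse directed edges: influence runs target -> source
    tibble::tibble(source = directed$target, target = directed$source),
    tibble::tibble(source = undirected$source, target = undirected$target),
    tibble::tibble(source = undirected$target, target = undirected$source)
  )
  oriented <- dplyr::distinct(oriented)
  genes <- sort(unique(c(oriented$source, oriented$target)))
  new_gene_network(genes,
                   from = match(oriented$source, genes),
                   to = match(oriented$target, genes))
}

new_gene_network <- function(genes, from, to) {
  stopifnot(length(from) == length(to))
  ord <- order(from, to)
  structure(
    list(genes = genes,
         edges = tibble::tibble(from = as.integer(from[ord]),
                                to = as.integer(to[ord]))),
    class = "gene_network"
  )
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$genes), " genes, ",
      nrow(x$edges), " oriented edges\n", sep = "")
  invisible(x)
}

#' Number of incoming edges per gene
#'
#' Counts, for each gene, the oriented edges pointing into it. This count
#' drives the per-gene damping factor of the propagation.
#'
#' @param network A `gene_network`.
#' @return Named integer vector over the network's gene universe.
#' @export
incoming_degree <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  deg <- tabulate(network$edges$to, nbins = length(network$genes))
  setNames(as.integer(deg), network$genes)
}

#' Sparse adjacency of the oriented network
#'
#' Entry (i, j) is 1 when the oriented edge j -> i exists, so columns index
#' source genes and rows target genes.
#'
#' @param network A `gene_network`.
#' @return A sparse `dgCMatrix`.
#' @export
adjacency_matrix <- function(network) {
  n <- length(network$genes)
  Matrix::sparseMatrix(i = network$edges$to, j = network$edges$from,
                       x = 1, dims = c(n, n),
                       dimnames = list(network$genes, network$genes))
}

#' Restrict a network to a gene universe
#'
#' Re-indexes a network onto `genes`: edges with an endpoint outside the
#' universe are dropped, and genes absent from the network are retained as
#' isolated nodes (zero degree, zero damping) so that every analysis shares
#' one consistent gene order.
#'
#' @param network A `gene_network`.
#' @param genes Character vector defining the new universe and its order.
#' @return A `gene_network` over exactly `genes`.
#' @export
align_network <- function(network, genes) {
  stopifnot(inherits(network, "gene_network"))
  src <- network$genes[network$edges$from]
  tgt <- network$genes[network$edges$to]
  keep <- src %in% genes & tgt %in% genes
  new_gene_network(genes, from = match(src[keep], genes),
                   to = match(tgt[keep], genes))
}

#' @export
tidy.gene_network <- function(x, ...) {
  tibble::tibble(source = x$genes[x$edges$from],
                 target = x$genes[x$edges$to])
}

#' @export
glance.gene_network <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), n_edges = nrow(x$edges))
}

#' Write an oriented network as a two-column TSV
#'
#' @param network A `gene_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  readr::write_tsv(tidy(network), path, col_names = TRUE)
  invisible(path)
}
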