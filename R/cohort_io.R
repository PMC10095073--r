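#' Remove genes that are zero in most samples
#'
#' Drops genes whose expression is exactly zero in more than
#' `zero_fraction` of the samples. A gene at exactly the threshold is kept.
#' When both a tumor and a normal matrix are supplied the zero fraction is
#' computed over the pooled samples.
#'
#' @param expr Numeric gene-by-sample matrix with gene symbols as rownames,
#'   or a data frame whose first column holds gene symbols.
#' @param zero_fraction Maximum tolerated fraction of zero entries per gene,
#'   in (0, 1]. Default 0.8.
#' @param more Optional second matrix (same genes, e.g. the normal samples)
#'   pooled with `expr` when computing zero fractions.
#'
#' @return The filtered `expr` with gene order preserved.
#' @export
filter_low_expression <- function(expr, zero_fraction = 0.8, more = NULL) {
  stopifnot(is.numeric(zero_fraction), zero_fraction > 0, zero_fraction <= 1)
  is_df <- is.data.frame(expr)
  m <- if (is_df) as.matrix(expr[, -1, drop = FALSE]) else expr
  if (is_df) rownames(m) <- as.character(expr[[1]])
  pool <- if (is.null(more)) m else cbind(m, more[rownames(m), , drop = FALSE])
  frac0 <- rowMeans(pool == 0)
  keep <- frac0 <= zero_fraction
  if (!any(keep)) {
    stop("all genes removed by the ", zero_fraction * 100,
         "% zero-expression filter", call. = FALSE)
  }
  if (is_df) expr[keep, , drop = FALSE] else expr[keep, , drop = FALSE]
}

#' Assign binary prognosis labels from survival data
#'
#' A patient who died before the criterion year is labelled `bad`; a patient
#' known to have survived past it (dead after, or alive with follow-up at
#' least as long) is labelled `good`. Patients censored alive before the
#' criterion are excluded by default since their prognosis class is unknown;
#' `censored_policy = "good"` preserves the literal died-before/not reading.
#'
#' @param clinical Data frame with columns `sample`, `vital_status`
#'   (`"dead"`/`"alive"`, case-insensitive) and `survival_years`.
#' @param criterion_years Positive criterion, in years.
#' @param censored_policy `"exclude"` (default) or `"good"` for
#'   alive-with-short-follow-up samples.
#'
#' @return A tibble with columns `sample` and `label` (factor with levels
#'   `good`, `bad`); excluded samples are dropped.
#' @export
assign_labels <- function(clinical, criterion_years,
                          censored_policy = c("exclude", "good")) {
  censored_policy <- match.arg(censored_policy)
  stopifnot(is.numeric(criterion_years), criterion_years > 0)
  need <- c("sample", "vital_status", "survival_years")
  if (!all(need %in% names(clinical))) {
    stop("clinical data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(clinical$survival_years < 0, na.rm = TRUE)) {
    stop("negative survival time", call. = FALSE)
  }
  status <- tolower(clinical$vital_status)
  if (!all(status %in% c("dead", "alive"))) {
    stop("vital_status must be 'dead' or 'alive'", call. = FALSE)
  }
  label <- dplyr::case_when(
    status == "dead" & clinical$survival_years < criterion_years ~ "bad",
    status == "dead" ~ "good",
    clinical$survival_years >= criterion_years ~ "good",
    censored_policy == "good" ~ "good",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(sample = as.character(clinical$sample),
                        label = factor(label, levels = c("good", "bad")))
  dplyr::filter(out, !is.na(.data$label))
}

#' Assemble an aligned prognosis cohort
#'
#' Aligns tumor expression, normal expression, somatic mutations and labels
#' on a shared gene universe and sample set, optionally applying the
#' zero-expression gene filter over the pooled tumor and normal samples.
#'
#' @param tumor_expr Gene-by-tumor-sample numeric matrix (rownames = genes).
#' @param normal_expr Gene-by-normal-sample numeric matrix over the same genes.
#' @param mutations Data frame with columns `sample`, `gene`, or a named list
#'   of character vectors (one mutated-gene set per tumor sample).
#' @param labels Tibble with columns `sample`, `label` as from
#'   [assign_labels()], or a named factor/character vector.
#' @param criterion_years Criterion year used for the labels (metadata).
#' @param zero_fraction Passed to [filter_low_expression()]; `NULL` skips
#'   the filter.
#'
#' @return A `cohort` object with elements `genes`, `tumor_expr`,
#'   `normal_expr`, `mutations` (named list), `labels` (named factor) and
#'   `criterion_years`.
#' @export
build_cohort <- function(tumor_expr, normal_expr, mutations, labels,
                         criterion_years = NA_real_, zero_fraction = 0.8) {
  stopifnot(is.matrix(tumor_expr), is.matrix(normal_expr))
  common <- intersect(rownames(tumor_expr), rownames(normal_expr))
  if (length(common) == 0) stop("tumor and normal matrices share no genes", call. = FALSE)
  tumor_expr <- tumor_expr[common, , drop = FALSE]
  normal_expr <- normal_expr[common, , drop = FALSE]
  if (!is.null(zero_fraction)) {
    tumor_expr <- filter_low_expression(tumor_expr, zero_fraction,
                                        more = normal_expr)
    normal_expr <- normal_expr[rownames(tumor_expr), , drop = FALSE]
  }
  genes <- rownames(tumor_expr)

  if (is.data.frame(labels)) {
    lab <- setNames(as.character(labels$label), labels$sample)
  } else {
    lab <- setNames(as.character(labels), names(labels))
  }
  samples <- intersect(colnames(tumor_expr), names(lab))
  if (length(samples) == 0) stop("no labelled sample has an expression column", call. = FALSE)
  lab <- factor(lab[samples], levels = c("good", "bad"))
  if (anyNA(lab)) stop("labels must be 'good' or 'bad'", call. = FALSE)
  if (nlevels(droplevels(lab)) < 2) {
    warning("cohort has a single prognosis class", call. = FALSE)
  }
  tumor_expr <- tumor_expr[, samples, drop = FALSE]

  if (is.data.frame(mutations)) {
    mut_list <- split(as.character(mutations$gene), as.character(mutations$sample))
  } else {
    mut_list <- mutations
  }
  mut <- lapply(setNames(samples, samples), function(s) {
    g <- as.character(unique(mut_list[[s]]))
    known <- g %in% genes
    if (any(!known)) {
      message(sum(!known), " mutated gene(s) of sample ", s,
              " absent from the gene universe; ignored")
    }
    g[known]
  })

  structure(
    list(genes = genes, tumor_expr = tumor_expr, normal_expr = normal_expr,
         mutations = mut, labels = lab, criterion_years = criterion_years),
    class = "cohort"
  )
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$genes), " genes; ",
      ncol(x$tumor_expr), " tumor samples (",
      sum(x$labels == "good"), " good / ", sum(x$labels == "bad"), " bad); ",
      ncol(x$normal_expr), " normal samples\n", sep = "")
  invisible(x)
}

#' @export
glance.cohort <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_tumor = ncol(x$tumor_expr),
    n_good = sum(x$labels == "good"),
    n_bad = sum(x$labels == "bad"),
    n_normal = ncol(x$normal_expr),
    criterion_years = x$criterion_years
  )
}

#' Read a gene-by-sample expression TSV
#'
#' First column gene symbols, remaining columns samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with genes as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a two-column (sample, gene) mutation TSV
#'
#' @param path TSV path.
#' @return Tibble with columns `sample`, `gene`.
#' @export
read_mutations_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  col_names = c("sample", "gene"), skip = guess_header(path, c("sample", "gene")))
}

#' Read a clinical TSV (sample, vital_status, survival_years)
#'
#' @param path TSV path.
#' @return Tibble with columns `sample`, `vital_status`, `survival_years`.
#' @export
read_clinical_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_names = c("sample", "vital_status", "survival_years"),
                  skip = guess_header(path, c("sample", "vital_status")))
}

guess_header <- function(path, expected) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(first) >= length(expected) &&
      all(tolower(first[seq_along(expected)]) == expected)) 1L else 0L
}
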