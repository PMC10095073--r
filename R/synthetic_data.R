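#' Specification of a synthetic prognosis cohort
#'
#' Describes a self-contained cohort with planted prognostic structure: a
#' sparse directed gene network with a densified module on the planted
#' genes, log-normal expression with planted tumor-vs-normal rank shifts,
#' an extra expression shift on planted genes in bad-prognosis tumors, and
#' mutation sets enriched on the planted drivers. Generation is a pure
#' function of the spec: the same spec always yields the same cohort.
#'
#' The defaults are the package's demo conditions: 300 genes, 1500 edges,
#' 30 good + 30 bad tumors, 20 normals, 20 planted genes, a strong
#' (3 SD) good-vs-bad effect, seed 42.
#'
#' @param n_genes,n_edges Network size.
#' @param n_tumor_good,n_tumor_bad,n_normal Sample counts.
#' @param n_planted_genes Number of planted prognostic driver genes.
#' @param rank_shift Tumor-vs-normal shift of planted genes, in log-scale
#'   units (displaces their expression ranks upward in every tumor).
#' @param group_effect Additional bad-vs-good shift on planted genes, in
#'   units of the per-gene log-scale SD. 0 gives a null cohort.
#' @param mutation_rate Background per-gene per-sample mutation probability.
#' @param driver_mutation_boost Multiplier on `mutation_rate` for planted
#'   genes (capped at 1).
#' @param sample_scale_sd Log-scale SD of the per-sample global scale
#'   factor (library size / tumor purity variation). Ranks within a sample
#'   are unaffected; absolute expression differences are.
#' @param outlier_rate Per-gene per-sample probability of a heavy-tailed
#'   expression spike (7-50 fold), the single-gene outliers typical of
#'   RNA-seq profiles. Spikes barely move ranks but dominate absolute
#'   expression differences.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list; `planted_genes` holds the planted gene
#'   symbols.
#' @export
synthetic_spec <- function(n_genes = 300, n_edges = 1500,
                           n_tumor_good = 30, n_tumor_bad = 30, n_normal = 20,
                           n_planted_genes = 20, rank_shift = 0.3,
                           group_effect = 3, mutation_rate = 0.05,
                           driver_mutation_boost = 5, sample_scale_sd = 0.15,
                           outlier_rate = 0.01, seed = 42) {
  stopifnot(n_genes >= 2, n_edges >= 0, n_edges <= n_genes * (n_genes - 1),
            n_tumor_good >= 1, n_tumor_bad >= 1, n_normal >= 1,
            n_planted_genes >= 1, n_planted_genes <= n_genes,
            rank_shift >= 0, group_effect >= 0,
            mutation_rate >= 0, mutation_rate <= 1,
            driver_mutation_boost >= 0, sample_scale_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1)
  genes <- sprintf("g%04d", seq_len(n_genes))
  planted <- sort(with_seed(seed, sample(genes, n_planted_genes)))
  structure(
    list(n_genes = n_genes, n_edges = n_edges, n_tumor_good = n_tumor_good,
         n_tumor_bad = n_tumor_bad, n_normal = n_normal,
         n_planted_genes = n_planted_genes, rank_shift = rank_shift,
         group_effect = group_effect, mutation_rate = mutation_rate,
         driver_mutation_boost = driver_mutation_boost,
         sample_scale_sd = sample_scale_sd, outlier_rate = outlier_rate,
         seed = seed,
         genes = genes, planted_genes = planted),
    class = "synthetic_spec"
  )
}

#' @exportS3Method base::print
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_genes, " genes / ", x$n_edges, " edges; ",
      x$n_tumor_good, "+", x$n_tumor_bad, " tumors, ", x$n_normal,
      " normals; ", x$n_planted_genes, " planted genes (effect ",
      x$group_effect, " SD); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate the synthetic gene network
#'
#' A random directed graph with `n_edges` edges, no self-loops, and a
#' densified module on the planted genes (about 20% of the edge budget is
#' spent inside the module, capped at its capacity).
#'
#' @param spec A [synthetic_spec()].
#' @return A `gene_network`; attribute `planted_genes` carries the module.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- spec$genes
  n <- spec$n_genes
  planted_idx <- match(spec$planted_genes, genes)
  net <- with_seed(spec$seed + 1, {
    n_mod <- min(length(planted_idx) * (length(planted_idx) - 1),
                 round(0.2 * spec$n_edges))
    mod_pairs <- expand.grid(from = planted_idx, to = planted_idx)
    mod_pairs <- mod_pairs[mod_pairs$from != mod_pairs$to, ]
    mod_sel <- mod_pairs[sample(nrow(mod_pairs), n_mod), ]
    edges <- unique(rbind(mod_sel, data.frame(from = integer(), to = integer())))
    while (nrow(edges) < spec$n_edges) {
      need <- spec$n_edges - nrow(edges)
      cand <- data.frame(from = sample(n, 2 * need + 10, replace = TRUE),
                         to = sample(n, 2 * need + 10, replace = TRUE))
      cand <- cand[cand$from != cand$to, ]
      edges <- unique(rbind(edges, cand))
    }
    edges <- edges[seq_len(spec$n_edges), ]
    new_gene_network(genes, from = edges$from, to = edges$to)
  })
  attr(net, "planted_genes") <- spec$planted_genes
  net
}

#' Generate the synthetic cohort
#'
#' Normal samples are drawn from per-gene log-normal baselines (per-gene
#' location drawn once per spec; values below 0.5 floored to zero, which
#' produces realistic all-but-silent genes for the zero-expression filter).
#' Tumor samples shift the planted genes up by `rank_shift` log units;
#' bad-prognosis tumors add `group_effect` log-scale SDs on the planted
#' genes. Mutations are Bernoulli with the planted genes boosted.
#'
#' @param spec A [synthetic_spec()].
#' @param raw If `TRUE`, return the raw tables (expression matrices,
#'   mutation and clinical tibbles) instead of a built `cohort`.
#' @param zero_fraction Zero-expression filter applied when building the
#'   cohort; `NULL` skips it.
#' @return A `cohort` (attribute `planted_genes` set), or a list of raw
#'   tables when `raw = TRUE`.
#' @export
generate_cohort <- function(spec, raw = FALSE, zero_fraction = 0.8) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dat <- with_seed(spec$seed + 2, {
    n <- spec$n_genes
    genes <- spec$genes
    planted <- genes %in% spec$planted_genes
    meanlog <- rnorm(n, mean = 1.5, sd = 1)
    sdlog <- 0.6
    n_tum <- spec$n_tumor_good + spec$n_tumor_bad
    tumor_ids <- sprintf("T%03d", seq_len(n_tum))
    normal_ids <- sprintf("N%03d", seq_len(spec$n_normal))
    label <- factor(rep(c("good", "bad"), c(spec$n_tumor_good, spec$n_tumor_bad)),
                    levels = c("good", "bad"))

    # per-sample global scale factor: library size / purity variation;
    # leaves within-sample ranks untouched
    draw <- function(mu, scale_shift) {
      x <- exp(rnorm(length(mu), mu + scale_shift, sdlog))
      spike <- rbinom(length(mu), 1, spec$outlier_rate) == 1
      x[spike] <- x[spike] * exp(runif(sum(spike), 2, 4))
      ifelse(x < 0.5, 0, x)
    }
    normal_scale <- rnorm(spec$n_normal, 0, spec$sample_scale_sd)
    tumor_scale <- rnorm(n_tum, 0, spec$sample_scale_sd)
    normal_expr <- vapply(seq_len(spec$n_normal),
                          function(i) draw(meanlog, normal_scale[i]),
                          numeric(n))
    mu_tumor <- meanlog + ifelse(planted, spec$rank_shift, 0)
    tumor_expr <- vapply(seq_len(n_tum), function(i) {
      mu <- mu_tumor
      if (label[i] == "bad") mu <- mu + ifelse(planted, spec$group_effect * sdlog, 0)
      draw(mu, tumor_scale[i])
    }, numeric(n))
    dimnames(tumor_expr) <- list(genes, tumor_ids)
    dimnames(normal_expr) <- list(genes, normal_ids)

    rate <- pmin(spec$mutation_rate *
                   ifelse(planted, spec$driver_mutation_boost, 1), 1)
    mut_mat <- vapply(tumor_ids, function(s) rbinom(n, 1, rate), numeric(n))
    mut_idx <- which(mut_mat == 1, arr.ind = TRUE)
    mutations <- tibble::tibble(sample = tumor_ids[mut_idx[, 2]],
                                gene = genes[mut_idx[, 1]])

    criterion <- 2
    survival <- ifelse(label == "bad", runif(n_tum, 0.1, criterion - 0.1),
                       criterion + runif(n_tum, 0.1, 5))
    clinical <- tibble::tibble(
      sample = tumor_ids,
      vital_status = ifelse(label == "bad", "dead", "alive"),
      survival_years = round(survival, 2)
    )
    list(tumor_expr = tumor_expr, normal_expr = normal_expr,
         mutations = mutations, clinical = clinical,
         labels = tibble::tibble(sample = tumor_ids, label = label),
         criterion_years = criterion)
  })
  if (raw) {
    dat$planted_genes <- spec$planted_genes
    return(dat)
  }
  cohort <- build_cohort(dat$tumor_expr, dat$normal_expr, dat$mutations,
                         dat$labels, criterion_years = dat$criterion_years,
                         zero_fraction = zero_fraction)
  attr(cohort, "planted_genes") <- intersect(spec$planted_genes, cohort$genes)
  cohort
}

#' Write a synthetic study to TSV files
#'
#' Writes the five plain-text inputs of the pipeline (network edge list,
#' tumor expression, normal expression, mutations, clinical) to a
#' directory, in the formats the readers of this package consume.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_tsvs <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- generate_network(spec)
  dat <- generate_cohort(spec, raw = TRUE)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    tumor_expr = file.path(dir, "tumor_expression.tsv"),
    normal_expr = file.path(dir, "normal_expression.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    clinical = file.path(dir, "clinical.tsv")
  )
  # oriented network re-emitted as directed edges; reversal is an involution,
  # so reading it back with integrate_networks() restores this orientation
  # only after a second reversal -- write source/target swapped to compensate
  readr::write_tsv(tibble::tibble(source = tidy(net)$target,
                                  target = tidy(net)$source,
                                  directed = TRUE),
                   paths["network"], col_names = FALSE)
  readr::write_tsv(tibble::as_tibble(dat$tumor_expr, rownames = "gene"),
                   paths["tumor_expr"])
  readr::write_tsv(tibble::as_tibble(dat$normal_expr, rownames = "gene"),
                   paths["normal_expr"])
  readr::write_tsv(dat$mutations, paths["mutations"], col_names = FALSE)
  readr::write_tsv(dat$clinical, paths["clinical"], col_names = FALSE)
  invisible(paths)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generation is pure.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
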