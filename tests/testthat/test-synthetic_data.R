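test_that("generation is a pure function of the spec", {
  spec <- small_spec()
  n1 <- generate_network(spec)
  n2 <- generate_network(spec)
  expect_identical(n1$edges, n2$edges)
  c1 <- suppressMessages(generate_cohort(spec))
  c2 <- suppressMessages(generate_cohort(spec))
  expect_identical(c1$tumor_expr, c2$tumor_expr)
  expect_identical(c1$mutations, c2$mutations)
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_network(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the planted module is denser than the network average", {
  spec <- synthetic_spec()
  net <- generate_network(spec)
  planted <- attr(net, "planted_genes")
  e <- tidy(net)
  internal <- sum(e$source %in% planted & e$target %in% planted)
  n_p <- length(planted)
  n <- length(net$genes)
  density_module <- internal / (n_p * (n_p - 1))
  density_global <- nrow(e) / (n * (n - 1))
  expect_gt(density_module, density_global)
})

test_that("edge-count limits and degenerate rates are honoured", {
  spec0 <- synthetic_spec(n_genes = 10, n_edges = 0, n_planted_genes = 2,
                          seed = 3)
  net0 <- generate_network(spec0)
  expect_equal(nrow(net0$edges), 0)
  expect_true(all(incoming_degree(net0) == 0))
  expect_error(synthetic_spec(n_genes = 5, n_edges = 100))

  spec_nm <- small_spec(mutation_rate = 0, driver_mutation_boost = 0)
  raw <- generate_cohort(spec_nm, raw = TRUE)
  expect_equal(nrow(raw$mutations), 0)
})

test_that("networks never contain self-loops", {
  spec <- synthetic_spec(n_genes = 40, n_edges = 600, n_planted_genes = 8,
                         seed = 5)
  net <- generate_network(spec)
  expect_true(all(net$edges$from != net$edges$to))
  expect_equal(nrow(net$edges), 600)
})

test_that("good-vs-bad t-test p-values are uniform on a null cohort", {
  # nuisance terms off: the per-sample scale factor correlates genes within
  # a sample, which invalidates a KS test on dependent p-values even though
  # each gene is marginally null
  spec <- synthetic_spec(n_genes = 1000, n_edges = 2000, group_effect = 0,
                         n_tumor_good = 25, n_tumor_bad = 25,
                         sample_scale_sd = 0, outlier_rate = 0, seed = 11)
  raw <- generate_cohort(spec, raw = TRUE)
  lab <- setNames(raw$labels$label, raw$labels$sample)
  p <- per_gene_test(raw$tumor_expr[, names(lab)[lab == "good"]],
                     raw$tumor_expr[, names(lab)[lab == "bad"]])
  # drop degenerate all-zero genes pinned at p = 1
  p_informative <- p[p < 1]
  ks <- stats::ks.test(p_informative, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong group effect powers the planted genes", {
  # nuisance terms off to isolate the power of the planted 3-SD effect
  spec <- synthetic_spec(n_tumor_good = 50, n_tumor_bad = 50,
                         sample_scale_sd = 0, outlier_rate = 0, seed = 13)
  raw <- generate_cohort(spec, raw = TRUE)
  lab <- setNames(raw$labels$label, raw$labels$sample)
  p <- per_gene_test(raw$tumor_expr[, names(lab)[lab == "good"]],
                     raw$tumor_expr[, names(lab)[lab == "bad"]])
  expect_gte(mean(p[raw$planted_genes] < 0.01), 0.9)
})

test_that("the built cohort exercises the zero filter and keeps labels", {
  spec <- synthetic_spec()  # at 300 genes a few all-but-silent genes arise
  coh <- suppressMessages(generate_cohort(spec))
  expect_lt(length(coh$genes), spec$n_genes)  # some silent genes dropped
  expect_equal(sum(coh$labels == "good"), spec$n_tumor_good)
  expect_equal(sum(coh$labels == "bad"), spec$n_tumor_bad)
  expect_true(all(attr(coh, "planted_genes") %in% coh$genes))
})

test_that("the TSV writer emits files the readers can reassemble", {
  dir <- withr::local_tempdir()
  spec <- small_spec()
  paths <- suppressMessages(write_synthetic_tsvs(spec, dir))
  expect_true(all(file.exists(paths)))

  el <- suppressMessages(read_edge_list(paths[["network"]],
                                        directed_default = TRUE))
  net <- integrate_networks(el)
  # reading back reverses the directed edges again: original orientation
  ref <- generate_network(spec)
  expect_equal(tidy(net) |> dplyr::arrange(source, target),
               tidy(ref) |> dplyr::arrange(source, target))

  tum <- read_expression_tsv(paths[["tumor_expr"]])
  nor <- read_expression_tsv(paths[["normal_expr"]])
  muts <- read_mutations_tsv(paths[["mutations"]])
  clin <- read_clinical_tsv(paths[["clinical"]])
  labs <- assign_labels(clin, criterion_years = 2)
  coh <- suppressMessages(build_cohort(tum, nor, muts, labs, 2))
  ref_coh <- suppressMessages(generate_cohort(spec))
  expect_equal(coh$tumor_expr, ref_coh$tumor_expr)
  expect_equal(sort(names(coh$mutations)), sort(names(ref_coh$mutations)))
  expect_equal(as.character(coh$labels), as.character(ref_coh$labels))
})
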