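# Shared fixtures, all built in code.

# Tiny oriented network from explicit edge tibbles.
edge_tbl <- function(source, target, directed = TRUE) {
  tibble::tibble(source = source, target = target, directed = directed)
}

# A 4-gene chain a -> b -> c plus isolated gene d (oriented edges given
# directly as undirected=FALSE inputs would be reversed; use pre-reversed
# directed input so the oriented result is the chain we name).
chain_network <- function() {
  # directed input b->a, c->b gets reversed into oriented a->b, b->c
  net <- integrate_networks(edge_tbl(c("b", "c"), c("a", "b")))
  align_network(net, c("a", "b", "c", "d"))
}

# Small synthetic study for module-level tests (fast to generate).
small_spec <- function(...) {
  synthetic_spec(n_genes = 60, n_edges = 240, n_tumor_good = 12,
                 n_tumor_bad = 12, n_normal = 8, n_planted_genes = 6,
                 seed = 7, ...)
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- small_spec()
      net <- generate_network(spec)
      coh <- suppressMessages(generate_cohort(spec))
      cache <<- list(spec = spec, network = net, cohort = coh)
    }
    cache
  }
})

# Brute-force win-rate oracle: explicit pairwise comparisons with ties = 0.5.
win_rate_brute <- function(s, mutated) {
  genes <- names(s)
  is_mut <- genes %in% mutated
  vapply(seq_along(s), function(i) {
    comp <- if (is_mut[i]) setdiff(seq_along(s), i) else which(is_mut)
    if (length(comp) == 0) comp <- setdiff(seq_along(s), i)
    wins <- sum(s[comp] < s[i]) + 0.5 * sum(s[comp] == s[i])
    wins / length(comp)
  }, numeric(1))
}

# Direct linear-solve oracle for the damped propagation fixed point.
propagate_solve <- function(W_norm, f, d) {
  n <- length(f)
  A <- diag(n) - diag(d) %*% as.matrix(W_norm)
  as.numeric(solve(A, (1 - d) * f))
}
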