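test_that("pairwise correlation is affine-invariant and matches the covariance formula", {
  # y = 2x + 1 exactly: r = 1
  x <- c(0, 1, 3, 2, 5)
  log2m <- rbind(x, 2 * x + 1, c(0, 4, 1, 2, 2)) + 8
  ids <- sprintf("t%d_r1", c(0, 3, 7, 11, 21))
  expr <- expr_from_log2(log2m, sample_ids = ids)
  corr <- pairwise_correlation(expr, per_sample = TRUE)
  pair12 <- corr[corr$gene_a == "g01" & corr$gene_b == "g02", ]
  expect_equal(pair12$r, 1, tolerance = 1e-12)
  expect_equal(pair12$p_value, 0)

  # textbook covariance formula on a 5-point pair
  a <- log2m[1, ]
  b <- log2m[3, ]
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  pair13 <- corr[corr$gene_a == "g01" & corr$gene_b == "g03", ]
  expect_equal(pair13$r, r_hand, tolerance = 1e-12)
  expect_equal(
    pair13$p_value,
    cor.test(a, b)$p.value,
    tolerance = 1e-10
  )

  # zero-variance genes are excluded and logged
  flat <- expr_from_log2(rbind(log2m, rep(8, 5)), sample_ids = ids)
  corr2 <- pairwise_correlation(flat, per_sample = TRUE)
  expect_false("g04" %in% c(corr2$gene_a, corr2$gene_b))
  expect_equal(attr(corr2, "dropped"), "g04")
})

test_that("edge thresholds behave at their degenerate extremes", {
  set.seed(4)
  sim <- simulate_timecourse(sim_config(n_genes = 30L, n_de = 0L, n_modules = 0L, seed = 4L))
  corr <- pairwise_correlation(sim$expr)

  expect_warning(
    empty <- build_network(corr, r_threshold = 1, p_threshold = 0.05),
    "no gene pair"
  )
  expect_equal(nrow(empty$nodes), 0L)

  complete <- build_network(corr, r_threshold = 0, p_threshold = 1)
  n <- nrow(complete$nodes)
  expect_equal(nrow(complete$edges), n * (n - 1) / 2)
  expect_equal(sum(complete$nodes$degree), 2 * nrow(complete$edges))
})

test_that("clustering coefficient: triangle 1, path centre 0, brute force elsewhere", {
  tri <- network_from_edges(data.frame(a = c("a", "b", "a"), b = c("b", "c", "c")))
  expect_equal(clustering_coefficient(tri, "a"), 1)

  path <- network_from_edges(data.frame(a = c("a", "b"), b = c("b", "c")))
  expect_equal(clustering_coefficient(path, "b"), 0)
  expect_error(clustering_coefficient(path, "zzz"), "not in network")

  set.seed(5)
  for (rep in 1:10) {
    edges <- random_edges(12, 0.3)
    if (nrow(edges) == 0) next
    net <- network_from_edges(data.frame(a = sprintf("n%02d", edges[, 1]),
      b = sprintf("n%02d", edges[, 2])))
    for (v in net$nodes$gene) {
      vid <- as.integer(sub("n", "", v))
      expect_equal(
        clustering_coefficient(net, v),
        brute_local_cc(edges, 12, vid)
      )
    }
    # cross-check against igraph's local transitivity
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
    tr <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    names(tr) <- igraph::V(g)$name
    expect_equal(net$nodes$clustering_coefficient, unname(tr[net$nodes$gene]))
  }
})

test_that("k-core decomposition: star, clique, clique-plus-pendant", {
  star <- network_from_edges(data.frame(a = "hub", b = sprintf("leaf%d", 1:5)))
  expect_true(all(kcore_decomposition(star) == 1L))

  k4 <- t(combn(c("a", "b", "c", "d"), 2))
  net4 <- network_from_edges(data.frame(a = k4[, 1], b = k4[, 2]))
  expect_true(all(kcore_decomposition(net4) == 3L))

  # K5 plus a pendant: clique nodes coreness 4, pendant 1
  k5 <- t(combn(sprintf("c%d", 1:5), 2))
  net5 <- network_from_edges(data.frame(
    a = c(k5[, 1], "c1"),
    b = c(k5[, 2], "pendant")
  ))
  core <- kcore_decomposition(net5)
  expect_equal(unname(core[sprintf("c%d", 1:5)]), rep(4L, 5))
  expect_equal(unname(core["pendant"]), 1L)
  cg <- core_genes(net5)
  expect_equal(cg$max_coreness, 4L)
  expect_setequal(cg$core_genes[[1]], sprintf("c%d", 1:5))
})

test_that("peeling equals the brute-force subgraph oracle and igraph on random graphs", {
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(8:50, 1)
    edges <- random_edges(n, runif(1, 0.05, 0.3))
    if (nrow(edges) == 0) next
    labels <- sprintf("n%02d", seq_len(n))
    net <- network_from_edges(data.frame(a = labels[edges[, 1]], b = labels[edges[, 2]]))
    core <- kcore_decomposition(net)
    oracle <- brute_coreness(edges, n)
    present <- match(net$nodes$gene, labels)
    expect_equal(unname(core[net$nodes$gene]), oracle[present])

    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
    ig <- igraph::coreness(g)
    expect_equal(unname(core[names(ig)]), unname(ig))

    # structural invariants
    expect_true(all(core[net$nodes$gene] <= net$nodes$degree))

    # removing an edge never increases coreness
    drop <- sample(nrow(net$edges), 1)
    net2 <- network_from_edges(net$edges[-drop, 1:2])
    core2 <- kcore_decomposition(net2)
    shared <- intersect(names(core2), names(core))
    expect_true(all(core2[shared] <= core[shared]))
  }
})

test_that("core genes are reported per component, small components excluded", {
  two <- network_from_edges(data.frame(
    a = c("a", "b", "c", "x", "y", "z", "x"),
    b = c("b", "c", "a", "y", "z", "w", "z")
  ))
  cg <- core_genes(two)
  expect_equal(nrow(cg), 2L)
  tri_row <- cg[vapply(cg$core_genes, function(g) "a" %in% g, logical(1)), ]
  expect_equal(tri_row$max_coreness, 2L)
  expect_setequal(tri_row$core_genes[[1]], c("a", "b", "c"))

  pair <- network_from_edges(data.frame(a = c("p", "a", "b", "c"), b = c("q", "b", "c", "a")))
  cg2 <- core_genes(pair, min_component_size = 3L)
  small <- cg2[cg2$n_nodes == 2L, ]
  expect_equal(small$core_genes[[1]], character(0))
})

test_that("a planted module is recovered as one component at maximal coreness", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_timecourse(sim_config(
      n_genes = 500L, n_de = 100L, n_modules = 1L, module_size = 30L,
      noise_sd = 0.2, effect_log2 = 1, seed = s
    ))
    de_genes <- differential_genes(call_differential(sim$expr))
    corr <- pairwise_correlation(sim$expr, genes = de_genes)
    net <- build_network(corr, r_threshold = 0.8, p_threshold = 0.05)
    mod <- sim$truth$module_of_gene$gene
    nodes <- net$nodes[net$nodes$gene %in% mod, ]
    nrow(nodes) == length(mod) &&
      length(unique(nodes$component_id)) == 1L &&
      all(nodes$coreness == max(net$nodes$coreness))
  }, logical(1))
  expect_true(mean(hits) >= 0.9)
})
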