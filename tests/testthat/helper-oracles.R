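# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and its vectorised shortcuts) so implementation and oracle can
# disagree.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, clipped at 1, mapped back to input order
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q_sorted[i] <- min(1, min(m * p[ord][j] / j))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# upper hypergeometric tail P(X >= k) as an explicit sum of point masses
brute_hyper_upper <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# adjacency list (list of integer vectors) from an edge matrix on 1..n
edges_to_adj <- function(edges, n) {
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]
    b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# coreness oracle: for each k, repeatedly delete nodes of degree < k in the
# remaining subgraph; a node's coreness is the largest k at which it survives
brute_coreness <- function(edges, n) {
  core <- integer(n)
  adj <- edges_to_adj(edges, n)
  max_k <- if (nrow(edges) > 0) max(lengths(adj)) else 0
  for (k in seq_len(max_k)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- vapply(seq_len(n), function(v) {
        if (!alive[v]) {
          return(-1L)
        }
        sum(alive[adj[[v]]])
      }, integer(1))
      kill <- which(alive & deg < k)
      if (length(kill) == 0) break
      alive[kill] <- FALSE
    }
    core[alive] <- k
  }
  core
}

# local clustering coefficient by explicit neighbour-pair counting
brute_local_cc <- function(edges, n, v) {
  adj <- edges_to_adj(edges, n)
  nb <- adj[[v]]
  d <- length(nb)
  if (d < 2) {
    return(0)
  }
  closed <- 0
  for (i in 1:(d - 1)) {
    for (j in (i + 1):d) {
      if (nb[j] %in% adj[[nb[i]]]) closed <- closed + 1
    }
  }
  2 * closed / (d * (d - 1))
}

# random simple graph as a 2-column integer edge matrix on 1..n
random_edges <- function(n, p) {
  pairs <- t(combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# small expression object from a genes x samples log2 matrix
expr_from_log2 <- function(log2_mat, genes = NULL, sample_ids = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(log2_mat)))
  if (!is.null(sample_ids)) colnames(log2_mat) <- sample_ids
  df <- as.data.frame(2^log2_mat)
  expression_matrix(cbind(data.frame(gene = genes), df))
}

# radhub_network from a plain edge tibble (skips correlation machinery)
network_from_edges <- function(edge_df) {
  corr <- tibble::tibble(
    gene_a = as.character(edge_df[[1]]),
    gene_b = as.character(edge_df[[2]]),
    r = 1, p_value = 0
  )
  build_network(corr, r_threshold = 0, p_threshold = 1)
}
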