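#' Pairwise Pearson correlation between gene trajectories
#'
#' Correlation of every unordered gene pair, by default over the
#' per-timepoint mean log-ratio trajectories (the same object the temporal
#' profiles are matched against); `per_sample = TRUE` correlates the raw
#' per-sample log2 intensities instead. A two-sided correlation-test p value
#' (t approximation on n - 2 degrees of freedom) is attached. Genes with a
#' zero-variance profile cannot be correlated; their pairs are excluded and
#' the genes reported in the `dropped` attribute.
#'
#' @param expr A `radhub_expr` object.
#' @param genes Optional gene subset (typically genes inside significant
#'   annotation terms).
#' @param per_sample Correlate per-sample values instead of per-timepoint
#'   trajectories.
#' @return A tibble with `gene_a`, `gene_b` (gene_a < gene_b), `r`,
#'   `p_value`.
#' @export
pairwise_correlation <- function(expr, genes = NULL, per_sample = FALSE) {
  if (per_sample) {
    values <- log2(expr_values(expr))
    if (!is.null(genes)) values <- values[intersect(genes, rownames(values)), , drop = FALSE]
  } else {
    values <- traj_values(logratio_trajectories(expr, genes = genes))
  }
  n_obs <- ncol(values)
  if (n_obs < 3L) stop("need at least 3 observations per gene")
  vars <- apply(values, 1L, stats::var)
  dropped <- rownames(values)[vars == 0]
  values <- values[vars > 0, , drop = FALSE]
  if (nrow(values) < 2L) stop("fewer than 2 genes with non-degenerate profiles")

  r <- stats::cor(t(values))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  df <- n_obs - 2L
  tstat <- rv * sqrt(df / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[abs(rv) >= 1] <- 0

  out <- tibble::tibble(
    gene_a = rownames(values)[idx[, 1L]],
    gene_b = rownames(values)[idx[, 2L]],
    r = rv,
    p_value = p
  )
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]
  out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  attr(out, "dropped") <- dropped
  attr(out, "n_obs") <- n_obs
  out
}

#' Build the co-expression network from a correlation table
#'
#' An edge joins two genes when `|r| >= r_threshold` and the correlation-test
#' p value is below `p_threshold` (set `p_threshold = 1` to disable the
#' gate). Isolated genes are dropped. Node degree, local clustering
#' coefficient, coreness (k-core level) and connected-component id are
#' computed for every retained gene.
#'
#' @param correlations Output of [pairwise_correlation()].
#' @param r_threshold Minimum `|r|` for an edge (default 0.8).
#' @param p_threshold Maximum correlation-test p for an edge (default 0.05).
#' @return A list of class `radhub_network` with `nodes` (tibble `gene`,
#'   `degree`, `clustering_coefficient`, `coreness`, `component_id`) and
#'   `edges` (tibble `gene_a`, `gene_b`, `r`).
#' @export
build_network <- function(correlations, r_threshold = 0.8, p_threshold = 0.05) {
  keep <- abs(correlations$r) >= r_threshold & correlations$p_value < p_threshold
  edges <- correlations[keep, c("gene_a", "gene_b", "r")]
  if (nrow(edges) == 0L) {
    warning("no gene pair passes the edge thresholds; returning an empty network")
    return(structure(
      list(
        nodes = tibble::tibble(
          gene = character(0), degree = integer(0),
          clustering_coefficient = numeric(0), coreness = integer(0),
          component_id = integer(0)
        ),
        edges = edges
      ),
      class = "radhub_network"
    ))
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- adjacency_sets(edges, nodes)
  degree <- lengths(adj)
  cc <- vapply(nodes, function(v) local_clustering(adj, v), numeric(1))
  core <- kcore_peel(adj)

  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
    directed = FALSE, vertices = nodes
  )
  comp <- igraph::components(g)$membership[nodes]

  structure(
    list(
      nodes = tibble::tibble(
        gene = nodes,
        degree = unname(degree[nodes]),
        clustering_coefficient = unname(cc),
        coreness = unname(core[nodes]),
        component_id = as.integer(unname(comp))
      ),
      edges = edges
    ),
    class = "radhub_network"
  )
}

# named list: node -> character vector of neighbours
adjacency_sets <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  both <- c(edges$gene_a, edges$gene_b)
  other <- c(edges$gene_b, edges$gene_a)
  sp <- split(other, both)
  for (v in names(sp)) adj[[v]] <- unique(sp[[v]])
  for (v in nodes) if (is.null(adj[[v]])) adj[[v]] <- character(0)
  adj
}

# local clustering coefficient: closed neighbour pairs / possible pairs
local_clustering <- function(adj, v) {
  nb <- adj[[v]]
  d <- length(nb)
  if (d < 2L) {
    return(0)
  }
  links <- 0L
  for (i in seq_len(d - 1L)) {
    links <- links + sum(nb[(i + 1L):d] %in% adj[[nb[i]]])
  }
  2 * links / (d * (d - 1L))
}

# k-core by iterative peeling: repeatedly delete nodes of degree < k;
# coreness(v) = largest k at which v survives
kcore_peel <- function(adj) {
  nodes <- names(adj)
  core <- stats::setNames(integer(length(nodes)), nodes)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  deg <- stats::setNames(lengths(adj), nodes)
  k <- 0L
  while (any(alive)) {
    repeat {
      peel <- names(which(alive & deg < k))
      if (length(peel) == 0L) break
      for (v in peel) {
        alive[v] <- FALSE
        nb <- adj[[v]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    core[names(which(alive))] <- k
    k <- k + 1L
  }
  core
}

#' Local clustering coefficient of a node
#'
#' Fraction of a node's neighbour pairs that are themselves connected:
#' `2 * links_among_neighbours / (deg * (deg - 1))`, defined as 0 for degree
#' below 2.
#'
#' @param network A `radhub_network`.
#' @param node Gene symbol.
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(network, node) {
  if (!node %in% network$nodes$gene) stop("node not in network: ", node)
  adj <- adjacency_sets(network$edges, network$nodes$gene)
  local_clustering(adj, node)
}

#' k-core decomposition of a network
#'
#' Coreness of every node: the largest `k` such that the node belongs to the
#' maximal subgraph in which every node has degree at least `k`. Computed by
#' iterative peeling.
#'
#' @param network A `radhub_network`.
#' @return Named integer vector of corenesses.
#' @export
kcore_decomposition <- function(network) {
  adj <- adjacency_sets(network$edges, network$nodes$gene)
  kcore_peel(adj)
}

#' Core (hub) genes per subnetwork
#'
#' Within each connected component, the genes attaining the component's
#' maximum coreness are its core genes — the hub-gene definition of the
#' k-core analysis. Components with fewer than `min_component_size` nodes
#' are reported but carry no core genes (a 2-node subnetwork has trivial
#' coreness). Core genes are ranked by degree (descending, ties
#' alphabetical).
#'
#' @param network A `radhub_network` (with coreness computed).
#' @param min_component_size Smallest component eligible for core-gene
#'   selection (default 3).
#' @return A tibble with one row per component: `component_id`, `n_nodes`,
#'   `max_coreness`, `core_genes` (list-column of ranked gene vectors).
#' @export
core_genes <- function(network, min_component_size = 3L) {
  nodes <- network$nodes
  if (nrow(nodes) == 0L) {
    return(tibble::tibble(
      component_id = integer(0), n_nodes = integer(0),
      max_coreness = integer(0), core_genes = list()
    ))
  }
  comp <- dplyr::group_by(nodes, .data$component_id)
  out <- dplyr::summarise(
    comp,
    n_nodes = dplyr::n(),
    max_coreness = max(.data$coreness),
    core_genes = list({
      sel <- .data$coreness == max(.data$coreness)
      g <- .data$gene[sel]
      d <- .data$degree[sel]
      g[order(-d, g)]
    }),
    .groups = "drop"
  )
  out$core_genes[out$n_nodes < min_component_size] <- list(character(0))
  dplyr::arrange(out, dplyr::desc(.data$n_nodes))
}

#' @export
print.radhub_network <- function(x, ...) {
  cat(
    "# Co-expression network: ", nrow(x$nodes), " genes, ", nrow(x$edges),
    " edges, ", length(unique(x$nodes$component_id)), " component(s); max k-core ",
    if (nrow(x$nodes) > 0L) max(x$nodes$coreness) else 0L, "\n",
    sep = ""
  )
  invisible(x)
}
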