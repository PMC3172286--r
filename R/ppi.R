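#' Case-insensitive intersection of two gene lists
#'
#' Symbols are uppercased before comparison (the package's convention for
#' joining mouse-cased microarray symbols against human-cased interaction and
#' literature resources). An optional mapping table (e.g. an orthology map)
#' is applied to both lists first.
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @param mapping Optional two-column data frame (`from`, `to`) translating
#'   symbols before the uppercase join.
#' @return A list of class `radhub_overlap`: `genes` (sorted uppercased
#'   intersection), `source_a_size`, `source_b_size`.
#' @export
overlap_genes <- function(list_a, list_b, mapping = NULL) {
  if (length(list_a) == 0L || length(list_b) == 0L) {
    stop("both gene lists must be non-empty")
  }
  map <- function(x) {
    if (!is.null(mapping)) {
      m <- match(toupper(x), toupper(mapping[[1L]]))
      x[!is.na(m)] <- mapping[[2L]][m[!is.na(m)]]
    }
    unique(toupper(x))
  }
  a <- map(list_a)
  b <- map(list_b)
  structure(
    list(
      genes = sort(intersect(a, b)),
      source_a_size = length(a),
      source_b_size = length(b)
    ),
    class = "radhub_overlap"
  )
}

#' @export
print.radhub_overlap <- function(x, ...) {
  cat(
    "# Overlap: ", length(x$genes), " genes shared by lists of ",
    x$source_a_size, " and ", x$source_b_size, "\n",
    sep = ""
  )
  invisible(x)
}

#' Extract the seed-based PPI subnetwork
#'
#' Retains the seed genes present in the PPI together with all their first
#' neighbours, then takes the induced subgraph (neighbour-neighbour edges are
#' kept; `star = TRUE` restricts to seed-incident edges only). Seeds absent
#' from the PPI are retained as isolated seed nodes.
#'
#' @param ppi A `radhub_ppi` edge tibble (see [read_edge_list()]).
#' @param seeds Character vector of seed symbols (uppercased internally).
#' @param star Keep only edges incident to a seed.
#' @return A list of class `radhub_subnet`: `nodes` (tibble `gene`, `role`
#'   in `seed`/`neighbor`, `degree` within the subnetwork) and `edges`.
#' @export
extract_seed_subnetwork <- function(ppi, seeds, star = FALSE) {
  seeds <- unique(toupper(seeds))
  ppi_nodes <- unique(c(ppi$from, ppi$to))
  present <- intersect(seeds, ppi_nodes)
  if (length(present) == 0L) {
    warning("no seed gene present in the PPI; returning isolated seeds")
  }
  incident <- ppi$from %in% present | ppi$to %in% present
  neighbors <- setdiff(unique(c(ppi$from[incident], ppi$to[incident])), seeds)
  retained <- c(seeds, neighbors)

  edges <- if (star) {
    ppi[incident, ]
  } else {
    ppi[ppi$from %in% retained & ppi$to %in% retained, ]
  }
  deg <- table(factor(c(edges$from, edges$to), levels = retained))
  nodes <- tibble::tibble(
    gene = retained,
    role = ifelse(retained %in% seeds, "seed", "neighbor"),
    degree = as.integer(deg[retained])
  )
  nodes <- dplyr::arrange(nodes, dplyr::desc(.data$degree), .data$gene)
  structure(
    list(nodes = nodes, edges = tibble::as_tibble(edges)),
    class = "radhub_subnet"
  )
}

#' Hub nodes of a PPI subnetwork
#'
#' Nodes whose within-subnetwork degree reaches `min_degree`, ranked by
#' degree descending with alphabetical tie-break. The default 11 corresponds
#' to the "degree above 10" hub rule.
#'
#' @param subnetwork A `radhub_subnet`.
#' @param min_degree Minimum degree (default 11).
#' @return A tibble with `gene`, `role`, `degree`.
#' @export
hub_nodes <- function(subnetwork, min_degree = 11L) {
  hubs <- dplyr::filter(subnetwork$nodes, .data$degree >= min_degree)
  dplyr::arrange(hubs, dplyr::desc(.data$degree), .data$gene)
}

#' @export
print.radhub_subnet <- function(x, ...) {
  cat(
    "# PPI subnetwork: ", sum(x$nodes$role == "seed"), " seeds + ",
    sum(x$nodes$role == "neighbor"), " neighbours, ", nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}
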