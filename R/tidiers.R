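#' @rdname radhub_tidiers
#' @name radhub_tidiers
#' @title Broom-style tidiers for pipeline results
#'
#' @description `tidy()` returns the per-item table of a result (one row per
#' gene-timepoint, profile, term, node, ...); `glance()` returns a one-row
#' summary.
#'
#' @param x A pipeline result object.
#' @param ... Unused.
#' @return A tibble.
NULL

#' @rdname radhub_tidiers
#' @export
tidy.radhub_de <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @rdname radhub_tidiers
#' @export
glance.radhub_de <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$gene)),
    n_timepoints = length(unique(x$timepoint_days)),
    n_significant_any = length(unique(x$gene[x$significant_any])),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' @rdname radhub_tidiers
#' @export
tidy.radhub_stem <- function(x, ...) {
  out <- tibble::as_tibble(unclass_tbl(x$clusters))
  out$steps <- collapse_chr(out$steps)
  out
}

#' @rdname radhub_tidiers
#' @export
glance.radhub_stem <- function(x, ...) {
  cl <- x$clusters
  tibble::tibble(
    n_profiles = nrow(cl),
    n_significant = sum(cl$significant),
    n_genes_clustered = sum(!is.na(x$assignment$profile_id)),
    n_genes_in_significant = sum(cl$n_genes[cl$significant]),
    alpha = attr(cl, "alpha") %||% NA_real_
  )
}

#' @rdname radhub_tidiers
#' @export
tidy.radhub_enrich <- function(x, ...) {
  out <- tibble::as_tibble(unclass_tbl(x))
  out$hits <- collapse_chr(out$hits)
  out
}

#' @rdname radhub_tidiers
#' @export
glance.radhub_enrich <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_significant_p05 = sum(x$p_fisher < 0.05),
    study_size = if (nrow(x) > 0L) x$n[1L] else NA_integer_,
    background_size = if (nrow(x) > 0L) x$N[1L] else NA_integer_
  )
}

#' @rdname radhub_tidiers
#' @export
tidy.radhub_network <- function(x, ...) x$nodes

#' @rdname radhub_tidiers
#' @export
glance.radhub_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = length(unique(x$nodes$component_id)),
    max_coreness = if (nrow(x$nodes) > 0L) max(x$nodes$coreness) else NA_integer_,
    mean_clustering = if (nrow(x$nodes) > 0L) mean(x$nodes$clustering_coefficient) else NA_real_
  )
}

#' @rdname radhub_tidiers
#' @export
tidy.radhub_subnet <- function(x, ...) x$nodes

#' @rdname radhub_tidiers
#' @export
glance.radhub_subnet <- function(x, ...) {
  tibble::tibble(
    n_seeds = sum(x$nodes$role == "seed"),
    n_neighbors = sum(x$nodes$role == "neighbor"),
    n_edges = nrow(x$edges)
  )
}

#' @rdname radhub_tidiers
#' @export
tidy.radhub_overlap <- function(x, ...) tibble::tibble(gene = x$genes)

#' @rdname radhub_tidiers
#' @export
glance.radhub_overlap <- function(x, ...) {
  tibble::tibble(
    n_overlap = length(x$genes),
    source_a_size = x$source_a_size,
    source_b_size = x$source_b_size
  )
}

#' @rdname radhub_tidiers
#' @export
tidy.radhub_qpcr <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @rdname radhub_tidiers
#' @export
tidy.radhub_concordance <- function(x, ...) x$detail

#' @rdname radhub_tidiers
#' @export
glance.radhub_concordance <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$detail),
    fraction_concordant = x$fraction_concordant
  )
}

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  for (a in c("alpha", "ease", "dropped", "n_obs", "n_assigned", "sample_info")) {
    attr(x, a) <- NULL
  }
  x
}
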