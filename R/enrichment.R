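#' Fisher's exact over-representation test across gene sets
#'
#' For every term, builds the 2x2 table of study hits `k` out of study size
#' `n` against term size `K` in a background of `N` genes, and reports the
#' one-tailed (over-representation) Fisher exact p — the upper hypergeometric
#' tail `P(X >= k)` — a Pearson chi-squared p for reference, the
#' Benjamini-Hochberg q across tested terms and the enrichment ratio
#' `(k/n)/(K/N)`. Terms are intersected with the background before testing;
#' terms with no background member are skipped.
#'
#' @param study Character vector of study genes; must be a subset of
#'   `background`.
#' @param gene_sets Annotation tibble (`term_id`, `term_name`, list-column
#'   `genes`), e.g. from [read_gmt()].
#' @param background Character vector: the gene universe (typically all genes
#'   on the array).
#' @param ease Use the EASE variant: Fisher on `k - 1` hits, the conservative
#'   penalty used by DAVID-style pathway reports.
#' @return A tibble of class `radhub_enrich` with columns `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p_fisher`, `p_chi2`, `chi2_reliable`,
#'   `q`, `enrichment_ratio`, `hits` (list-column), sorted by `p_fisher`.
#' @export
fisher_enrichment <- function(study, gene_sets, background, ease = FALSE) {
  study <- unique(study)
  background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders) > 0L) {
    stop(
      "study genes absent from background: ",
      paste(utils::head(offenders, 10L), collapse = ", ")
    )
  }
  N <- length(background)
  n <- length(study)
  term_genes <- lapply(gene_sets$genes, intersect, background)
  K <- lengths(term_genes)
  keep <- K > 0L
  term_genes <- term_genes[keep]
  K <- K[keep]
  hits <- lapply(term_genes, intersect, study)
  k <- lengths(hits)

  k_test <- if (ease) pmax(k - 1L, 0L) else k
  p_fisher <- stats::phyper(k_test - 1L, K, N - K, n, lower.tail = FALSE)
  chi <- chi2_enrichment(k, n, K, N)

  out <- tibble::tibble(
    term_id = gene_sets$term_id[keep],
    term_name = gene_sets$term_name[keep],
    k = k, n = n, K = K, N = N,
    p_fisher = p_fisher,
    p_chi2 = chi$p_value,
    chi2_reliable = chi$reliable,
    q = bh_fdr(p_fisher),
    enrichment_ratio = (k / n) / (K / N),
    hits = hits
  )
  out <- dplyr::arrange(out, .data$p_fisher, .data$term_id)
  structure(out,
    ease = ease,
    class = c("radhub_enrich", class(tibble::tibble()))
  )
}

#' Pearson chi-squared test for a 2x2 enrichment table
#'
#' Advisory companion to the Fisher test (reported, never used for
#' selection). No continuity correction. When any expected cell count falls
#' below 1 the p value is flagged unreliable rather than suppressed.
#'
#' @param k,n,K,N Study hits, study size, term size, background size
#'   (vectorised over terms).
#' @return A tibble with `statistic`, `p_value`, `reliable`.
#' @export
chi2_enrichment <- function(k, n, K, N) {
  o11 <- k
  o12 <- n - k
  o21 <- K - k
  o22 <- N - n - K + k
  if (any(c(o11, o12, o21, o22) < 0)) stop("2x2 table has a negative cell")
  tot <- N
  r1 <- o11 + o12
  r2 <- o21 + o22
  c1 <- o11 + o21
  c2 <- o12 + o22
  e11 <- r1 * c1 / tot
  e12 <- r1 * c2 / tot
  e21 <- r2 * c1 / tot
  e22 <- r2 * c2 / tot
  expected0 <- e11 == 0 | e12 == 0 | e21 == 0 | e22 == 0
  stat <- ifelse(
    expected0, 0,
    (o11 - e11)^2 / e11 + (o12 - e12)^2 / e12 +
      (o21 - e21)^2 / e21 + (o22 - e22)^2 / e22
  )
  tibble::tibble(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    reliable = !expected0 & e11 >= 1 & e12 >= 1 & e21 >= 1 & e22 >= 1
  )
}

#' Pathway enrichment (DAVID-style display options)
#'
#' Identical machinery to [fisher_enrichment()] over a pathway gene-set
#' collection. `ease = TRUE` applies the conservative EASE variant (Fisher on
#' `k - 1`); `david_style = TRUE` adds an `fdr_percent` column (q x 100), the
#' display convention of DAVID pathway tables.
#'
#' @inheritParams fisher_enrichment
#' @param pathway_sets Pathway GMT tibble.
#' @param david_style Report FDR as a percentage column.
#' @return A `radhub_enrich` tibble (with `fdr_percent` when requested).
#' @export
pathway_enrichment <- function(study, pathway_sets, background,
                               ease = FALSE, david_style = FALSE) {
  out <- fisher_enrichment(study, pathway_sets, background, ease = ease)
  if (david_style) out$fdr_percent <- out$q * 100
  out
}

# ancestor sets (term -> all ancestors) from a child->parent edge table
dag_ancestors <- function(dag) {
  parents <- split(dag$parent, dag$child)
  memo <- new.env(parent = emptyenv())
  walk <- function(node, seen = character(0)) {
    if (!is.null(memo[[node]])) {
      return(memo[[node]])
    }
    if (node %in% seen) stop("cycle detected at term ", node)
    ps <- parents[[node]]
    if (is.null(ps)) {
      memo[[node]] <- character(0)
      return(character(0))
    }
    anc <- unique(c(ps, unlist(lapply(ps, walk, seen = c(seen, node)))))
    memo[[node]] <- anc
    anc
  }
  all_nodes <- unique(c(dag$child, dag$parent))
  stats::setNames(lapply(all_nodes, walk), all_nodes)
}

#' Build the map of significant terms
#'
#' Graph over the significant terms with a child-to-parent edge wherever one
#' significant term is an ancestor of another in the annotation DAG and no
#' third significant term lies between them (transitive reduction over the
#' significant set), the structure drawn in GO-map figures.
#'
#' @param significant_terms Character vector of significant term ids.
#' @param dag Term-parent tibble (`child`, `parent`), acyclic.
#' @return A list of class `radhub_gomap` with `nodes` (character) and
#'   `edges` (tibble `child`, `parent`).
#' @export
build_go_map <- function(significant_terms, dag) {
  assert_acyclic(dag)
  sig <- unique(significant_terms)
  anc <- dag_ancestors(dag)
  get_anc <- function(x) if (is.null(anc[[x]])) character(0) else anc[[x]]

  edges <- list()
  for (a in sig) {
    sig_anc <- intersect(get_anc(a), sig)
    for (b in sig_anc) {
      # drop (a, b) if another significant term sits on a path a ~> z ~> b
      between <- vapply(
        setdiff(sig_anc, b),
        function(z) b %in% get_anc(z),
        logical(1)
      )
      if (!any(between)) edges[[length(edges) + 1L]] <- c(a, b)
    }
  }
  edge_tbl <- if (length(edges) == 0L) {
    tibble::tibble(child = character(0), parent = character(0))
  } else {
    m <- do.call(rbind, edges)
    tibble::tibble(child = m[, 1L], parent = m[, 2L])
  }
  structure(list(nodes = sig, edges = edge_tbl), class = "radhub_gomap")
}

#' @export
print.radhub_gomap <- function(x, ...) {
  cat(
    "# Significant-term map: ", length(x$nodes), " terms, ",
    nrow(x$edges), " subsumption edges\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.radhub_enrich <- function(x, ...) {
  cat(
    "# Enrichment table: ", nrow(x), " terms tested against N = ",
    x$N[1L], " background genes\n",
    sep = ""
  )
  NextMethod()
}
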