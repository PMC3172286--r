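#' Run the full hub-gene discovery pipeline
#'
#' Executes the analysis end to end: per-timepoint differential calling,
#' model-profile temporal clustering of the differential genes, term
#' enrichment of the clustered genes with the significant-term map,
#' correlation-network construction over the genes inside significant terms
#' with k-core hub detection, literature-overlap seeding of the PPI
#' subnetwork with degree-ranked hubs, and (when a Ct table is supplied)
#' 2^-ddCt validation with direction concordance. Counts of genes entering
#' and surviving each stage are logged and returned. Outputs are
#' deterministic given the inputs and `config$seed`.
#'
#' @param expr A `radhub_expr` object or path to an expression TSV.
#' @param gene_sets Annotation tibble or path to a GMT file.
#' @param dag Term-parent tibble or path to a two-column TSV.
#' @param ppi `radhub_ppi` edge tibble or path to an edge list.
#' @param literature Character vector of literature-mined symbols or path to
#'   a one-per-line list.
#' @param ct Optional Ct tibble or path for the qPCR validation stage.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when set, every intermediate table is
#'   written as TSV.
#' @param quiet Suppress progress messages (they are always captured in the
#'   returned `log`).
#' @return A list of class `radhub_report` with elements `differential`,
#'   `stem`, `enrichment`, `go_map`, `network`, `core_genes`, `overlap`,
#'   `subnetwork`, `hubs`, optionally `qpcr` and `concordance`, plus `log`
#'   and `config`.
#' @export
run_pipeline <- function(expr, gene_sets, dag, ppi, literature, ct = NULL,
                         config = run_config(), out_dir = NULL, quiet = FALSE) {
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  expr <- stage("read_inputs", if (is.character(expr)) read_expression(expr) else expr)
  gene_sets <- stage("read_inputs", if (is.character(gene_sets)) read_gmt(gene_sets) else gene_sets)
  dag <- stage("read_inputs", if (is.character(dag)) read_term_dag(dag) else dag)
  ppi <- stage("read_inputs", if (is.character(ppi)) read_edge_list(ppi) else ppi)
  literature <- stage("read_inputs", {
    if (is.character(literature) && length(literature) == 1L && file.exists(literature)) {
      read_gene_list(literature)
    } else {
      literature
    }
  })
  if (!is.null(ct) && is.character(ct)) ct <- stage("read_inputs", read_ct_table(ct))
  say("inputs: ", nrow(expr), " genes, ", nrow(sample_info(expr)), " samples")

  de <- stage("diffexpr", call_differential(expr, alpha = config$alpha_de))
  de_genes <- differential_genes(de, rule = "p_any", alpha = config$alpha_de)
  say("diffexpr: ", length(de_genes), " of ", nrow(expr), " genes differential at any timepoint")
  if (length(de_genes) == 0L) stop("pipeline stage 'diffexpr' failed: no differential genes", call. = FALSE)

  stem <- stage("stem_clustering", cluster_timecourse(
    expr,
    genes = de_genes,
    n_profiles = config$n_model_profiles,
    max_unit_change = config$max_unit_change,
    alpha = config$alpha_profile,
    seed = config$seed
  ))
  sig_profiles <- stem$clusters$profile_id[stem$clusters$significant]
  clustered_genes <- sort(stem$assignment$gene[
    !is.na(stem$assignment$profile_id) & stem$assignment$profile_id %in% sig_profiles
  ])
  say(
    "stem_clustering: ", length(sig_profiles), " significant profiles holding ",
    length(clustered_genes), " of ", length(de_genes), " genes"
  )

  background <- expr$gene
  enrich <- stage("enrichment", fisher_enrichment(clustered_genes, gene_sets, background))
  sig_terms <- enrich$term_id[enrich$p_fisher < config$alpha_enrich]
  go_map <- stage("enrichment", build_go_map(sig_terms, dag))
  selected <- sort(unique(unlist(enrich$hits[enrich$term_id %in% sig_terms])))
  say(
    "enrichment: ", length(sig_terms), " of ", nrow(enrich),
    " terms significant; ", length(selected), " genes inside significant terms"
  )

  network <- stage("coexpression_network", {
    if (length(selected) >= 2L) {
      corr <- pairwise_correlation(expr, genes = selected)
      suppressWarnings(build_network(
        corr,
        r_threshold = config$correlation_threshold, p_threshold = 0.05
      ))
    } else {
      warning("fewer than 2 selected genes; skipping network construction")
      build_empty_network()
    }
  })
  cores <- stage("coexpression_network", core_genes(network))
  say(
    "coexpression_network: ", nrow(network$nodes), " genes, ", nrow(network$edges),
    " edges, ", nrow(cores), " component(s), ",
    length(unlist(cores$core_genes)), " core genes"
  )

  overlap <- stage("ppi_overlap", overlap_genes(de_genes, literature))
  subnet <- stage("ppi_overlap", suppressWarnings(extract_seed_subnetwork(ppi, overlap$genes)))
  hubs <- stage("ppi_overlap", hub_nodes(subnet, min_degree = config$hub_min_degree))
  say(
    "ppi_overlap: ", length(overlap$genes), " overlapping genes, subnetwork of ",
    nrow(subnet$nodes), " nodes, ", nrow(hubs), " hubs at degree >= ",
    config$hub_min_degree
  )

  report <- list(
    differential = de, stem = stem, enrichment = enrich, go_map = go_map,
    network = network, core_genes = cores, overlap = overlap,
    subnetwork = subnet, hubs = hubs, config = config
  )
  if (!is.null(ct)) {
    report$qpcr <- stage("qpcr", ddct_fold(ct))
    report$concordance <- stage("qpcr", concordance(de, report$qpcr))
    say(
      "qpcr: ", nrow(report$qpcr), " gene-timepoint folds; direction concordance ",
      sprintf("%.2f", report$concordance$fraction_concordant)
    )
  }
  report$log <- log
  class(report) <- "radhub_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

build_empty_network <- function() {
  structure(
    list(
      nodes = tibble::tibble(
        gene = character(0), degree = integer(0),
        clustering_coefficient = numeric(0), coreness = integer(0),
        component_id = integer(0)
      ),
      edges = tibble::tibble(gene_a = character(0), gene_b = character(0), r = numeric(0))
    ),
    class = "radhub_network"
  )
}

collapse_chr <- function(x) vapply(x, paste, character(1), collapse = ",")

#' Write every pipeline table to a directory
#'
#' @param report A `radhub_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  w <- function(x, f) readr::write_tsv(x, p(f), progress = FALSE)

  w(tibble::as_tibble(report$differential), "differential.tsv")
  cl <- tibble::as_tibble(report$stem$clusters)
  cl$steps <- collapse_chr(cl$steps)
  w(cl, "profile_clusters.tsv")
  w(report$stem$assignment, "gene_profiles.tsv")
  en <- tibble::as_tibble(report$enrichment)
  en$hits <- collapse_chr(en$hits)
  w(en, "enrichment.tsv")
  w(report$go_map$edges, "go_map_edges.tsv")
  w(report$network$nodes, "network_nodes.tsv")
  w(report$network$edges, "network_edges.tsv")
  cg <- report$core_genes
  cg$core_genes <- collapse_chr(cg$core_genes)
  w(cg, "core_genes.tsv")
  readr::write_lines(report$overlap$genes, p("overlap_genes.txt"))
  w(report$subnetwork$nodes, "subnetwork_nodes.tsv")
  w(report$subnetwork$edges, "subnetwork_edges.tsv")
  w(report$hubs, "ppi_hubs.tsv")
  if (!is.null(report$qpcr)) {
    w(tibble::as_tibble(report$qpcr), "qpcr_folds.tsv")
    w(report$concordance$detail, "qpcr_concordance.tsv")
  }
  readr::write_lines(report$log, p("pipeline_log.txt"))
  invisible(report)
}

#' @export
print.radhub_report <- function(x, ...) {
  cat("# Hub-gene discovery report\n")
  for (line in x$log) cat("  ", line, "\n", sep = "")
  invisible(x)
}
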