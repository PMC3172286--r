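#' Read a normalized expression matrix from TSV
#'
#' The file must be tab-separated with the gene symbol in the first column.
#' Remaining columns are sample intensities. Sample identities come either
#' from a metadata sidecar (`meta`, a TSV with columns `sample_id`,
#' `timepoint_days`, `replicate`, `group`) or from the `t{days}_r{rep}`
#' header convention; the sidecar wins when both are available.
#'
#' @param path Path to the expression TSV.
#' @param meta Optional path to a sample-metadata sidecar TSV.
#' @return A `radhub_expr` tibble (see [expression_matrix()]).
#' @export
read_expression <- function(path, meta = NULL) {
  values <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  info <- NULL
  if (!is.null(meta)) {
    info <- readr::read_tsv(meta, show_col_types = FALSE, progress = FALSE)
  }
  expression_matrix(values, sample_info = info)
}

#' Write an expression matrix to TSV
#'
#' @param x A `radhub_expr` object.
#' @param path Output path.
#' @param meta Optional path for the sample-metadata sidecar.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path, meta = NULL) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  if (!is.null(meta)) readr::write_tsv(sample_info(x), meta, progress = FALSE)
  invisible(x)
}

#' Read gene-set annotations in GMT format
#'
#' Standard GMT: one term per line, `term_id <tab> description <tab> gene...`.
#' Duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `term_name` and a list-column
#'   `genes` (character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  out <- tibble::tibble(
    term_id = vapply(fields, `[[`, character(1), 1L),
    term_name = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  )
  if (anyDuplicated(out$term_id)) {
    stop(
      "duplicate term_id: ",
      paste(unique(out$term_id[duplicated(out$term_id)]), collapse = ", ")
    )
  }
  empty <- lengths(out$genes) == 0L
  if (any(empty)) stop("empty gene set for term ", out$term_id[which(empty)[1L]])
  out
}

#' Write gene sets to GMT
#'
#' @param sets A tibble with `term_id`, `term_name` and list-column `genes`.
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    sets[, c("term_id", "term_name", "genes")],
    function(term_id, term_name, genes) {
      paste(c(term_id, term_name, genes), collapse = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(sets)
}

#' Read a term-parent table for the annotation DAG
#'
#' Two-column TSV (`child`, `parent`); the edge set must be acyclic.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `child`, `parent`.
#' @export
read_term_dag <- function(path) {
  dag <- readr::read_tsv(
    path,
    col_names = c("child", "parent"), col_types = "cc", progress = FALSE
  )
  # tolerate a header row
  if (nrow(dag) > 0L && identical(tolower(unlist(dag[1L, ])), c("child", "parent"))) {
    dag <- dag[-1L, ]
  }
  dag <- dplyr::distinct(dag)
  assert_acyclic(dag)
  dag
}

assert_acyclic <- function(dag) {
  if (nrow(dag) == 0L) {
    return(invisible(TRUE))
  }
  g <- igraph::graph_from_data_frame(dag, directed = TRUE)
  if (!igraph::is_dag(g)) stop("term-parent table contains a cycle")
  invisible(TRUE)
}

#' Read an undirected PPI edge list
#'
#' Whitespace- or tab-separated symbol pairs. Symbols are uppercased (all
#' cross-species symbol joins in this package are case-insensitive),
#' self-loops dropped, and duplicate edges in either orientation collapsed.
#'
#' @param path Path to the edge-list file.
#' @return A tibble of class `radhub_ppi` with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  short <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(short) > 0L) stop("edge-list line ", short[1L], " has fewer than 2 fields")
  ppi_network(tibble::tibble(
    from = vapply(fields, `[[`, character(1), 1L),
    to = vapply(fields, `[[`, character(1), 2L)
  ))
}

#' Construct a PPI network from an edge table
#'
#' @param edges Data frame with two symbol columns. Undirected semantics:
#'   self-loops are dropped and reverse duplicates collapsed; symbols
#'   uppercased.
#' @return A tibble of class `radhub_ppi` with columns `from`, `to`.
#' @export
ppi_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  names(edges)[1:2] <- c("from", "to")
  edges <- dplyr::mutate(
    edges,
    from = toupper(.data$from), to = toupper(.data$to)
  )
  edges <- dplyr::filter(edges, .data$from != .data$to)
  # canonical orientation so {a,b} and {b,a} collapse
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- dplyr::distinct(edges, .data$from, .data$to)
  structure(edges, class = c("radhub_ppi", class(tibble::tibble())))
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path Path to the list file.
#' @return Character vector of symbols (as written; case handling happens at
#'   comparison time, see [overlap_genes()]).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path, progress = FALSE))
  x[nzchar(x)]
}

#' Read a qPCR Ct table
#'
#' TSV with columns `gene`, `timepoint_days`, `condition`
#' (`control`/`treated`), `replicate`, `ct_target`, `ct_reference`.
#'
#' @param path Path to the Ct TSV.
#' @return A tibble with the columns above.
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "gene", "timepoint_days", "condition", "replicate",
    "ct_target", "ct_reference"
  )
  miss <- setdiff(required, names(ct))
  if (length(miss) > 0L) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  bad <- !(ct$ct_target > 0 & ct$ct_target < 45 & ct$ct_reference > 0 & ct$ct_reference < 45)
  if (any(bad)) stop("Ct value outside (0, 45) at row ", which(bad)[1L])
  ct
}
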