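#' Volcano-style view of the differential table
#'
#' One panel per timepoint; log2 fold change against -log10 p, genes passing
#' the selection rule highlighted.
#'
#' @param object A `radhub_de` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radhub_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_fc, y = -log10(.data$p_value),
    colour = .data$significant_any
  )) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~timepoint_days, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change vs baseline", y = "-log10 p",
      colour = "significant at\nany timepoint"
    ) +
    ggplot2::theme_minimal()
}

#' Significant model temporal profiles
#'
#' Step trajectories of the significant profiles (or all profiles when none
#' is significant), one panel each, annotated with member counts.
#'
#' @param object A `radhub_stem` result from [cluster_timecourse()].
#' @param only_significant Show significant profiles only (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radhub_stem <- function(object, only_significant = TRUE, ...) {
  cl <- tibble::as_tibble(object$clusters)
  if (only_significant && any(cl$significant)) cl <- cl[cl$significant, ]
  tps <- attr(object$trajectories, "timepoints") %||%
    seq_along(cl$steps[[1L]])
  df <- tidyr::unnest_longer(
    dplyr::mutate(cl,
      label = sprintf("profile %d (n=%d)", .data$profile_id, .data$n_genes),
      timepoint = list(tps)
    ),
    c("steps", "timepoint")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$steps)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "days after irradiation", y = "model units") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Top terms by Fisher p, sized by study hits and coloured by enrichment
#' ratio.
#'
#' @param object A `radhub_enrich` table.
#' @param top Number of terms to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radhub_enrich <- function(object, top = 20L, ...) {
  df <- utils::head(dplyr::arrange(tibble::as_tibble(object), .data$p_fisher), top)
  df$term_name <- factor(df$term_name, levels = rev(df$term_name))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_fisher), y = .data$term_name,
    size = .data$k, colour = .data$enrichment_ratio
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "-log10 Fisher p", y = NULL,
      size = "study hits", colour = "enrichment\nratio"
    ) +
    ggplot2::theme_minimal()
}

#' Co-expression network layout
#'
#' Force-directed layout (seeded, deterministic) with nodes coloured by
#' coreness — the k-core level that defines the hub genes.
#'
#' @param object A `radhub_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radhub_network <- function(object, seed = 0L, ...) {
  if (nrow(object$nodes) == 0L) stop("cannot plot an empty network")
  g <- igraph::graph_from_data_frame(
    object$edges[, c("gene_a", "gene_b")],
    directed = FALSE, vertices = object$nodes$gene
  )
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1L], y = xy[, 2L])
  edges <- dplyr::left_join(
    dplyr::left_join(object$edges,
      dplyr::select(nodes, gene_a = "gene", xa = "x", ya = "y"),
      by = "gene_a"
    ),
    dplyr::select(nodes, gene_b = "gene", xb = "x", yb = "y"),
    by = "gene_b"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      colour = "grey75", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$coreness, size = .data$degree)
    ) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(colour = "k-core", size = "degree") +
    ggplot2::theme_void()
}

#' qPCR fold-change bars
#'
#' Fold change per gene and timepoint with one-standard-deviation error
#' bars; the dashed line marks no change.
#'
#' @param object A `radhub_qpcr` table from [ddct_fold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radhub_qpcr <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$timepoint_days), y = .data$fold
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$fold - .data$sd, 0), ymax = .data$fold + .data$sd),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "days after irradiation", y = "fold change (2^-ddCt)") +
    ggplot2::theme_minimal()
}
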