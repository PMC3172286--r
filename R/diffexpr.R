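#' Two-sample t test (Welch by default)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value; `equal_var = TRUE` switches to the pooled-variance
#' (classical Student) form. Degenerate variance is handled by convention:
#' both groups constant with equal means gives p = 1, both constant with
#' different means gives p = 0.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_var Use the pooled-variance statistic instead of Welch.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(x, y, equal_var = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  res <- welch_t_rows(matrix(x, 1L), matrix(y, 1L), equal_var = equal_var)
  tibble::tibble(statistic = res$t[1L], df = res$df[1L], p_value = res$p[1L])
}

# row-wise Welch / pooled t over two matrices with matching rows
welch_t_rows <- function(a, b, equal_var = FALSE) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  if (equal_var) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2L, length(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  t_stat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  # zero variance in both groups: equal means -> no evidence (p = 1),
  # unequal means -> infinitely strong evidence (p = 0)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
    t_stat[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0, Inf *
      sign(ma[degenerate] - mb[degenerate]))
    df[degenerate] <- NA_real_
  }
  list(t = t_stat, df = df, p = p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q values, order-preserving with respect to the input
#' positions.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of q values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-timepoint differential expression against baseline
#'
#' For every gene and every non-baseline timepoint, tests the log2
#' intensities of that timepoint's replicates against the baseline replicates
#' (Welch t by default) and reports the log2 fold change, the raw p value and
#' the Benjamini-Hochberg q value (adjusted across genes within each
#' timepoint). A gene is flagged `significant_any` if its raw p falls below
#' `alpha` at one or more timepoints — the time-course selection rule this
#' analysis is built around; q values are reported alongside so callers can
#' apply an FDR rule instead.
#'
#' @param expr A `radhub_expr` object (intensity scale).
#' @param alpha Per-timepoint significance level for the selection rule.
#' @param equal_var Use pooled-variance t instead of Welch.
#' @param baseline_pooled Designs hybridising one sham chip per batch record
#'   every sham chip as a baseline replicate; all baseline chips always form
#'   one pooled control group. With the default `FALSE`, a baseline holding
#'   fewer than 2 chips is an error pointing at this flag; with `TRUE` the
#'   error message instead states that a single sham chip cannot be pooled.
#'   Either way at least 2 baseline chips are required for the t test.
#' @return A tibble of class `radhub_de` in long form: `gene`,
#'   `timepoint_days`, `log2_fc`, `p_value`, `q_value`, and the per-gene flag
#'   `significant_any` repeated across a gene's rows.
#' @export
call_differential <- function(expr, alpha = 0.05, equal_var = FALSE,
                              baseline_pooled = FALSE) {
  info <- sample_info(expr)
  values <- log2(expr_values(expr))
  base_ids <- info$sample_id[info$group == "baseline"]
  if (length(base_ids) == 0L) stop("matrix has no baseline samples")
  if (length(base_ids) < 2L) {
    if (!baseline_pooled) {
      stop(
        "baseline has fewer than 2 replicates; ",
        "set baseline_pooled = TRUE to pool all sham chips into one control group"
      )
    }
    # pooling needs something to pool: one sham chip cannot support a t test
    stop("cannot pool a single sham chip into a baseline group")
  }
  baseline <- values[, base_ids, drop = FALSE]

  tps <- sort(setdiff(unique(info$timepoint_days), 0L))
  rows <- lapply(tps, function(tp) {
    ids <- info$sample_id[info$timepoint_days == tp]
    if (length(ids) < 2L) {
      stop("timepoint ", tp, " has fewer than 2 replicates")
    }
    grp <- values[, ids, drop = FALSE]
    ht <- welch_t_rows(grp, baseline, equal_var = equal_var)
    tibble::tibble(
      gene = rownames(values),
      timepoint_days = tp,
      log2_fc = unname(rowMeans(grp) - rowMeans(baseline)),
      p_value = unname(ht$p),
      q_value = unname(bh_fdr(ht$p))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$gene),
    significant_any = any(.data$p_value < alpha)
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, .data$gene, .data$timepoint_days)
  structure(out,
    alpha = alpha,
    class = c("radhub_de", class(tibble::tibble()))
  )
}

#' Genes selected by the differential rule
#'
#' @param de A `radhub_de` table.
#' @param rule `"p_any"` (raw p below alpha at any timepoint, the default
#'   selection rule) or `"q_any"` (BH q below alpha at any timepoint).
#' @param alpha Cutoff; defaults to the alpha the table was built with.
#' @return Character vector of gene symbols.
#' @export
differential_genes <- function(de, rule = c("p_any", "q_any"), alpha = NULL) {
  rule <- match.arg(rule)
  if (is.null(alpha)) alpha <- attr(de, "alpha") %||% 0.05
  stat <- if (rule == "p_any") de$p_value else de$q_value
  sort(unique(de$gene[stat < alpha]))
}

#' @export
print.radhub_de <- function(x, ...) {
  cat(
    "# Differential table: ", length(unique(x$gene)), " genes x ",
    length(unique(x$timepoint_days)), " timepoints; ",
    length(unique(x$gene[x$significant_any])), " genes significant at any timepoint\n",
    sep = ""
  )
  NextMethod()
}
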