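#' Relative quantification by the 2^-ddCt method
#'
#' For each gene and timepoint: per-replicate `dCt = ct_target -
#' ct_reference`; `ddCt = mean dCt(treated) - mean dCt(control)`; `fold =
#' 2^-ddCt` (the Livak convention — means are taken on the dCt scale before
#' exponentiation). The standard deviation comes from the per-replicate
#' treated folds computed against the control mean dCt.
#'
#' @param ct A Ct tibble with columns `gene`, `timepoint_days`, `condition`
#'   (`control` / `treated`), `replicate`, `ct_target`, `ct_reference` (see
#'   [read_ct_table()]).
#' @return A tibble of class `radhub_qpcr` with `gene`, `timepoint_days`,
#'   `fold`, `sd`, `n_treated`, `n_control`.
#' @export
ddct_fold <- function(ct) {
  required <- c("gene", "timepoint_days", "condition", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(required, names(ct))
  if (length(miss) > 0L) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  ct <- dplyr::mutate(ct, dct = .data$ct_target - .data$ct_reference)

  out <- dplyr::group_by(ct, .data$gene, .data$timepoint_days)
  out <- dplyr::summarise(
    out,
    n_treated = sum(.data$condition == "treated"),
    n_control = sum(.data$condition == "control"),
    mean_dct_control = mean(.data$dct[.data$condition == "control"]),
    mean_dct_treated = mean(.data$dct[.data$condition == "treated"]),
    sd = stats::sd(2^-(.data$dct[.data$condition == "treated"] -
      mean(.data$dct[.data$condition == "control"]))),
    .groups = "drop"
  )
  incomplete <- out$n_treated == 0L | out$n_control == 0L
  if (any(incomplete)) {
    i <- which(incomplete)[1L]
    stop(
      "missing condition for gene ", out$gene[i],
      " at timepoint ", out$timepoint_days[i]
    )
  }
  out <- dplyr::mutate(
    out,
    fold = 2^-(.data$mean_dct_treated - .data$mean_dct_control)
  )
  out <- dplyr::select(
    out, "gene", "timepoint_days", "fold", "sd", "n_treated", "n_control"
  )
  structure(out, class = c("radhub_qpcr", class(tibble::tibble())))
}

#' Direction concordance between array and qPCR fold changes
#'
#' Compares the sign of the array log2 fold change with the sign of the qPCR
#' log2 fold for every gene/timepoint present in both tables.
#'
#' @param array_fc A `radhub_de` table (or any tibble with `gene`,
#'   `timepoint_days`, `log2_fc`).
#' @param qpcr A `radhub_qpcr` table from [ddct_fold()].
#' @return A list of class `radhub_concordance`: `detail` (tibble with
#'   per-pair signs and a `concordant` flag) and `fraction_concordant`.
#' @export
concordance <- function(array_fc, qpcr) {
  detail <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(array_fc), "gene", "timepoint_days", "log2_fc"),
    dplyr::select(tibble::as_tibble(qpcr), "gene", "timepoint_days", "fold"),
    by = c("gene", "timepoint_days")
  )
  if (nrow(detail) == 0L) stop("no shared gene/timepoint between array and qPCR tables")
  detail <- dplyr::mutate(
    detail,
    sign_array = sign(.data$log2_fc),
    sign_qpcr = sign(log2(.data$fold)),
    concordant = .data$sign_array == .data$sign_qpcr
  )
  structure(
    list(
      detail = detail,
      fraction_concordant = mean(detail$concordant)
    ),
    class = "radhub_concordance"
  )
}

#' @export
print.radhub_concordance <- function(x, ...) {
  cat(
    "# Array/qPCR direction concordance: ",
    sprintf("%.1f%%", 100 * x$fraction_concordant),
    " over ", nrow(x$detail), " gene-timepoint pairs\n",
    sep = ""
  )
  invisible(x)
}
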