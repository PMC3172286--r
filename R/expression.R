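#' Construct an expression matrix object
#'
#' The central data container of the package: a wide tibble with one row per
#' gene (first column `gene`) and one numeric column per array sample, plus a
#' sample-metadata table attached as the `"sample_info"` attribute. Sample
#' columns follow the `t{days}_r{replicate}` naming convention (e.g. `t3_r2`
#' is replicate 2 at 3 days after irradiation) unless an explicit metadata
#' table is supplied.
#'
#' @param values A data frame whose first column is the gene symbol and whose
#'   remaining columns are numeric intensities, one per sample.
#' @param sample_info Optional tibble with columns `sample_id`,
#'   `timepoint_days`, `replicate`, `group`. When `NULL` it is derived from
#'   the sample column names. Timepoint 0 is the sham-irradiated baseline;
#'   all other timepoints are irradiated groups.
#'
#' @return A tibble of class `radhub_expr`.
#' @export
expression_matrix <- function(values, sample_info = NULL) {
  values <- tibble::as_tibble(values)
  if (ncol(values) < 2L) {
    stop("expression matrix needs a gene column and at least one sample column")
  }
  names(values)[1L] <- "gene"
  values$gene <- as.character(values$gene)

  dup <- values$gene[duplicated(values$gene)]
  if (length(dup) > 0L) {
    stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  }

  sample_ids <- names(values)[-1L]
  for (s in sample_ids) {
    col <- values[[s]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1L]
      stop("non-numeric value in column '", s, "', row ", bad)
    }
    if (anyNA(col)) {
      stop("missing value in column '", s, "', row ", which(is.na(col))[1L])
    }
  }

  if (is.null(sample_info)) {
    sample_info <- parse_sample_ids(sample_ids)
  } else {
    sample_info <- validate_sample_info(sample_info, sample_ids)
  }

  structure(values,
    sample_info = sample_info,
    class = c("radhub_expr", class(tibble::tibble()))
  )
}

#' Sample metadata of an expression matrix
#'
#' @param x An object created by [expression_matrix()] or [read_expression()].
#' @return A tibble with columns `sample_id`, `timepoint_days`, `replicate`,
#'   `group`.
#' @export
sample_info <- function(x) {
  info <- attr(x, "sample_info")
  if (is.null(info)) info <- parse_sample_ids(setdiff(names(x), "gene"))
  info
}

# `t{days}_r{rep}` header convention -> metadata tibble
parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^t([0-9]+)_r([0-9]+)$", ids))
  bad <- ids[vapply(m, length, integer(1)) == 0L]
  if (length(bad) > 0L) {
    stop(
      "sample id(s) not in t{days}_r{rep} form and no metadata given: ",
      paste(bad, collapse = ", ")
    )
  }
  tp <- vapply(m, function(x) as.integer(x[2L]), integer(1))
  rep <- vapply(m, function(x) as.integer(x[3L]), integer(1))
  tibble::tibble(
    sample_id = ids,
    timepoint_days = tp,
    replicate = rep,
    group = ifelse(tp == 0L, "baseline", "irradiated")
  )
}

validate_sample_info <- function(info, sample_ids) {
  info <- tibble::as_tibble(info)
  required <- c("sample_id", "timepoint_days", "replicate", "group")
  miss <- setdiff(required, names(info))
  if (length(miss) > 0L) {
    stop("sample_info is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(info$sample_id)) stop("duplicate sample_id in sample_info")
  extra <- setdiff(sample_ids, info$sample_id)
  if (length(extra) > 0L) {
    stop("samples absent from sample_info: ", paste(extra, collapse = ", "))
  }
  info <- info[match(sample_ids, info$sample_id), required]
  if (!all(info$group %in% c("baseline", "irradiated"))) {
    stop("group must be 'baseline' or 'irradiated'")
  }
  if (!all((info$timepoint_days == 0) == (info$group == "baseline"))) {
    stop("timepoint_days == 0 must coincide with group == 'baseline'")
  }
  info
}

# numeric matrix (genes x samples) view of the container
expr_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  rownames(m) <- x$gene
  m
}

#' @export
print.radhub_expr <- function(x, ...) {
  info <- sample_info(x)
  cat(
    "# Expression matrix: ", nrow(x), " genes x ", nrow(info), " samples (",
    length(unique(info$timepoint_days)), " timepoints)\n",
    sep = ""
  )
  NextMethod()
}
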