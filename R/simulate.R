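#' Simulation configuration
#'
#' Parameters of the synthetic bone-marrow time-course generator. Defaults
#' emulate the study design the analysis targets: a 5-point course at 0, 3,
#' 7, 11 and 21 days after irradiation with 4 replicates per group (the
#' baseline gets the same replicate count so the per-timepoint t test is
#' well-posed), log-normal intensities, additive log2 noise, unit-change
#' temporal profiles for the planted differential genes, and co-expressed
#' modules sharing a latent trajectory.
#'
#' @param n_genes Total number of genes.
#' @param n_de Number of planted differential genes.
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per module (>= 3); modules are carved out of the
#'   differential genes, so `n_modules * module_size <= n_de`.
#' @param n_active_profiles Size of the profile pool the non-module
#'   differential genes draw from. Short recovery courses concentrate in a
#'   few temporal patterns, so planting spreads the signal over a handful of
#'   profiles rather than all of them; module profiles are reserved and do
#'   not count toward the pool.
#' @param timepoints Integer vector of timepoints in days; must include 0.
#' @param n_replicates Replicates per timepoint (baseline included).
#' @param noise_sd Per-sample additive noise on the log2 scale.
#' @param effect_log2 log2 units per unit change of a planted profile.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   intensity.
#' @param seed Integer seed; every generator draw depends on it.
#' @return A list of class `radhub_simconfig`.
#' @export
sim_config <- function(n_genes = 1000L, n_de = 200L, n_modules = 2L,
                       module_size = 30L, n_active_profiles = 6L,
                       timepoints = c(0L, 3L, 7L, 11L, 21L),
                       n_replicates = 4L, noise_sd = 0.2, effect_log2 = 1,
                       baseline_mean = 8, baseline_sd = 1.5, seed = 0L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_de = as.integer(n_de),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    n_active_profiles = as.integer(n_active_profiles),
    timepoints = as.integer(sort(unique(timepoints))),
    n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd, effect_log2 = effect_log2,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_de > cfg$n_genes) stop("n_de must not exceed n_genes")
  if (cfg$n_modules > 0L && cfg$module_size < 3L) stop("module_size must be >= 3")
  if (cfg$n_modules * cfg$module_size > cfg$n_de) {
    stop("modules require n_modules * module_size <= n_de")
  }
  if (cfg$n_active_profiles < 1L) stop("n_active_profiles must be positive")
  if (!0L %in% cfg$timepoints) stop("timepoints must include the baseline 0")
  if (length(cfg$timepoints) < 2L) stop("need at least one non-baseline timepoint")
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$effect_log2 <= 0) stop("effect_log2 must be positive")
  structure(cfg, class = "radhub_simconfig")
}

# model profiles used for planting: the same 50 spread-out profiles the
# clustering step selects, so "true profile" is well-defined downstream
planting_profiles <- function(cfg, n_profiles = 50L, max_unit_change = 2L) {
  candidates <- enumerate_candidate_profiles(length(cfg$timepoints), max_unit_change)
  select_model_profiles(candidates, min(n_profiles, nrow(candidates)))
}

# module profiles must be mutually distinguishable in correlation space
pick_module_profiles <- function(profiles, n_modules, max_abs_r = 0.5) {
  sm <- do.call(rbind, profiles$steps)
  r <- stats::cor(t(sm))
  chosen <- integer(0)
  for (i in seq_len(nrow(profiles))) {
    if (length(chosen) == n_modules) break
    if (all(abs(r[i, chosen]) < max_abs_r)) chosen <- c(chosen, i)
  }
  if (length(chosen) < n_modules) {
    stop("cannot find ", n_modules, " mutually decorrelated module profiles")
  }
  chosen
}

#' Simulate an expression time course with planted structure
#'
#' Baseline log2 intensities are drawn per gene from
#' `Normal(baseline_mean, baseline_sd)`. Non-differential genes stay flat
#' over time apart from per-sample `Normal(0, noise_sd)` log2 noise. Each
#' planted differential gene follows one of the 50 spread-out integer
#' unit-change model profiles, scaled by `effect_log2`. Genes of the same
#' module share one profile (module profiles are mutually decorrelated,
#' pairwise |r| < 0.5, and reserved for modules), so their per-timepoint
#' trajectories are highly correlated; all other differential genes draw
#' their profile uniformly from the remaining model profiles. Values are
#' emitted on the intensity scale (`2^log2`).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `radhub_sim` with elements `expr` (a
#'   `radhub_expr`), and `truth`: a list with `de_genes`,
#'   `profile_of_gene` (tibble `gene`, `profile_id`), `module_of_gene`
#'   (tibble `gene`, `module_id`), `profiles` (the model-profile tibble) and
#'   `module_profiles` (tibble `module_id`, `profile_id`).
#' @export
simulate_timecourse <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  tps <- cfg$timepoints
  n_tp <- length(tps)
  profiles <- planting_profiles(cfg)

  de_genes <- sort(sample(genes, cfg$n_de))
  module_rows <- if (cfg$n_modules > 0L) pick_module_profiles(profiles, cfg$n_modules) else integer(0)

  profile_of <- stats::setNames(rep(NA_integer_, cfg$n_de), de_genes)
  module_of <- stats::setNames(rep(NA_integer_, cfg$n_de), de_genes)
  pos <- 1L
  for (m in seq_len(cfg$n_modules)) {
    idx <- pos:(pos + cfg$module_size - 1L)
    profile_of[idx] <- profiles$profile_id[module_rows[m]]
    module_of[idx] <- m
    pos <- pos + cfg$module_size
  }
  free <- which(is.na(profile_of))
  if (length(free) > 0L) {
    pool <- setdiff(profiles$profile_id, profiles$profile_id[module_rows])
    if (length(pool) == 0L) pool <- profiles$profile_id
    if (length(pool) > cfg$n_active_profiles) {
      pool <- sample(pool, cfg$n_active_profiles)
    }
    profile_of[free] <- sample(pool, length(free), replace = TRUE)
  }

  step_mat <- do.call(rbind, profiles$steps)
  rownames(step_mat) <- as.character(profiles$profile_id)

  mu0 <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(mu0) <- genes
  # per-gene x timepoint mean on log2 scale
  mean_mat <- matrix(mu0, cfg$n_genes, n_tp)
  de_idx <- match(de_genes, genes)
  mean_mat[de_idx, ] <- mean_mat[de_idx, ] +
    step_mat[as.character(profile_of), , drop = FALSE] * cfg$effect_log2

  sample_ids <- as.vector(t(outer(tps, seq_len(cfg$n_replicates),
    function(tp, r) sprintf("t%d_r%d", tp, r)
  )))
  tp_of_sample <- rep(tps, each = cfg$n_replicates)
  log2_values <- mean_mat[, match(tp_of_sample, tps), drop = FALSE] +
    matrix(
      stats::rnorm(cfg$n_genes * length(sample_ids), 0, cfg$noise_sd),
      cfg$n_genes, length(sample_ids)
    )
  colnames(log2_values) <- sample_ids

  expr <- expression_matrix(dplyr::bind_cols(
    tibble::tibble(gene = genes),
    tibble::as_tibble(2^log2_values)
  ))

  truth <- list(
    de_genes = de_genes,
    profile_of_gene = tibble::tibble(gene = de_genes, profile_id = unname(profile_of)),
    module_of_gene = tibble::tibble(
      gene = de_genes[!is.na(module_of)],
      module_id = module_of[!is.na(module_of)]
    ),
    profiles = profiles,
    module_profiles = tibble::tibble(
      module_id = seq_len(cfg$n_modules),
      profile_id = profiles$profile_id[module_rows]
    )
  )
  structure(list(expr = expr, truth = truth, config = cfg), class = "radhub_sim")
}

#' Simulate annotation terms with one planted enriched term
#'
#' Builds a gene-set collection over the simulated gene universe: one
#' planted term concentrated in the differential genes plus uniform
#' background terms, and a star-shaped term DAG linking every term to a
#' single root.
#'
#' @param sim A `radhub_sim` object (or its `truth` element plus `genes`).
#' @param n_terms Number of background terms.
#' @param term_size Size of each background term.
#' @param planted_size Size of the planted term.
#' @param planted_de How many of the planted term's genes are differential.
#' @param seed Seed for the term draws.
#' @return A list with `sets` (GMT-shaped tibble), `dag` (tibble `child`,
#'   `parent`) and `enriched_terms` (character).
#' @export
simulate_annotations <- function(sim, n_terms = 20L, term_size = 40L,
                                 planted_size = 50L, planted_de = 40L,
                                 seed = 1L) {
  genes <- sim$expr$gene
  de <- sim$truth$de_genes
  if (planted_de > length(de)) stop("planted_de exceeds the number of DE genes")
  if (planted_size - planted_de > length(setdiff(genes, de))) {
    stop("not enough non-differential genes for the planted term")
  }
  set.seed(seed)
  planted <- c(
    sample(de, planted_de),
    sample(setdiff(genes, de), planted_size - planted_de)
  )
  background <- lapply(seq_len(n_terms), function(i) sample(genes, term_size))
  sets <- tibble::tibble(
    term_id = c("TERM:PLANTED", sprintf("TERM:%04d", seq_len(n_terms))),
    term_name = c("planted enriched process", sprintf("background process %d", seq_len(n_terms))),
    genes = c(list(planted), background)
  )
  dag <- tibble::tibble(child = sets$term_id, parent = "TERM:ROOT")
  list(sets = sets, dag = dag, enriched_terms = "TERM:PLANTED")
}

#' Simulate a PPI network and a literature gene list
#'
#' The PPI is an Erdos-Renyi graph over uppercased gene symbols with a
#' densified clique planted on a chosen seed set. The literature list
#' overlaps the differential genes by exactly `k_overlap` symbols; the rest
#' of the list is filled with symbols outside the expression universe,
#' mimicking text-mined genes from other studies.
#'
#' @param sim A `radhub_sim` object.
#' @param k_overlap Number of differential genes present in the literature
#'   list (the planted overlap; 42 in the motivating study).
#' @param n_literature Total length of the literature list.
#' @param edge_prob Background edge probability of the random PPI.
#' @param clique_size Size of the densified clique planted on the first
#'   `clique_size` overlap genes.
#' @param seed Seed for the draws.
#' @return A list with `ppi` (a `radhub_ppi` edge tibble), `literature`
#'   (character vector) and `overlap_truth` (uppercased planted overlap).
#' @export
simulate_ppi_and_literature <- function(sim, k_overlap = 42L,
                                        n_literature = 514L,
                                        edge_prob = 0.02,
                                        clique_size = 6L, seed = 2L) {
  de <- sim$truth$de_genes
  if (k_overlap > length(de)) stop("k_overlap exceeds the number of DE genes")
  set.seed(seed)
  overlap <- if (k_overlap > 0L) sort(sample(de, k_overlap)) else character(0)
  extra <- sprintf("LIT%04d", seq_len(n_literature - k_overlap))
  literature <- sample(c(overlap, extra))

  nodes <- toupper(literature)
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < edge_prob
  edges <- tibble::tibble(
    from = nodes[pairs[keep, 1L]],
    to = nodes[pairs[keep, 2L]]
  )
  clique <- toupper(utils::head(overlap, clique_size))
  if (length(clique) >= 2L) {
    cp <- utils::combn(clique, 2L)
    edges <- dplyr::bind_rows(edges, tibble::tibble(from = cp[1L, ], to = cp[2L, ]))
  }
  list(
    ppi = ppi_network(edges),
    literature = literature,
    overlap_truth = toupper(overlap)
  )
}

#' Simulate a qPCR Ct table for known fold changes
#'
#' Reference-gene Ct is constant (default 20 cycles) plus noise in both
#' conditions; the treated target Ct sits `log2(fold)` cycles below the
#' control target Ct, the closed-form inverse of the 2^-ddCt rule. Three
#' replicates per condition by default.
#'
#' @param fold_changes Tibble with columns `gene`, `timepoint_days`, `fold`
#'   (true intensity-scale fold change vs control).
#' @param n_replicates Replicates per condition.
#' @param ct_reference Mean reference-gene Ct.
#' @param ct_control Mean control-condition target Ct.
#' @param noise_sd Per-well Ct noise (cycles).
#' @param seed Seed for the noise draws.
#' @return A Ct tibble with columns `gene`, `timepoint_days`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @export
simulate_qpcr <- function(fold_changes, n_replicates = 3L, ct_reference = 20,
                          ct_control = 24, noise_sd = 0.1, seed = 3L) {
  stopifnot(all(c("gene", "timepoint_days", "fold") %in% names(fold_changes)))
  if (any(fold_changes$fold <= 0)) stop("fold changes must be positive")
  set.seed(seed)
  grid <- tidyr::expand_grid(
    fold_changes,
    condition = c("control", "treated"),
    replicate = seq_len(n_replicates)
  )
  grid <- dplyr::mutate(
    grid,
    ct_target = ct_control -
      ifelse(.data$condition == "treated", log2(.data$fold), 0) +
      stats::rnorm(dplyr::n(), 0, noise_sd),
    ct_reference = ct_reference + stats::rnorm(dplyr::n(), 0, noise_sd)
  )
  dplyr::select(
    grid, "gene", "timepoint_days", "condition", "replicate",
    "ct_target", "ct_reference"
  )
}

#' Generate and optionally write the full synthetic input bundle
#'
#' One call producing everything the pipeline consumes — expression matrix,
#' annotation GMT + term DAG, PPI edge list, literature gene list, qPCR Ct
#' table — together with the ground-truth labels. With `dir` set, each piece
#' is written in its external format (TSV / GMT / plain list) plus truth
#' sidecar tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @param k_overlap,n_literature Forwarded to [simulate_ppi_and_literature()].
#' @return A list of class `radhub_bundle` with elements `sim`,
#'   `annotations`, `ppi`, `qpcr` and, when written, `paths`.
#' @export
simulate_study_inputs <- function(cfg = sim_config(), dir = NULL,
                                  k_overlap = 42L, n_literature = 514L) {
  sim <- simulate_timecourse(cfg)
  ann <- simulate_annotations(sim, seed = cfg$seed + 1L)
  ppi <- simulate_ppi_and_literature(sim,
    k_overlap = min(k_overlap, cfg$n_de),
    n_literature = n_literature, seed = cfg$seed + 2L
  )
  # true fold at the first non-baseline timepoint of a few planted genes
  tp1 <- setdiff(cfg$timepoints, 0L)[1L]
  picks <- utils::head(sim$truth$profile_of_gene, 6L)
  steps1 <- vapply(
    picks$profile_id,
    function(id) sim$truth$profiles$steps[[match(id, sim$truth$profiles$profile_id)]][2L],
    integer(1)
  )
  fc <- tibble::tibble(
    gene = picks$gene, timepoint_days = tp1,
    fold = 2^(steps1 * cfg$effect_log2)
  )
  qpcr <- simulate_qpcr(fc, seed = cfg$seed + 3L)

  out <- list(sim = sim, annotations = ann, ppi = ppi, qpcr_truth = fc, qpcr = qpcr)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_expression(sim$expr, p("expression.tsv"))
    write_gmt(ann$sets, p("annotations.gmt"))
    readr::write_tsv(ann$dag, p("term_dag.tsv"), col_names = FALSE, progress = FALSE)
    readr::write_tsv(ppi$ppi, p("ppi_edges.tsv"), col_names = FALSE, progress = FALSE)
    readr::write_lines(ppi$literature, p("literature_genes.txt"))
    readr::write_tsv(qpcr, p("ct_table.tsv"), progress = FALSE)
    readr::write_lines(sim$truth$de_genes, p("truth_de_genes.txt"))
    readr::write_tsv(sim$truth$profile_of_gene, p("truth_profiles.tsv"), progress = FALSE)
    readr::write_tsv(sim$truth$module_of_gene, p("truth_modules.tsv"), progress = FALSE)
    out$paths <- list(
      expression = p("expression.tsv"), gmt = p("annotations.gmt"),
      dag = p("term_dag.tsv"), ppi = p("ppi_edges.tsv"),
      literature = p("literature_genes.txt"), ct = p("ct_table.tsv")
    )
  }
  structure(out, class = "radhub_bundle")
}
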