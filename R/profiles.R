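#' Enumerate candidate model temporal profiles
#'
#' A model profile is an integer trajectory over the time course that starts
#' at 0 and changes by at most `max_unit_change` units between consecutive
#' timepoints. The all-flat profile is excluded, giving
#' `(2c + 1)^(T - 1) - 1` candidates for `T` timepoints and maximum unit
#' change `c`. Candidates are returned in lexicographic order of their step
#' vectors.
#'
#' @param n_timepoints Number of timepoints `T` (including baseline), >= 2.
#' @param max_unit_change Maximum per-step change `c`, >= 1.
#' @return A tibble with `candidate_id` and list-column `steps` (integer
#'   vectors of length `n_timepoints` starting at 0).
#' @export
enumerate_candidate_profiles <- function(n_timepoints, max_unit_change) {
  stopifnot(n_timepoints >= 2L, max_unit_change >= 1L)
  d <- seq.int(-max_unit_change, max_unit_change)
  diffs <- as.matrix(expand.grid(rep(list(d), n_timepoints - 1L)))
  cum <- diffs
  if (ncol(diffs) > 1L) {
    for (j in 2L:ncol(diffs)) cum[, j] <- cum[, j - 1L] + diffs[, j]
  }
  steps <- cbind(0L, cum)
  steps <- steps[rowSums(abs(steps)) > 0L, , drop = FALSE]
  ord <- do.call(order, as.data.frame(steps))
  steps <- steps[ord, , drop = FALSE]
  tibble::tibble(
    candidate_id = seq_len(nrow(steps)),
    steps = lapply(seq_len(nrow(steps)), function(i) as.integer(steps[i, ]))
  )
}

#' Select a spread-out set of model profiles
#'
#' Greedy max-min selection under the distance `d(x, y) = 1 - r(x, y)`
#' (Pearson correlation of step vectors), the standard prototype-selection
#' step of short time-series clustering: start from the lexicographically
#' smallest candidate, then repeatedly add the candidate whose minimum
#' distance to the already-chosen set is largest, breaking ties by
#' lexicographic order. Fully deterministic.
#'
#' @param candidates Output of [enumerate_candidate_profiles()].
#' @param m Number of profiles to select (`<=` number of candidates).
#' @return A tibble with `profile_id` (0-based, in selection order) and
#'   list-column `steps`.
#' @export
select_model_profiles <- function(candidates, m) {
  n <- nrow(candidates)
  if (m > n) stop("m (", m, ") exceeds the number of candidates (", n, ")")
  S <- do.call(rbind, candidates$steps)
  if (m == n) {
    return(tibble::tibble(profile_id = seq_len(n) - 1L, steps = candidates$steps))
  }
  d <- 1 - stats::cor(t(S))
  chosen <- 1L # candidates are already in lexicographic order
  min_d <- d[, 1L]
  while (length(chosen) < m) {
    min_d[chosen] <- -Inf
    # ties resolve to the smallest index = lexicographically smallest
    nxt <- which(min_d >= max(min_d) - 1e-12)[1L]
    chosen <- c(chosen, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  tibble::tibble(
    profile_id = seq_along(chosen) - 1L,
    steps = candidates$steps[chosen]
  )
}

#' Per-gene log-ratio trajectories relative to baseline
#'
#' For each gene, the mean log2 intensity at each timepoint minus the mean
#' log2 baseline intensity; the baseline element is 0 by construction. This
#' is the object the model profiles are matched against and the default
#' input of the co-expression network.
#'
#' @param expr A `radhub_expr` object (intensity scale).
#' @param genes Optional character vector restricting to a gene subset.
#' @return A tibble with column `gene` and one numeric column `t{days}` per
#'   timepoint, ordered by time.
#' @export
logratio_trajectories <- function(expr, genes = NULL) {
  info <- sample_info(expr)
  values <- log2(expr_values(expr))
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(values))
    if (length(missing) > 0L) {
      stop("gene(s) not in matrix: ", paste(utils::head(missing, 5L), collapse = ", "))
    }
    values <- values[genes, , drop = FALSE]
  }
  tps <- sort(unique(info$timepoint_days))
  means <- vapply(
    tps,
    function(tp) rowMeans(values[, info$sample_id[info$timepoint_days == tp], drop = FALSE]),
    numeric(nrow(values))
  )
  if (nrow(values) == 1L) means <- matrix(means, nrow = 1L)
  traj <- means - means[, 1L]
  colnames(traj) <- paste0("t", tps)
  out <- tibble::tibble(gene = rownames(values))
  out <- dplyr::bind_cols(out, tibble::as_tibble(traj))
  attr(out, "timepoints") <- tps
  out
}

traj_values <- function(traj) {
  m <- as.matrix(traj[, setdiff(names(traj), "gene"), drop = FALSE])
  rownames(m) <- traj$gene
  m
}

# correlation of each trajectory row against each profile row;
# zero-variance rows propagate NA
profile_correlations <- function(traj_mat, step_mat) {
  tv <- apply(traj_mat, 1L, stats::var)
  r <- suppressWarnings(stats::cor(t(traj_mat), t(step_mat)))
  r[tv == 0, ] <- NA_real_
  r
}

#' Assign genes to their closest model profile
#'
#' Each gene goes to the profile minimizing `1 - r(trajectory, steps)`;
#' exact ties break toward the lowest `profile_id`. Genes whose trajectory
#' has zero variance cannot be correlated and land in a reserved
#' "unassigned" bucket (`profile_id = NA`).
#'
#' @param trajectories Output of [logratio_trajectories()].
#' @param profiles Output of [select_model_profiles()].
#' @return A tibble with `gene`, `profile_id` (integer or `NA`) and
#'   `distance`.
#' @export
assign_profiles <- function(trajectories, profiles) {
  tm <- traj_values(trajectories)
  sm <- do.call(rbind, profiles$steps)
  r <- profile_correlations(tm, sm)
  d <- 1 - r
  pick <- integer(nrow(d))
  dist <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    if (anyNA(row)) {
      pick[i] <- NA_integer_
      dist[i] <- NA_real_
    } else {
      j <- which(row <= min(row) + 1e-12)[1L]
      pick[i] <- j
      dist[i] <- row[j]
    }
  }
  tibble::tibble(
    gene = rownames(tm),
    profile_id = profiles$profile_id[pick],
    distance = dist
  )
}

# all permutations of 1..k as a matrix (k! rows); k is small here
permutations_of <- function(k) {
  if (k == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Permutation significance of model-profile memberships
#'
#' The expected share of genes per profile is estimated by re-assigning every
#' gene after permuting the order of the non-baseline timepoints (the
#' baseline stays fixed because trajectories are ratios to it). For a 5-point
#' course all 4! = 24 permutations are enumerated exactly; for longer courses
#' 240 random permutations are sampled. The observed member count is then
#' compared to a Binomial upper tail at the expected fraction, with
#' Bonferroni correction across profiles.
#'
#' @param trajectories Output of [logratio_trajectories()].
#' @param profiles Output of [select_model_profiles()].
#' @param assignment Optional precomputed [assign_profiles()] result.
#' @param alpha Significance level applied to the Bonferroni-corrected p.
#' @param seed Seed for permutation sampling when the course has more than 5
#'   timepoints (exact enumeration makes it irrelevant at 5).
#' @return A tibble of class `radhub_clusters` with one row per profile:
#'   `profile_id`, `steps`, `n_genes`, `n_expected`, `p_value`,
#'   `p_bonferroni`, `significant`.
#' @export
profile_significance <- function(trajectories, profiles, assignment = NULL,
                                 alpha = 0.001, seed = 0L) {
  if (is.null(assignment)) assignment <- assign_profiles(trajectories, profiles)
  tm <- traj_values(trajectories)
  sm <- do.call(rbind, profiles$steps)
  k <- ncol(tm) - 1L # non-baseline timepoints
  if (factorial(k) <= 240) {
    perms <- permutations_of(k)
  } else {
    set.seed(seed)
    perms <- t(replicate(240L, sample.int(k)))
  }

  n_assigned <- sum(!is.na(assignment$profile_id))
  m <- nrow(profiles)
  frac <- matrix(0, nrow(perms), m)
  for (p in seq_len(nrow(perms))) {
    permuted <- tm[, c(1L, 1L + perms[p, ]), drop = FALSE]
    r <- profile_correlations(permuted, sm)
    d <- 1 - r
    ok <- stats::complete.cases(d)
    if (any(ok)) {
      pick <- apply(d[ok, , drop = FALSE], 1L, function(row) {
        which(row <= min(row) + 1e-12)[1L]
      })
      tab <- tabulate(pick, nbins = m)
      frac[p, ] <- tab / max(sum(ok), 1L)
    }
  }
  expected_frac <- colMeans(frac)

  observed <- vapply(
    profiles$profile_id,
    function(id) sum(assignment$profile_id == id, na.rm = TRUE),
    integer(1)
  )
  p_value <- ifelse(
    observed == 0L,
    1,
    stats::pbinom(observed - 1L, n_assigned, expected_frac, lower.tail = FALSE)
  )
  # profile untouched by data and permutations alike: no evidence, p = 1
  p_value[expected_frac == 0 & observed == 0L] <- 1

  out <- tibble::tibble(
    profile_id = profiles$profile_id,
    steps = profiles$steps,
    n_genes = observed,
    n_expected = n_assigned * expected_frac,
    p_value = p_value,
    p_bonferroni = pmin(p_value * m, 1),
    significant = pmin(p_value * m, 1) < alpha
  )
  structure(out,
    alpha = alpha, n_assigned = n_assigned,
    class = c("radhub_clusters", class(tibble::tibble()))
  )
}

#' Cluster a time course against model temporal profiles
#'
#' Convenience wrapper running the full short time-series clustering step:
#' enumerate candidates, select `n_profiles` spread-out model profiles,
#' assign genes by correlation and score each profile's membership by exact
#' timepoint-permutation significance.
#'
#' @param expr A `radhub_expr` object.
#' @param genes Optional gene subset (typically the differential genes).
#' @param n_profiles Number of model profiles (default 50).
#' @param max_unit_change Maximum per-step change (default 2).
#' @param alpha Corrected significance level for a profile (default 0.001).
#' @param seed Seed forwarded to [profile_significance()].
#' @return A list of class `radhub_stem` with elements `profiles`,
#'   `assignment` and `clusters` (the `radhub_clusters` tibble).
#' @export
cluster_timecourse <- function(expr, genes = NULL, n_profiles = 50L,
                               max_unit_change = 2L, alpha = 0.001, seed = 0L) {
  traj <- logratio_trajectories(expr, genes = genes)
  n_tp <- length(attr(traj, "timepoints"))
  candidates <- enumerate_candidate_profiles(n_tp, max_unit_change)
  profiles <- select_model_profiles(candidates, n_profiles)
  assignment <- assign_profiles(traj, profiles)
  clusters <- profile_significance(traj, profiles,
    assignment = assignment,
    alpha = alpha, seed = seed
  )
  structure(
    list(profiles = profiles, assignment = assignment, clusters = clusters,
         trajectories = traj),
    class = "radhub_stem"
  )
}

#' @export
print.radhub_stem <- function(x, ...) {
  cl <- x$clusters
  cat(
    "# Model-profile clustering: ", nrow(cl), " profiles, ",
    sum(cl$significant), " significant; ",
    sum(cl$n_genes[cl$significant]), " genes in significant clusters\n",
    sep = ""
  )
  invisible(x)
}
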