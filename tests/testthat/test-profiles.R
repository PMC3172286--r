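test_that("candidate enumeration matches the closed form and the smallest case", {
  for (c_max in 1:3) {
    for (n_tp in 3:5) {
      cand <- enumerate_candidate_profiles(n_tp, c_max)
      expect_equal(nrow(cand), (2 * c_max + 1)^(n_tp - 1) - 1)
      expect_true(all(vapply(cand$steps, function(s) s[1] == 0L, logical(1))))
      expect_true(all(vapply(
        cand$steps,
        function(s) max(abs(diff(s))) <= c_max, logical(1)
      )))
    }
  }
  expect_equal(nrow(enumerate_candidate_profiles(5, 1)), 80L)
  expect_equal(nrow(enumerate_candidate_profiles(5, 2)), 624L)

  smallest <- enumerate_candidate_profiles(2, 1)
  expect_equal(smallest$steps, list(c(0L, -1L), c(0L, 1L)))
})

test_that("profile selection is greedy max-min, deterministic, and complete at m = n", {
  cand <- enumerate_candidate_profiles(5, 2)
  all_sel <- select_model_profiles(cand, nrow(cand))
  expect_equal(all_sel$steps, cand$steps)
  expect_error(select_model_profiles(cand, nrow(cand) + 1), "exceeds")

  two <- select_model_profiles(enumerate_candidate_profiles(2, 1), 2)
  r <- cor(two$steps[[1]], two$steps[[2]])
  expect_equal(r, -1) # the two candidates are anti-correlated (d = 2)

  sel <- select_model_profiles(cand, 10)
  expect_equal(sel, select_model_profiles(cand, 10)) # deterministic

  # the greedy set is at least as spread out as random subsets
  sm <- do.call(rbind, sel$steps)
  d <- 1 - cor(t(sm))
  min_d_greedy <- min(d[upper.tri(d)])
  full <- do.call(rbind, cand$steps)
  dc <- 1 - cor(t(full))
  set.seed(0)
  min_d_random <- replicate(1000, {
    idx <- sample(nrow(cand), 10)
    sub <- dc[idx, idx]
    min(sub[upper.tri(sub)])
  })
  expect_true(all(min_d_greedy >= min_d_random))
})

test_that("log-ratio trajectories are anchored at zero and track planted profiles", {
  sim <- simulate_timecourse(sim_config(
    n_genes = 40L, n_de = 10L, n_modules = 1L,
    module_size = 5L, noise_sd = 0, seed = 2L
  ))
  traj <- logratio_trajectories(sim$expr)
  m <- as.matrix(traj[, -1])
  expect_true(all(m[, 1] == 0))

  # a flat gene gives the zero vector
  flat_gene <- setdiff(traj$gene, sim$truth$de_genes)[1]
  expect_true(all(m[traj$gene == flat_gene, ] == 0))

  # planted genes with no noise are exactly proportional to their steps
  pg <- sim$truth$profile_of_gene[1, ]
  steps <- sim$truth$profiles$steps[[match(pg$profile_id, sim$truth$profiles$profile_id)]]
  expect_equal(
    unname(m[traj$gene == pg$gene, ]), steps * 1.0,
    tolerance = 1e-10
  )
})

test_that("assignment picks the zero-distance profile, honours ties and inversions", {
  profiles <- select_model_profiles(enumerate_candidate_profiles(5, 1), 20)
  sm <- do.call(rbind, profiles$steps)

  traj <- tibble::tibble(gene = "x")
  traj <- dplyr::bind_cols(traj, tibble::as_tibble(
    matrix(as.numeric(sm[3, ]), 1, 5, dimnames = list(NULL, paste0("t", 0:4)))
  ))
  asg <- assign_profiles(traj, profiles)
  expect_equal(asg$profile_id, profiles$profile_id[3])
  expect_equal(asg$distance, 0, tolerance = 1e-12)

  # inverted trajectory must match the anti-correlated profile when present;
  # the full candidate set is closed under negation, so it always is
  cand <- enumerate_candidate_profiles(5, 1)
  all_profiles <- select_model_profiles(cand, nrow(cand))
  am <- do.call(rbind, all_profiles$steps)
  asg0 <- assign_profiles(traj, all_profiles)
  inv <- traj
  inv[1, -1] <- -inv[1, -1]
  asg_inv <- assign_profiles(inv, all_profiles)
  r_inv <- cor(
    as.numeric(inv[1, -1]),
    am[match(asg_inv$profile_id, all_profiles$profile_id), ]
  )
  expect_equal(r_inv, 1, tolerance = 1e-12)
  expect_false(asg_inv$profile_id == asg0$profile_id)

  # zero-variance trajectory lands in the unassigned bucket
  zero <- traj
  zero[1, -1] <- 0
  expect_true(is.na(assign_profiles(zero, profiles)$profile_id))
})

test_that("assignment is equivariant under gene relabelling", {
  sim <- simulate_timecourse(sim_config(n_genes = 60L, n_de = 20L, n_modules = 0L, seed = 5L))
  profiles <- select_model_profiles(enumerate_candidate_profiles(5, 2), 50)
  traj <- logratio_trajectories(sim$expr)
  asg <- assign_profiles(traj, profiles)
  perm <- sample(nrow(traj))
  asg_perm <- assign_profiles(traj[perm, ], profiles)
  expect_equal(asg_perm$gene, asg$gene[perm])
  expect_equal(asg_perm$profile_id, asg$profile_id[perm])
})

test_that("planted differential genes are assigned to their true profile", {
  sim <- simulate_timecourse(sim_config(
    n_genes = 500L, n_de = 100L, n_modules = 1L, module_size = 30L,
    noise_sd = 0.2, effect_log2 = 1, seed = 7L
  ))
  st <- cluster_timecourse(sim$expr, genes = sim$truth$de_genes)
  hit <- dplyr::inner_join(st$assignment, sim$truth$profile_of_gene,
    by = "gene", suffix = c("_called", "_true")
  )
  expect_gt(mean(hit$profile_id_called == hit$profile_id_true, na.rm = TRUE), 0.9)
})

test_that("profile significance: empty profiles get p = 1, planted clusters reach p < 0.001", {
  # all genes flat + tiny noise: most profiles hold nothing
  set.seed(9)
  log2m <- matrix(rnorm(30 * 20, 8, 0.05), 30, 20)
  ids <- as.vector(t(outer(c(0, 3, 7, 11, 21), 1:4, function(t, r) sprintf("t%d_r%d", t, r))))
  expr <- expr_from_log2(log2m, sample_ids = ids)
  st <- cluster_timecourse(expr)
  empty <- st$clusters[st$clusters$n_genes == 0, ]
  expect_true(all(empty$p_value == 1))

  # a dense planted cluster is detected at corrected p < 0.001 across seeds
  sig <- vapply(1:5, function(s) {
    sim <- simulate_timecourse(sim_config(
      n_genes = 300L, n_de = 100L, n_modules = 1L, module_size = 100L,
      noise_sd = 0.2, effect_log2 = 1, seed = s
    ))
    st <- cluster_timecourse(sim$expr, genes = differential_genes(call_differential(sim$expr)))
    true_profile <- sim$truth$module_profiles$profile_id[1]
    row <- st$clusters[st$clusters$profile_id == true_profile, ]
    row$significant && row$p_bonferroni < 0.001
  }, logical(1))
  expect_true(all(sig))
})
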