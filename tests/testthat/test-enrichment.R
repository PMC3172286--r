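make_sets <- function(...) {
  sets <- list(...)
  tibble::tibble(
    term_id = names(sets),
    term_name = names(sets),
    genes = unname(sets)
  )
}

test_that("Fisher enrichment matches the hypergeometric-sum oracle and its bounds", {
  background <- sprintf("g%03d", 1:100)
  study <- background[1:20]

  # term = whole background: k = n and p = 1 (no enrichment possible)
  full <- fisher_enrichment(study, make_sets(all = background), background)
  expect_equal(full$k, 20L)
  expect_equal(full$p_fisher, 1)

  # N=100, n=20, K=10, k=5
  term <- c(background[1:5], background[90:94])
  res <- fisher_enrichment(study, make_sets(t = term), background)
  expect_equal(res$k, 5L)
  expect_equal(res$p_fisher, brute_hyper_upper(5, 20, 10, 100), tolerance = 1e-14)
  expect_equal(
    res$p_fisher,
    fisher.test(
      matrix(c(5, 15, 5, 75), 2, byrow = TRUE),
      alternative = "greater"
    )$p.value,
    tolerance = 1e-12
  )

  # k=2 of the same shape: enrichment ratio (2/20)/(10/100) = 1
  term2 <- c(background[1:2], background[85:92])
  res2 <- fisher_enrichment(study, make_sets(t = term2), background)
  expect_equal(res2$enrichment_ratio, 1.0)

  expect_error(
    fisher_enrichment(c(study, "NOT_THERE"), make_sets(t = term), background),
    "NOT_THERE"
  )

  # terms with no background member are skipped
  res3 <- fisher_enrichment(study, make_sets(gone = c("x1", "x2"), t = term), background)
  expect_equal(res3$term_id, "t")
})

test_that("chi-squared p matches the hand formula and stats::chisq.test", {
  bal <- chi2_enrichment(25, 50, 50, 100)
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)

  # table (10, 10, 10, 70): chi2 = sum (O - E)^2 / E by hand
  o <- c(10, 10, 10, 70)
  e <- c(20 * 20, 20 * 80, 80 * 20, 80 * 80) / 100
  stat_hand <- sum((o - e)^2 / e)
  res <- chi2_enrichment(10, 20, 20, 100)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(
    res$p_value,
    suppressWarnings(chisq.test(matrix(o, 2, byrow = TRUE), correct = FALSE)$p.value),
    tolerance = 1e-12
  )
  expect_true(res$reliable)

  tiny <- chi2_enrichment(1, 2, 1, 200)
  expect_false(tiny$reliable)
  expect_error(chi2_enrichment(5, 20, 4, 100), "negative")
})

test_that("Fisher and chi-squared agree on ordering for well-filled tables", {
  set.seed(1)
  tables <- t(replicate(100, {
    repeat {
      N <- sample(200:600, 1)
      n <- sample(60:150, 1)
      K <- sample(60:150, 1)
      k <- rhyper(1, K, N - K, n)
      cells <- c(k, n - k, K - k, N - n - K + k)
      if (all(cells >= 10)) {
        return(c(k, n, K, N))
      }
    }
  }))
  p_fisher <- apply(tables, 1, function(x) {
    phyper(x[1] - 1, x[3], x[4] - x[3], x[2], lower.tail = FALSE)
  })
  p_chi <- chi2_enrichment(tables[, 1], tables[, 2], tables[, 3], tables[, 4])
  # one-sided Fisher vs two-sided chi2: compare on signed surprise
  enriched <- tables[, 1] > tables[, 2] * tables[, 3] / tables[, 4]
  signed_chi <- ifelse(enriched, p_chi$p_value / 2, 1 - p_chi$p_value / 2)
  expect_gt(cor(rank(p_fisher), rank(signed_chi)), 0.99)
})

test_that("EASE variant penalises k by one and reduces to Fisher when off", {
  background <- sprintf("g%03d", 1:100)
  study <- background[1:20]
  singleton <- make_sets(t = c(background[1], background[50:57]))
  eased <- pathway_enrichment(study, singleton, background, ease = TRUE)
  expect_equal(eased$p_fisher, 1) # k = 1 tested as 0
  plain <- pathway_enrichment(study, singleton, background, ease = FALSE)
  expect_equal(
    tibble::as_tibble(plain),
    tibble::as_tibble(fisher_enrichment(study, singleton, background))
  )
  david <- pathway_enrichment(study, singleton, background, david_style = TRUE)
  expect_equal(david$fdr_percent, david$q * 100)
})

test_that("q values do not depend on term order and more hits never raise p", {
  background <- sprintf("g%03d", 1:200)
  study <- background[1:40]
  set.seed(2)
  sets <- make_sets(
    a = sample(background, 30), b = sample(background, 50),
    c = sample(background, 10), d = sample(background, 80)
  )
  res <- fisher_enrichment(study, sets, background)
  res_rev <- fisher_enrichment(study, sets[4:1, ], background)
  expect_equal(
    res[order(res$term_id), c("term_id", "p_fisher", "q")],
    res_rev[order(res_rev$term_id), c("term_id", "p_fisher", "q")]
  )

  # monotonicity: adding a term member to the study can only lower that term's p
  for (i in 1:20) {
    set.seed(i)
    term <- sample(background, 40)
    study_i <- sample(background, 50)
    extra <- setdiff(term, study_i)
    if (length(extra) == 0) next
    p0 <- fisher_enrichment(study_i, make_sets(t = term), background)$p_fisher
    p1 <- fisher_enrichment(c(study_i, extra[1]), make_sets(t = term), background)$p_fisher
    expect_lte(p1, p0)
  }
})

test_that("the significant-term map is the transitive reduction over significant terms", {
  dag <- tibble::tibble(
    child = c("a", "b", "x"),
    parent = c("b", "c", "c")
  )
  # chain a -> b -> c, all significant: both direct edges, no shortcut
  map_all <- build_go_map(c("a", "b", "c"), dag)
  expect_setequal(
    paste(map_all$edges$child, map_all$edges$parent),
    c("a b", "b c")
  )
  # only a and c significant: the path contracts to one edge
  map_ac <- build_go_map(c("a", "c"), dag)
  expect_equal(map_ac$edges, tibble::tibble(child = "a", parent = "c"))

  # unrelated terms: edgeless node set
  map_none <- build_go_map(c("a", "x"), dag)
  expect_equal(nrow(map_none$edges), 0L)
  expect_setequal(map_none$nodes, c("a", "x"))

  cyclic <- tibble::tibble(child = c("a", "b"), parent = c("b", "a"))
  expect_error(build_go_map(c("a", "b"), cyclic), "cycle")
})

test_that("the planted enriched term ranks first on synthetic data", {
  first <- vapply(1:5, function(s) {
    sim <- simulate_timecourse(sim_config(
      n_genes = 500L, n_de = 100L,
      n_modules = 0L, seed = s
    ))
    ann <- simulate_annotations(sim, seed = s + 100L)
    de <- call_differential(sim$expr)
    study <- differential_genes(de)
    res <- fisher_enrichment(study, ann$sets, sim$expr$gene)
    res$term_id[1] == "TERM:PLANTED"
  }, logical(1))
  expect_true(all(first))
})
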