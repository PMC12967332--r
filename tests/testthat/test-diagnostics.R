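test_that("rank reversal is an involution that preserves the P multiset", {
  scores <- tibble::tibble(gene = c("g1", "g2", "g3"), p = c(0.1, 0.5, 0.9))
  rev1 <- reverse_ranks(scores)
  expect_equal(rev1$p[rev1$gene == "g1"], 0.9)
  expect_equal(rev1$p[rev1$gene == "g2"], 0.5)
  expect_equal(rev1$p[rev1$gene == "g3"], 0.1)
  expect_equal(dplyr::arrange(reverse_ranks(rev1), gene),
               dplyr::arrange(scores, gene))
  set.seed(9)
  big <- tibble::tibble(gene = sprintf("g%03d", 1:200), p = runif(200))
  revb <- reverse_ranks(big)
  expect_equal(sort(revb$p), sort(big$p))
  expect_equal(revb$gene, big$gene)  # row order preserved
  expect_equal(dplyr::arrange(reverse_ranks(revb), gene),
               dplyr::arrange(big, gene))
})

test_that("the reversal diagnostic separates suitable from dependent inputs", {
  sim <- simulate_fishnet_data(planted_modules = 1, seed = 23)
  expect_equal(rank_reversal_diagnostic(sim$scores, sim$modules), 0)
  # planted large-p module: reversal promotes its genes to the top
  simu <- simulate_fishnet_data(planted_modules = 1, signal = "large_p",
                                seed = 23)
  expect_gte(rank_reversal_diagnostic(simu$scores, simu$modules), 1)
  dep <- simulate_dependent_pair(seed = 23)
  expect_gte(rank_reversal_diagnostic(dep$scores, dep$modules), 1)
})

test_that("module P histograms bin correctly and conserve counts", {
  ones <- tibble::tibble(p_raw = rep(1, 7))
  h <- module_p_histogram(ones, n_bins = 10)
  expect_equal(h$count[10], 7)
  expect_equal(sum(h$count), 7)
  set.seed(5)
  mixed <- tibble::tibble(p_raw = runif(123))
  expect_equal(sum(module_p_histogram(mixed)$count), 123)
  edge <- tibble::tibble(p_raw = c(1e-12, 0.05, 0.051, 1))
  h2 <- module_p_histogram(edge, n_bins = 20)
  expect_equal(h2$count[1], 2)
  expect_equal(h2$count[2], 1)
  expect_equal(h2$count[20], 1)
})

test_that("replication evaluation applies the cohort's Bonferroni threshold", {
  sim <- simulate_fishnet_data(planted_modules = 1, seed = 42)
  res <- fishnet(sim$scores, sim$modules, sim$annotations, seed = 7,
                 trait = "t1")
  n_rep <- 500
  rep_genes <- c(res$gene_ids, sprintf("x%03d", seq_len(n_rep - length(res$gene_ids))))
  thr <- 0.05 / n_rep
  rep_scores <- tibble::tibble(
    gene = rep_genes,
    p = c(rep(0.8 * thr, 2),                       # first two replicate
          rep(0.5, length(res$gene_ids) - 2),
          runif(n_rep - length(res$gene_ids), 0.2, 1))
  )
  ev <- evaluate_replication(res, rep_scores)
  expect_equal(ev$summary$n_quads, length(res$gene_ids))
  expect_equal(ev$summary$n_replicated, 2L)
  expect_equal(ev$summary$bonferroni_alpha_replication, thr)
  expect_true(is.na(ev$summary$n_reproduced))  # no replication run given

  # self-comparison: reproduction rate 1
  ev2 <- evaluate_replication(res, sim$scores, res)
  expect_equal(ev2$summary$reproduction_rate, 1)

  # genes absent from the replication universe are not replicated, and listed
  rep_small <- rep_scores[-1, ]
  ev3 <- evaluate_replication(res, rep_small)
  expect_equal(ev3$summary$n_missing_from_replication, 1L)
  expect_equal(ev3$summary$n_replicated, 1L)
  expect_false(ev3$genes$replicated[is.na(ev3$genes$p_replication)][1])
})

test_that("empty discovery sets yield a zero-quad report with flagged rates", {
  tin <- tiny_inputs()
  empty <- fishnet(tin$scores, tin$modules, tin$annotations, seed = 5, M = 10,
                   alpha_module = 0)
  ev <- evaluate_replication(empty, tin$scores)
  expect_equal(ev$summary$n_quads, 0)
  expect_true(is.na(ev$summary$replication_rate))
})
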