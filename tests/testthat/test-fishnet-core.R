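test_that("empirical FDR and quantile follow the counting rules exactly", {
  expect_equal(compute_fdr(7, rep(0L, 10)), 0)
  expect_equal(compute_fdr(3, c(2L, 4L)), 1)      # mean 3 over 3
  expect_true(is.na(compute_fdr(0, c(1L, 2L))))
  expect_error(compute_fdr(-1, c(1L)), "non-negative")

  expect_equal(compute_quantile(4, c(0L, 1L, 2L, 3L)), 1)
  expect_equal(compute_quantile(0, c(0L, 0L, 0L)), 0)  # ties do not count
  expect_equal(compute_quantile(2, c(0L, 1L, 1L, 5L)), 0.75)
  expect_equal(compute_quantile(1, c(1L, 1L)), 0)
})

test_that("top-j sets are exact, nested and computed from observed p", {
  set.seed(3)
  scores <- tibble::tibble(gene = sprintf("g%02d", 1:30), p = runif(30))
  expect_setequal(top_genes(scores, 30), scores$gene)
  b5 <- top_genes(scores, 5); b12 <- top_genes(scores, 12)
  expect_length(b5, 5)
  expect_true(all(b5 %in% b12))
  expect_error(top_genes(scores, 31), "j must be")
  expect_error(top_genes(scores, 0), "j must be")
  ties <- tibble::tibble(gene = c("zz", "aa", "mm"), p = rep(0.2, 3))
  expect_equal(top_genes(ties, 2), c("aa", "mm"))
})

test_that("configuration validates ranges and warns outside tested bounds", {
  expect_error(fishnet_config(M = 0))
  expect_error(fishnet_config(j_step = 0))
  expect_warning(fishnet_config(fdr_threshold = 0.2), "fdr_threshold")
  expect_warning(fishnet_config(quantile_threshold = 0.5), "quantile_threshold")
  expect_silent(fishnet_config(fdr_threshold = 0.01, quantile_threshold = 0.8))
})

test_that("candidate genes require both module and term enrichment", {
  tin <- tiny_inputs()
  # module m1 (5 smallest p, covered by TA) drives the candidate set
  cand <- candidate_genes(tin$scores, tin$modules, tin$annotations,
                          fishnet_config(seed = 1))
  expect_setequal(cand, sprintf("g%02d", 1:5))

  # no significant module at alpha 0 -> empty set
  expect_length(candidate_genes(tin$scores, tin$modules, tin$annotations,
                                fishnet_config(alpha_module = 0, seed = 1)), 0)

  # criterion-2 gate: annotations that cannot be enriched exclude everything
  ann_far <- tibble::tibble(term = "TX", name = "unrelated",
                            gene = sprintf("g%02d", 20:30))
  expect_length(candidate_genes(tin$scores, tin$modules, ann_far,
                                fishnet_config(seed = 1)), 0)
})

test_that("permutation ensembles are deterministic given the seed", {
  tin <- tiny_inputs()
  cfg <- fishnet_config(M = 15, seed = 99, j_min = 2, j_step = 1)
  e1 <- permute_and_collect(tin$scores, tin$modules, tin$annotations, cfg)
  e2 <- permute_and_collect(tin$scores, tin$modules, tin$annotations, cfg)
  expect_identical(e1$observed, e2$observed)
  expect_identical(e1$permuted, e2$permuted)
  expect_identical(e1$pbonf, e2$pbonf)
  expect_length(e1$permuted, 15)
  expect_error(fishnet_config(M = 0, seed = 1))
})

test_that("rank-filter search accepts planted signal at the initial j", {
  sim <- simulate_fishnet_data(planted_modules = 1, seed = 101)
  res <- fishnet(sim$scores, sim$modules, sim$annotations, seed = 11)
  expect_true(res$accepted)
  expect_equal(res$j_final, 50)        # round(0.05 * 1000)
  expect_equal(nrow(res$trace), 1)     # first j suffices
  expect_gt(length(res$gene_ids), 0)
  expect_true(all(res$gene_ids %in% sim$truth))
  # the final set is A_0 restricted to the top-j genes
  expect_setequal(res$gene_ids,
                  intersect(res$a0, top_genes(sim$scores, res$j_final)))
})

test_that("an empty candidate set fails fast without permutation work", {
  tin <- tiny_inputs()
  res <- fishnet(tin$scores, tin$modules, tin$annotations, seed = 5, M = 10,
                 alpha_module = 0)
  expect_false(res$accepted)
  expect_length(res$gene_ids, 0)
  expect_equal(nrow(res$trace), 0)
})

test_that("simple mode is a superset of the permutation-tested result", {
  sim <- simulate_fishnet_data(planted_modules = 1, seed = 55)
  rsimple <- fishnet(sim$scores, sim$modules, sim$annotations, mode = "simple")
  rfull <- fishnet(sim$scores, sim$modules, sim$annotations, seed = 2)
  expect_true(all(rfull$gene_ids %in% rsimple$gene_ids))
  expect_true(is.na(rsimple$accepted))
  expect_true(is.na(rsimple$fdr))
})

test_that("module-filter search stops immediately with no module at 0.1", {
  # interleaved ranks: every module statistic sits mid-distribution
  scores <- tibble::tibble(gene = sprintf("g%02d", 1:12), p = (1:12) / 12)
  modules <- tibble::tibble(
    module = rep(c("m1", "m2", "m3"), times = 4),
    gene = scores$gene
  )
  ann <- tibble::tibble(term = "T1", name = "t", gene = scores$gene)
  res <- fishnet(scores, modules, ann,
                 mode = "module_filter", seed = 7, M = 10)
  expect_false(res$accepted)
  expect_length(res$gene_ids, 0)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$trace$c0[1], 0L)
})

test_that("both thresholding mechanisms recover the planted top-j genes", {
  sim <- simulate_fishnet_data(planted_modules = 1, seed = 77)
  r1 <- fishnet(sim$scores, sim$modules, sim$annotations, seed = 3)
  r2 <- fishnet(sim$scores, sim$modules, sim$annotations,
                mode = "module_filter", seed = 3)
  expect_true(r1$accepted)
  expect_true(r2$accepted)
  planted_top <- intersect(sim$truth, top_genes(sim$scores, r1$j_final))
  expect_true(all(planted_top %in% intersect(r1$gene_ids, r2$gene_ids)))
})

test_that("result accessors expose per-gene provenance and run summary", {
  sim <- simulate_fishnet_data(planted_modules = 1, seed = 42)
  res <- fishnet(sim$scores, sim$modules, sim$annotations, seed = 7,
                 trait = "trait-x")
  td <- tidy(res)
  expect_setequal(td$gene, res$gene_ids)
  expect_equal(td$rank, sort(td$rank))   # ordered by rank
  expect_true(all(td$modules != ""))
  expect_true(all(td$terms != ""))
  gl <- glance(res)
  expect_equal(gl$n_genes, length(res$gene_ids))
  expect_equal(gl$seed, 7L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res, type = "modules"), "ggplot")
})
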