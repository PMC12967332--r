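test_that("whole-universe module yields an input-independent p", {
  n <- 15
  s1 <- tibble::tibble(gene = sprintf("g%02d", 1:n), p = runif(n))
  s2 <- tibble::tibble(gene = sprintf("g%02d", 1:n), p = rbeta(n, 0.3, 2))
  m1 <- score_module(rank_transform(s1), s1$gene)
  m2 <- score_module(rank_transform(s2), s2$gene)
  expect_equal(m1$statistic, m2$statistic)  # conserved constant
  expect_equal(m1$p_raw, m2$p_raw)
  expect_equal(m1$p_raw, 1)                 # T is constant under permutation
})

test_that("small-universe module p matches the label-permutation oracle", {
  set.seed(31)
  n <- 20
  scores <- tibble::tibble(gene = sprintf("g%02d", 1:n), p = runif(n))
  rt <- rank_transform(scores)
  chi2v <- rt$chi2[order(rt$rank)]
  # module = the 5 genes with smallest p
  mod_genes <- rt$gene[rt$rank <= 5]
  sm <- score_module(rt, mod_genes)
  p_orc <- perm_oracle_module_p(chi2v, 1:5, B = 1e4, seed = 5)
  se <- sqrt(max(p_orc, 1 / 1e4) * (1 - min(p_orc, 1 - 1 / 1e4)) / 1e4)
  expect_lt(abs(sm$p_raw - p_orc), 3 * se + 0.01)
  # that module is the most extreme 5-subset: exactly 1 / choose(20, 5)
  expect_equal(sm$p_raw, 1 / choose(20, 5), tolerance = 1e-6)

  # a random mid-range module
  idx <- sample.int(n, 6)
  sm2 <- score_module(rt, rt$gene[rt$rank %in% idx])
  p_orc2 <- perm_oracle_module_p(chi2v, idx, B = 1e4, seed = 6)
  expect_lt(abs(sm2$p_raw - p_orc2),
            3 * sqrt(p_orc2 * (1 - p_orc2) / 1e4) + 0.01)
})

test_that("module p is rank-invariant under strictly monotone transforms", {
  set.seed(8)
  scores <- tibble::tibble(gene = sprintf("g%03d", 1:120), p = runif(120))
  modules <- tibble::tibble(module = rep(sprintf("m%d", 1:6), each = 8),
                            gene = sample(scores$gene, 48))
  e0 <- enrich_modules(scores, modules)
  for (f in list(function(p) p^2, function(p) pmin(1, p / 10))) {
    e1 <- enrich_modules(dplyr::mutate(scores, p = f(p)), modules)
    expect_equal(e1$p_raw, e0$p_raw)
  }
})

test_that("Bonferroni control uses the number of modules actually tested", {
  tin <- tiny_inputs()
  # add a too-small module and one disjoint from the universe
  modules <- dplyr::bind_rows(
    tin$modules,
    tibble::tibble(module = "tiny", gene = c("g01", "g02")),
    tibble::tibble(module = "alien", gene = c("zz1", "zz2", "zz3"))
  )
  enr <- enrich_modules(tin$scores, modules)
  expect_equal(attr(enr, "n_tested"), 4)
  expect_setequal(attr(enr, "skipped"), c("tiny", "alien"))
  expect_equal(enr$p_bonferroni, pmin(1, enr$p_raw * 4))

  enr0 <- enrich_modules(tin$scores, tin$modules, alpha_module = 0)
  expect_false(any(enr0$significant))

  expect_error(
    enrich_modules(tin$scores,
                   tibble::tibble(module = "alien", gene = c("x", "y", "z"))),
    "no testable modules"
  )
})

test_that("promoting a member gene to a better rank never hurts the module", {
  set.seed(13)
  n <- 40
  scores <- tibble::tibble(gene = sprintf("g%02d", 1:n),
                           p = sort(runif(n)))
  mod <- scores$gene[c(10, 20, 30, 35)]
  p0 <- score_module(rank_transform(scores), mod)$p_raw
  # move the worst member to rank 1
  scores2 <- scores
  scores2$p[35] <- scores2$p[1] / 2
  p1 <- score_module(rank_transform(scores2), mod)$p_raw
  expect_lte(p1, p0)
})

test_that("family-wise error of the module screen is controlled under the null", {
  n_rep <- 200
  hits <- vapply(seq_len(n_rep), function(r) {
    set.seed(1000 + r)
    scores <- tibble::tibble(gene = sprintf("g%03d", 1:300), p = runif(300))
    modules <- tibble::tibble(
      module = rep(sprintf("m%02d", 1:20), each = 10),
      gene = sample(scores$gene, 200)
    )
    any(enrich_modules(scores, modules)$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
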