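test_that("hypergeometric p matches exact enumeration", {
  # the worked instance: universe 20, term 5, module 6, overlap 4
  inst <- make_ora_instance(20, 5, 6, 4)
  res <- ora_module(inst$module, inst$ann, inst$universe, min_overlap = 1)
  expect_equal(res$k_overlap, 4)
  expect_equal(res$p_raw, 0.0139318885449, tolerance = 1e-10)
  expect_equal(res$p_raw, hyper_tail_oracle(4, 5, 6, 20), tolerance = 1e-12)

  # random instances across small universes
  set.seed(17)
  for (i in 1:25) {
    n_u <- sample(5:30, 1)
    m <- sample(2:(n_u - 1), 1)
    n_mod <- sample(2:(n_u - 1), 1)
    k <- sample(max(1, m + n_mod - n_u):min(m, n_mod), 1)
    inst <- make_ora_instance(n_u, m, n_mod, k)
    res <- ora_module(inst$module, inst$ann, inst$universe, min_overlap = 1)
    expect_equal(res$p_raw, hyper_tail_oracle(k, m, n_mod, n_u),
                 tolerance = 1e-12)
  }
})

test_that("overlap filtering and degenerate terms behave as specified", {
  inst <- make_ora_instance(20, 5, 6, 0)
  expect_equal(nrow(ora_module(inst$module, inst$ann, inst$universe,
                               min_overlap = 1)), 0)
  inst1 <- make_ora_instance(20, 5, 6, 1)
  expect_equal(nrow(ora_module(inst1$module, inst1$ann, inst1$universe,
                               min_overlap = 2)), 0)
  # term covering the whole universe: overlap is the whole module, p = 1
  universe <- sprintf("u%02d", 1:12)
  ann <- tibble::tibble(term = "ALL", name = "all", gene = universe)
  res <- ora_module(universe[1:5], ann, universe, min_overlap = 1)
  expect_equal(res$k_overlap, res$n_module)
  expect_equal(res$p_raw, 1)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  p10 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(bh_adjust(p10), bh_oracle(p10), tolerance = 1e-12)
  expect_equal(bh_adjust(p10),
               c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.1057142857,
                 0.216, 0.216, 0.216),
               tolerance = 1e-9)
  # permutation equivariance: adjusted value follows its p
  set.seed(2)
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # step-up rejection set is recovered by thresholding q
  alpha <- 0.05
  m <- length(p10)
  classic <- {
    s <- sort(p10)
    kmax <- suppressWarnings(max(which(s <= alpha * seq_len(m) / m)))
    if (is.finite(kmax)) p10 <= s[kmax] else rep(FALSE, m)
  }
  expect_equal(bh_adjust(p10) <= alpha, classic)
})

test_that("greedy redundancy reduction keeps the strongest, non-overlapping terms", {
  mk <- function(term, p, genes) {
    tibble::tibble(term = term, name = term, module = "m", k_overlap =
                     length(genes), m_term = 10L, n_module = 10L,
                   n_universe = 100L, p_raw = p, q_bh = p, enriched = TRUE,
                   overlap = list(genes))
  }
  dup <- dplyr::bind_rows(mk("A", 0.001, c("g1", "g2")),
                          mk("B", 0.01, c("g1", "g2")))
  kept <- reduce_redundancy(dup)
  expect_equal(kept$term, "A")

  disj <- dplyr::bind_rows(mk("A", 0.001, c("g1", "g2")),
                           mk("B", 0.01, c("g3", "g4")))
  expect_equal(nrow(reduce_redundancy(disj)), 2)

  mixed <- dplyr::bind_rows(mk("A", 0.001, c("g1", "g2", "g3")),
                            mk("B", 0.002, c("g1", "g2", "g4")),
                            mk("C", 0.003, c("g7", "g8")))
  expect_equal(reduce_redundancy(mixed, 1.0 + 1e-9)$term, c("A", "B", "C"))
  k2 <- reduce_redundancy(mixed, 0.5)
  expect_true("A" %in% k2$term)          # never drops the most significant
  expect_false("B" %in% k2$term)         # Jaccard 1/2 with A

  # tightening the threshold never grows the candidate union
  loose <- unique(unlist(reduce_redundancy(mixed, 0.9)$overlap))
  tight <- unique(unlist(reduce_redundancy(mixed, 0.3)$overlap))
  expect_true(all(tight %in% loose))
})
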