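# Independent oracles and tiny fixture builders shared across tests.

# Label-permutation oracle for the module statistic: shuffle which genes hold
# which rank B times and count shuffles whose k-subset sum reaches the
# observed sum. Independent of the package's DP / chi-squared code paths.
perm_oracle_module_p <- function(chi2v, member_idx, B = 1e4, seed = 1) {
  set.seed(seed)
  n <- length(chi2v)
  k <- length(member_idx)
  t0 <- sum(chi2v[member_idx])
  # each shuffle = first k positions of a random permutation of 1..n
  keys <- matrix(runif(B * n), nrow = n)
  picks <- apply(keys, 2, function(r) order(r)[seq_len(k)])
  sums <- colSums(matrix(chi2v[picks], nrow = k))
  mean(sums >= t0)
}

# Exact hypergeometric upper tail by explicit enumeration of the pmf.
hyper_tail_oracle <- function(k_overlap, m_term, n_module, n_universe) {
  lo <- max(0, m_term + n_module - n_universe)
  hi <- min(m_term, n_module)
  if (k_overlap > hi) return(0)
  xs <- max(lo, k_overlap):hi
  sum(choose(m_term, xs) * choose(n_universe - m_term, n_module - xs)) /
    choose(n_universe, n_module)
}

# Hand-style step-up BH: sort, p * m / i, running min from the largest rank.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(s)))
  adj[order(o)]
}

# Gene sets realizing given ORA counts (universe, term, module, overlap).
make_ora_instance <- function(n_u, m, n_mod, k) {
  universe <- sprintf("u%02d", seq_len(n_u))
  term_genes <- universe[seq_len(m)]
  module <- c(universe[seq_len(k)],                       # overlap
              universe[m + seq_len(n_mod - k)])           # non-term genes
  ann <- tibble::tibble(term = "T1", name = "t", gene = term_genes)
  list(universe = universe, module = module, ann = ann)
}

# Small deterministic inputs: 30 genes, 4 modules, 3 terms. Module m1 holds
# the lowest-P genes and is fully covered by term TA.
tiny_inputs <- function() {
  genes <- sprintf("g%02d", 1:30)
  p <- c(1e-6, 2e-6, 5e-6, 1e-5, 2e-5, seq(0.05, 0.99, length.out = 25))
  scores <- tibble::tibble(gene = genes, p = p)
  modules <- dplyr::bind_rows(
    tibble::tibble(module = "m1", gene = genes[1:5]),
    tibble::tibble(module = "m2", gene = genes[6:13]),
    tibble::tibble(module = "m3", gene = genes[14:22]),
    tibble::tibble(module = "m4", gene = genes[23:30])
  )
  annotations <- dplyr::bind_rows(
    tibble::tibble(term = "TA", name = "planted process", gene = genes[1:7]),
    tibble::tibble(term = "TB", name = "other process", gene = genes[8:20]),
    tibble::tibble(term = "TC", name = "third process", gene = genes[15:30])
  )
  list(scores = scores, modules = modules, annotations = annotations)
}
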