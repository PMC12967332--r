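#' Rank-based chi-squared transformation of gene P-values
#'
#' Monotonically transforms gene-level P-values into chi-squared scores using
#' only their ranks: the gene with rank `r` (1 = smallest P, ties broken by
#' ascending gene id) receives the empirical quantile `r / (N + 1)` and the
#' score `qchisq(r / (N + 1), df = 1, lower.tail = FALSE)`. Any strictly
#' monotone transform of the P-values therefore leaves the scores unchanged,
#' and the sum of scores over the universe depends only on `N`.
#'
#' @param scores A gene score table (see [as_gene_scores()]).
#' @return A tibble with columns `gene`, `p`, `rank`, `ptilde`, `chi2`,
#'   ordered by rank.
#' @export
rank_transform <- function(scores) {
  scores <- as_gene_scores(scores)
  n <- nrow(scores)
  ord <- order(scores$p, scores$gene)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$ptilde <- out$rank / (n + 1)
  out$chi2 <- qchisq(out$ptilde, df = 1, lower.tail = FALSE)
  out
}

# chi-squared score for each rank 1..n (rank 1 = largest score)
chi2_by_rank <- function(n) {
  qchisq(seq_len(n) / (n + 1), df = 1, lower.tail = FALSE)
}

# Exact null distribution of the sum of k distinct rank scores under uniform
# random rank assignment, for all k <= kmax, by dynamic programming on a
# discretized score grid. Returns tail/cdf lookups on integerized sums.
# Exact up to the grid resolution (~2^18 bins over the largest possible sum).
perm_null_dp <- function(chi2v, kmax, nbins = 262144L) {
  n <- length(chi2v)
  kmax <- as.integer(min(kmax, n))
  topsum <- sum(sort(chi2v, decreasing = TRUE)[seq_len(kmax)])
  delta <- topsum / nbins
  v <- as.integer(round(chi2v / delta))
  s <- sum(sort(v, decreasing = TRUE)[seq_len(kmax)])
  ways <- matrix(0, nrow = kmax + 1L, ncol = s + 1L)
  ways[1L, 1L] <- 1
  for (vi in v) {
    for (c in kmax:1L) {
      if (vi > 0L) {
        ways[c + 1L, (vi + 1L):(s + 1L)] <-
          ways[c + 1L, (vi + 1L):(s + 1L)] + ways[c, 1L:(s + 1L - vi)]
      } else {
        ways[c + 1L, ] <- ways[c + 1L, ] + ways[c, ]
      }
    }
  }
  upper <- ways
  cdf <- ways
  for (c in seq_len(kmax)) {
    upper[c + 1L, ] <- rev(cumsum(rev(ways[c + 1L, ])))
    cdf[c + 1L, ] <- cumsum(ways[c + 1L, ])
  }
  list(n = n, kmax = kmax, v = v, smax = s,
       upper = upper, cdf = cdf, total = choose(n, 0:kmax))
}

# P(sum of k distinct rank scores >= observed sum) under the permutation null.
# member_ranks are the ranks (1..n) held by the module's genes.
perm_null_tail <- function(dp, member_ranks) {
  n <- dp$n
  k <- length(member_ranks)
  if (k == n) return(1)
  if (k <= dp$kmax) {
    t0 <- sum(dp$v[member_ranks])
    return(dp$upper[k + 1L, t0 + 1L] / dp$total[k + 1L])
  }
  kc <- n - k
  stopifnot(kc <= dp$kmax)
  t0 <- sum(dp$v[-member_ranks])
  # sum over module >= T0  <=>  sum over complement <= total - T0
  dp$cdf[kc + 1L, t0 + 1L] / dp$total[kc + 1L]
}

# module p-value for a set of member ranks; dp is NULL for the chi-squared
# (large-N) branch
module_p <- function(member_ranks, chi2v, dp = NULL) {
  k <- length(member_ranks)
  stat <- sum(chi2v[member_ranks])
  p <- if (!is.null(dp)) perm_null_tail(dp, member_ranks)
       else pchisq(stat, df = k, lower.tail = FALSE)
  c(statistic = stat, p_raw = max(p, .Machine$double.xmin))
}

#' Score one module for enrichment of low P-values
#'
#' Sums the rank-based chi-squared scores of the module's genes (restricted to
#' the scored universe) and computes the upper-tail probability of that sum
#' under the null that ranks are assigned to genes at random. For universes
#' with at most `exact_n_max` genes the permutation null is computed exactly
#' by dynamic programming; for larger universes the sum is referred to a
#' chi-squared distribution with `k` degrees of freedom, to which the
#' permutation null converges.
#'
#' @param chi A rank-transformed score table from [rank_transform()].
#' @param module_genes Character vector of the module's gene ids.
#' @param exact_n_max Largest universe size for which the exact permutation
#'   null is used (default 100).
#' @return A one-row tibble with `k`, `statistic`, `p_raw`, and the member
#'   genes as a list-column, or `NULL` when no module gene is in the universe.
#' @export
score_module <- function(chi, module_genes, exact_n_max = 100) {
  stopifnot(all(c("gene", "rank", "chi2") %in% names(chi)))
  n <- nrow(chi)
  ranks <- chi$rank[chi$gene %in% module_genes]
  k <- length(ranks)
  if (k == 0) return(NULL)
  chi2v <- chi$chi2[order(chi$rank)]
  dp <- if (n <= exact_n_max && min(k, n - k) >= 1) {
    perm_null_dp(chi2v, min(k, n - k))
  } else NULL
  res <- if (k == n) {
    # whole-universe module: T is constant under permutation
    c(statistic = sum(chi2v), p_raw = 1)
  } else {
    module_p(ranks, chi2v, dp)
  }
  tibble(k = k, statistic = unname(res["statistic"]),
         p_raw = unname(res["p_raw"]),
         genes = list(sort(chi$gene[chi$rank %in% ranks])))
}

#' Module enrichment analysis
#'
#' Tests every module for enrichment of genes with low P-values using the
#' rank-based chi-squared statistic, and applies Bonferroni correction across
#' the modules actually tested. Modules with fewer than `min_module_size`
#' scored genes are skipped (reported via attribute `skipped`), and the
#' Bonferroni divisor is the number of modules tested after that filter.
#'
#' @param scores A gene score table.
#' @param modules A module collection (long tibble `module`, `gene`).
#' @param alpha_module Significance level on the Bonferroni-adjusted module
#'   P-value (default 0.05).
#' @param min_module_size Minimum number of scored member genes (default 3).
#' @param exact_n_max See [score_module()].
#' @return A tibble with one row per tested module: `module`, `k`,
#'   `statistic`, `p_raw`, `p_bonferroni`, `significant`, and member `genes`
#'   (list-column). Attributes: `n_tested`, `alpha_module`, `skipped`.
#' @export
enrich_modules <- function(scores, modules, alpha_module = 0.05,
                           min_module_size = 3, exact_n_max = 100) {
  chi <- rank_transform(scores)
  modules <- as_module_collection(modules)
  eng <- build_enrich_engine(chi, modules, min_module_size = min_module_size,
                             exact_n_max = exact_n_max)
  if (length(eng$module_ids) == 0) abort("no testable modules after size filtering")
  res <- engine_enrich(eng, eng$obs_rank)
  out <- tibble(
    module = eng$module_ids,
    k = eng$module_k,
    statistic = res$statistic,
    p_raw = res$p_raw,
    p_bonferroni = res$p_bonferroni,
    significant = res$p_bonferroni <= alpha_module,
    genes = eng$module_genes
  )
  out <- arrange(out, .data$p_raw, .data$module)
  attr(out, "n_tested") <- length(eng$module_ids)
  attr(out, "alpha_module") <- alpha_module
  attr(out, "skipped") <- eng$skipped
  out
}

# Precompute everything reusable across rank permutations: gene indexing,
# rank-score grid, module membership indices, and (small universes) the exact
# permutation-null tables shared by all modules and permutations.
build_enrich_engine <- function(chi, modules, min_module_size = 3,
                                exact_n_max = 100) {
  n <- nrow(chi)
  genes <- chi$gene
  chi2v <- chi$chi2[order(chi$rank)]
  obs_rank <- chi$rank
  names(obs_rank) <- genes
  sets <- set_list(modules, "module")
  idx <- lapply(sets, function(g) which(genes %in% g))
  k <- lengths(idx)
  keep <- k >= min_module_size & k >= 1
  skipped <- names(sets)[!keep]
  idx <- idx[keep]
  dp <- NULL
  if (n <= exact_n_max && length(idx) > 0) {
    kmax <- max(pmin(lengths(idx), n - lengths(idx)))
    if (kmax >= 1) dp <- perm_null_dp(chi2v, kmax)
  }
  list(
    n = n, genes = genes, chi2v = chi2v, obs_rank = unname(obs_rank),
    module_ids = names(idx), module_idx = idx,
    module_k = unname(lengths(idx)),
    module_genes = lapply(idx, function(i) sort(genes[i])),
    dp = dp, skipped = skipped
  )
}

# Module statistics and p-values for one rank assignment (a permutation of
# 1..n aligned with eng$genes).
engine_enrich <- function(eng, rank_of_gene) {
  chi2g <- eng$chi2v[rank_of_gene]
  stat <- vapply(eng$module_idx, function(i) sum(chi2g[i]), numeric(1))
  if (!is.null(eng$dp)) {
    p <- vapply(seq_along(eng$module_idx), function(m) {
      perm_null_tail(eng$dp, rank_of_gene[eng$module_idx[[m]]])
    }, numeric(1))
  } else {
    p <- pchisq(stat, df = eng$module_k, lower.tail = FALSE)
    p[eng$module_k == eng$n] <- 1  # constant statistic under permutation
  }
  p <- pmax(p, .Machine$double.xmin)
  m <- length(p)
  list(statistic = unname(stat), p_raw = unname(p),
       p_bonferroni = pmin(1, unname(p) * m), n_tested = m)
}
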