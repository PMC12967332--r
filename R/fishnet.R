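#' Configuration for the permutation-based FISHNET test
#'
#' Collects and validates every tunable parameter of the pipeline. The
#' permutation-test thresholds warn when set outside the ranges explored in
#' the method's sensitivity analysis (FDR 0.01-0.10, quantile 0.80-0.99).
#'
#' @param M Number of rank permutations (default 200).
#' @param fdr_threshold Empirical FDR acceptance threshold (default 0.05).
#' @param quantile_threshold Acceptance threshold on the quantile of the
#'   observed candidate count among permutation counts (default 0.99).
#' @param j_init_fraction Initial top-gene fraction; `j` starts at
#'   `round(j_init_fraction * N)` (default 0.05).
#' @param j_step Decrement of `j` per iteration (default 10).
#' @param j_min Smallest `j` attempted (default 10).
#' @param alpha_module Bonferroni-adjusted module significance level
#'   (default 0.05).
#' @param min_module_size Minimum scored module size (default 3).
#' @param ora_fdr_threshold BH threshold for term enrichment (default 0.05).
#' @param min_overlap Minimum module/term overlap tested (default 2).
#' @param jaccard_threshold Redundancy-reduction threshold (default 0.5).
#' @param universe ORA universe mode, `"annotated"` or `"all"`.
#' @param exact_n_max Largest universe for the exact module null
#'   (see [score_module()]).
#' @param module_p_schedule Decreasing Bonferroni-adjusted module P-value
#'   thresholds for the module-filter search (default geometric halving from
#'   0.1 down to ~1e-6).
#' @param mode One of `"rank_filter"`, `"module_filter"`, `"simple"`.
#' @param seed Integer seed; `NULL` draws one at run time (recorded in the
#'   result).
#' @return A list of class `fishnet_config`.
#' @export
fishnet_config <- function(M = 200, fdr_threshold = 0.05,
                           quantile_threshold = 0.99,
                           j_init_fraction = 0.05, j_step = 10, j_min = 10,
                           alpha_module = 0.05, min_module_size = 3,
                           ora_fdr_threshold = 0.05, min_overlap = 2,
                           jaccard_threshold = 0.5,
                           universe = c("annotated", "all"),
                           exact_n_max = 100,
                           module_p_schedule = 0.1 * 2^-(0:17),
                           mode = c("rank_filter", "module_filter", "simple"),
                           seed = NULL) {
  mode <- match.arg(mode)
  universe <- match.arg(universe)
  stopifnot(M >= 1, M == round(M), j_step >= 1, j_min >= 1,
            j_init_fraction > 0, j_init_fraction <= 1,
            fdr_threshold > 0, quantile_threshold > 0, quantile_threshold <= 1,
            alpha_module >= 0, min_module_size >= 1, min_overlap >= 1,
            all(diff(module_p_schedule) < 0), all(module_p_schedule > 0))
  if (fdr_threshold < 0.01 || fdr_threshold > 0.10) {
    warn("fdr_threshold outside the tested range [0.01, 0.10]")
  }
  if (quantile_threshold < 0.80 || quantile_threshold > 0.99) {
    warn("quantile_threshold outside the tested range [0.80, 0.99]")
  }
  structure(list(
    M = as.integer(M), fdr_threshold = fdr_threshold,
    quantile_threshold = quantile_threshold,
    j_init_fraction = j_init_fraction, j_step = as.integer(j_step),
    j_min = as.integer(j_min), alpha_module = alpha_module,
    min_module_size = as.integer(min_module_size),
    ora_fdr_threshold = ora_fdr_threshold,
    min_overlap = as.integer(min_overlap),
    jaccard_threshold = jaccard_threshold, universe = universe,
    exact_n_max = exact_n_max, module_p_schedule = module_p_schedule,
    mode = mode, seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "fishnet_config")
}

# round-half-away-from-zero for the initial j
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic per-permutation child seed, independent of execution order
child_seed <- function(seed, i) {
  s <- (as.numeric(seed) + 48271 * as.numeric(i)) %% (2^31 - 1)
  as.integer(s) + 1L
}

# Full pipeline engine: module-enrichment engine plus a lazy per-module ORA
# cache. Term enrichment depends only on a module's (fixed) member set, so it
# is computed once per module and shared across all permutations.
build_fishnet_engine <- function(scores, modules, annotations, config) {
  chi <- rank_transform(scores)
  modules <- as_module_collection(modules)
  annotations <- as_annotation_set(annotations)
  eng <- build_enrich_engine(chi, modules,
                             min_module_size = config$min_module_size,
                             exact_n_max = config$exact_n_max)
  if (length(eng$module_ids) == 0) abort("no testable modules after size filtering")
  eng$chi <- chi
  eng$annotations <- annotations
  eng$universe <- ora_universe(eng$genes, annotations, config$universe)
  eng$config <- config
  eng$ora_cache <- new.env(parent = emptyenv())
  eng
}

# kept enriched terms and candidate-gene contribution of one module (cached)
module_ora <- function(eng, m) {
  key <- as.character(m)
  hit <- get0(key, envir = eng$ora_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  cfg <- eng$config
  ora <- ora_module(eng$module_genes[[m]], eng$annotations, eng$universe,
                    min_overlap = cfg$min_overlap,
                    fdr_threshold = cfg$ora_fdr_threshold,
                    module_id = eng$module_ids[m])
  kept <- reduce_redundancy(ora[ora$enriched, , drop = FALSE],
                            cfg$jaccard_threshold)
  cand <- if (nrow(kept) > 0) sort(unique(unlist(kept$overlap))) else character(0)
  val <- list(ora = ora, kept = kept, cand = cand)
  assign(key, val, envir = eng$ora_cache)
  val
}

# candidate genes given the module Bonferroni-adjusted p-values of one run
candidates_at <- function(eng, p_bonferroni, threshold) {
  sig <- which(p_bonferroni <= threshold)
  if (length(sig) == 0) return(character(0))
  sort(unique(unlist(lapply(sig, function(m) module_ora(eng, m)$cand))))
}

#' Observed candidate FISHNET genes
#'
#' The set `A_0`: genes that lie in a module significantly enriched for low
#' P-values (Bonferroni-adjusted module P at most `alpha_module`) and are in
#' the overlap of a kept enriched annotation term of that module.
#'
#' @inheritParams fishnet
#' @param config A [fishnet_config()].
#' @return Sorted character vector of candidate gene ids (possibly empty).
#' @export
candidate_genes <- function(scores, modules, annotations,
                            config = fishnet_config()) {
  eng <- build_fishnet_engine(scores, modules, annotations, config)
  res <- engine_enrich(eng, eng$obs_rank)
  candidates_at(eng, res$p_bonferroni, config$alpha_module)
}

#' Candidate ensembles over rank permutations
#'
#' Computes the observed candidate set `A_0` and, for `i = 1..M`, the
#' candidate set `A_i` obtained after assigning the observed rank multiset to
#' genes uniformly at random. Permutation `i` is drawn under a child seed
#' derived from `config$seed` and `i`, so the ensemble is reproducible and
#' independent of execution order.
#'
#' @inheritParams candidate_genes
#' @return A list of class `fishnet_ensemble` with elements `observed`
#'   (`A_0`), `permuted` (list of `M` gene sets), `perm_sig_modules`
#'   (significant-module count per permutation), `obs_sig_modules`,
#'   `pbonf` (matrix `(M+1) x n_modules` of Bonferroni-adjusted module
#'   P-values, row 1 = observed), and the engine used.
#' @export
permute_and_collect <- function(scores, modules, annotations,
                                config = fishnet_config()) {
  if (is.null(config$seed)) abort("config$seed must be set for permutations")
  eng <- build_fishnet_engine(scores, modules, annotations, config)
  M <- config$M
  n_mod <- length(eng$module_ids)
  pbonf <- matrix(NA_real_, nrow = M + 1L, ncol = n_mod,
                  dimnames = list(NULL, eng$module_ids))
  res0 <- engine_enrich(eng, eng$obs_rank)
  pbonf[1L, ] <- res0$p_bonferroni
  observed <- candidates_at(eng, res0$p_bonferroni, config$alpha_module)
  permuted <- vector("list", M)
  sig_counts <- integer(M)
  for (i in seq_len(M)) {
    set.seed(child_seed(config$seed, i))
    rk <- sample.int(eng$n)
    res <- engine_enrich(eng, rk)
    pbonf[i + 1L, ] <- res$p_bonferroni
    sig_counts[i] <- sum(res$p_bonferroni <= config$alpha_module)
    permuted[[i]] <- candidates_at(eng, res$p_bonferroni, config$alpha_module)
  }
  structure(list(
    observed = observed, permuted = permuted,
    perm_sig_modules = sig_counts,
    obs_sig_modules = sum(res0$p_bonferroni <= config$alpha_module),
    pbonf = pbonf, engine = eng, config = config
  ), class = "fishnet_ensemble")
}

#' Top-j genes by observed P-value
#'
#' The set `B_j`: the `j` genes with the smallest observed P-values, ties
#' broken by ascending gene id. Always computed from the original
#' (unpermuted) P-values.
#'
#' @param scores A gene score table.
#' @param j Number of genes, `1 <= j <= N`.
#' @return Character vector of exactly `j` gene ids.
#' @export
top_genes <- function(scores, j) {
  chi <- rank_transform(scores)
  n <- nrow(chi)
  if (j < 1 || j > n) abort(paste0("j must be in 1..", n))
  chi$gene[chi$rank <= j]
}

#' Empirical FDR from permutation candidate counts
#'
#' `mean(perm_counts) / c0`; undefined (`NA`) when the observed count `c0`
#' is zero, in which case the acceptance criteria fail at this step.
#'
#' @param c0 Observed candidate count (non-negative integer).
#' @param perm_counts Integer vector of permutation candidate counts.
#' @return The empirical FDR, or `NA_real_` when `c0 == 0`.
#' @export
compute_fdr <- function(c0, perm_counts) {
  if (c0 < 0) abort("c0 must be non-negative")
  stopifnot(length(perm_counts) >= 1)
  if (c0 == 0) return(NA_real_)
  mean(perm_counts) / c0
}

#' Quantile of the observed count among permutation counts
#'
#' Fraction of permutation counts strictly less than `c0`; ties do not count
#' toward the quantile, so `c0 = 0` with all-zero permutation counts yields 0
#' (conservative).
#'
#' @inheritParams compute_fdr
#' @return A value in `[0, 1]`.
#' @export
compute_quantile <- function(c0, perm_counts) {
  stopifnot(length(perm_counts) >= 1)
  mean(perm_counts < c0)
}

#' Rank-filter search for the final FISHNET gene set
#'
#' Starting from `j = round(j_init_fraction * N)` and decreasing by `j_step`,
#' intersects each candidate set `A_i` with the observed top-j set `B_j` and
#' accepts the first `j` at which the empirical FDR is at most
#' `fdr_threshold` and the quantile of the observed count is at least
#' `quantile_threshold`. If `j` falls below `j_min`, the result is not
#' accepted and the gene set is empty; the per-j trace is always returned.
#'
#' @param ensemble A [permute_and_collect()] ensemble.
#' @param scores The gene score table the ensemble was built from.
#' @param config A [fishnet_config()]; defaults to the ensemble's.
#' @return A `fishnet_result` object.
#' @export
rank_filter_search <- function(ensemble, scores, config = NULL) {
  stopifnot(inherits(ensemble, "fishnet_ensemble"))
  config <- config %||% ensemble$config
  eng <- ensemble$engine
  chi <- rank_transform(scores)
  n <- nrow(chi)
  j0 <- max(config$j_min, round_half_away(config$j_init_fraction * n))
  trace <- list()
  accepted <- FALSE
  genes <- character(0)
  j_final <- NA_integer_
  c0_final <- 0L
  fdr_final <- NA_real_
  q_final <- NA_real_
  j <- j0
  if (length(ensemble$observed) > 0) {
    ranked_genes <- chi$gene
    a0 <- ensemble$observed
    while (j >= config$j_min) {
      bj <- ranked_genes[seq_len(j)]
      c0 <- length(intersect(a0, bj))
      pc <- vapply(ensemble$permuted,
                   function(a) length(intersect(a, bj)), integer(1))
      fdr <- compute_fdr(c0, pc)
      qq <- compute_quantile(c0, pc)
      trace[[length(trace) + 1L]] <- tibble(
        j = j, c0 = c0, mean_perm = mean(pc), fdr = fdr, quantile = qq
      )
      ok <- !is.na(fdr) && fdr <= config$fdr_threshold &&
        qq >= config$quantile_threshold
      if (ok) {
        accepted <- TRUE
        genes <- sort(intersect(a0, bj))
        j_final <- j; c0_final <- c0; fdr_final <- fdr; q_final <- qq
        break
      }
      j <- j - config$j_step
    }
  }
  new_fishnet_result(
    genes = genes, accepted = accepted, mode = "rank_filter",
    j_final = j_final, module_p_threshold_final = NA_real_,
    c0 = c0_final, fdr = fdr_final, quantile = q_final,
    trace = if (length(trace)) bind_rows(trace) else
      tibble(j = integer(0), c0 = integer(0), mean_perm = numeric(0),
             fdr = numeric(0), quantile = numeric(0)),
    ensemble = ensemble, eng = eng, config = config
  )
}

#' Module-filter search for the final FISHNET gene set
#'
#' Alternative thresholding: instead of shrinking the top-j gene filter, the
#' candidate sets are restricted to modules whose Bonferroni-adjusted
#' P-values pass an increasingly stringent threshold, starting at 0.1 and
#' following `config$module_p_schedule`. The first threshold at which the
#' FDR and quantile criteria are met is returned.
#'
#' @inheritParams candidate_genes
#' @return A `fishnet_result` object.
#' @export
module_filter_search <- function(scores, modules, annotations,
                                 config = fishnet_config(mode = "module_filter")) {
  ensemble <- permute_and_collect(scores, modules, annotations, config)
  eng <- ensemble$engine
  trace <- list()
  accepted <- FALSE
  genes <- character(0)
  t_final <- NA_real_
  c0_final <- 0L
  fdr_final <- NA_real_
  q_final <- NA_real_
  for (t in config$module_p_schedule) {
    a0 <- candidates_at(eng, ensemble$pbonf[1L, ], t)
    c0 <- length(a0)
    if (c0 == 0) {
      trace[[length(trace) + 1L]] <- tibble(
        threshold = t, c0 = 0L, mean_perm = NA_real_,
        fdr = NA_real_, quantile = NA_real_
      )
      break  # candidate sets only shrink as t decreases
    }
    pc <- vapply(seq_len(config$M), function(i) {
      length(candidates_at(eng, ensemble$pbonf[i + 1L, ], t))
    }, integer(1))
    fdr <- compute_fdr(c0, pc)
    qq <- compute_quantile(c0, pc)
    trace[[length(trace) + 1L]] <- tibble(
      threshold = t, c0 = c0, mean_perm = mean(pc), fdr = fdr, quantile = qq
    )
    if (!is.na(fdr) && fdr <= config$fdr_threshold &&
        qq >= config$quantile_threshold) {
      accepted <- TRUE
      genes <- a0
      t_final <- t; c0_final <- c0; fdr_final <- fdr; q_final <- qq
      break
    }
  }
  new_fishnet_result(
    genes = genes, accepted = accepted, mode = "module_filter",
    j_final = NA_integer_, module_p_threshold_final = t_final,
    c0 = c0_final, fdr = fdr_final, quantile = q_final,
    trace = if (length(trace)) bind_rows(trace) else
      tibble(threshold = numeric(0), c0 = integer(0), mean_perm = numeric(0),
             fdr = numeric(0), quantile = numeric(0)),
    ensemble = ensemble, eng = eng, config = config
  )
}

#' One-shot top-5% filter without permutation testing
#'
#' Applies the three candidate criteria once: the result is
#' `A_0` intersected with the top `round(j_init_fraction * N)` genes. No
#' permutations are run; the FDR and quantile fields are absent (`NA`).
#'
#' @inheritParams candidate_genes
#' @return A `fishnet_result` object with `accepted = NA`.
#' @export
simple_mode <- function(scores, modules, annotations,
                        config = fishnet_config(mode = "simple")) {
  eng <- build_fishnet_engine(scores, modules, annotations, config)
  res0 <- engine_enrich(eng, eng$obs_rank)
  a0 <- candidates_at(eng, res0$p_bonferroni, config$alpha_module)
  n <- eng$n
  j0 <- max(config$j_min, round_half_away(config$j_init_fraction * n))
  bj <- eng$genes[eng$obs_rank <= j0]
  genes <- sort(intersect(a0, bj))
  ensemble <- structure(list(
    observed = a0, permuted = list(), perm_sig_modules = integer(0),
    obs_sig_modules = sum(res0$p_bonferroni <= config$alpha_module),
    pbonf = matrix(res0$p_bonferroni, nrow = 1,
                   dimnames = list(NULL, eng$module_ids)),
    engine = eng, config = config
  ), class = "fishnet_ensemble")
  new_fishnet_result(
    genes = genes, accepted = NA, mode = "simple",
    j_final = j0, module_p_threshold_final = NA_real_,
    c0 = length(genes), fdr = NA_real_, quantile = NA_real_,
    trace = tibble(j = j0, c0 = length(genes), mean_perm = NA_real_,
                   fdr = NA_real_, quantile = NA_real_),
    ensemble = ensemble, eng = eng, config = config
  )
}

#' Run the full FISHNET pipeline
#'
#' Identifies "FISHNET genes": genes that (1) lie in a network module
#' significantly enriched for low P-values, (2) are annotated by a functional
#' term over-represented in that module, and (3) survive the selected
#' thresholding mechanism together with the permutation-based empirical FDR
#' and quantile test.
#'
#' @param scores Gene score table: a data frame with columns `gene` and `p`
#'   (see [as_gene_scores()]).
#' @param modules Module collection: long data frame `module`, `gene`.
#' @param annotations Annotation set: data frame `term`, (`name`,) `gene`.
#' @param mode Thresholding mechanism (see [fishnet_config()]).
#' @param trait Optional trait label recorded for replication evaluation.
#' @param seed Integer seed; drawn (and recorded) when `NULL`.
#' @param config Optional ready-made [fishnet_config()]; when supplied, the
#'   `mode`/`seed` arguments and `...` are ignored.
#' @param ... Further arguments passed to [fishnet_config()].
#' @return A `fishnet_result` object; see [tidy.fishnet_result()],
#'   [glance.fishnet_result()] and [autoplot.fishnet_result()].
#' @export
fishnet <- function(scores, modules, annotations,
                    mode = c("rank_filter", "module_filter", "simple"),
                    trait = "", seed = NULL, config = NULL, ...) {
  if (is.null(config)) {
    mode <- match.arg(mode)
    if (is.null(seed) && mode != "simple") {
      seed <- sample.int(.Machine$integer.max - 1L, 1L)
      inform(paste0("no seed supplied; drew seed ", seed))
    }
    config <- fishnet_config(mode = mode, seed = seed, ...)
  }
  result <- switch(config$mode,
    simple = simple_mode(scores, modules, annotations, config),
    module_filter = module_filter_search(scores, modules, annotations, config),
    rank_filter = {
      ens <- permute_and_collect(scores, modules, annotations, config)
      rank_filter_search(ens, scores, config)
    }
  )
  result$labels <- list(
    network = attr(as_module_collection(modules), "source_label") %||% "",
    algorithm = attr(as_module_collection(modules), "algorithm_label") %||% "",
    trait = trait
  )
  result
}
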