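#' Reverse the gene ranking
#'
#' Reassigns P-values so that the gene holding rank `r` (smallest P first,
#' ties by gene id) receives the P-value originally held by rank
#' `N + 1 - r`: the most significant genes become the least significant and
#' vice versa. The multiset of P-values is preserved exactly.
#'
#' @param scores A gene score table.
#' @return A gene score table with the rank assignment reversed, in the
#'   original row order.
#' @export
reverse_ranks <- function(scores) {
  scores <- as_gene_scores(scores)
  chi <- rank_transform(scores)
  n <- nrow(chi)
  rev_p <- chi$p[n + 1 - chi$rank]  # chi is ordered by rank
  newp <- rev_p[match(scores$gene, chi$gene)]
  tibble(gene = scores$gene, p = newp)
}

#' Rank-reversal suitability diagnostic
#'
#' Runs module enrichment on the rank-reversed scores and returns the number
#' of Bonferroni-significant modules. Under the model assumption that low
#' P-values are distributed independently of module structure, genes holding
#' the largest P-values should not cluster in modules, so the count should
#' be 0. A positive count flags dependency between the summary statistics
#' and the modules — typical when a co-expression network was built from the
#' same expression data that produced the P-values.
#'
#' @inheritParams enrich_modules
#' @return Integer count of significant modules after rank reversal.
#' @export
rank_reversal_diagnostic <- function(scores, modules, alpha_module = 0.05,
                                     min_module_size = 3, exact_n_max = 100) {
  enr <- enrich_modules(reverse_ranks(scores), modules,
                        alpha_module = alpha_module,
                        min_module_size = min_module_size,
                        exact_n_max = exact_n_max)
  sum(enr$significant)
}

#' Histogram of raw module P-values
#'
#' Equal-width bins on `[0, 1]` of the raw (unadjusted) module P-values from
#' [enrich_modules()]. Substantial excess mass in the top bin (P near 1) is
#' the U-shape signature of within-module P-value dependency.
#'
#' @param modules_tested Tibble of tested modules with a `p_raw` column.
#' @param n_bins Number of bins (default 20).
#' @return A tibble with `bin`, `lower`, `upper`, `mid`, `count`; counts sum
#'   to the number of tested modules.
#' @export
module_p_histogram <- function(modules_tested, n_bins = 20) {
  stopifnot(is.data.frame(modules_tested), "p_raw" %in% names(modules_tested),
            nrow(modules_tested) >= 1)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(modules_tested$p_raw, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx < 1] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin = seq_len(n_bins),
    lower = breaks[-(n_bins + 1)],
    upper = breaks[-1],
    mid = (breaks[-(n_bins + 1)] + breaks[-1]) / 2,
    count = counts
  )
}

#' Discovery/replication evaluation
#'
#' Evaluates the genes of a discovery-run result against a replication
#' cohort. A discovery hit is *replicated* if its P-value in the replication
#' scores passes that cohort's own Bonferroni threshold
#' (`alpha / N_replication`); it is *reproduced* if the same
#' (gene, network, algorithm, trait) quad is also identified in the
#' replication run. Genes absent from the replication universe count as not
#' replicated and are listed.
#'
#' @param discovery A `fishnet_result` from the discovery cohort (its
#'   `labels` identify the quad).
#' @param replication_scores Gene score table of the replication cohort.
#' @param replication_result Optional `fishnet_result` from the replication
#'   cohort; when absent, reproduction fields are `NA`.
#' @param alpha Family-wise level for the replication Bonferroni threshold
#'   (default 0.05).
#' @return A list of class `fishnet_eval` with `summary` (one-row tibble)
#'   and `genes` (per-gene detail).
#' @export
evaluate_replication <- function(discovery, replication_scores,
                                 replication_result = NULL, alpha = 0.05) {
  stopifnot(inherits(discovery, "fishnet_result"))
  replication_scores <- as_gene_scores(replication_scores)
  n_rep <- nrow(replication_scores)
  thr <- alpha / n_rep
  genes <- discovery$gene_ids
  n_quads <- length(genes)
  have_rep_run <- !is.null(replication_result)
  labels_match <- TRUE
  if (have_rep_run) {
    stopifnot(inherits(replication_result, "fishnet_result"))
    labels_match <- identical(discovery$labels, replication_result$labels)
    if (!labels_match) {
      warn("discovery and replication labels differ; no quad can be reproduced")
    }
  }
  p_rep <- replication_scores$p[match(genes, replication_scores$gene)]
  missing <- is.na(p_rep)
  replicated <- !missing & p_rep <= thr
  reproduced <- if (have_rep_run) {
    labels_match & genes %in% replication_result$gene_ids
  } else rep(NA, n_quads)
  detail <- tibble(
    gene = genes,
    p_replication = p_rep,
    in_replication_universe = !missing,
    replicated = replicated,
    reproduced = reproduced
  )
  summary <- tibble(
    n_quads = n_quads,
    n_replicated = if (n_quads > 0) sum(replicated) else 0L,
    n_reproduced = if (have_rep_run && n_quads > 0) sum(reproduced) else NA_integer_,
    replication_rate = if (n_quads > 0) sum(replicated) / n_quads else NA_real_,
    reproduction_rate = if (have_rep_run && n_quads > 0)
      sum(reproduced) / n_quads else NA_real_,
    bonferroni_alpha_replication = thr,
    n_missing_from_replication = sum(missing),
    network = discovery$labels$network,
    algorithm = discovery$labels$algorithm,
    trait = discovery$labels$trait
  )
  structure(list(summary = summary, genes = detail), class = "fishnet_eval")
}

#' @export
print.fishnet_eval <- function(x, ...) {
  s <- x$summary
  cat("FISHNET replication evaluation\n")
  cat("  quads: ", s$n_quads, "\n", sep = "")
  cat("  replicated: ", s$n_replicated,
      " (rate ", format(s$replication_rate), ", Bonferroni alpha ",
      format(s$bonferroni_alpha_replication), ")\n", sep = "")
  if (!is.na(s$n_reproduced)) {
    cat("  reproduced: ", s$n_reproduced,
        " (rate ", format(s$reproduction_rate), ")\n", sep = "")
  }
  if (s$n_missing_from_replication > 0) {
    cat("  missing from replication universe: ",
        s$n_missing_from_replication, "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.fishnet_eval <- function(x, ...) x$genes

#' @export
glance.fishnet_eval <- function(x, ...) x$summary
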