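# Assemble the user-facing result object from the search internals.
# Per-gene provenance (P, rank, harboring modules, annotating terms) is
# resolved here so the ensemble and engine need not be retained.
new_fishnet_result <- function(genes, accepted, mode, j_final,
                               module_p_threshold_final, c0, fdr, quantile,
                               trace, ensemble, eng, config) {
  res0 <- engine_enrich(eng, eng$obs_rank)
  modules_tbl <- tibble(
    module = eng$module_ids,
    k = eng$module_k,
    statistic = res0$statistic,
    p_raw = res0$p_raw,
    p_bonferroni = res0$p_bonferroni,
    significant = res0$p_bonferroni <= config$alpha_module,
    genes = eng$module_genes
  )
  modules_tbl <- arrange(modules_tbl, .data$p_raw, .data$module)
  sig_idx <- which(res0$p_bonferroni <= config$alpha_module)
  terms_tbl <- purrr::map_dfr(sig_idx, function(m) {
    mo <- module_ora(eng, m)
    if (nrow(mo$ora) == 0) return(NULL)
    out <- mo$ora
    out$kept <- out$term %in% mo$kept$term
    out
  })
  if (nrow(terms_tbl) == 0) {
    terms_tbl <- tibble(term = character(0), name = character(0),
                        module = character(0), k_overlap = integer(0),
                        m_term = integer(0), n_module = integer(0),
                        n_universe = integer(0), p_raw = numeric(0),
                        q_bh = numeric(0), enriched = logical(0),
                        overlap = list(), kept = logical(0))
  }
  chi <- eng$chi
  gene_rows <- chi[chi$gene %in% genes, c("gene", "p", "rank")]
  gene_rows$modules <- vapply(gene_rows$gene, function(g) {
    ms <- eng$module_ids[sig_idx][vapply(sig_idx, function(m)
      g %in% eng$module_genes[[m]], logical(1))]
    paste(sort(ms), collapse = ";")
  }, character(1))
  kept_terms <- terms_tbl[terms_tbl$kept & terms_tbl$enriched, , drop = FALSE]
  gene_rows$terms <- vapply(gene_rows$gene, function(g) {
    tt <- kept_terms$term[vapply(kept_terms$overlap, function(o) g %in% o,
                                 logical(1))]
    paste(sort(unique(tt)), collapse = ";")
  }, character(1))
  gene_rows <- arrange(gene_rows, .data$rank)
  structure(list(
    genes = gene_rows,
    gene_ids = sort(genes),
    accepted = accepted,
    mode = mode,
    j_final = j_final,
    module_p_threshold_final = module_p_threshold_final,
    c0 = c0, fdr = fdr, quantile = quantile,
    trace = trace,
    modules = modules_tbl,
    terms = terms_tbl,
    a0 = ensemble$observed,
    perm_sig_modules = ensemble$perm_sig_modules,
    obs_sig_modules = ensemble$obs_sig_modules,
    n_genes_universe = eng$n,
    config = config,
    labels = list(network = "", algorithm = "", trait = "")
  ), class = "fishnet_result")
}

#' @export
print.fishnet_result <- function(x, ...) {
  cat("FISHNET result (mode: ", x$mode, ")\n", sep = "")
  cat("  universe: ", x$n_genes_universe, " genes; ",
      nrow(x$modules), " modules tested, ",
      sum(x$modules$significant), " significant\n", sep = "")
  cat("  candidate genes |A_0|: ", length(x$a0), "\n", sep = "")
  if (x$mode == "rank_filter") {
    cat("  j_final: ", x$j_final, "\n", sep = "")
  } else if (x$mode == "module_filter") {
    cat("  module-P threshold: ", format(x$module_p_threshold_final), "\n",
        sep = "")
  }
  if (!is.na(x$accepted)) {
    cat("  FDR: ", format(x$fdr), "  quantile: ", format(x$quantile),
        "  accepted: ", x$accepted, "\n", sep = "")
  }
  cat("  FISHNET genes: ", length(x$gene_ids), "\n", sep = "")
  if (length(x$gene_ids) > 0) {
    cat("   ", paste(head(x$gene_ids, 10), collapse = ", "),
        if (length(x$gene_ids) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Per-gene view of a FISHNET result
#'
#' @param x A `fishnet_result`.
#' @param ... Unused.
#' @return A tibble with one row per FISHNET gene: `gene`, `p`, `rank`, the
#'   significant modules containing it and the kept enriched terms annotating
#'   it (semicolon-joined).
#' @export
tidy.fishnet_result <- function(x, ...) {
  as_tibble(x$genes)
}

#' One-row summary of a FISHNET run
#'
#' @param x A `fishnet_result`.
#' @param ... Unused.
#' @return A one-row tibble with run-level counts, the final threshold, the
#'   empirical FDR and quantile, and the acceptance flag.
#' @export
glance.fishnet_result <- function(x, ...) {
  tibble(
    n_genes = length(x$gene_ids),
    accepted = x$accepted,
    mode = x$mode,
    j_final = x$j_final,
    module_p_threshold = x$module_p_threshold_final,
    c0 = x$c0,
    fdr = x$fdr,
    quantile = x$quantile,
    n_candidates = length(x$a0),
    n_modules_tested = nrow(x$modules),
    n_modules_significant = sum(x$modules$significant),
    n_genes_universe = x$n_genes_universe,
    M = x$config$M,
    seed = x$config$seed %||% NA_integer_
  )
}

#' Plot a FISHNET result
#'
#' `type = "trace"` draws the empirical FDR and quantile along the search
#' path (per `j` or per module-P threshold); `type = "modules"` draws the
#' histogram of raw module P-values, the main input diagnostic (a U-shape
#' with excess mass near 1 flags dependency between the summary statistics
#' and the module structure).
#'
#' @param object A `fishnet_result`.
#' @param type `"trace"` or `"modules"`.
#' @param bins Number of histogram bins for `type = "modules"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fishnet_result <- function(object, type = c("trace", "modules"),
                                    bins = 20, ...) {
  type <- match.arg(type)
  if (type == "modules") {
    h <- module_p_histogram(object$modules, n_bins = bins)
    return(
      ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
        ggplot2::geom_col(width = 1 / bins, fill = "steelblue",
                          colour = "grey30") +
        ggplot2::labs(x = "raw module P-value", y = "modules",
                      title = "Module P-value distribution") +
        ggplot2::theme_minimal()
    )
  }
  tr <- object$trace
  xvar <- if (object$mode == "module_filter") "threshold" else "j"
  long <- tidyr::pivot_longer(
    tr[, c(xvar, "fdr", "quantile")],
    cols = c("fdr", "quantile"), names_to = "metric", values_to = "value"
  )
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data[[xvar]], y = .data$value,
                                    colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = if (xvar == "j") "top-j cutoff" else
      "module-P threshold", y = NULL,
      title = "Permutation test trace") +
    ggplot2::theme_minimal()
  if (xvar == "threshold") p <- p + ggplot2::scale_x_log10()
  p
}
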