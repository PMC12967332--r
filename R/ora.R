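#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted P-values, order-preserving and capped at 1.
#' A thin wrapper over [stats::p.adjust()] kept as the package's single
#' multiple-testing surface.
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Over-representation analysis for one module
#'
#' Tests every annotation term for over-representation among a module's
#' member genes with the hypergeometric upper tail: with a universe of
#' `n_universe` genes of which `m_term` carry the term, and `n_module` module
#' genes drawn, `p_raw = P(X >= k_overlap)`. Terms overlapping the module in
#' fewer than `min_overlap` genes are not tested. BH adjustment is applied
#' across the terms tested for this module.
#'
#' @param module_genes Character vector of module member gene ids, or a
#'   one-row tibble from [enrich_modules()] (its `genes` list-column is used).
#' @param annotations An annotation set (see [as_annotation_set()]).
#' @param universe Character vector of gene ids forming the reference
#'   universe. Module genes outside the universe are ignored.
#' @param min_overlap Minimum overlap for a term to be tested (default 2).
#' @param fdr_threshold BH threshold defining `enriched` (default 0.05).
#' @param module_id Optional module label carried into the output.
#' @return A tibble with one row per tested term: `term`, `name`, `module`,
#'   `k_overlap`, `m_term`, `n_module`, `n_universe`, `p_raw`, `q_bh`,
#'   `enriched`, and the overlap genes as list-column `overlap`.
#' @export
ora_module <- function(module_genes, annotations, universe,
                       min_overlap = 2, fdr_threshold = 0.05,
                       module_id = NA_character_) {
  if (is.data.frame(module_genes)) {
    stopifnot(nrow(module_genes) == 1, "genes" %in% names(module_genes))
    if ("module" %in% names(module_genes) && is.na(module_id)) {
      module_id <- module_genes$module
    }
    module_genes <- module_genes$genes[[1]]
  }
  annotations <- as_annotation_set(annotations)
  universe <- unique(universe)
  n_u <- length(universe)
  stopifnot(n_u > 0)
  members <- intersect(module_genes, universe)
  n_mod <- length(members)
  term_sets <- set_list(annotations, "term")
  term_names <- vapply(split(annotations$name, annotations$term),
                       `[`, character(1), 1)
  rows <- purrr::imap(term_sets, function(gset, id) {
    tg <- intersect(gset, universe)
    ov <- intersect(tg, members)
    if (length(ov) < min_overlap) return(NULL)
    m <- length(tg)
    k <- length(ov)
    p <- phyper(k - 1, m, n_u - m, n_mod, lower.tail = FALSE)
    tibble(term = id, name = unname(term_names[id]), module = module_id,
           k_overlap = k, m_term = m, n_module = n_mod, n_universe = n_u,
           p_raw = p, overlap = list(sort(ov)))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(tibble(term = character(0), name = character(0),
                  module = character(0), k_overlap = integer(0),
                  m_term = integer(0), n_module = integer(0),
                  n_universe = integer(0), p_raw = numeric(0),
                  q_bh = numeric(0), enriched = logical(0),
                  overlap = list()))
  }
  out <- bind_rows(rows)
  out$q_bh <- bh_adjust(out$p_raw)
  out$enriched <- out$q_bh <= fdr_threshold
  out <- out[, c("term", "name", "module", "k_overlap", "m_term", "n_module",
                 "n_universe", "p_raw", "q_bh", "enriched", "overlap")]
  arrange(out, .data$p_raw, .data$term)
}

#' Greedy redundancy reduction of enriched terms
#'
#' Deterministic replacement for exemplar-based redundancy filtering of
#' annotation terms with highly overlapping member genes: terms are visited
#' in order of ascending `p_raw` (ties by term id) and a term is kept only if
#' its overlap-gene Jaccard similarity with every previously kept term is
#' below `jaccard_threshold`. The most significant term is always kept.
#'
#' @param terms Enriched-term tibble from [ora_module()] (a single module).
#' @param jaccard_threshold Similarity above which a term is considered
#'   redundant (default 0.5). Values above 1 disable filtering.
#' @return The kept subset of `terms`, in ascending `p_raw` order.
#' @export
reduce_redundancy <- function(terms, jaccard_threshold = 0.5) {
  if (nrow(terms) == 0) return(terms)
  stopifnot("overlap" %in% names(terms))
  terms <- arrange(terms, .data$p_raw, .data$term)
  if (jaccard_threshold > 1) return(terms)
  kept <- integer(0)
  for (i in seq_len(nrow(terms))) {
    gi <- terms$overlap[[i]]
    redundant <- FALSE
    for (j in kept) {
      gj <- terms$overlap[[j]]
      jac <- length(intersect(gi, gj)) / length(union(gi, gj))
      if (jac >= jaccard_threshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  terms[kept, , drop = FALSE]
}

# ORA reference universe: scored genes restricted (by default) to those
# appearing in at least one annotation term.
ora_universe <- function(scored_genes, annotations, mode = c("annotated", "all")) {
  mode <- match.arg(mode)
  if (mode == "all") return(scored_genes)
  intersect(scored_genes, unique(annotations$gene))
}
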