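#' Simulate synthetic FISHNET inputs with optional planted signal
#'
#' Generates a gene universe, a random module partition, annotation terms,
#' and a P-value table. Background genes receive `p ~ Uniform(0, 1)`.
#' Planted modules receive P-values from a signal model: `"beta"` draws
#' `p ~ Beta(shape1, shape2)` (the standard low-P spike with `shape1 < 1`),
#' `"large_p"` draws `p ~ 1 - Beta(shape1, shape2)` (genes clustered near
#' P = 1), `"uniform"` leaves them at background. Each planted module gets
#' one aligned annotation term covering `annotation_alignment` of its genes
#' plus random decoy genes; further random terms provide background
#' annotation coverage. Fully deterministic given `seed`.
#'
#' @param n_genes Universe size (default 1000).
#' @param n_modules Number of modules (default 50).
#' @param module_size_range Inclusive size range for random modules
#'   (default 10-30).
#' @param n_terms Number of random annotation terms (default 30).
#' @param term_size_range Inclusive size range for random terms
#'   (default 10-50).
#' @param planted_modules Integer indices (in `1..n_modules`) of planted
#'   modules (default none).
#' @param planted_size Size of each planted module (default 20).
#' @param signal Signal model for planted genes.
#' @param signal_shape Length-2 Beta shape parameters (default `c(0.1, 1)`).
#' @param annotation_alignment Fraction of each planted module covered by
#'   its aligned term (default 1).
#' @param planted_term_decoys Random non-module genes added to each aligned
#'   term (default 10).
#' @param overlap_fraction Fraction of extra genes shared into each module
#'   from the rest of the universe (default 0: disjoint modules).
#' @param seed Integer seed (required).
#' @return A list with `scores`, `modules`, `annotations`, `truth` (character
#'   vector of all planted signal genes) and `truth_sets` (per planted
#'   module).
#' @export
simulate_fishnet_data <- function(n_genes = 1000, n_modules = 50,
                                  module_size_range = c(10, 30),
                                  n_terms = 30, term_size_range = c(10, 50),
                                  planted_modules = integer(0),
                                  planted_size = 20,
                                  signal = c("beta", "uniform", "large_p"),
                                  signal_shape = c(0.1, 1),
                                  annotation_alignment = 1,
                                  planted_term_decoys = 10,
                                  overlap_fraction = 0,
                                  seed) {
  signal <- match.arg(signal)
  stopifnot(!missing(seed), length(signal_shape) == 2,
            annotation_alignment >= 0, annotation_alignment <= 1,
            all(planted_modules %in% seq_len(n_modules)))
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  sizes <- sample(seq(module_size_range[1], module_size_range[2]),
                  n_modules, replace = TRUE)
  sizes[planted_modules] <- planted_size
  sizes <- fit_partition(sizes, n_genes, module_size_range[1],
                         fixed = planted_modules)
  pool <- sample(genes)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  module_ids <- sprintf("M%03d", seq_len(n_modules))
  sets <- lapply(seq_len(n_modules), function(m) pool[starts[m]:ends[m]])
  names(sets) <- module_ids
  if (overlap_fraction > 0) {
    sets <- lapply(sets, function(g) {
      extra <- max(0L, round(overlap_fraction * length(g)))
      unique(c(g, sample(setdiff(genes, g), extra)))
    })
  }
  modules <- bind_rows(purrr::imap(sets, function(g, id)
    tibble(module = id, gene = g)))
  modules <- as_module_collection(modules, source_label = "synthetic",
                                  algorithm_label = "synthetic")
  p <- runif(n_genes)
  names(p) <- genes
  truth_sets <- list()
  for (m in planted_modules) {
    pg <- sets[[module_ids[m]]]
    np <- length(pg)
    p[pg] <- switch(signal,
      beta = rbeta(np, signal_shape[1], signal_shape[2]),
      large_p = 1 - rbeta(np, signal_shape[1], signal_shape[2]),
      uniform = p[pg]
    )
    truth_sets[[module_ids[m]]] <- sort(pg)
  }
  p <- pmin(pmax(p, 1e-300), 1)
  scores <- tibble(gene = genes, p = unname(p[genes]))
  term_rows <- list()
  for (i in seq_len(n_terms)) {
    sz <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    term_rows[[i]] <- tibble(term = sprintf("T%03d", i),
                             name = sprintf("random process %d", i),
                             gene = sample(genes, sz))
  }
  for (m in planted_modules) {
    pg <- sets[[module_ids[m]]]
    ncov <- round(annotation_alignment * length(pg))
    covered <- if (ncov > 0) sample(pg, ncov) else character(0)
    decoys <- sample(setdiff(genes, pg), planted_term_decoys)
    term_rows[[length(term_rows) + 1L]] <- tibble(
      term = sprintf("TP%03d", m),
      name = sprintf("planted process %d", m),
      gene = c(covered, decoys)
    )
  }
  annotations <- as_annotation_set(bind_rows(term_rows))
  list(
    scores = scores, modules = modules, annotations = annotations,
    truth = sort(unique(unlist(truth_sets))), truth_sets = truth_sets
  )
}

#' Simulate inputs with within-module P-value dependency
#'
#' Emulates the pathology of running the method on a co-expression network
#' built from the same expression data that produced the P-values: each
#' module's genes draw their P-values around a shared module-level center,
#' `p ~ Beta(1 + kappa * c, 1 + kappa * (1 - c))`, with some modules centered
#' near 0 and some near 1. The result is within-module P correlation and a
#' U-shaped module P-value distribution; the rank-reversal diagnostic should
#' fire on such inputs. `kappa = 0` reduces every draw to `Uniform(0, 1)`,
#' i.e. the independent fixture.
#'
#' @inheritParams simulate_fishnet_data
#' @param kappa Concentration of gene P-values around their module center
#'   (default 50). 0 disables the dependency.
#' @param n_high,n_low Number of modules with centers near 1 / near 0
#'   (defaults 5 and 5); remaining modules get centers uniform on (0, 1).
#' @return A list with `scores`, `modules`, `annotations` and `centers`.
#' @export
simulate_dependent_pair <- function(n_genes = 1000, n_modules = 50,
                                    module_size_range = c(10, 30),
                                    n_terms = 30, term_size_range = c(10, 50),
                                    kappa = 50, n_high = 5, n_low = 5,
                                    seed) {
  stopifnot(!missing(seed), kappa >= 0, n_high + n_low <= n_modules)
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  sizes <- sample(seq(module_size_range[1], module_size_range[2]),
                  n_modules, replace = TRUE)
  sizes <- fit_partition(sizes, n_genes, module_size_range[1])
  pool <- sample(genes)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  module_ids <- sprintf("M%03d", seq_len(n_modules))
  sets <- lapply(seq_len(n_modules), function(m) pool[starts[m]:ends[m]])
  names(sets) <- module_ids
  modules <- bind_rows(purrr::imap(sets, function(g, id)
    tibble(module = id, gene = g)))
  modules <- as_module_collection(modules, source_label = "synthetic-dependent",
                                  algorithm_label = "synthetic")
  centers <- runif(n_modules)
  kind <- rep("mid", n_modules)
  if (n_high > 0) {
    hi <- seq_len(n_high)
    centers[hi] <- runif(n_high, 0.90, 0.98); kind[hi] <- "high"
  }
  if (n_low > 0) {
    lo <- n_high + seq_len(n_low)
    centers[lo] <- runif(n_low, 0.02, 0.10); kind[lo] <- "low"
  }
  p <- runif(n_genes)
  names(p) <- genes
  if (kappa > 0) {
    for (m in seq_len(n_modules)) {
      g <- sets[[module_ids[m]]]
      p[g] <- rbeta(length(g), 1 + kappa * centers[m],
                    1 + kappa * (1 - centers[m]))
    }
  }
  p <- pmin(pmax(p, 1e-300), 1)
  scores <- tibble(gene = genes, p = unname(p[genes]))
  term_rows <- lapply(seq_len(n_terms), function(i) {
    sz <- sample(seq(term_size_range[1], term_size_range[2]), 1)
    tibble(term = sprintf("T%03d", i),
           name = sprintf("random process %d", i),
           gene = sample(genes, sz))
  })
  annotations <- as_annotation_set(bind_rows(term_rows))
  list(
    scores = scores, modules = modules, annotations = annotations,
    centers = tibble(module = module_ids, center = centers, kind = kind)
  )
}

# Shrink the largest adjustable modules toward min_size until the partition
# fits the universe; hard error when even minimal sizes cannot fit.
fit_partition <- function(sizes, n_genes, min_size, fixed = integer(0)) {
  adjustable <- setdiff(seq_along(sizes), fixed)
  floor_total <- sum(sizes[fixed]) + min_size * length(adjustable)
  if (floor_total > n_genes) {
    abort("infeasible spec: module sizes exceed the gene universe")
  }
  while (sum(sizes) > n_genes) {
    cand <- adjustable[sizes[adjustable] > min_size]
    i <- cand[which.max(sizes[cand])]
    sizes[i] <- sizes[i] - 1L
  }
  sizes
}

#' Precision and recall against planted truth
#'
#' @param result A `fishnet_result` or a character vector of gene ids.
#' @param truth Character vector of planted signal genes.
#' @return A one-row tibble with `precision`, `recall`, `n_genes`,
#'   `n_truth`, and `empty_genes` flagging the convention that an empty gene
#'   set has precision 1.
#' @export
recovery_score <- function(result, truth) {
  genes <- if (inherits(result, "fishnet_result")) result$gene_ids
           else as.character(result)
  stopifnot(length(truth) > 0)
  hit <- length(intersect(genes, truth))
  tibble(
    precision = if (length(genes) == 0) 1 else hit / length(genes),
    recall = hit / length(truth),
    n_genes = length(genes),
    n_truth = length(truth),
    empty_genes = length(genes) == 0
  )
}
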