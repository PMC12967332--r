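#' Write the result tables of a FISHNET run
#'
#' Writes plain TSV tables (`fishnet_genes.tsv`, `significant_modules.tsv`,
#' `enriched_terms.tsv`, `trace.tsv`, `diagnostics.tsv`) and a key-value run
#' summary (`run_summary.yaml`) capturing every parameter and the seed.
#' Empty results produce header-only tables; re-running with the same inputs
#' and seed reproduces the files byte for byte.
#'
#' @param result A `fishnet_result`.
#' @param dir Output directory (created if needed).
#' @param reversal Optional integer from [rank_reversal_diagnostic()],
#'   reported in `diagnostics.tsv`.
#' @return `dir`, invisibly.
#' @export
write_fishnet_report <- function(result, dir, reversal = NULL) {
  stopifnot(inherits(result, "fishnet_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  join <- function(x) vapply(x, function(v) paste(sort(v), collapse = ";"),
                             character(1))
  readr::write_tsv(result$genes, file.path(dir, "fishnet_genes.tsv"),
                   progress = FALSE)
  mods <- result$modules
  mods$genes <- join(mods$genes)
  readr::write_tsv(mods, file.path(dir, "significant_modules.tsv"),
                   progress = FALSE)
  terms <- result$terms
  terms$overlap <- join(terms$overlap)
  readr::write_tsv(terms, file.path(dir, "enriched_terms.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$trace, file.path(dir, "trace.tsv"),
                   progress = FALSE)
  diag <- tibble(
    reversal_significant_modules =
      if (is.null(reversal)) NA_integer_ else as.integer(reversal),
    mode = result$mode,
    j_final = result$j_final,
    module_p_threshold = result$module_p_threshold_final,
    c0 = result$c0,
    fdr = result$fdr,
    quantile = result$quantile,
    accepted = result$accepted,
    n_candidates = length(result$a0),
    n_modules_significant = sum(result$modules$significant),
    n_fishnet_genes = length(result$gene_ids)
  )
  readr::write_tsv(diag, file.path(dir, "diagnostics.tsv"), progress = FALSE)
  cfg <- result$config
  summary <- c(
    unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    list(
      network = result$labels$network,
      algorithm = result$labels$algorithm,
      trait = result$labels$trait,
      n_genes_universe = result$n_genes_universe,
      tie_break = "ascending gene id"
    )
  )
  yaml::write_yaml(summary, file.path(dir, "run_summary.yaml"))
  invisible(dir)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records tool version, timestamps, input file digests, the seed and all
#' parameters, plus per-stage counts — enough to reproduce the run given the
#' input files.
#'
#' @param result A `fishnet_result`.
#' @param dir Output directory.
#' @param inputs Named list of input file paths (digested with MD5).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(result, dir, inputs = list()) {
  stopifnot(inherits(result, "fishnet_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digests <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  cfg <- unclass(result$config)
  manifest <- list(
    tool = "fishnetr",
    version = as.character(utils::packageVersion("fishnetr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = digests,
    parameters = cfg[!vapply(cfg, is.null, logical(1))],
    labels = result$labels,
    counts = list(
      n_genes_universe = result$n_genes_universe,
      n_modules_tested = nrow(result$modules),
      n_modules_significant = sum(result$modules$significant),
      n_enriched_terms = sum(result$terms$enriched),
      n_candidates = length(result$a0),
      n_fishnet_genes = length(result$gene_ids)
    ),
    trace = lapply(seq_len(nrow(result$trace)), function(i)
      as.list(result$trace[i, ]))
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Run the pipeline end to end from a configuration list
#'
#' Reads the inputs, runs module enrichment, term over-representation, the
#' selected thresholding search, and the rank-reversal diagnostic, then
#' writes the report tables and a run manifest to `config$out`.
#'
#' @param config A named list (e.g. from a YAML file): `scores`, `modules`,
#'   `annotations` (paths), optionally `dialect` (`"monet"`/`"gmt"`),
#'   `gene_column`, `p_column`, `mode`, `seed`, `out`, `network`,
#'   `algorithm`, `trait`, and any [fishnet_config()] parameter.
#' @return The `fishnet_result`, invisibly.
#' @export
run_fishnet_pipeline <- function(config) {
  req <- c("scores", "modules", "annotations", "out")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0) abort(paste0("missing config keys: ",
                                     paste(miss, collapse = ", ")))
  scores <- read_gene_scores(config$scores,
                             gene_column = config$gene_column %||% "gene",
                             p_column = config$p_column %||% "p")
  modules <- read_modules(config$modules,
                          dialect = config$dialect %||% "monet",
                          source_label = config$network %||% "",
                          algorithm_label = config$algorithm %||% "")
  annotations <- read_gmt(config$annotations)
  cfg_names <- setdiff(names(formals(fishnet_config)), "")
  cfg_args <- config[intersect(names(config), cfg_names)]
  cfg <- do.call(fishnet_config, cfg_args)
  if (is.null(cfg$seed) && cfg$mode != "simple") {
    cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
    inform(paste0("no seed supplied; drew seed ", cfg$seed))
  }
  result <- fishnet(scores, modules, annotations,
                    trait = config$trait %||% "", config = cfg)
  reversal <- rank_reversal_diagnostic(
    scores, modules, alpha_module = cfg$alpha_module,
    min_module_size = cfg$min_module_size, exact_n_max = cfg$exact_n_max)
  write_fishnet_report(result, config$out, reversal = reversal)
  write_run_manifest(result, config$out,
                     inputs = config[c("scores", "modules", "annotations")])
  if (isTRUE(result$accepted)) {
    inform(paste0("accepted: ", length(result$gene_ids), " FISHNET genes"))
  } else if (identical(result$accepted, FALSE)) {
    inform("significance criteria not met at any threshold; no genes returned")
  }
  invisible(result)
}
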