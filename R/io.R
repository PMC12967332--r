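#' Validate a gene score table
#'
#' Normalizes a data frame of gene-level association P-values into the
#' two-column form used throughout the package: `gene` (unique identifier)
#' and `p` (P-value in (0, 1]). Identifiers are matched as exact strings
#' after trimming surrounding whitespace; case is preserved.
#'
#' @param x A data frame with one row per gene.
#' @param gene,p Names of the identifier and P-value columns.
#' @return A tibble with columns `gene` and `p`.
#' @export
as_gene_scores <- function(x, gene = "gene", p = "p") {
  stopifnot(is.data.frame(x))
  if (!gene %in% names(x)) abort(paste0("column '", gene, "' not found"))
  if (!p %in% names(x)) abort(paste0("column '", p, "' not found"))
  out <- tibble(
    gene = trimws(as.character(x[[gene]])),
    p = suppressWarnings(as.numeric(x[[p]]))
  )
  bad <- which(is.na(out$p))
  if (length(bad) > 0) {
    warn(paste0("dropping ", length(bad), " row(s) with missing/non-numeric p"))
    out <- out[-bad, , drop = FALSE]
  }
  if (nrow(out) == 0) abort("empty gene score table")
  oob <- which(out$p <= 0 | out$p > 1)
  if (length(oob) > 0) {
    abort(paste0("p-value out of range (0, 1] at row ", oob[1],
                 " (gene '", out$gene[oob[1]], "')"))
  }
  if (any(out$gene == "")) abort("empty gene identifier")
  dup <- out$gene[duplicated(out$gene)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene identifier(s): ",
                 paste(unique(dup)[seq_len(min(5, length(unique(dup))))],
                       collapse = ", ")))
  }
  out
}

#' Read gene-level summary statistics
#'
#' Reads a delimited text file (TSV or CSV, chosen from the extension unless
#' `delim` is given) with a header row into a validated gene score table.
#'
#' @param path Path to the file.
#' @param gene_column,p_column Column names holding gene identifiers and
#'   P-values.
#' @param delim Field delimiter; `NULL` picks `","` for `.csv`, tab otherwise.
#' @return A tibble with columns `gene` and `p`.
#' @export
read_gene_scores <- function(path, gene_column = "gene", p_column = "p",
                             delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  as_gene_scores(raw, gene = gene_column, p = p_column)
}

#' Write a gene score table
#'
#' @param scores A gene score table (see [as_gene_scores()]).
#' @param path Output path; written as TSV with a header.
#' @export
write_gene_scores <- function(scores, path) {
  scores <- as_gene_scores(scores)
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}

#' Validate a module collection
#'
#' Normalizes a long data frame of (module, gene) memberships. A gene may
#' belong to several modules; duplicated (module, gene) pairs are collapsed.
#'
#' @param x A data frame with columns `module` and `gene`.
#' @param source_label,algorithm_label Optional provenance labels (network
#'   name and module-detection algorithm); stored as attributes.
#' @return A tibble with columns `module` and `gene`.
#' @export
as_module_collection <- function(x, source_label = NULL, algorithm_label = NULL) {
  stopifnot(is.data.frame(x), all(c("module", "gene") %in% names(x)))
  out <- distinct(tibble(
    module = trimws(as.character(x$module)),
    gene = trimws(as.character(x$gene))
  ))
  if (nrow(out) == 0) abort("empty module collection")
  if (any(out$module == "")) abort("empty module identifier")
  attr(out, "source_label") <- source_label %||% attr(x, "source_label") %||% ""
  attr(out, "algorithm_label") <- algorithm_label %||% attr(x, "algorithm_label") %||% ""
  out
}

#' Read network modules
#'
#' Supports two dialects. `monet`: one module per line, first tab-separated
#' field the module id, remaining fields gene ids; a second field that parses
#' as a number on a line with three or more fields is treated as a module
#' score and skipped. `gmt`: standard GMT (id, description, genes).
#'
#' @param path Path to the module file.
#' @param dialect `"monet"` or `"gmt"`.
#' @param source_label,algorithm_label Provenance labels recorded on the
#'   returned collection.
#' @return A tibble with columns `module` and `gene`.
#' @export
read_modules <- function(path, dialect = c("monet", "gmt"),
                         source_label = "", algorithm_label = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  ids <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    f <- f[f != ""]
    if (dialect == "gmt") {
      if (length(f) < 3) { warn(paste0("skipping short line ", i)); next }
      id <- f[1]; genes <- f[-(1:2)]
    } else {
      id <- f[1]; genes <- f[-1]
      # tolerate MONET's optional numeric module-score second field
      if (length(f) >= 3 && !is.na(suppressWarnings(as.numeric(f[2])))) {
        genes <- f[-(1:2)]
      }
      if (length(genes) == 0) { warn(paste0("skipping empty module line ", i)); next }
    }
    if (id %in% ids) abort(paste0("duplicate module id: ", id))
    ids <- c(ids, id)
    rows[[i]] <- tibble(module = id, gene = genes)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) abort("no modules parsed")
  as_module_collection(bind_rows(rows), source_label = source_label,
                       algorithm_label = algorithm_label)
}

#' Write network modules
#'
#' @param modules A module collection (see [as_module_collection()]).
#' @param path Output path.
#' @param dialect `"monet"` (id TAB genes...) or `"gmt"` (id TAB "na" TAB
#'   genes...).
#' @export
write_modules <- function(modules, path, dialect = c("monet", "gmt")) {
  dialect <- match.arg(dialect)
  modules <- as_module_collection(modules)
  sets <- split(modules$gene, modules$module)
  sets <- sets[order(names(sets))]
  lines <- vapply(names(sets), function(id) {
    g <- sort(sets[[id]])
    if (dialect == "gmt") paste(c(id, "na", g), collapse = "\t")
    else paste(c(id, g), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate an annotation set
#'
#' @param x A data frame with columns `term`, `gene` and optionally `name`
#'   (a human-readable term description).
#' @return A tibble with columns `term`, `name`, `gene`.
#' @export
as_annotation_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("term", "gene") %in% names(x)))
  nm <- if ("name" %in% names(x)) as.character(x$name) else as.character(x$term)
  out <- distinct(tibble(
    term = trimws(as.character(x$term)),
    name = nm,
    gene = trimws(as.character(x$gene))
  ))
  if (nrow(out) == 0) abort("empty annotation set")
  # one description per term
  nn <- tapply(out$name, out$term, function(v) length(unique(v)))
  if (any(nn > 1)) abort("conflicting descriptions for a term id")
  out
}

#' Read annotation gene sets in GMT format
#'
#' Standard GMT: `term_id TAB description TAB gene TAB gene ...` per line.
#' Lines with fewer than three fields are skipped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term`, `name`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  ids <- character(0)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    f <- f[f != ""]
    if (length(f) < 3) { warn(paste0("skipping short line ", i)); next }
    id <- f[1]
    if (id %in% ids) abort(paste0("duplicate term id: ", id))
    ids <- c(ids, id)
    rows[[i]] <- tibble(term = id, name = f[2], gene = f[-(1:2)])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) abort("no terms parsed")
  as_annotation_set(bind_rows(rows))
}

#' Write annotation gene sets in GMT format
#'
#' @param annotations An annotation set (see [as_annotation_set()]).
#' @param path Output path.
#' @export
write_gmt <- function(annotations, path) {
  annotations <- as_annotation_set(annotations)
  sets <- split(annotations$gene, annotations$term)
  sets <- sets[order(names(sets))]
  nms <- vapply(split(annotations$name, annotations$term), `[`, character(1), 1)
  lines <- vapply(names(sets), function(id) {
    paste(c(id, nms[[id]], sort(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# named list of gene-id character vectors, one per module/term
set_list <- function(x, id_col) {
  split(x$gene, x[[id_col]])
}
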