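#' Construct a gene set
#'
#' A gene set is a named list of gene symbols, typically a disease risk-gene
#' list (e.g. rare schizophrenia high-risk genes from exome sequencing, GWAS
#' fine-mapped genes, ASD or DD/ID genes). Symbols are kept as supplied;
#' matching against a promoter universe is a separate, explicit step so that
#' the matched/unmatched split can be reported, mirroring the usual
#' "total genes" vs "database-matched genes" accounting.
#'
#' @param name Set name (single string).
#' @param symbols Character vector of gene symbols. Duplicates are removed,
#'   keeping first occurrence.
#' @return Object of class `gene_set` with fields `name`, `symbols`,
#'   `matched` (universe gene ids; empty until [match_gene_set()] is called)
#'   and `unmatched`.
#' @export
gene_set <- function(name, symbols) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.character(symbols) || length(symbols) == 0L) {
    stop("'symbols' must be a non-empty character vector", call. = FALSE)
  }
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  if (length(symbols) == 0L) stop("gene set is empty", call. = FALSE)
  structure(list(name = name, symbols = symbols,
                 matched = character(0), unmatched = character(0)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d symbols", x$name, length(x$symbols)))
  if (length(x$matched) || length(x$unmatched)) {
    cat(sprintf(" (%d matched, %d unmatched)", length(x$matched), length(x$unmatched)))
  }
  cat("\n")
  invisible(x)
}

#' Read a gene set from a plain-text symbol list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored;
#' surrounding whitespace is stripped; duplicates are dropped keeping first
#' occurrence.
#'
#' @param path Path to the text file.
#' @param name Set name; defaults to the file name without extension.
#' @return A [gene_set].
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("gene set file not found: %s", path), call. = FALSE)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop(sprintf("gene set file '%s' contains no symbols", path), call. = FALSE)
  }
  gene_set(name, lines)
}

#' Write a gene set to a plain-text symbol list
#' @param gs A [gene_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  writeLines(gs$symbols, path)
  invisible(path)
}

#' Match a gene set against a promoter universe
#'
#' Matching is exact after case-folding: a symbol matches a universe gene id
#' when their upper-case forms are equal. No alias or identifier-database
#' resolution is attempted. Symbols that case-fold to the same form are
#' collapsed (first occurrence kept). The operation is idempotent.
#'
#' @param gs A [gene_set].
#' @param universe A [promoter_universe], a per-gene summary `data.frame`
#'   with a `gene_id` column (count-level workflows), or a character vector
#'   of gene ids.
#' @return The gene set with `matched` filled with the universe's spelling of
#'   each matched symbol and `unmatched` with the remaining symbols as
#'   supplied. `matched` and `unmatched` partition the (case-folded,
#'   de-duplicated) symbols.
#' @export
match_gene_set <- function(gs, universe) {
  stopifnot(inherits(gs, "gene_set"))
  ids <- if (inherits(universe, "promoter_universe")) {
    gene_ids(universe)
  } else if (is.data.frame(universe) && "gene_id" %in% names(universe)) {
    universe$gene_id
  } else if (is.character(universe)) {
    universe
  } else {
    stop("'universe' must be a promoter_universe, a summary data.frame or gene ids",
         call. = FALSE)
  }
  match_gene_set_ids(gs, ids)
}

# matching against a plain id vector; used both for sequence universes and
# for count-level summary tables
match_gene_set_ids <- function(gs, ids) {
  stopifnot(inherits(gs, "gene_set"))
  if (length(ids) == 0L) stop("universe is empty", call. = FALSE)
  folded <- toupper(gs$symbols)
  keep <- !duplicated(folded)
  symbols <- gs$symbols[keep]
  folded <- folded[keep]
  idx <- match(folded, toupper(ids))
  gs$matched <- ids[idx[!is.na(idx)]]
  gs$unmatched <- symbols[is.na(idx)]
  gs
}
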