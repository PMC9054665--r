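#' Upper-tail cumulative hypergeometric probability
#'
#' Probability of observing `k` or more motif-containing genes in a sample of
#' size `n` drawn without replacement from a universe of `N` genes of which
#' `K` contain the motif: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This
#' is the over-representation p-value used for gene-set enrichment.
#' `P(X >= 0)` is exactly 1. Computed through the exact hypergeometric
#' survival function.
#'
#' @param N Universe size.
#' @param K Motif-containing genes in the universe.
#' @param n Sample (matched gene set) size.
#' @param k Motif-containing genes in the sample.
#' @return The upper-tail probability, a number in (0, 1].
#' @examples
#' hypergeom_upper(16455, 7653, 28, 19)  # ~0.0186
#' @export
hypergeom_upper <- function(N, K, n, k) {
  N <- check_int(N, "N"); K <- check_int(K, "K")
  n <- check_int(n, "n"); k <- check_int(k, "k")
  if (N < 0L) stop("'N' must be >= 0", call. = FALSE)
  if (K < 0L || K > N) stop("'K' must satisfy 0 <= K <= N", call. = FALSE)
  if (n < 0L || n > N) stop("'n' must satisfy 0 <= n <= N", call. = FALSE)
  if (k < 0L || k > min(n, K)) {
    stop("'k' must satisfy 0 <= k <= min(n, K)", call. = FALSE)
  }
  if (k == 0L) return(1)
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment controlling the false discovery rate: sort the
#' p-values ascending, set `adj_i = min_{j >= i} (p_j * m / j)` capped at 1,
#' and return in input order. The family is the caller's choice; within this
#' package each results table (one motif, all gene sets) forms one family.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) == 0L) {
    stop("'pvals' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation of motif-containing genes in one gene set
#'
#' Builds the 2x2 margin (universe size `N`, motif-containing genes `K`,
#' matched set size `n`, motif-containing set members `k`) from a per-gene
#' summary table and a matched gene set, and tests over-representation with
#' the upper-tail cumulative hypergeometric probability.
#'
#' @param summaries Per-gene summary `data.frame` for the whole universe, as
#'   produced by [summarize_genes()] (columns `gene_id`, `has_motif` used).
#' @param gs A matched [gene_set] (run [match_gene_set()] first; the matched
#'   ids must be present in `summaries`).
#' @return One-row `data.frame` of class `enrichment_result`: `set`,
#'   `total_genes` (symbols as supplied), `matched_genes` (n),
#'   `containing_genes` (k), `percent` (100 k/n), `p_hyper`, and `p_adj`
#'   (NA until family correction, see [enrich_gene_sets()]).
#' @export
enrich_gene_set <- function(summaries, gs) {
  stopifnot(is.data.frame(summaries),
            all(c("gene_id", "has_motif") %in% names(summaries)),
            inherits(gs, "gene_set"))
  if (length(gs$matched) == 0L) {
    stop(sprintf("gene set '%s' has no matched genes (run match_gene_set first)",
                 gs$name), call. = FALSE)
  }
  idx <- match(gs$matched, summaries$gene_id)
  if (any(is.na(idx))) {
    stop(sprintf("gene set '%s': matched ids absent from the universe summary",
                 gs$name), call. = FALSE)
  }
  N <- nrow(summaries)
  K <- sum(summaries$has_motif)
  n <- length(gs$matched)
  k <- sum(summaries$has_motif[idx])
  out <- data.frame(set = gs$name,
                    total_genes = length(gs$symbols),
                    matched_genes = n,
                    containing_genes = k,
                    percent = 100 * k / n,
                    p_hyper = hypergeom_upper(N, K, n, k),
                    p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "universe") <- c(N = N, K = K)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment table for a family of gene sets
#'
#' Runs [enrich_gene_set()] for every set and applies Benjamini-Hochberg
#' correction across the family (one motif, all sets — the grouping used for
#' each results table).
#'
#' @param summaries Per-gene summary for the universe ([summarize_genes()]).
#' @param sets List of matched [gene_set] objects.
#' @return `data.frame` of class `enrichment_table`, one row per set, columns
#'   `set`, `total_genes`, `matched_genes`, `containing_genes`, `percent`,
#'   `p_hyper`, `p_adj`; attribute `universe` holds `c(N, K)`.
#' @export
enrich_gene_sets <- function(summaries, sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  rows <- lapply(sets, function(gs) enrich_gene_set(summaries, gs))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$p_adj <- bh_adjust(out$p_hyper)
  rownames(out) <- NULL
  attr(out, "universe") <- attr(rows[[1L]], "universe")
  attr(out, "motif") <- attr(summaries, "motif")
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, digits = 4, ...) {
  u <- attr(x, "universe")
  m <- attr(x, "motif")
  cat(sprintf("Motif-gene over-representation%s: universe N = %d, containing K = %d (%.2f%%)\n",
              if (!is.null(m)) sprintf(" [%s]", m) else "", u["N"], u["K"],
              100 * u["K"] / u["N"]))
  df <- as.data.frame(x)
  df$percent <- round(df$percent, 2)
  df$p_hyper <- signif(df$p_hyper, digits)
  df$p_adj <- signif(df$p_adj, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.enrichment_table <- function(object, alpha = 0.05, ...) {
  sig <- object$set[object$p_adj <= alpha]
  cat(sprintf("%d of %d gene sets significant at FDR %.2g%s\n",
              length(sig), nrow(object), alpha,
              if (length(sig)) paste0(": ", paste(sig, collapse = ", ")) else ""))
  invisible(object)
}
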