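#' Define an exact DNA motif
#'
#' Motifs are exact DNA strings (no ambiguity codes, no position-weight
#' matrices), scanned by default on both strands: a minus-strand occurrence is
#' an exact plus-strand match of the reverse complement, reported at the
#' offset of its leftmost plus-strand base.
#'
#' @param name Motif name (e.g. "GC-box").
#' @param pattern DNA string over A/C/G/T, length 4 to 12.
#' @param both_strands Scan both strands? Default `TRUE`.
#' @return Object of class `motif_spec` with fields `name`, `pattern`,
#'   `revcomp` and `both_strands`.
#' @examples
#' motif_spec("GC-box", "GGGCGG")
#' @export
motif_spec <- function(name, pattern, both_strands = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  if (grepl("[^ACGT]", pattern)) {
    stop("motif pattern must contain only A/C/G/T", call. = FALSE)
  }
  if (nchar(pattern) < 4L || nchar(pattern) > 12L) {
    stop("motif pattern length must be between 4 and 12", call. = FALSE)
  }
  stopifnot(is.logical(both_strands), length(both_strands) == 1L)
  structure(list(name = name, pattern = pattern,
                 revcomp = reverse_complement(pattern),
                 both_strands = both_strands),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("Motif '%s': %s (revcomp %s), %s\n", x$name, x$pattern, x$revcomp,
              if (x$both_strands) "both strands" else "plus strand only"))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x DNA string over A/C/G/T/N.
#' @return The reverse complement, as a character string.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' The canonical Sp1/Sp4-family motifs
#'
#' The GC-box (GGGCGG) is the high-affinity binding site of Sp1/Sp4
#' transcription factors in the proximal promoter; the GA-box (GGGAGG) is the
#' ancestral lower-affinity variant; CCCCTCC is the MAZ binding motif and
#' ACGCCC the KLF13 binding motif, used as comparison and negative-control
#' motifs respectively.
#'
#' @return Named list of [motif_spec] objects: `gc_box`, `ga_box`, `maz`,
#'   `klf13`.
#' @export
standard_motifs <- function() {
  list(gc_box = motif_spec("GC-box", "GGGCGG"),
       ga_box = motif_spec("GA-box", "GGGAGG"),
       maz    = motif_spec("MAZ",    "CCCCTCC"),
       klf13  = motif_spec("KLF13",  "ACGCCC"))
}

#' Scan a motif across promoter sequences
#'
#' Reports every exact, possibly overlapping occurrence of the motif. Plus
#' strand: positions where the sequence equals the pattern. Minus strand (if
#' `both_strands`): positions where the sequence equals the reverse complement
#' of the pattern. `start` is the TSS-relative offset of the occurrence's
#' leftmost plus-strand base. Positions containing N never match.
#'
#' @param universe A [promoter_universe] (all genes are scanned).
#' @param motif A [motif_spec].
#' @return `data.frame` with columns `gene_id`, `motif`, `strand` ("+"/"-"),
#'   `start` (integer TSS-relative offset), sorted by gene (storage order),
#'   then `start`, then strand. Zero rows when nothing matches (including a
#'   motif longer than the sequences).
#' @export
scan_motif <- function(universe, motif) {
  stopifnot(inherits(universe, "promoter_universe"), inherits(motif, "motif_spec"))
  lo <- universe$region[1L]
  ids <- gene_ids(universe)
  one_strand <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, universe$sequences, fixed = TRUE)
    starts <- Biostrings::startIndex(m)
    n <- lengths(starts)
    if (sum(n) == 0L) {
      return(data.frame(gene_id = character(0), motif = character(0),
                        strand = character(0), start = integer(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(gene_id = rep(ids, n),
               motif = motif$name,
               strand = strand,
               start = unlist(starts, use.names = FALSE) + lo - 1L,
               stringsAsFactors = FALSE)
  }
  occ <- one_strand(motif$pattern, "+")
  if (motif$both_strands && motif$revcomp != motif$pattern) {
    occ <- rbind(occ, one_strand(motif$revcomp, "-"))
  } else if (motif$both_strands && motif$revcomp == motif$pattern) {
    # palindromic motif: every plus-strand site is also a minus-strand site
    minus <- occ
    minus$strand <- "-"
    occ <- rbind(occ, minus)
  }
  occ <- occ[order(match(occ$gene_id, ids), occ$start, occ$strand), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Per-gene motif count, presence flag and GC content in a window
#'
#' An occurrence belongs to the window when its start offset (leftmost
#' plus-strand base) lies in `[window[1], window[2]]`, even if the motif
#' extends past the right edge. GC content is the fraction of G or C bases in
#' the window on the plus strand; since every G pairs with a C, this equals
#' the both-strand G-or-C count divided by twice the window length. N bases
#' count as non-GC.
#'
#' @param universe A [promoter_universe].
#' @param motif A [motif_spec].
#' @param window Integer `c(lo, hi)`, TSS-relative, inclusive; must lie inside
#'   the universe region. Default `c(-140, -41)`, the proximal promoter window
#'   where GC-boxes are concentrated.
#' @return `data.frame` with one row per gene: `gene_id`, `n_occurrences`,
#'   `has_motif`, `gc_content`; attribute `window` records the window used.
#' @export
summarize_genes <- function(universe, motif, window = c(-140L, -41L)) {
  stopifnot(inherits(universe, "promoter_universe"), inherits(motif, "motif_spec"))
  window <- check_window(window, universe$region)
  occ <- scan_motif(universe, motif)
  occ <- occ[occ$start >= window[1L] & occ$start <= window[2L], , drop = FALSE]
  ids <- gene_ids(universe)
  counts <- integer(length(ids))
  if (nrow(occ)) {
    tab <- table(factor(occ$gene_id, levels = ids))
    counts <- as.integer(tab)
  }
  lo <- universe$region[1L]
  sub <- Biostrings::subseq(universe$sequences,
                            start = window[1L] - lo + 1L,
                            end = window[2L] - lo + 1L)
  gc <- as.vector(Biostrings::letterFrequency(sub, letters = "GC")) /
    (window[2L] - window[1L] + 1L)
  out <- data.frame(gene_id = ids,
                    n_occurrences = counts,
                    has_motif = counts >= 1L,
                    gc_content = gc,
                    stringsAsFactors = FALSE)
  attr(out, "window") <- window
  attr(out, "motif") <- motif$name
  out
}

#' Positional motif-frequency profile
#'
#' Slides a window of `window_size` nt across `profile_region` in 1-nt steps
#' and reports, for each window start `s`:
#' \describe{
#'   \item{`genes_with_hit`}{fraction of genes with at least one occurrence
#'     starting in `[s, s + window_size - 1]` (the percentages-of-containing-
#'     genes track; with a 100-nt window this is the coarse profile used to
#'     inspect upstream motif density).}
#'   \item{`per_position_occurrence`}{`window_size` must equal the motif
#'     length; fraction of genes with an occurrence starting exactly at `s`
#'     (the fine-grained relative-abundance track).}
#' }
#'
#' @param universe A [promoter_universe].
#' @param motif A [motif_spec].
#' @param window_size Window width in nt (e.g. 6 for the fine track, 100 for
#'   the coarse track).
#' @param profile_region Integer `c(lo, hi)` sub-region to profile; defaults
#'   to the whole universe region.
#' @param mode `"genes_with_hit"` (default) or `"per_position_occurrence"`.
#' @param genes Optional character vector restricting the profile to a subset
#'   of genes (e.g. a matched disease gene set); default all genes.
#' @return `data.frame` of class `motif_profile` with columns `window_start`
#'   and `fraction`; attributes `motif`, `window_size`, `mode`, `region`,
#'   `n_genes`.
#' @export
motif_profile <- function(universe, motif, window_size,
                          profile_region = NULL,
                          mode = c("genes_with_hit", "per_position_occurrence"),
                          genes = NULL) {
  stopifnot(inherits(universe, "promoter_universe"), inherits(motif, "motif_spec"))
  mode <- match.arg(mode)
  if (is.null(profile_region)) profile_region <- universe$region
  profile_region <- check_window(profile_region, universe$region)
  window_size <- check_int(window_size, "window_size")
  span <- profile_region[2L] - profile_region[1L] + 1L
  if (window_size < 1L) stop("'window_size' must be >= 1", call. = FALSE)
  if (window_size > span) {
    stop(sprintf("window_size (%d) exceeds the profiled region span (%d)",
                 window_size, span), call. = FALSE)
  }
  if (mode == "per_position_occurrence" && window_size != nchar(motif$pattern)) {
    stop("per_position_occurrence mode requires window_size equal to the motif length",
         call. = FALSE)
  }
  occ <- scan_motif(universe, motif)
  ids <- gene_ids(universe)
  if (!is.null(genes)) {
    keep <- ids %in% genes
    if (!any(keep)) stop("no profiled genes present in the universe", call. = FALSE)
    ids <- ids[keep]
    occ <- occ[occ$gene_id %in% ids, , drop = FALSE]
  }
  n_genes <- length(ids)
  lo <- profile_region[1L]
  hi <- profile_region[2L]
  s_max <- hi - window_size + 1L
  starts <- lo:s_max
  nw <- length(starts)

  if (mode == "per_position_occurrence") {
    # distinct (gene, start) pairs: a palindromic motif's paired +/- hits at
    # one position count the gene once
    key <- unique(paste(occ$gene_id, occ$start))
    pos <- as.integer(sub("^\\S+ ", "", key))
    pos <- pos[pos >= lo & pos <= s_max]
    frac <- tabulate(pos - lo + 1L, nbins = nw) / n_genes
  } else {
    # per gene, merge the window-start intervals covered by each occurrence,
    # then accumulate coverage with a +1/-1 difference array
    delta <- numeric(nw + 1L)
    occ <- occ[occ$start >= lo & occ$start <= hi, , drop = FALSE]
    if (nrow(occ)) {
      by_gene <- split(occ$start, occ$gene_id)
      for (st in by_gene) {
        a <- pmax(unique(st) - window_size + 1L, lo)
        b <- pmin(unique(st), s_max)
        ok <- a <= b
        if (!any(ok)) next
        iv <- merge_intervals(a[ok], b[ok])
        delta[iv$a - lo + 1L] <- delta[iv$a - lo + 1L] + 1
        delta[iv$b - lo + 2L] <- delta[iv$b - lo + 2L] - 1
      }
    }
    frac <- cumsum(delta[seq_len(nw)]) / n_genes
  }
  out <- data.frame(window_start = starts, fraction = frac)
  attr(out, "motif") <- motif$name
  attr(out, "window_size") <- window_size
  attr(out, "mode") <- mode
  attr(out, "region") <- profile_region
  attr(out, "n_genes") <- n_genes
  class(out) <- c("motif_profile", "data.frame")
  out
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("Motif profile: %s, %d-nt windows, mode %s, region (%d, %d), %d genes\n",
              attr(x, "motif"), attr(x, "window_size"), attr(x, "mode"),
              attr(x, "region")[1L], attr(x, "region")[2L], attr(x, "n_genes")))
  cat(sprintf("  %d window starts; fraction range [%.4g, %.4g]\n",
              nrow(x), min(x$fraction), max(x$fraction)))
  invisible(x)
}

# merge sorted-by-start closed integer intervals [a_i, b_i] into disjoint ones
merge_intervals <- function(a, b) {
  o <- order(a)
  a <- a[o]; b <- b[o]
  if (length(a) > 1L) {
    keep_a <- a[1L]; keep_b <- b[1L]
    ra <- integer(0); rb <- integer(0)
    for (i in 2L:length(a)) {
      if (a[i] <= keep_b + 1L) {
        keep_b <- max(keep_b, b[i])
      } else {
        ra <- c(ra, keep_a); rb <- c(rb, keep_b)
        keep_a <- a[i]; keep_b <- b[i]
      }
    }
    a <- c(ra, keep_a); b <- c(rb, keep_b)
  }
  list(a = a, b = b)
}

check_window <- function(window, reg) {
  if (length(window) != 2L || !is.numeric(window) || any(is.na(window))) {
    stop("window must be an integer vector c(lo, hi)", call. = FALSE)
  }
  window <- as.integer(window)
  if (window[1L] > window[2L]) stop("window lo must be <= hi", call. = FALSE)
  if (window[1L] < reg[1L] || window[2L] > reg[2L]) {
    stop(sprintf("window (%d, %d) lies outside the universe region (%d, %d)",
                 window[1L], window[2L], reg[1L], reg[2L]), call. = FALSE)
  }
  window
}

#' Write motif occurrences or a profile track as TSV
#'
#' @param x A `data.frame` of occurrences from [scan_motif()], a gene summary
#'   from [summarize_genes()], or a [motif_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
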