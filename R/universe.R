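#' Construct a promoter universe
#'
#' A promoter universe holds one TSS-anchored promoter sequence per gene, all
#' sharing a common coordinate frame. Offsets are integers with the
#' transcription start site (TSS) at 0; a universe covering `(-500, 100)` spans
#' the closed interval from 500 nt upstream to 100 nt downstream of the TSS
#' (601 nt).
#'
#' @param sequences Named character vector of DNA sequences (one per gene;
#'   names are gene identifiers), or a [Biostrings::DNAStringSet]. All
#'   sequences must have equal length and contain only A, C, G, T, N.
#' @param start_offset Integer, TSS-relative offset of the first base of every
#'   sequence (e.g. -500).
#' @return An object of class `promoter_universe`: a list with elements
#'   `sequences` (a `DNAStringSet`, upper-cased) and `region` (integer vector
#'   `c(start, end)` of TSS-relative offsets, ends inclusive).
#' @examples
#' u <- promoter_universe(c(G1 = "ACGT", G2 = "GGCC"), start_offset = -2)
#' region(u)  # -2 .. 1
#' @export
promoter_universe <- function(sequences, start_offset) {
  start_offset <- check_int(start_offset, "start_offset")
  if (is.character(sequences)) {
    ids <- names(sequences)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("every sequence must be named with a gene id", call. = FALSE)
    }
    seqs <- toupper(sequences)
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0L)) {
      i <- which(bad > 0L)[1L]
      stop(sprintf(
        "invalid character %s in sequence of gene '%s' at position %d (only A/C/G/T/N allowed)",
        substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]
      ), call. = FALSE)
    }
    seqs <- Biostrings::DNAStringSet(seqs)
  } else if (methods::is(sequences, "DNAStringSet")) {
    seqs <- sequences
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("every sequence must be named with a gene id", call. = FALSE)
    }
    alf <- Biostrings::alphabetFrequency(seqs)
    extra <- rowSums(alf[, setdiff(colnames(alf), c("A", "C", "G", "T", "N")),
                         drop = FALSE])
    if (any(extra > 0L)) {
      i <- which(extra > 0L)[1L]
      pos <- regexpr("[^ACGTN]", as.character(seqs[[i]]))
      stop(sprintf(
        "invalid character in sequence of gene '%s' at position %d (only A/C/G/T/N allowed)",
        ids[i], pos
      ), call. = FALSE)
    }
  } else {
    stop("'sequences' must be a named character vector or a DNAStringSet",
         call. = FALSE)
  }
  if (length(seqs) == 0L) stop("universe must contain at least one promoter", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    stop(sprintf("all promoter sequences must have equal length (found lengths %s)",
                 paste(sort(unique(w)), collapse = ", ")), call. = FALSE)
  }
  if (w[1L] < 1L) stop("promoter sequences must have length >= 1", call. = FALSE)
  structure(
    list(sequences = seqs,
         region = c(start_offset, start_offset + w[1L] - 1L)),
    class = "promoter_universe"
  )
}

#' @export
length.promoter_universe <- function(x) length(x$sequences)

#' Gene identifiers of a promoter universe
#' @param universe A `promoter_universe`.
#' @return Character vector of gene ids, in storage order.
#' @export
gene_ids <- function(universe) {
  stopifnot(inherits(universe, "promoter_universe"))
  names(universe$sequences)
}

#' TSS-relative region covered by a promoter universe
#' @param universe A `promoter_universe`.
#' @return Integer vector `c(start, end)`, both inclusive, TSS at 0.
#' @export
region <- function(universe) {
  stopifnot(inherits(universe, "promoter_universe"))
  universe$region
}

#' @export
print.promoter_universe <- function(x, ...) {
  cat(sprintf("Promoter universe: %d genes, region (%d, %d) relative to TSS, %d nt\n",
              length(x), x$region[1L], x$region[2L],
              x$region[2L] - x$region[1L] + 1L))
  invisible(x)
}

#' Read promoter sequences from a FASTA file
#'
#' The first whitespace-delimited token of each FASTA header is taken as the
#' gene id. The TSS-relative coordinate frame is not encoded in FASTA, so the
#' offset of the first base must be declared by the caller.
#'
#' @param fasta_path Path to a FASTA file of promoter sequences, one per gene,
#'   all of equal length.
#' @param start_offset Integer, TSS-relative offset of the first base
#'   (e.g. -500 for the canonical (-500, 100) frame).
#' @return A [promoter_universe].
#' @seealso [write_promoters()]
#' @export
read_promoters <- function(fasta_path, start_offset) {
  if (!file.exists(fasta_path)) {
    stop(sprintf("FASTA file not found: %s", fasta_path), call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  x <- as.character(seqs)
  names(x) <- ids
  promoter_universe(x, start_offset)
}

#' Write a promoter universe to FASTA
#'
#' Inverse of [read_promoters()]: reading the written file back with the same
#' `start_offset` reproduces the universe exactly.
#'
#' @param universe A `promoter_universe`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(universe, path) {
  stopifnot(inherits(universe, "promoter_universe"))
  Biostrings::writeXStringSet(universe$sequences, path, width = 80L)
  invisible(path)
}

check_int <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer", what), call. = FALSE)
  }
  as.integer(x)
}
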