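# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's own code paths.

# reverse complement by table lookup + reversal
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive scanner: compare every length-m substring to the pattern and (if
# both_strands) to its reverse complement; returns data.frame(strand, start)
# in TSS-relative coordinates
oracle_scan <- function(seq, pattern, start_offset, both_strands = TRUE) {
  m <- nchar(pattern)
  L <- nchar(seq)
  out <- data.frame(strand = character(0), start = integer(0))
  if (m > L) return(out)
  subs <- substring(seq, 1:(L - m + 1), m:L)
  plus <- which(subs == pattern)
  rc <- oracle_revcomp(pattern)
  minus <- if (both_strands) which(subs == rc) else integer(0)
  out <- rbind(
    data.frame(strand = rep("+", length(plus)),
               start = as.integer(plus + start_offset - 1)),
    data.frame(strand = rep("-", length(minus)),
               start = as.integer(minus + start_offset - 1))
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exhaustive hypergeometric upper tail by pmf enumeration (small N only)
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]])))
  writeLines(lines, path)
  path
}

# published over-representation margins: per-set (total, matched n,
# containing k) with universe N and containing K, printed p, FDR and percent
# columns, and the number of printed decimals of each value
gcbox_table <- function() {
  list(N = 16455L, K = 7653L,
       n = c(28L, 47L, 63L, 357L, 88L, 258L),
       k = c(19L, 31L, 36L, 184L, 42L, 141L),
       p = c(0.0186, 0.0056, 0.058, 0.0306, 0.4503, 0.005),
       p_dec = c(4, 4, 3, 4, 4, 3),
       fdr = c(0.037, 0.017, 0.07, 0.046, 0.45, 0.017),
       fdr_dec = c(3, 3, 2, 3, 2, 3),
       pct = c(67.86, 65.96, 57.14, 51.54, 47.73, 54.65))
}

gabox_table <- function() {
  list(N = 16455L, K = 5485L,
       n = c(28L, 47L, 63L, 357L, 88L, 258L),
       k = c(10L, 18L, 25L, 126L, 37L, 118L),
       p = c(0.4645, 0.2813, 0.1738, 0.2295, 0.0539, 0.00002),
       p_dec = c(4, 4, 4, 4, 4, 5),
       fdr = c(0.4645, 0.3375, 0.3375, 0.3375, 0.1617, 0.0001),
       fdr_dec = c(4, 4, 4, 4, 4, 4))
}

match_ids <- function(gs, summ) match_gene_set(gs, summ)
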