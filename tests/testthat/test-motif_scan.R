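gc_box <- motif_spec("GC-box", "GGGCGG")

test_that("motif_spec validates and derives the reverse complement", {
  expect_equal(gc_box$revcomp, "CCGCCC")
  expect_error(motif_spec("x", "GGXCGG"), "A/C/G/T")
  expect_error(motif_spec("x", "ACG"), "length")
  expect_error(motif_spec("x", "ACGTACGTACGTA"), "length")
  expect_equal(motif_spec("x", "gggcgg")$pattern, "GGGCGG")
})

test_that("scan_motif reports exact bidirectional occurrences in TSS coordinates", {
  u <- promoter_universe(c(G1 = "GGGCGG"), start_offset = -140)
  occ <- scan_motif(u, gc_box)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$strand, "+")
  expect_equal(occ$start, -140L)

  u2 <- promoter_universe(c(G1 = "CCGCCC"), start_offset = -10)
  occ2 <- scan_motif(u2, gc_box)
  expect_equal(occ2$strand, "-")
  expect_equal(occ2$start, -10L)

  # overlapping occurrences all count
  u3 <- promoter_universe(c(G1 = "GGGCGGGCGG"), start_offset = 0)
  occ3 <- scan_motif(u3, gc_box)
  expect_equal(occ3$start, c(0L, 4L))
  expect_equal(occ3$strand, c("+", "+"))

  expect_equal(nrow(scan_motif(promoter_universe(c(G1 = "AAAAAA"), 0), gc_box)), 0L)

  # motif longer than sequence: empty, not an error
  expect_equal(nrow(scan_motif(promoter_universe(c(G1 = "ACGT"), 0), gc_box)), 0L)
})

test_that("positions containing N never match", {
  u <- promoter_universe(c(G1 = "GGGNGGGCGG"), start_offset = 0)
  occ <- scan_motif(u, gc_box)
  expect_equal(occ$start, 4L)
})

test_that("plus-only scanning suppresses minus-strand hits", {
  m1 <- motif_spec("GC-box", "GGGCGG", both_strands = FALSE)
  u <- promoter_universe(c(G1 = "CCGCCCGGGCGG"), start_offset = 0)
  occ <- scan_motif(u, m1)
  expect_equal(occ$strand, "+")
  expect_equal(occ$start, 6L)
})

test_that("a palindromic motif at one start counts as two stranded occurrences", {
  pal <- motif_spec("pal", "GCGC")
  u <- promoter_universe(c(G1 = "AAGCGCAA"), start_offset = 0)
  occ <- scan_motif(u, pal)
  expect_equal(nrow(occ), 2L)
  expect_setequal(occ$strand, c("+", "-"))
  expect_equal(unique(occ$start), 2L)
})

test_that("scanner agrees with the naive substring oracle on random sequences", {
  withr::local_seed(42)
  motifs <- list(gc_box, motif_spec("GA-box", "GGGAGG"),
                 motif_spec("MAZ", "CCCCTCC"), motif_spec("KLF13", "ACGCCC"))
  for (i in 1:40) {
    len <- sample(6:1000, 1)
    gc <- runif(1, 0.3, 0.7)
    s <- random_dna(len, gc)
    off <- sample(-500:0, 1)
    u <- promoter_universe(setNames(s, "G"), off)
    for (mo in motifs) {
      got <- scan_motif(u, mo)
      want <- oracle_scan(s, mo$pattern, off)
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("reverse-complementing the universe mirrors occurrence positions", {
  withr::local_seed(9)
  s <- random_dna(300, 0.6)
  u <- promoter_universe(setNames(s, "G"), -150)
  rcu <- promoter_universe(setNames(oracle_revcomp(s), "G"), -150)
  occ <- scan_motif(u, gc_box)
  occ_rc <- scan_motif(rcu, gc_box)
  # an occurrence starting at offset t (length m) maps to a mirrored start
  m <- nchar(gc_box$pattern)
  lo <- -150; hi <- 149
  mirrored <- sort(lo + hi - occ$start - (m - 1L))
  expect_equal(sort(occ_rc$start), mirrored)
  expect_equal(nrow(occ), nrow(occ_rc))
})

test_that("window membership is start-based and GC content is plus-strand fraction", {
  # occurrence starting exactly at the right edge is in; one past is out
  seq1 <- paste0(strrep("A", 99), "GGGCGG", strrep("A", 45))  # starts at -41
  u1 <- promoter_universe(setNames(seq1, "G"), -140)
  s1 <- summarize_genes(u1, gc_box, window = c(-140, -41))
  expect_equal(s1$n_occurrences, 1L)
  expect_true(s1$has_motif)

  seq2 <- paste0(strrep("A", 100), "GGGCGG", strrep("A", 44))  # starts at -40
  u2 <- promoter_universe(setNames(seq2, "G"), -140)
  s2 <- summarize_genes(u2, gc_box, window = c(-140, -41))
  expect_equal(s2$n_occurrences, 0L)
  expect_false(s2$has_motif)

  u3 <- promoter_universe(c(G1 = strrep("GC", 50), G2 = strrep("ACGT", 25),
                            G3 = strrep("N", 100)), -100)
  s3 <- summarize_genes(u3, gc_box, window = c(-100, -1))
  expect_equal(s3$gc_content, c(1.0, 0.5, 0.0))

  expect_error(summarize_genes(u3, gc_box, window = c(-200, -1)), "outside")
})

test_that("plus-strand GC fraction equals the both-strand count over twice the length", {
  withr::local_seed(5)
  s <- random_dna(200, 0.55)
  u <- promoter_universe(setNames(s, "G"), -100)
  got <- summarize_genes(u, gc_box, window = c(-80, -21))$gc_content
  win <- substr(s, -80 - (-100) + 1, -21 - (-100) + 1)
  both <- win  # plus strand
  minus <- oracle_revcomp(win)
  n_gc_both <- sum(strsplit(both, "")[[1]] %in% c("G", "C")) +
    sum(strsplit(minus, "")[[1]] %in% c("G", "C"))
  expect_equal(got, n_gc_both / (2 * nchar(win)))
})

test_that("profiles match a brute-force recount and sum to the occurrence total", {
  withr::local_seed(11)
  n <- 30
  seqs <- setNames(vapply(1:n, function(i) random_dna(150, 0.6), ""),
                   sprintf("G%02d", 1:n))
  u <- promoter_universe(seqs, -100)
  occ <- scan_motif(u, gc_box)

  ws <- 20
  pr <- motif_profile(u, gc_box, ws, mode = "genes_with_hit")
  for (j in seq_len(nrow(pr))) {
    s <- pr$window_start[j]
    hit <- vapply(names(seqs), function(g) {
      any(occ$gene_id == g & occ$start >= s & occ$start <= s + ws - 1)
    }, NA)
    expect_equal(pr$fraction[j], mean(hit))
  }

  pp <- motif_profile(u, gc_box, nchar(gc_box$pattern),
                      mode = "per_position_occurrence")
  expect_equal(sum(pp$fraction) * n, nrow(occ))
  expect_true(all(pp$fraction >= 0 & pp$fraction <= 1))
})

test_that("profile of a uniformly planted universe plateaus at 1 over the planted start", {
  seqs <- setNames(vapply(1:20, function(i) {
    paste0(strrep("A", 400), "GGGCGG", strrep("A", 195))
  }, ""), sprintf("G%02d", 1:20))
  u <- promoter_universe(seqs, -500)  # motif starts at -100 in every gene
  pr <- motif_profile(u, gc_box, 100, profile_region = c(-500, 50))
  covering <- pr$window_start <= -100 & pr$window_start + 99 >= -100
  expect_true(all(pr$fraction[covering] == 1))
  expect_true(all(pr$fraction[!covering] == 0))

  none <- motif_profile(u, motif_spec("MAZ", "CCCCTCC"), 100,
                        profile_region = c(-500, 50))
  expect_true(all(none$fraction == 0))
})

test_that("profile argument validation", {
  u <- promoter_universe(c(G1 = strrep("A", 50)), -25)
  expect_error(motif_profile(u, gc_box, 100), "exceeds")
  expect_error(motif_profile(u, gc_box, 10, mode = "per_position_occurrence"),
               "motif length")
  expect_error(motif_profile(u, gc_box, 6, profile_region = c(-30, 10)),
               "outside")
})
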