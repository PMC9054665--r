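---
title: "Promoter motif enrichment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif enrichment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promotif)
```

## The model

`promotif` asks a single statistical question in several guises: are exact
transcription-factor binding motifs — above all the GC-box GGGCGG, the
high-affinity Sp1/Sp4 site of the proximal promoter — distributed differently
in a group of genes than in the genome-wide promoter universe?

The data model is deliberately minimal. A *promoter universe* is one
sequence per gene on a common TSS-anchored integer coordinate frame; a
*motif* is an exact DNA word scanned on both strands; a *gene set* is a list
of symbols matched case-insensitively against the universe. All downstream
statistics are functions of three per-gene quantities computed in a window:
the number of occurrences whose start offset falls in the window, the derived
presence flag, and the window's GC fraction.

### Coordinate frame

Offsets are integers with the TSS base at 0 and all interval ends inclusive,
so the canonical promoter export region "(−500, 100)" is the 601-nt closed
interval [−500, +100], and the proximal analysis window "(−140, −41)" is
exactly 100 nt. Databases differ on whether the TSS is position 0 or +1 and
on end inclusivity; since no convention can be recovered from a FASTA export,
the frame is declared by the caller (`start_offset`) and everything else
follows by construction. If your source places the TSS at +1, shift
`start_offset` by one; every window argument is configurable.

### Scanning rules

- Both strands by default: a minus-strand occurrence is an exact plus-strand
  match of the reverse complement, reported at its leftmost plus-strand base.
- Overlapping occurrences all count (GGGCGGGCGG contains two GC-boxes); no
  de-overlap rule exists in the exact-word setting that would not be
  arbitrary.
- Window membership is start-based: an occurrence belongs to [lo, hi] iff its
  start offset does, even if the word runs past hi. This matches how a
  motif-length window shifted by 1 nt accumulates counts, and it makes window
  counts additive across adjacent windows. The alternative (full containment)
  differs by at most motif-length − 1 positions at the right edge.
- N bases never match and count as non-GC — ambiguity is treated
  conservatively in both the scanner and the GC computation.
- A palindromic word at one start yields one occurrence per strand. This
  cannot arise for the four built-in motifs (none is its own reverse
  complement) but keeps the rule uniform for user motifs; the per-position
  profile counts *genes*, so such a pair is not double-counted there.

GC content is computed on the plus strand. Counting G-or-C over both strands
and dividing by twice the window length gives the identical number (each G
pairs with a C), which the test suite asserts rather than assumes.

### Over-representation

With `N` universe genes, `K` of them motif-containing, and `k` containing
genes among a matched set of size `n`, the p-value is the upper-tail
cumulative hypergeometric probability `P(X ≥ k)`, evaluated through the
exact survival function (`phyper(k − 1, ..., lower.tail = FALSE)`), with
`P(X ≥ 0) = 1` exactly. The upper tail is the right reading of "cumulative"
here: it reproduces published enrichment tables from their count margins to
their printed precision, which a lower-tail reading does not.

Benjamini–Hochberg correction is applied within one family per results
table: one motif, all gene sets tested against it. Correcting each motif's
table separately reproduces published adjusted columns; a joint family
across motifs would be more conservative and can be had by calling
`bh_adjust()` on the pooled column. Note that BH step-up is *not* idempotent
— re-adjusting an adjusted column moves values further toward 1 — so adjusted
values are reported once, from the raw p-values.

### Group comparisons

The count comparison is a randomization test that respects the data's
nesting: a disease group is a *subset* of the motif-containing universe, so
the null is built by drawing uniform subsets of the same size from that
background (9,999 by default) and recomputing the difference of means.
Labels are never exchanged between two disjoint samples because no such
disjoint design exists here. The p-value is two-sided with the add-one
convention `(1 + #{|T*| ≥ |T|}) / (n_perm + 1)`, bounded below by
`1/(n_perm + 1)`. Drawing from the full background rather than
background-minus-group is the default; with groups of tens against a
background of thousands the two nulls are indistinguishable, and both are
available by construction (pass any background vector).

GC-content comparisons use Welch's *t* (unequal variances; group sizes here
differ by two orders of magnitude) via `t.test`, or classical one-way ANOVA
via `oneway.test(var.equal = TRUE)` for multi-group layouts. The statistic
of the permutation test is the mean difference — the simplest falsifiable
choice for a boxplotted count comparison.

## The synthetic generator

`gen_universe()` draws every base i.i.d. with `P(G) = P(C) = g/2`, then
plants `Poisson(plant_rate)` copies of the motif per gene (truncated to the
non-overlapping capacity of the window, floored at `min_copies`) at uniform
non-overlapping starts in `plant_window`, on a uniformly chosen strand,
overwriting background bases in place so the coordinate frame is preserved.
`gen_gene_set()` samples without replacement with odds
`enrichment_odds : 1` for motif-containing versus other genes; odds of 1
gives an exactly uniform null set.

Defaults are the study conditions the pipeline is meant to emulate: region
(−500, 100), proximal window (−140, −41), GC fraction 0.5, and
`plant_rate = 0.58`, chosen once so that planted copies
(`1 − e^(−0.58) ≈ 0.44`) plus chance background matches
(`≈ 1 − (1 − 2·0.25⁶)^100 ≈ 0.047` of the remainder) put the baseline
fraction of GC-box-containing genes at ≈ 46.5%, the genome-wide figure for
human promoter collections. What the generator does *not* emulate: CpG
islands and dinucleotide structure, GC heterogeneity between genes,
correlated motif clustering, and alternative promoters. Passing calibration
and power tests on this generator therefore validates the *statistics*
(exactness of the hypergeometric null, reproducibility of the permutation
null, direction and magnitude of power), not the biology of real promoters.

`min_copies` exists because a Poisson count model — the natural choice for
occurrence counts, and the one used — leaves `e^{−λ}` of genes with zero
copies at any finite rate, so "every gene carries the motif" fixtures
(profile plateau tests, saturation checks) need an explicit floor rather
than a large rate.

## Numerical and calibration choices

- **Problem sizes.** The shipped calibration studies use universes of
  2,000–4,000 genes, 500 null sets of 50 genes, and 200 enriched sets of 100
  genes at odds 4 — large enough that the baseline fraction is estimated to
  under a point and power against odds-4 enrichment is essentially 1, while
  a full run stays in seconds.
- **Discreteness and the null check.** The hypergeometric p-value is
  discrete (for sets of 50 its support has ~50 atoms, the largest ≈ 0.11),
  so under a perfectly calibrated null a *two-sided* KS test against the
  uniform rejects on ties alone. Super-uniformity — `P(p ≤ α) ≤ α` — is a
  one-sided property, and the calibration check is therefore the one-sided
  KS statistic `D⁺ = max(ecdf − uniform)` (`alternative = "greater"`),
  supplemented by direct empirical rejection-rate bounds at α = 0.01, 0.05,
  0.1.
- **Seeds.** Every stochastic operation takes one explicit integer seed and
  restores the caller's RNG state; identical (inputs, config, seed) triples
  produce byte-identical output files, and run metadata records the seed.
- **Ties in the permutation test.** `|T*| ≥ |T|` is evaluated with a
  relative tolerance of 1e−12 so that exact ties (common with integer
  counts) are counted as exceedances, matching exhaustive enumeration.
- **Degenerate inputs** fail loudly and early: duplicate gene ids, non-ACGTN
  characters (with position), ragged sequence lengths, windows outside the
  region, empty matched sets, zero-variance t tests, infeasible set sizes.
  Zero matches in set matching is a reported outcome, not an error.

## Known limitations

- Exact words only: no IUPAC degeneracy, no position-weight matrices, no
  motif discovery. The motifs this pipeline targets are defined as exact
  hexamers/heptamers.
- Symbol matching is case-folded string equality; alias or cross-database
  identifier resolution is the data supplier's responsibility.
- One promoter per gene is required; selecting a representative promoter
  from multi-TSS annotation happens upstream.
- The count-level fixtures (`table1_fixture()`, `table2_fixture()`) carry
  margins, presence flags and a placeholder GC column — they validate the
  enrichment arithmetic, not sequence-level scanning, which is exercised by
  the synthetic generator and the oracle tests instead.
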