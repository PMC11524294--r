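---
title: "Methods: calling and characterizing nuclear RNA-editing sites"
author: "nucredit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and characterizing nuclear RNA-editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucredit)
```

# Scope and coordinate conventions

`nucredit` analyses RNA editing in *transcript space*: reads are assumed
aligned to primary transcript sequences (one per gene), so a site is a
(transcript, position) pair and substitution labels never involve strand
flips. All file formats carry 1-based inclusive coordinates; everything in
memory is 0-based half-open; the conversion happens only in the I/O layer.
Editing types are stored on the DNA alphabet and reported with U on the
RNA side ("C-to-U" for a C>T column).

# The error model behind site calling

A pileup column with coverage $n$ and alternative-base count $a$ is a
candidate when $n \ge 50$ high-quality reads (Phred mean $\ge 20$) and
$a \ge 1$. The null hypothesis is that the mismatches are sequencing
error: with per-base error rate $\varepsilon$, a specific alternative base
is expected in $n\varepsilon/3$ reads (error spread uniformly over the
three non-reference bases — the minimal assumption in the absence of a
stated machine error profile). The observed column $(a,\; n-a)$ is
contrasted with the expected column
$(\mathrm{round}(n\varepsilon/3),\; n-\mathrm{round}(n\varepsilon/3))$ in
a 2×2 table, and the one-sided (greater) Fisher exact p-value is the
hypergeometric tail of the (1,1) cell. Choices worth stating:

* **One-sided.** The claim under test is always an excess of mismatches,
  never a deficit.
* **Rounding.** The expected count uses round-half-to-even (R's `round`),
  so results are bit-reproducible across platforms.
* **Error-rate source.** By default $\varepsilon = 10^{-q/10}$ from the
  column's mean quality $q$; a global `error_rate` can override it when
  qualities are synthetic or untrusted.
* **FDR.** p-values across all candidates are Benjamini–Hochberg adjusted
  and sites kept at $q < 0.05$ *strictly*, matching the convention
  "adjusted p-values less than 0.05".
* **Degenerate inputs.** $a = 0$ gives $p = 1$; an empty candidate set
  yields an empty, well-typed call set.

Read-level filters (perfect 22-nt seed, at most 3 mismatches per read)
are modeled by `filter_read()` for alignment records; pileups are assumed
to contain already-filtered reads, since a base-count pileup no longer
carries read identity.

At the suite's study conditions (coverage ~60–100, $\varepsilon = 0.001$)
the caller is strongly conservative: a single error read has
$p \approx 0.5$, and BH across hundreds of candidates requires roughly ten
error reads on one column before anything is called, which is why the
null-replicate false-call rate measured by the tests sits near zero — well
under the nominal 5%.

# Characterization

Codon position is $((\text{pos} - \text{cds\_start}) \bmod 3) + 1$;
synonymy compares translations of the reference codon and the codon with
the edited base substituted (standard genetic code; stops are a 21st class
"*"). Editing density divides site counts by summed region length in kb
over *all supplied transcripts* (the template space); `edited_only = TRUE`
restricts the denominator to edited transcripts. Per-amino-acid rates
divide events by codon-table degeneracy (e.g. D = 2, W = 1, stop = 3) —
the reading forced by "ratio of editing sites to the number of degenerate
codons" — with `denominator = "usage"` available for the
codon-occurrence alternative. RPKM is `count / (length_kb * millions of
mapped reads)`; `log2` is taken only on positive values, with an optional
pseudocount (default 0).

# Coexpression clustering via the Shared Coexpression Matrix

Expression of each edited gene is multiplied by its mean editing degree
(averaged over the gene's sites), turning RPKM into an estimate of
*edited-transcript* abundance; PPR genes are unedited and enter
unadjusted. The network uses tie-corrected Spearman correlation with an
edge at $\rho \ge 0.7$ and one-sided $p \le 0.05$ (t approximation on
$n-2$ df). Both thresholds are exposed: the source analysis states
neither, and 0.7/0.05 are conventional coexpression defaults.

The SCM entry $(i,j)$ counts genes coexpressed with both $i$ and $j$.
Decomposition is greedy:

1. Seed with the unassigned pair maximizing the SCM entry ("highest
   coexpression strength" read as the largest shared-partner count, since
   the primer is drawn from the matrix being decomposed); ties break by
   larger $\rho$, then lexicographic gene ids, making runs deterministic.
2. Recruit the third gene with significant shared-neighbor overlap with
   *both* seeds. Significance is the one-sided hypergeometric tail on
   shared neighbors: with $N$ genes in the network, the overlap of two
   independent neighbor sets of sizes $d_i, d_j$ (excluding the pair
   itself) is $\mathrm{Hypergeom}(N-2, d_i, d_j)$. The test itself is not
   specified by the source description; the hypergeometric shared-neighbor
   null is the standard choice.
3. Repeatedly add any gene significant with at least three current
   members.
4. Close the cluster, delete its members from the network, and repeat.
   Deleted genes no longer count as shared neighbors for later clusters —
   the reading of "removed from SCM" adopted here; it makes late clusters
   conditionally independent of earlier ones.

A seed pair that cannot recruit a third member is dissolved and masked
from future seeding, so clusters always have $\ge 3$ members.

# Motif discovery

For C-to-U sites with a full ±5 flank, an 4×11 composition matrix is
compared position-by-position (excluding the invariant center) to the
background matrix built from *every* C residue with full context in all
supplied transcripts, by a goodness-of-fit chi-square on 3 df (the
independence variant on two count tables is available as a flag).
Zero background proportions are floored at $1/(4\,n_\text{contexts})$ and
the column renormalized, keeping the statistic finite; the floor is
logged. Testing requires at least 20 sites — a guardrail for chi-square
validity, not a value from the source analysis. A position is labeled `R`
when significant at $\alpha = 0.05$ with purine fraction $\ge 0.6$
(`Y` for the mirror case), `N` otherwise; the core is the −1/0/+1 triplet.

Because ten null positions are each tested at $\alpha = 0.05$, about one
flank position in two scans will be spuriously significant; the core call
only uses −1/+1, so far-position false positives do not change the motif.
The test suite measures exactly this calibration: detection at −1/+1 in
≥95% of motif-planted runs, a per-position false-positive rate compatible
with $\alpha$ at ±4/±5, and ~5% positional false positives when no motif
is planted. A conjunction-style criterion ("all four far positions clean
in ≥95% of runs") would be statistically incoherent at $\alpha = 0.05$
($0.95^4 \approx 0.81$ expected), so the per-position reading is the one
implemented.

# What the synthetic-data generator emulates

The generator produces every pipeline input with the structure the
analysis assumes, under one seed with per-operation RNG streams (seed +
fixed offset), so outputs are byte-stable and adding an operation never
perturbs the others.

* **Transcripts**: contiguous 5'UTR/CDS/3'UTR; CDS starts ATG, ends with
  a stop, no internal in-frame stop. Default length ranges (100–300 /
  300–1500 / 200–600 nt) are typical plant primary-transcript scales.
* **Planted sites**: distinct positions with a full ±5 flank; type weights
  default to the observed dominance structure (the four major types
  carrying 61.3% of events); degrees uniform on [0.20, 0.64], centered on
  the observed ~0.42 mean editing degree.
* **Pileups**: truncated-Poisson coverage (mean 100, comfortably above
  the 50-read floor), exact multinomial counts with uniform error 0.001
  per base (a free parameter — no per-base error rate is stated by the
  source analysis), and the column quality encodes the simulated error
  rate so the caller's quality-derived $\varepsilon$ matches the
  generator's by construction.
* **Expression**: log-normal values whose underlying Gaussians share a
  cluster latent profile with loading chosen through the bivariate-normal
  relation $\rho_{normal} = 2\sin(\pi\rho_s/6)$, so the *Spearman*
  correlation hits the configured target; 30 samples by default (the
  library count of the motivating data). Five samples is the hard floor —
  rank correlation below that is noise.
* **Flanking motif**: with probability `motif_prob` the −1/+1 bases of a
  planted C-to-U site are rewritten to A/G (equal odds), never creating an
  internal in-frame stop (the four purine pairs are tried in random
  order) and never overwriting another planted site. The default 0.6
  yields an observed purine fraction of ~0.8
  ($0.6 + 0.4 \times 0.5$ background), matching the ~79% reported at
  −1/+1 in the motivating study.
* **Labels**: two strata (7,036 endosymbiont-derived vs 35,000 other
  genes) with edited fractions 0.273 / 0.195 — the published contrast —
  and GO terms assigned independently of editing (a true enrichment
  null).

What it does *not* emulate, and hence what green tests do not show about
real data: read-level artifacts (mapping bias, indels, splice
misalignment, strand bleed), genotype SNPs masquerading as edits,
overdispersed coverage, correlated errors along reads, isoform mixtures,
and any biological coupling between editing degree and expression. The
caller's measured FDR is an error-model property, not protection against
misalignment.

# Problem sizes used by the test suite

Unit and property tests run at deliberately small scales chosen for tight
statistical bounds: 1,000 null pileup replicates of ~400 columns for FDR,
500 planted sites at coverage 100 for sensitivity and degree bias,
exhaustive enumeration of hypergeometric instances to $N \le 60$ and
Fisher tables to coverage 60 (spot checks to 200), 20 seeds × 30 genes ×
200 samples for cluster recovery, and 100 seeded runs × 220 sites for
motif detection and null calibration. The full suite completes in under
two minutes on one CPU.

# Known limitations

* One primary transcript per gene; multi-isoform collapse is the caller's
  upstream responsibility.
* No genotype-aware SNP exclusion: the design assumes RNA-seq from the
  sequenced genotype, so DNA-RNA differences are not confounded by
  polymorphism.
* BAM/SAM ingestion is out of scope; `read_pileup()` documents the seam
  where an mpileup-style adapter would plug in.
* The SCM decomposition is order-dependent by design (greedy with
  deterministic tie-breaks); it recovers planted block structure
  accurately but is not a globally optimal partition.
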