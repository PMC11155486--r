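---
title: "Characterizing spliced-leader trans-spliced genes from 5' tag data"
author: "outronscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing spliced-leader trans-spliced genes from 5' tag data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

In tunicates such as *Ciona*, and in nematodes, a large fraction of genes
undergo spliced-leader (SL) trans-splicing: the 16-nt 5' exon of a small
SL RNA is joined onto a pre-mRNA at a trans-splice acceptor site (TAS),
and the 5' region upstream of the TAS — the outron — is discarded. A
5'-end sequencing library (TSS-seq style oligo-capping) therefore
contains two read populations: reads that begin with the SL sequence mark
TAS positions, and capped reads mark transcription start sites (TSSs).

`outronscan` implements the downstream characterization of such data as a
reusable, fully tested pipeline:

1. **Tag calling** — classify reads by SL prefix, map their 5' ends,
   cluster them, call TAS (with an AG acceptor-context filter) and TSSs
   (requiring open-chromatin support from ATAC-like peaks).
2. **Gene classification** — redefine gene bodies from known plus novel
   transcripts, detect operons, label genes trans-spliced /
   non-trans-spliced / ambiguous, locate each gene's major TAS on its
   transcript structure, and estimate a per-gene trans-splicing ratio.
3. **Splice-site strength** — train PWM or maximum-entropy models over
   fixed donor (9 nt, $-3..+6$) and acceptor (23 nt, $-20..+3$) windows
   and compare score distributions between gene groups.
4. **Local enrichment** — 30-bp sliding-window nucleotide-content tests
   (one-sided Mann–Whitney, BH-adjusted) and a two-stage local motif
   enrichment test: binomial against an intergenic background, then
   Fisher's exact against control genes.

Because the original datasets live in external archives, the package is
exercised end to end on a synthetic genome with planted ground truth; the
generator is a first-class, tested module, not a fixture.

## Statistical models

**Tag model.** A gene with true trans-splicing ratio $\rho$ emits each
5'-end tag from the SL pool with probability $\rho$ and from the capped
pool otherwise; tag totals are Poisson. The estimator
$\hat\rho = \mathrm{TAS\ tags}/(\mathrm{TAS} + \mathrm{TSS\ tags})$ uses
the gene's *total* SL tag mass (major plus minor acceptor sites) and is
therefore the binomial MLE; at depth $10^4$ it concentrates within
$3\sqrt{\rho(1-\rho)/n}$ of the truth. The direction of the ratio (TAS
in the numerator, so larger means more trans-splicing) is a package
convention chosen to agree with the TS-High/TS-Low naming; the split at
threshold $t$ is boundary-inclusive ($\hat\rho \ge t \Rightarrow$
TS-High).

**First-acceptor-site preference.** With $k$ of $n$ spliced genes whose
major TAS coincides with their first cis-splice acceptor site, the
upper-tail binomial p-value is computed against the background proportion
$p_0$ of first acceptor sites among all cis acceptor sites. Whether $p_0$
should be counted per acceptor site or per gene is genuinely open; the
per-site definition is the default and the per-gene alternative (mean of
$1/\#\mathrm{AS}$) is exposed as a flag.

**Splice-site strength.** The signal model is either a PWM (independent
columns, pseudocount-smoothed) or a maximum-entropy distribution fitted
by iterative proportional fitting (IPF) under marginal constraints.
Scores are $\log_2 P_{signal}/P_{background}$. Two numerical points
matter:

* Constraint consistency. Separately smoothed single-position and
  pairwise marginals are mutually inconsistent, and IPF cannot converge
  on an inconsistent constraint set. The pair-constrained model therefore
  uses adjacent-pair marginals only — these are mutually consistent after
  smoothing and imply the single-position marginals.
* Window width. The donor 9-mer space ($4^9$) is fitted on the full
  table; the acceptor 23-mer space ($4^{23}$) cannot be enumerated, so
  the acceptor model is factorized over adjacent-pair blocks and scored
  as a first-order Markov chain. With single-position constraints only,
  both representations reduce exactly to the PWM, which is asserted in
  the tests.
* Training pooling. When two groups are compared, the scoring model is
  trained on the pooled site set. Training on one group alone inflates
  that group's in-sample scores at the small n typical here and biases
  the comparison; pooling makes the finite-sample overfit symmetric. The
  published analysis used a fixed externally trained model, which has the
  same symmetry property; training from user-supplied sites keeps this
  package download-free and organism-agnostic, a documented
  generalization.

**Windowed enrichment.** Content profiles use 30-bp windows; only the
width is prescribed by the source protocol, so the 10-bp step is a
package default (configurable). Genes shorter than a window's end simply
drop out of that window's sample, so window sample sizes vary with outron
length; windows with fewer than 2 genes per group are marked untested.
Fold enrichment uses group means by default (medians optional — the
source does not say which was used). The motif test follows the two-stage
protocol exactly: stage 1 is an upper-tail binomial per window with
$n$ = number of target sequences, $k$ = targets with $\ge 1$ hit starting
in the window and $p$ = background hit fraction (3000 intergenic
sequences in the published protocol; smaller at desk scale); windows with
BH FDR < 0.05 are candidates. Stage 2 is a one-sided Fisher's exact test
of targets against control genes on the candidate windows; a motif is
locally enriched iff at least one window survives at FDR < 0.05. The
formulas count *sequences* with a motif, not hit counts, so presence /
absence per sequence is the implemented definition; the point-probability
formulas are read as the standard upper-tail tests in the enrichment
direction.

**Motif scanning.** PWM scanning reimplements the FIMO approach: the
log-likelihood-ratio score per window, with the score p-value computed
from the exact null distribution of the integer-discretized score under
the background model, by dynamic programming over positions
(discretization: 2000 bins over the total score range). Hits require
p $\le 10^{-4}$ (FIMO's default). A consequence worth knowing: a motif
narrower than 7 nt cannot reach $10^{-4}$ under a uniform background
($4^{-6} \approx 2.4\times10^{-4}$), which mirrors FIMO's behavior.

**Statistical primitives.** Binomial and hypergeometric tails use R's
distribution functions; the Mann–Whitney U test is implemented in the
package because exact p-values with midrank ties are needed at small n:
for $n+m \le 16$ all $\binom{n+m}{n}$ assignments of pooled midranks are
enumerated (exact even under ties), above that a normal approximation
with tie-corrected variance and continuity correction is used. BH
adjustment wraps `p.adjust`.

## The synthetic genome generator

`simConfig()` defaults define the packaged study conditions:

* 200 genes on 2 x 150 kb chromosomes of i.i.d. uniform background
  sequence (uniformity makes the enrichment nulls exact);
* 20% of genes in operons of 2–3 members (same strand, zero intergenic
  gap, every non-first member starting exactly at a TAS);
* 60% of free-standing genes trans-spliced, half with the major TAS at
  the first cis acceptor site (TS-1stAS), half inside the first-exon
  5' UTR (TS-5UTR);
* outron lengths log-normal with median 458 bp (the observed median for
  trans-spliced genes), sdlog 0.4, truncated below at 240 bp so every
  outron contains the planted-bias core — the truncation point and sdlog
  are package choices, since only the median is reported;
* per-gene true ratios $\rho \sim \mathrm{Beta}(2,2)$ (a unimodal,
  symmetric spread over $[0,1]$; the true distribution is not published);
* minor TAS scattered within 50 bp of the major site at geometrically
  decaying tag shares (decay 0.45), each with a planted AG context;
* a 1.5-fold sampling weight on G and T in outron bases of trans-spliced
  genes, stopping 23 nt short of the first acceptor so the
  acceptor-window comparison stays neutral;
* first donor sites of trans-spliced genes degenerate (beyond the
  invariant GT) with probability equal to the gene's $\rho$ — this plants
  both the weaker-donor contrast against non-trans-spliced genes and its
  association with trans-splicing efficiency;
* reads of 50 nt (SL included when present), zero sequencing error by
  default, exact-match 5'-end mapping. The default SL sequence is a
  synthetic 16-mer, AU-rich like the natural leader, not the organism's
  sequence.

What the generator does **not** emulate: sequencing errors beyond a
uniform substitution option, soft-clipped or spliced alignments,
expression-level variation beyond Poisson depth, internal priming or
recapping artifacts beyond simple decoy clusters, isoform complexity
(one transcript of two exons per gene), and base composition structure of
real genomes. Passing tests therefore demonstrate correctness of the
algorithms under their stated assumptions, not performance on real
libraries; with real data the exact-match mapper should be replaced by a
spliced aligner upstream of `clusterTags()`.

## Degenerate inputs and tie-breaks

* Cluster modes tie-break 5'-most on the cluster's strand; so does the
  major-TAS choice (ties are logged).
* "No intergenic distance" for operons is implemented as gap $\le 0$
  (abutting or overlapping), the strict reading implied by the contrast
  with the older <100 bp rule.
* TAS/acceptor coincidence is an exact single-base position match.
* Genes without a measurable TSS (operon-internal members, rejected
  clusters) have an undefined ratio and are excluded from the High/Low
  analysis.
* Stage-1 windows with zero background hit rate but $k>0$ get p-value 0
  (degenerate exact tail); degenerate Fisher margins give p = 1.
* Motif merging aligns at the best ungapped offset by mean per-column
  Pearson correlation (ties resolved toward the longer overlap, which
  keeps periodic motifs stable) and averages members onto the
  lexicographically first motif of each single-linkage cluster, making
  the result order-invariant. The true merging procedure of the source
  is in unpublished supplementary material; this is a documented
  stand-in.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run the pipeline at sizes
chosen to exercise every code path at desk scale: the 200-gene genome at
tag depth $10^3$ for site-calling recovery, 60 genes at depth $10^4$ for
ratio recovery, 1000 random layouts for the operon oracle, 100 simulated
seeds at 200 sites/group for the weak-donor power check, 1000 null
replicates for calibration of the windowed test, and 20 seeds each for
the planted/never-planted motif detection rates. Headline counts from
the original study (thousands of trans-spliced genes, 3000 background
sequences) derive from external archives and are deliberately not
reproduced; every number the package reports is recomputed from its own
simulations.

## Limitations

* The maximum-entropy acceptor model is a factorized approximation;
  scores are comparable within one model but are not MaxEntScan scores.
* The binomial stage-1 test treats the background hit fraction as a known
  proportion, as the published formula does; uncertainty in the
  background is ignored.
* The first-AS location analysis assumes single-intron transcript
  structure suffices to exercise the category logic; deeper intron chains
  are supported by the code (`AS_k`) but not planted by the generator.
* Human-data curation, transcript assembly, peak calling and BLAST-based
  homolog search are out of scope by design.
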