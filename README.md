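# outronscan

Characterization of spliced-leader (SL) trans-spliced genes from 5'-end
sequencing tags.

In tunicates and nematodes, many pre-mRNAs receive the 16-nt 5' exon of
an SL RNA at a trans-splice acceptor site (TAS); the region upstream of
the TAS (the *outron*) is discarded. In a 5'-tag library, reads starting
with the SL sequence pinpoint TAS positions while capped reads pinpoint
transcription start sites (TSSs). `outronscan` turns those two read
populations into a full characterization of trans-spliced genes:

* **Tag calling** — SL-prefix read classification, exact 5'-end mapping,
  single-linkage tag clustering, TAS calling with a strand-aware AG
  acceptor-context filter, TSS calling with ATAC open-chromatin support.
* **Gene classification** — gene-body redefinition from known + novel
  transcripts, operon detection (same strand, zero intergenic gap,
  downstream members starting at a TAS), trans-spliced /
  non-trans-spliced / ambiguous status, major-TAS location categories
  (first-exon 5' UTR, k-th cis acceptor site, ...), the binomial test for
  first-acceptor-site preference, and the per-gene trans-splicing ratio
  ratio = TAS tags / (TAS + TSS tags) with a TS-High/TS-Low split.
* **Splice-site strength** — PWM and maximum-entropy models over donor
  (9 nt, -3..+6) and acceptor (23 nt, -20..+3) windows; log2-odds
  scores; Mann-Whitney group comparisons with BH correction.
* **Local enrichment** — 30-bp sliding-window nucleotide-content tests
  (one-sided Mann-Whitney + BH) and the two-stage local motif
  enrichment test: per-window binomial
  P = C(n,k) p^k (1-p)^(n-k) (upper tail) against intergenic background
  sequences, then one-sided Fisher's exact on candidate windows against
  control genes; a motif is locally enriched iff >= 1 window has
  FDR < 0.05. Motif hits come from a FIMO-style PWM scanner with exact
  DP-computed score p-values; redundant motifs are merged by best-offset
  column correlation.
* **Synthetic benchmark** — a seeded genome generator that plants
  operons, outrons (log-normal, median 458 bp), minor TAS within 50 bp
  of major sites, per-gene Beta-distributed trans-splicing ratios,
  GU-biased outron composition, weak first donors coupled to the
  trans-splicing ratio, motif occurrences, ATAC peaks and decoy
  artifacts — with complete ground truth, so every stage is testable.

## Worked example

```r
library(outronscan)
cfg <- simConfigFromYaml(system.file("extdata", "demo_config.yaml",
                                     package = "outronscan"))
res <- runPipeline(cfg, outDir = "demo-out")
table(res$classification$status)
#> non_trans_spliced     trans_spliced
#>                 8                32
head(subset(res$classification, status == "trans_spliced",
            select = c(gene_id, major_tas, location, group,
                       ts_ratio, ts_class)), 5)
#>     gene_id major_tas        location    group  ts_ratio ts_class
#> 1 gene_0001       532 5UTR_first_exon  TS-5UTR 0.2688172   TS_Low
#> 2 gene_0002      1051         5UTR_nd    other        NA     <NA>
#> 3 gene_0003      2041 5UTR_first_exon  TS-5UTR 0.3762887   TS_Low
#> 4 gene_0004      3641            AS_1 TS-1stAS 0.4884793   TS_Low
#> 5 gene_0005      5029            AS_1 TS-1stAS 0.2835052   TS_Low
```

Each trans-spliced gene carries its most tag-supported (major) TAS, the
location of that site on the transcript (`AS_1` = first cis-splice
acceptor site; `5UTR_first_exon` = first-exon 5' UTR; `5UTR_nd` = 5' UTR
of a transcript whose own 5' end is not a confirmed TSS, e.g.
operon-internal genes), and the estimated trans-splicing ratio where a
TSS was measurable. On this 40-gene demo the windowed G+U content test
flags 16 of 22 outron windows at FDR < 0.05 (the planted outron bias),
while the splice-strength contrast is underpowered at this size — the
power properties are checked at n = 200/group by the acceptance script.
`evaluateAgainstTruth(res$sim, res)` reports recovery against the
planted truth (on this demo: all major TAS at exact coordinates, all
decoy clusters rejected, all gene statuses correct).

The same run from a shell:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml \
    --out demo-out
```

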