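# ClockRegulome

Liver fibrosis is driven by hepatic stellate cells (HSCs) switching from a
quiescent (qHSC) to an activated myofibroblast (aHSC) state. The circadian
transcription factor CLOCK dimerises with BMAL1 and binds E-box motifs
(CACGTG); a dominant-negative CLOCK mutant de-represses its direct targets.
`ClockRegulome` is an R package for epigenomics/regulatory-genomics analysts
that infers a **CLOCK regulome** in HSCs by intersecting three evidence
layers, and ships the supporting analyses around it:

- **Regulome inference** — a gene *g* is called when
  (i) an ATAC-seq peak has concentration ratio `conc_q / conc_a > 2`
  (or the inverse) after a 0.5 pseudocount,
  (ii) the peak sequence contains an E-box by PWM log-odds scanning
  (score ≥ 0.8 · max score, in bits), and
  (iii) *g* is the peak's nearest gene by TSS distance and is >1.5-fold
  up- or down-regulated in CLOCK-mutant cells in the matching state.
  Up in the mutant ⇒ *repressed* by wild-type CLOCK; down ⇒ *activated*.
- **Expression module** — pairwise contrasts (log2FC, pooled t-test,
  Benjamini–Hochberg FDR), the 3×3 direction-pattern clustering (cluster 4 =
  up in mutant & up on activation; cluster 6 = down/down), and primed-gene
  selection (fold > 1.5, p < 0.1).
- **Motif module** — double-strand PWM scanner with N handling, MEME-format
  I/O, and one-sided Fisher motif enrichment.
- **Enrichment module** — exact hypergeometric over-representation of any
  gene list against a GMT collection,
  `p = Σ_{i≥k} C(K,i)·C(N−K,n−i) / C(N,n)`.
- **Rhythm module** — 24 h centred moving-average detrending and
  damped-cosine fitting `A·e^{−λt}·cos(2πt/T + φ)` of bioluminescence
  reporter traces, with a rhythmicity call.
- **Cohort module** — FIB-4 = (age × AST)/(platelets × √ALT), stratification
  by liver stiffness (<8 / 8–15 / >15 kPa) or FIB-4 (<1.3 / 1.3–3.2 / >3.2),
  Kruskal–Wallis with Dunn post-hoc comparisons.
- **Synthetic-data module** — generates every input (annotation, peaks +
  FASTA, six-condition expression, traces, cohort, GMT) with planted ground
  truth and engineered decoys, so the full pipeline is testable end to end.

## Worked example

```r
library(ClockRegulome)

cfg   <- simulationConfig(seed = 1)       # defaults = study conditions
study <- simulateRegulomeStudy(cfg)

ctr   <- standardContrasts(study$expression)
hm    <- peakHasMotif(study$sequences, eboxPWM())
calls <- inferRegulome(study$peaks, study$genes, hm,
                       ctr$mut_q, ctr$mut_a_t0)
head(calls, 4)
#>   gene_id      mode  peak_id   peak_state expression_fold    log2fc            p distance_bp
#> 1   G0006 repressed peak0001 open-in-qHSC        1.672666 0.7421493 0.0109638224         206
#> 2   G0019 repressed peak0002 open-in-qHSC        1.667676 0.7378393 0.0218425015         258
#> 3   G0020 repressed peak0003 open-in-qHSC        2.007756 1.0055840 0.0099290611         248
#> 4   G0031 repressed peak0004 open-in-qHSC        1.781877 0.8333980 0.0008965356         290
table(calls$mode)
#> activated repressed
#>        17        20
```

Each row is one gene with its full evidence chain: the supporting peak, the
cell state in which it is open, the signed mutant-vs-WT linear fold change
and the peak-to-TSS distance. Of the 40 planted regulome genes, 37 are
recovered at this seed (the rest fall under the strict 1.5-fold expression
gate by replicate noise) and none of the 30 engineered decoys is called.

```r
enr <- enrichGeneSets(calls$gene_id[calls$mode == "repressed"],
                      study$gene_sets, universe = study$genes$gene_id)
head(enr[, c("term", "k", "K", "p", "fdr")], 3)
#>          term  k  K            p          fdr
#> 1 SET_PLANTED 17 20 6.772144e-19 1.354429e-17
#> 2      SET009  5 21 4.233274e-02 2.960420e-01
#> 3      SET003  7 36 4.440630e-02 2.960420e-01

fitDampedCosine(study$trace)
#> RhythmFit: period 23.527 h, amplitude 1.012, damping 0.01007/h, phase 0.051 rad
#>   R^2 = 0.9297; rhythmic (band 18-32 h, 865 points, init 30.34 h)
```

The planted gene set dominates the enrichment ranking, and the fitted
period recovers the 23.5 h rhythm the trace was generated with.

```r
grp <- stratifyPatients(study$cohort)           # LSM bands
compareGroups(study$cohort$biomarker, grp)
#> Kruskal-Wallis: H = 74.65 , p = 6.161e-17
#> Groups:
#>         group   n   median       iqr
#>           low 146 50.22432  9.900819
#>  intermediate  19 57.62104  8.794853
#>          high  31 72.26644 11.120337
#> Dunn pairwise (bonferroni-adjusted):
#>        group1       group2         z            p        p_adj
#>           low intermediate -2.623530 8.702367e-03 2.610710e-02
#>           low         high -8.521307 1.577627e-17 4.732881e-17
#>  intermediate         high -3.587656 3.336640e-04 1.000992e-03

round(fib4Score(60, 40, 40, 150), 3)
#> [1] 2.53
```

The serum biomarker rises monotonically across the fibrosis strata and the
cirrhotic (high-LSM) group separates decisively.

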