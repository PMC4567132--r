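# xciscope

Infer the X-chromosome-inactivation (XCI) status of female tumors from
three layers of molecular evidence, and relate it to cancer-testis-antigen
(CTA) expression, global methylation, and clinical outcome.

## The problem

In female cells one X chromosome is transcriptionally silenced (the
inactive X, Xi), its CpG islands methylated and its silencing maintained
by the long noncoding RNA *XIST*. Tumors — notably serous carcinomas with
high copy-number instability — can lose this state in two ways: the Xi can
be partially demethylated while *XIST* is retained ("Xa+", partial
reactivation), or a mitotic segregation error can leave the cell with two
active X chromosomes and no Xi at all ("two Xa": X-wide CpG-island
hypomethylation with low *XIST*, without a compensating whole-X deletion).
Distinguishing these states matters because many immunotherapy-relevant
CTA genes are X-linked and epigenetically controlled.

`xciscope` classifies each tumor into one of three groups —
`preserved_Xi`, `Xa_plus`, `two_Xa` — from:

1. **CpG-island methylation** on chrX (450K-style beta values in [0, 1]):
   samples are stratified by histology and clustered by complete-linkage
   hierarchical clustering (Euclidean distance), and each sample's mean
   X-island beta is classed *hyper* / *partial* / *hypo*;
2. **XIST expression** (log2 RSEM + 1), classed *high* / *low*;
3. **Segmented copy number** (SEG log2 ratios) summarized to arm-level
   calls, which (a) distinguish a true two-Xa state from a whole-Xi
   deletion, and (b) drive an override: a sample whose *selective*
   arm-level hypomethylation coincides with a deletion of the same arm
   lost that arm of its **Xi** — the remaining Xi is intact, so the sample
   is reassigned to `preserved_Xi`.

Downstream stages compare CTA panel expression (mean of log2(RSEM+1) over
the panel) and global autosomal CpG-island methylation across groups
(Welch t-test / one-way ANOVA with the usual `NS` / `*` / `**` / `***`
bands), cross-tabulate clinical covariates against the groups with an
exact r×c (generalized Fisher) test, and run Kaplan–Meier/log-rank and
stage-adjusted Cox proportional-hazards survival models.

Because cohort-scale inputs are not shipped, the package includes a
synthetic-cohort generator (`simulate_xci_cohort()`) with known
ground-truth XCI states, matched SEG/methylation arm-deletion signatures,
methylation-coupled CTA expression, and stage-confounded survival, so the
entire pipeline is testable by parameter recovery.

## Worked example

```r
library(xciscope)

co  <- simulate_xci_cohort(xci_sim_config(seed = 1))   # 360 samples
fit <- xci_classify(co$methylation, co$manifest, co$clinical,
                    seg = co$seg, expression = co$expression)
print(fit)
```

```
XCI status classification (sample-level assignment, k = 3 per stratum, 500 X-island probes)

               preserved_Xi two_Xa Xa_plus
  endometrioid           60     60      60
  serous                 60     60      60

 6 sample(s) rescued by the Xi-arm-deletion override
```

All 360 calls match the generator's ground truth here, and the six
simulated Xi-arm-deletion tumors — whose one arm is hypomethylated *and*
deleted while *XIST* stays high — are pulled back into `preserved_Xi` by
the override (`override_applied = TRUE` in `as.data.frame(fit)`).

Clinical cross-tabulation and the exact test:

```r
fisher_exact_rxc(rbind(c(232, 49), c(19, 33), c(25, 13)))$p_value
#> 8.394646e-11
```

Survival, stage-adjusted:

```r
d   <- simulate_survival(400, xci_hr = 1.6)
cox <- cox_stage_adjusted(d$time, d$event, d$xci_group, d$stage)
print(cox)
#>               term               hr        p
#>           stageIII 4.39 (3.07-6.26) 3.58e-16
#>            stageIV 5.21 (3.14-8.65) 1.62e-10
#>  xci_groupXa_plus 1.54 (1.04-2.28) 3.14e-02
#>   xci_grouptwo_Xa 1.71 (1.14-2.57) 9.73e-03
```

The whole flow (simulate → classify → associate → outcomes) runs from one
YAML config via `run_xci_pipeline()` or the thin CLI at
`inst/cli/xciscope.R`.

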