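# emtlnc

Epithelial–mesenchymal transition (EMT) is a reversible shift of epithelial
tumor cells toward a migratory, therapy-resistant mesenchymal state. `emtlnc`
quantifies this "EMTness" from bulk or single-cell expression matrices using
long non-coding RNAs (lncRNAs) anchored to the five canonical EMT markers —
VIM, FN1, SNAI1, SNAI2 (mesenchymal) and CDH1 (epithelial) — and carries the
score through the downstream analyses a tumor-plasticity study needs:
survival association, protein-correlation screens and drug-sensitivity
screens. It is aimed at computational biologists working with TCGA-style
expression + clinical tables, RPPA-style protein matrices and cell-line IC50
panels.

## The model

**Signature derivation.** Every candidate lncRNA g is profiled by Spearman
correlation against the marker panel across samples. A candidate is

- *mesenchymal* if rho(g, VIM) > 0.35, rho > 0.1 with at least two of
  FN1/SNAI1/SNAI2, and rho(g, CDH1) < −0.2;
- *epithelial* if rho(g, CDH1) > 0.35, negative rho with at least two of
  FN1/SNAI1/SNAI2, and rho(g, VIM) < −0.2.

Each selected lncRNA gets the weight

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>g</sub> = rho(g, CDH1) + rho(g, VIM)*

which is positive for mesenchymal and negative for epithelial lncRNAs.

**EMT score.** For sample *s* with expression *x<sub>g,s</sub>* (FPKM-like),

&nbsp;&nbsp;&nbsp;&nbsp;*EMT<sub>s</sub> = Σ<sub>g</sub> w<sub>g</sub> · x<sub>g,s</sub>*

Higher scores mean a more mesenchymal sample. The published 15-coefficient
signature (14 mesenchymal lncRNAs with weights 0.04–0.18 plus RP4-568C11.4
with weight −0.048) ships with the package: `published_signature()`.

Samples are stratified at score quartiles into Epithelial,
Epithelial-Mesenchymal, Mesenchymal-Epithelial and Mesenchymal classes (or
three classes with the middle quartiles merged, as for cell-line panels), and
the score feeds Kaplan–Meier / log-rank comparisons, univariate and
multivariate Cox regression, an EMT-score × protein screen (|rho| > 0.2,
FDR 0.05) and an IC50 drug screen (|rho| ≥ 0.15, sign split, Fisher exact
enrichment).

A synthetic cohort generator (`default_emt_spec()`, `simulate_emt_cohort()`)
draws a latent EMT level per sample, plants marker/lncRNA/protein/drug
loadings on it and attaches proportional-hazards survival, so every stage is
testable against known ground truth.

## Worked example

```r
library(emtlnc)

spec   <- default_emt_spec()                 # 4 cancer types x 500 samples
cohort <- simulate_emt_cohort(spec, seed = 1)

candidates <- setdiff(cohort$expression$feature, marker_panel())
sig <- derive_signature(cohort$expression, candidates = candidates)
#> selected 15 of 215 candidate(s) (14 mesenchymal, 1 epithelial)
head(sig, 3)
#>   lncrna        emt_class   weight
#> 1 RP11-404O13.1 mesenchymal  0.242
#> 2 RP11-383H13.1 mesenchymal  0.232
#> 3 AC108463.1    mesenchymal  0.211

scores <- assign_classes(score_samples(cohort$expression, sig))
table(scores$emt_class)
#>             Epithelial Epithelial-Mesenchymal Mesenchymal-Epithelial
#>                    500                    500                    500
#>            Mesenchymal
#>                    500

clin <- dplyr::left_join(cohort$clinical, scores, by = "sample")
tidy(cox_fit(clin, "score"))
#>   term  estimate hazard_ratio conf.low conf.high  p.value     n n_event
#> 1 score  0.00558         1.01     1.00      1.01 4.84e-13  2000    1401

spearman_rho(scores$score, cohort$truth$latent$latent)
#> [1] 0.9702675
```

All 15 planted lncRNAs are recovered with their planted class; the hazard
ratio per score unit is above 1 (higher EMT, shorter survival — the score
spans tens of units, so 1.01/unit is a strong effect), and the derived score
tracks the generating latent EMT axis at Spearman rho 0.97.

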