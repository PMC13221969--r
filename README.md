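# brainmetsig

Consensus discovery of transcriptomic signatures shared by brain metastases
of different primary cancers.

## The problem

Metastatic tumor cells carry two overlapping transcriptional imprints: their
tissue of origin and the organ they colonize. In expression data from
metastasis biopsies the tissue-of-origin signal dominates — samples cluster
by tumor type, not by metastatic site — so asking "what do brain metastases
have in common?" across breast cancer, melanoma and lymphoma requires a
workflow that controls for cancer type at every step. `brainmetsig`
implements such a workflow for gene-by-sample log2 expression matrices with
a three-group design (group 1: brain-metastasis biopsies; group 2:
extra-cerebral biopsies from patients with brain metastases; group 3:
extra-cerebral biopsies from patients without), as collected in a
133-sample, three-cancer cohort. It is aimed at translational researchers
studying organ tropism who need the full chain — normalization, selection,
confirmation, external validation, and the bench-side quantification
statistics — reproducible from one seed.

## The method

1. **Preprocess** — quantile normalization (limma), optional probe→gene
   median collapse, and gene-wise removal of nuisance covariates (RIN as a
   centered continuous covariate, center as categorical; aliased columns
   detected and dropped).
2. **Cross-type filter** — among brain samples only, remove genes whose
   expression differs across cancer types (Kruskal-Wallis, χ² with 2 df,
   Bonferroni or raw-p mode).
3. **Per-type SAM** — within each cancer type, score brain vs
   extra-cerebral with the modified t statistic
   `d_g = (x̄_brain − x̄_extra) / (s_g + s0)`, where `s_g` is the unequal-n
   pooled SE and the fudge factor `s0` minimizes the coefficient of
   variation of the spread of `d` across windows of `s`. Empirical
   q-values come from seeded label permutations (1000 per type by
   default): `q_g = π̂0 · mean_perm #{|d*| ≥ |d_g|} / #{|d| ≥ |d_g|}`,
   monotone-enforced.
4. **Consensus** — genes with `q ≤ 0.05` and concordant fold-change sign
   in *all three* types; up-regulated genes ranked by the median of their
   per-type d-scores.
5. **GLM confirmation** — per gene, logistic (location ~ expression) and
   Gaussian (expression ~ location) models adjusted for type and center,
   BH-corrected Wald tests.
6. **Meta-analysis** — per-gene fixed-effects inverse-variance pooling of
   external log2 fold changes, `w = 1/SE²`, pooled
   `SE = (Σw)^(−1/2)`, Wald Z, 95% CI, plus a signature concordance
   report.

A seeded synthetic-cohort generator reproduces the study design (133
samples: 13/11/5 brain and 45/51/8 extra-cerebral across breast, melanoma,
lymphoma) with planted shared signature genes and known nuisance effects,
so every stage can be tested against ground truth. Downstream validation
statistics — 2^−ΔΔCt relative quantification, IHC scoring (intensity grade ×
percentage code, max 12), Cohen's κ, Mann-Whitney with exact small-sample
enumeration, Pearson correlation, metastatic surface-area ratios — are
included.

## Worked example

```r
library(brainmetsig)

cfg <- cohort_config(seed = 11, signature_log2fc_range = c(2, 6.5))
cohort <- generate_cohort(cfg)
res <- run_pipeline(run_config(n_perm = 1000, seed = 11, run_glm = FALSE),
                    m = cohort$matrix, meta = cohort$metadata)
head(res$signature[, c("gene_id", "rank", "median_sam_score", "direction")])
```

```
     gene_id rank median_sam_score direction
1 gene_14747    1         7.388875        up
2 gene_13826    2         7.187115        up
3 gene_11179    3         6.871845        up
4 gene_13097    4         6.869841        up
5 gene_06951    5         6.751020        up
6 gene_07136    6         6.696621        up
```

On this seed the consensus contains 21 up-regulated genes (all 21 planted,
no false positives; 2 of the 23 planted genes fall below the q ≤ 0.05 bar
in the small lymphoma contrast) and 2 of the 3 planted down-regulated
genes. The per-type fudge factors chosen by the CV rule were 0.46 (breast),
0.48 (melanoma) and 1.10 (lymphoma), recorded in `res$manifest$s0`.

Pooling two external effect estimates for one gene:

```r
eff <- data.frame(dataset_id = c("a", "b"), gene_id = "KLK6",
                  log2fc = c(1.0, 2.0), se = c(0.5, 1.0))
pool_fixed_effects(eff)
```

```
  gene_id n_datasets_present weight_sum pooled_log2fc pooled_se        z
1    KLK6                  2          5           1.2 0.4472136 2.683282
            p    ci_low  ci_high
1 0.007290358 0.3234614 2.076539
```

The weights are 4 and 1, so the pooled fold change is 1.2 with
SE = 5^(−1/2) ≈ 0.447 — the gene is confirmed up-regulated (Z ≈ 2.68,
p ≈ 0.007).

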