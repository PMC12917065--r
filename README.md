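# quadtil

Quadrat-based spatial coupling of CD8+ tumor-infiltrating lymphocytes
(TILs) and cancer cells, with downstream treatment contrasts and
survival analysis.

## The problem

In pancreatic ductal adenocarcinoma (PDAC), the *density* of CD8+ T
cells is an incomplete readout of immune surveillance: what matters is
how tightly the T cells track the local cancer-cell population.
Image-analysis platforms can export the coordinates of every annotated
cancer cell and CD8+ cell on a resected slide; `quadtil` turns those
coordinate tables into a per-patient *spatial coupling* statistic and
relates it to neoadjuvant therapy (NAT) and overall survival.

The pipeline, mirroring routine digital-pathology practice:

1. keep only CD8+ cells within 50 um of a tumor gland (the TILs);
2. exclude subjects with fewer than 10 cancer or 10 CD8 cells;
3. rescale coordinates 1:1000 (um to mm) and count both cell classes on
   a 500 um x 500 um quadrat grid, discarding quadrats empty of both;
4. per subject, fit the negative-binomial GLM

   cd8_j ~ NB(mu_j, theta),  log mu_j = alpha + beta * cancer_j

   over active quadrats j. The slope `beta` is the coupling statistic:
   by the log link, n extra cancer cells in a quadrat multiply the
   expected CD8 count by exp(n * beta) (the *fold change*);
5. contrast arms at the cohort level — OLS on log(beta) with clinical
   covariates, OLS on the quadrat-wise SD of cancer counts
   (intratumoral heterogeneity), and an NB mixed model with a
   cancer-count x treatment interaction and subject random intercepts;
6. split the cohort at the median beta and test the grouping in
   Kaplan-Meier curves and a multivariate Cox model (Efron ties).

Because slide-level coordinate data are rarely shareable, the package
includes a synthetic-cohort generator (`simulate_cohort()`) with known
ground truth: Thomas-cluster cancer patterns (gland-like clumps), CD8
counts drawn from the exact quadrat-level NB law, cohort-like clinical
covariates, and proportional-hazards survival. Every pipeline stage is
validated against it.

## Worked example

```r
library(quadtil)

coh <- simulate_cohort(seed = 1, n_inadequate = 5)   # 66 subjects, 5 deficient
res <- run_pipeline(patterns_to_cell_table(coh$patterns), coh$clinical,
                    out_dir = "quadtil_out", quiet = TRUE)

med <- attr(res$table, "arm_medians")
cat(sprintf("arm medians: naive %.4f  NAT %.4f\n", med["naive"], med["NAT"]))
cat(sprintf("fold change per 10 cancer cells: naive %.2f  NAT %.2f\n",
            fold_change(med[["naive"]], 10), fold_change(med[["NAT"]], 10)))
print(res$km_groups)
```

prints (numbers from this exact run):

```
arm medians: naive 0.0067  NAT 0.0160
fold change per 10 cancer cells: naive 1.07  NAT 1.17
Kaplan-Meier fit by slope_group
       group  n events   median    lower    upper
  LowerSlope 30     24 894.9390 324.0668 1191.978
 HigherSlope 31     21 948.3561 276.6346 1799.620
```

Reading: 61 of 66 simulated subjects pass the cell-count rule; the NAT
arm's median coupling slope (0.0160) is about twice the naive arm's
(0.0067), i.e. 10 extra cancer cells in a quadrat come with a 17% rise
in expected CD8 count in NAT patients versus 7% in naive ones. The
written `quadtil_out/report.txt` adds the covariate-adjusted contrasts
(log-slope ratio 1.62, p = 0.04; NAT quadrat-SD reduction 12.1), the
mixed-model fixed effects, and the median-split Cox hazard ratio with
its confidence interval.

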