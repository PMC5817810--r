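# npcmiR

miRNA-based molecular subtyping and distant-metastasis risk modelling for
nasopharyngeal carcinoma (NPC).

NPC cohorts profiled for microRNA expression show reproducible molecular
subtypes, one of which — marked by loss of tumor-suppressor miRNAs and an
epithelial–mesenchymal-transition phenotype — carries a markedly worse
distant-metastasis-free survival (DMFS). `npcmiR` implements the complete
analysis that discovers such subtypes and turns them into a prognostic
model, for bioinformaticians who want each stage as a tested, reusable
function:

* **Discovery** — subsampled consensus clustering (1000 iterations, 0.9
  subsampling, average linkage on Pearson distance `1 − r`) of the top-300
  most variable miRNAs (median absolute deviation), cluster count chosen by
  the gap statistic `gap(k) = E*[log W_k] − log W_k`, and restriction to
  core samples with positive silhouette width `s(i) = (b−a)/max(a,b)`.
* **Classification** — compact signature via one-vs-rest SAM
  (`d = Δmean/(s + s0)`, permutation FDR < 0.01) plus a Mann–Whitney AUC
  separation filter (> 0.9), then a linear SVM whose calls transfer to new
  cohorts after per-cohort centering.
* **Risk modelling** — subtype-vs-rest differential expression
  (|log2FC| > 1, BH-adjusted p < 0.05), univariate Cox screening
  (Wald p < 0.05), a multivariate Cox proportional-hazards model
  `h(t|x) = h₀(t)·exp(β·x)`, and median risk-score stratification into
  high/low DMFS-risk groups with hazard ratios and log-rank tests; plus a
  harness comparing competing signatures under frozen coefficients.
* **Synthetic cohorts** — a generator planting known subtypes, marker
  effects, batch effects and proportional-hazards survival, so every stage
  is validated against ground truth without any data download.

Batch correction (ComBat), survival fitting (`survival`), moderated tests
(`limma`) and the SVM (`e1071`) use the standard packages; the consensus,
gap, SAM and signature machinery is implemented here and checked against
brute-force oracles in the test suite.

## Worked example

Discover subtypes on a planted three-subtype cohort (90 tumors × 300
miRNAs, marker effect ±2 log2 units, residual sd 0.5):

```r
library(npcmiR)

mk <- list(marker_spec("S1", sprintf("mir%04d", 1:10),  2),
           marker_spec("S2", sprintf("mir%04d", 11:20), -2),
           marker_spec("S3", sprintf("mir%04d", 21:30),  2))
coh <- simulate_cohort(90, 300, c(S1 = 0.4, S2 = 0.35, S3 = 0.25),
                       markers = mk, noise_sd = 0.5,
                       spec = survival_spec(0.03, beta = c(0.2, 1.1),
                                            censor_time = 60),
                       hazard_by = "subtype", seed = 42)
run <- run_discovery(coh$expression, pipeline_config(seed = 42))
run$gap
#> gap statistic over k = 2..6 ( 50 reference sets ):  chosen k = 3
#>  k   logW    gap     se
#>  2 3.6414 0.0944 0.0038
#>  3 3.4947 0.2233 0.0046
#>  4 3.4816 0.2189 0.0054
#>  5 3.4666 0.2154 0.0052
#>  6 3.4509 0.2124 0.0055
table(run$labels, coh$labels)
#>        S1 S2 S3
#>   NPC1 36  0  0
#>   NPC2  0 31  0
#>   NPC3  0  0 23
```

The gap curve peaks at k = 3 (the planted count), the 30 planted markers
are exactly the selected signature, and the classifier reproduces the
hidden labels. The model can be frozen to JSON
(`write_subtype_model(run$model, "model.json")`) and applied to any cohort
containing the signature (`run_classify("model.json", new_expr)`).

Build the metastasis-risk model on a two-subtype cohort whose hazard
follows a score over the suppressed markers:

```r
mk2 <- list(marker_spec("S1", sprintf("mir%04d", 1:6),  2),
            marker_spec("S2", sprintf("mir%04d", 7:12), -2))
coh2 <- simulate_cohort(300, 80, c(S1 = 0.5, S2 = 0.5), markers = mk2,
                        noise_sd = 0.5,
                        spec = survival_spec(0.04, beta = -0.4,
                                             censor_time = 60),
                        hazard_by = "score",
                        score_features = sprintf("mir%04d", 7:12),
                        score_weights = 0.25, seed = 7)
labels <- setNames(as.character(coh2$labels), names(coh2$labels))
rr <- run_risk_model(coh2$expression, coh2$clinical, labels,
                     risk_class = "S2", pipeline_config(seed = 7))
rr$stratification
#> risk stratification at cutoff -3.402: 150 high / 150 low
#>   HR (high vs low) 3.59 (95% CI 2.73-4.72), log-rank p = 2.88e-22
```

All 12 subtype markers pass the differential screen (|log2FC| > 1,
adjusted p < 0.05) and the univariate Cox filter, and the median split of
the fitted risk score separates distant-metastasis hazard about 3.6-fold —
the planted group hazard ratio is ~e^1 per score unit, so this is the
expected order. See `?evaluate_signature` for comparing alternative
signatures on the same cohorts with frozen coefficients and cutoff.

The methods vignette (`vignettes/npcmiR-methods.Rmd`) documents the models,
the defaults and every place a convention had to be chosen.

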