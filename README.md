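# methrisk

DNA-methylation marker discovery and composite carcinogenic-risk
classification for non-alcoholic steatohepatitis (NASH).

## The problem

NASH is now a leading precancerous condition for hepatocellular carcinoma
(HCC), but surveillance of every NASH patient is impractical. Tissue from
patients in whom HCC has already arisen (NASH-W) carries DNA-methylation
alterations, relative to normal liver tissue (NLT), that are established at
the precancerous stage and inherited or strengthened in the tumour itself —
so methylation status of a liver biopsy can flag patients at high
carcinogenic risk before a tumour is detectable. `methrisk` implements the
full analytical chain for building and applying such risk criteria:

1. **Probe QC** — drop array probes with detection call proportion < 90%
   (commonly polymorphism artefacts) and all probes on chromosomes X/Y.
2. **Differential screen** — per-probe Welch's unequal-variance *t* test of
   β values (NASH-W vs NLT), Bonferroni-corrected, with an effect gate
   |Δβ| > 0.1 where Δβ = mean β(NASH-W) − mean β(NLT).
3. **Stage-trend filter** — Jonckheere–Terpstra test that the alteration is
   monotone along NLT → NASH-W → tumour, in the direction of Δβ. The
   statistic is the concordant cross-group pair count
   J = Σ_{g<h} #{(x∈g, y∈h) : y > x} (+ ½ per tie).
4. **Marker panel selection** — ROC analysis (AUC = Mann–Whitney
   P(case > control)); stage 1 keeps probes with AUC > 0.95 vs NLT and
   fixes each cutoff at the Youden-index maximiser
   (J = sensitivity + specificity − 1); stage 2 keeps markers with ≥ 85%
   specificity against NASH tissue from patients *without* HCC (NASH-O),
   so the panel estimates risk within the disease population.
5. **Logistic risk model** — odds of HCC coincidence from ballooning,
   Brunt fibrosis stage and marker methylation, with separation detection.
6. **HPLC quantification** — anion-exchange chromatograms of bisulfite-PCR
   products are baseline-corrected, deconvolved into exponentially
   modified Gaussian peaks (1 vs 2 components by corrected AIC; bimodal /
   shoulder / single patterns by a valley rule), and converted to relative
   methylation rates through the affine standard curve
   percent(rt) = 100·(rt − rt₀)/(rt₁₀₀ − rt₀) anchored on the 0% and 100%
   methylated control products of the same run; multi-peak rates are the
   area-weighted mean of per-component rates.
7. **Composite risk call** — a sample is carcinogenic-risk-positive when at
   least *k* of *n* marker criteria are satisfied (2 of 3 in the validated
   design).

Because the underlying patient data are not redistributable, the package
ships a first-class synthetic-data module: group-structured β-value
cohorts with planted hyper/hypo differential probes and stage trends, and
chromatograms with known component rates, so every stage is testable
against ground truth.

## Worked example

```r
library(methrisk)

cfg <- pipeline_config(
  cohort = cohort_config(
    group_sizes = c("NLT" = 12, "NASH-O" = 15, "NASH-W" = 10, "T" = 10),
    n_probes = 2000, n_differential = 12, seed = 7),
  max_hplc_markers = 3,
  hplc = chrom_spec(noise_sd = 0.002, seed = 107))
res <- run_pipeline(cfg)
res
#> Methylation risk pipeline
#>   probe cascade: probes_input=2000, probes_retained=1949,
#>     probes_differential=12, probes_trend=12, probes_auc_stage=12,
#>     panel_markers=12, hplc_markers=3
#>   composite call: sensitivity 100.0%, specificity 100.0%

res$performance
#> Composite risk call: sensitivity 100% (n=10), specificity 100% (n=12)
#> Samples by number of satisfied marker criteria:
#>           0  1  2  3
#>   NLT    12  0  0  0
#>   NASH-W  0  0  0 10
```

Reading the output: of 2000 simulated probes, 1949 survive QC (low-call and
sex-chromosome probes removed); all 12 planted differential probes — and no
null probe — pass the Welch/Bonferroni/Δβ screen, the stage-trend filter
and both panel gates; the three highest-AUC markers are quantified from
simulated chromatograms and the 2-of-3 composite rule separates the ten
NASH-W samples from the twelve NLT samples completely (the histogram rows
count samples by how many marker criteria they satisfy). Per-marker output
looks like:

```r
head(res$panel$entries[, c("marker_id", "cutoff", "direction", "auc")], 3)
#>    marker_id    cutoff direction auc
#> 1 cg00000125 0.7870651      hypo   1
#> 2 cg00000249 0.3033083      hypo   1
#> 3 cg00000377 0.4853012     hyper   1
```

Each stage is equally usable on its own (`filter_probes()`,
`welch_screen()`, `jonckheere_terpstra()`, `roc_auc()`, `youden_cutoff()`,
`select_panel()`, `multivariate_risk_model()`, `fit_peaks()`,
`calibrate()`, `methylation_rate()`, `classify_cohort()`), and all
artifacts have plain-text readers/writers (`read_beta_matrix()`,
`read_panel()`, `read_chromatogram()`, ...).

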