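# cohgraph

Coherence-based weighted graph analysis of resting-state EEG, built
for two-group clinical comparisons such as discriminating amnestic
from non-amnestic mild cognitive impairment (aMCI vs naMCI). The
package takes multichannel epoched EEG (EDF or plain-text epoch
matrices; the reference geometry is the 19-electrode 10–20 montage,
200 Hz, ten 2-s epochs per subject) and runs the complete analysis:

1. **Connectivity** — magnitude-squared coherence between all channel
   pairs, `COH_xy(f) = |S_xy(f)|² / (S_xx(f) S_yy(f))`, estimated by
   epoch-averaged Hann-tapered cross-spectra and averaged over the
   canonical bands (delta 0.1–4, theta 4–8, alpha 8–13, beta 13–30,
   gamma 30–50 Hz) into one weighted adjacency matrix per band.
2. **Graph measures** — twelve global weighted measures per subject ×
   band: average degree, average strength, radius, diameter,
   characteristic path length, global efficiency, local efficiency,
   clustering coefficient, transitivity, Louvain modularity,
   assortativity, small-worldness (Maslov–Sneppen nulls). Connection
   lengths are inverse weights; all deterministic measures are
   validated against brute-force oracles, Louvain against exhaustive
   partition enumeration.
3. **Group statistics** — two-sided permutation tests (5000
   relabelings, exact enumeration for tiny groups) on every measure ×
   band, Benjamini–Hochberg FDR across the family, plus Pearson
   correlations of selected measures with cognitive scores.
4. **Classification** — logistic regression, linear SVM, random
   forest, gradient boosting, neural network and naive Bayes on the
   selected graph measures plus sex and MMSE, under 10 stratified
   70/30 splits, reporting precision, recall, accuracy, F1 and AUC.

Because clinical EEG of this kind is rarely shareable, the package
ships a synthetic cohort generator (`synth_config()`,
`generate_cohort()`) with band-specific modular coupling, planted
group effects and a latent-trait covariate model, so the entire
pipeline is testable end to end with known ground truth. See
`vignettes/coherence-networks.Rmd` for the model and every design
choice.

## Worked example

```r
library(cohgraph)

# a synthetic two-group cohort: group B's beta-band intra-module
# coupling is raised by the documented planted effect 0.2
cfg <- synth_config(n_per_group = 30,
                    group_effect_intra = c(beta = 0.2), seed = 1)
cohort <- generate_cohort(cfg)

config <- default_config()            # bands, 5000 permutations, FDR 0.05
metrics <- cohort_metrics(cohort$subjects, config)
res <- compare_groups(metrics, cohort$covariates, config)
subset(res, significant, c(measure, band, mean_A, mean_B, p_fdr))
```

```
                  measure  band mean_A mean_B    p_fdr
38               strength  beta 3.2588 4.1171 0.001714
42      global_efficiency  beta 0.1827 0.2323 0.001714
43       local_efficiency  beta 0.1621 0.1849 0.001714
44 clustering_coefficient  beta 0.3902 0.3171 0.001714
45           transitivity  beta 0.3902 0.3171 0.001714
46             modularity  beta 0.2245 0.3337 0.001714
47          assortativity  beta 0.2106 0.4157 0.001714
...
```

The planted coupling shift surfaces exactly where it should: the
beta-band measures move together (modularity 0.22 → 0.33 in the
affected group) and survive FDR at the permutation floor, with only
borderline hits elsewhere. Then:

```r
features <- build_features(metrics, cohort$covariates,
                           c("modularity_beta", "radius_gamma",
                             "sex", "mmse"))
report <- evaluate_classifiers(features, config)
report[, c("classifier", "precision", "recall", "accuracy", "f1", "auc")]
```

gives one row per classifier with the four confusion-matrix metrics
(pooled over the 10 splits) and AUC:

```
         classifier precision recall accuracy    f1   auc
1          logistic     0.989  0.989    0.989 0.989 1.000
2               svm     1.000  1.000    1.000 1.000 1.000
3     random_forest     1.000  1.000    1.000 1.000 1.000
4 gradient_boosting     1.000  0.911    0.956 0.953 0.956
5    neural_network     1.000  1.000    1.000 1.000 1.000
6       naive_bayes     1.000  1.000    1.000 1.000 1.000
```

(near-perfect separation is expected here: the synthetic effect size
was chosen for testability, not clinical realism).

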