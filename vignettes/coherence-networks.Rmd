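---
title: "Coherence-based EEG networks: model, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-based EEG networks: model, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cohgraph implements a complete resting-state EEG connectivity analysis
for two-group clinical comparisons (its motivating use case is
discriminating amnestic from non-amnestic mild cognitive impairment):
magnitude-squared coherence between all channel pairs in canonical
frequency bands, twelve global measures of the resulting weighted
graphs, permutation tests with false-discovery-rate control,
correlations between network measures and cognitive scores, and a
six-classifier benchmark on the selected measures. Because clinical
EEG of this kind is rarely shareable, the package also ships a
synthetic cohort generator with known band-specific network structure;
every downstream stage is tested against it and against brute-force
oracles.

## Data model

An `epoch_set` holds one subject's recording as `n_epochs x n_channels
x n_samples` in microvolts. The reference geometry is the classic
19-electrode 10-20 montage sampled at 200 Hz with ten 2-s epochs per
subject; nothing in the code depends on those numbers beyond defaults.
Readers exist for EDF (each data record is decoded, converted to
microvolts via the physical-dimension field, concatenated and re-cut
into non-overlapping 2-s windows, dropping any trailing remainder) and
for a plain-text epoch matrix format that round-trips losslessly.
Channel order is always canonicalized to a configured label list so
adjacency matrices are comparable across subjects. Reference montage
is deliberately out of scope: signals are analysed as recorded, and
coherence values inherit whatever referencing the amplifier applied.

## Coherence estimation

For channels $x, y$ the magnitude-squared coherence is

$$\mathrm{COH}_{xy}(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

with $S_{xy}$ the cross-spectral density. We estimate $S$ by Welch's
method with one segment per epoch: each epoch is Hann-tapered and
Fourier-transformed, and cross-products are averaged across the $K$
epochs. Sub-segmenting 2-s epochs would destroy the 0.5 Hz resolution
the delta band needs, so the degrees of freedom come entirely from the
epoch count; $K = 1$ makes coherence identically 1 and is refused.

Band graphs average $\mathrm{COH}_{xy}(f)$ over the FFT bins inside a
half-open interval $[f_{\text{low}}, f_{\text{high}})$, DC always
excluded; the default bands are delta 0.1–4, theta 4–8, alpha 8–13,
beta 13–30 and gamma 30–50 Hz, so on the 0.5 Hz grid delta effectively
starts at 0.5 Hz. An alternative found in the literature — time-domain
bandpass filtering before coherence — is not implemented: averaging
the full coherence spectrum over in-band bins is mathematically
equivalent in expectation and avoids filter edge artifacts. With $K$
independent epochs the coherence of truly independent channels has
expectation close to $1/K$ (about 0.1 at the default ten epochs); this
positive bias floor is a property of the estimator and is calibrated
empirically in the test suite.

## The twelve graph measures

Each band graph is a dense symmetric weighted adjacency $W \in [0,1]$,
zero diagonal; no thresholding is applied by default (an optional
`edge_threshold` exists because published average degrees near 10–12
on 19 electrodes imply some upstream sparsification, which we do not
attempt to reverse-engineer). Conventions follow the weighted variants
standard in brain-connectivity toolboxes:

* **degree, strength** — mean count of incident edges (weight > 0) and
  mean incident weight. On dense coherence graphs degree is constant
  at $N-1$.
* **distances** — connection length $1/W_{ij}$, all-pairs Dijkstra;
  disconnected pairs are infinite, excluded from the characteristic
  path length, contribute zero to efficiency, and eccentricities use
  finite distances only.
* **radius, diameter, characteristic path length, global efficiency**
  — minimum/maximum eccentricity, mean finite distance, mean inverse
  distance.
* **clustering, transitivity** — geometric-mean (Onnela) triangle
  intensities with weights rescaled by the maximum, normalised per
  node by $k(k-1)$ or globally by total triples.
* **local efficiency** — cube-root weighted convention: inverse
  shortest-path distances among a node's neighbours computed on
  cube-rooted connection lengths, weighted by
  $(w_{ij} w_{ih})^{1/3}$.
* **modularity** — weighted Newman $Q$ maximised by our Louvain
  implementation with 10 randomised restarts (resolution $\gamma = 1$);
  the one-module partition ($Q = 0$) is always admissible, so reported
  $Q \ge 0$. At 19 nodes Louvain matches exhaustive partition
  enumeration in ≥ 90% of random instances and never exceeds it.
* **assortativity** — Pearson correlation of endpoint strengths across
  edges, each edge weighted by its weight; regular graphs have
  undefined correlation, reported as 0 with a warning.
* **small-worldness** — $\sigma = (C/\langle C_{\text{null}}\rangle) /
  (L/\langle L_{\text{null}}\rangle)$ with 20 Maslov–Sneppen
  degree-preserving rewired nulls (10 swap attempts per edge) that
  retain the weight multiset.

Two structural facts about *dense* coherence graphs matter for
interpretation: degree is exactly $N-1$ for every subject, and a
complete graph admits no degree-preserving rewiring, so the null
networks equal the original and $\sigma \equiv 1$. Both measures are
therefore constants across subjects at threshold 0; the group
comparison flags them as degenerate rather than pretending to test
them. They become informative as soon as a positive edge threshold is
configured.

All deterministic measures are validated against independent
brute-force oracles (Floyd–Warshall distances, exhaustive triangle
enumeration, direct weighted correlations) to 1e-9 on random graphs of
up to 8 nodes; Louvain against exhaustive enumeration of all set
partitions; path-based hot loops run in C++ because the calibration
experiments below touch tens of thousands of graphs.

## Group statistics

Every measure × band cell is compared between the two groups with a
two-sided permutation test on the difference of means: the pooled
subjects are relabelled either exhaustively (automatic whenever
$\binom{n_A+n_B}{n_A} \le 10^4$, giving exact p values) or by 5000
random relabelings with the small-sample correction
$p = (1 + \#\{|d_{\text{null}}| \ge |d_{\text{obs}}|\})/(B+1)$.
The family of all 60 tests is then adjusted by
Benjamini–Hochberg; the FDR family is configurable since published
analyses rarely state it. Cells with zero pooled variance (the dense
degree and small-worldness constants) are flagged `degenerate`, carry
$p = 1$, and are never significant. Correlations between selected
measures and cognitive scores are plain Pearson tests, reported
unadjusted, mirroring common practice.

## Synthetic cohorts

Each channel $c$ in band $b$ is a mixture of band-limited,
unit-variance Gaussian latent oscillators,

$$x_c = \sum_b \alpha_b\, s_{\text{module}(c), b} + \beta_b\, s_{\text{global}, b} + \varepsilon,$$

with fresh latents per epoch, white sensor noise $\varepsilon$, and
FFT-masked white noise as the band-limiting device (pure sinusoids
would make coherence estimation degenerate). Intra-module coupling
$\alpha_b$ drives within-module coherence, $\beta_b$ drives global
coherence; group B's couplings can be shifted additively per band, and
each subject deviates from its group coupling by a per-band jitter
(SD 0.05) on which the cognitive scores load linearly — so correlation
recovery is a testable property with known ground truth
(`true_jitter`). Default couplings ($\alpha = 0.4$, $\beta = 0.2$,
noise SD equal to the oscillator scale) put band coherences in the
0.1–0.5 range typical of scalp EEG. The documented planted effect for
power experiments raises group B's beta-band $\alpha$ by 0.2, which
elevates group-B beta-band modularity by about 0.1 — an effect chosen
for testability, not clinical realism, since no usable effect sizes
are published for this design. The generator does **not** model volume
conduction, 1/f spectra or artifacts; passing tests demonstrate the
pipeline's statistical correctness on its stated model, not robustness
to those realities of scalp EEG.

Per-subject RNG streams are derived from the master seed by counter,
so cohorts are bit-reproducible and independent of generation order.

## Calibration experiments and their design

Two simulation studies back the statistical claims, at sizes chosen to
keep the default test run modest: 200 null cohorts (no group effect,
n = 20 per group, full 19-channel geometry, permutation count reduced
to 500) for type-I error, and 20 planted-effect cohorts (n = 60 per
group) for power. The type-I check needs care: the ~50 non-degenerate
tests inside one cohort share the same 40 subjects and are strongly
positively correlated — their per-cohort rejection counts have roughly
five times binomial variance — so a binomial confidence band computed
on the pooled 10,000 tests would have far less than its nominal
coverage. The suite therefore builds the 95% band for the pooled
rejection fraction from the 200 independent per-cohort fractions
(CLT), and additionally checks a single cell (beta-band modularity)
across cohorts against exact Binomial(200, 0.05) bounds, the one
pooling for which a binomial band is distributionally correct.

## Classification

Six classifiers — logistic regression, linear-kernel SVM, random
forest (100 trees), gradient boosting (100 rounds), a single hidden
layer neural network (2 × features units, weight decay 0.01) and
Gaussian naive Bayes — are evaluated under 10 stratified 70/30
train/test splits from a fixed master seed. Standardization is fitted
on each training fold only (the leakage-free default; published
pipelines are often silent on this). Confusion counts are pooled
across repeats (micro-average) for precision, recall, accuracy and F1
by the textbook formulas, with zero-denominator ratios reported as 0
with a warning; AUC uses the pooled test-fold scores with a fixed
score orientation so that anti-symmetry in the score holds exactly.
Per-repeat metrics are also returned because aggregation conventions
differ between studies. Hyperparameters are deliberately fixed, not
tuned: the benchmark measures whether the selected features carry
signal, not the ceiling of any particular learner.

## Known limitations

* Coherence is not robust to volume conduction; imaginary coherency,
  PLV or wPLI are out of scope by design.
* Dense-graph degree and small-worldness are uninformative constants
  (see above); interpreting them requires an explicit edge threshold.
* The EDF reader targets the plain continuous EDF produced by this
  package and standard clinical exporters; EDF+ annotations are
  ignored and BDF/BrainVision/FIF are unsupported.
* The delta band's nominal 0.1 Hz edge is unreachable at 0.5 Hz
  resolution; the first usable bin is 0.5 Hz.
* Permutation tests compare means; covariate-adjusted designs (age,
  education) are not implemented.
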