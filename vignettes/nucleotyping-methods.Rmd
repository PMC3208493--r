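---
title: "Chromatin texture and DNA ploidy scoring of Feulgen-stained nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin texture and DNA ploidy scoring of Feulgen-stained nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Large-scale genomic instability re-arranges interphase chromatin. In
monolayers of Feulgen-stained nuclei the stain is stoichiometric for DNA, so
a transmitted-light image of a nucleus carries two kinds of information at
once: the *total* absorbance measures DNA content (ploidy), and the
*spatial organisation* of absorbance measures chromatin texture. This
package implements both readouts on the same galleries of segmented nucleus
images — one grey-level image plus a binary mask per nucleus, grouped per
patient — and a patient-level classifier that separates a low-risk
(non-dysplastic) from a high-risk (dysplastic) group.

## Grey level entropy matrices

Texture is summarised by the grey level entropy matrix (GLEM). For every
mask-true pixel the first-order entropy

$$E = -\sum_i P(i)\,\log_2 P(i)$$

is computed over the grey-level frequencies $P(i)$ inside the $w \times w$
window centred on it ($w = 9$ by default). The GLEM element $P(i, j \mid w)$
is then the estimated probability that a pixel with grey level $i$ has local
entropy falling in bin $j$. Homogeneous chromatin yields low entropies,
heterogeneous chromatin high ones, so the matrix captures the joint
distribution of staining intensity and local disorder.

Numerical conventions, all isolated behind `glem_params()`:

* Images are re-quantised from the capture depth (1024 grey levels) to
  $G = 64$ by linear floor binning before any texture computation
  (`requantise()`). Floor binning preserves optical-density ordering.
* Entropies are in bits (base-2 logs), the convention of the texture
  literature this matrix family comes from; the base only rescales the
  entropy axis.
* The entropy axis is discretised onto $B = 64$ equal-width bins over
  $[0, \log_2 G]$, keeping the matrix square; the bin index is
  $\lfloor E \cdot B / \log_2 G \rfloor$ clamped to $B-1$.
* Windows are clipped at image borders and restricted to mask-true pixels,
  with $P(i)$ normalised by the pixels actually counted. Padding would
  invent grey levels, and unmasked windows would let background glass
  dominate the rim of the nucleus. Whether the original instrument
  restricted windows to the mask is not documented; this choice is recorded
  here and implemented in one place (`src/glem.cpp`).

## Adaptive Mahalanobis-weighted features

Rather than a fixed battery of matrix statistics, two *adaptive* features
are learned from the training set. Nuclei are first stratified by pixel
area into groups A0 (< 1000 px), A1 (1000–1999 px), …, A10 (≥ 10000 px), so
texture is always compared between nuclei of similar size. The area 10000
itself is assigned to A10: the published interval pattern leaves that single
value unstated, and A9 ends at 9999, so A10 is taken as ≥ 10000 for
totality. Within each area group $a$ and class $\omega$:

1. per training case, the element-wise mean and (population) variance of
   that case's nuclear GLEMs;
2. across the cases of each class, the unweighted element-wise mean of the
   per-case matrices, giving $\bar P(i,j \mid w, A_a, \omega)$ and
   $\bar\sigma^2(i,j \mid w, A_a, \omega)$.

The two-step average weights every case equally regardless of how many
nuclei it contributed. From these come the class difference matrix
$\Delta = \bar P_1 - \bar P_2$ (class 1 is fixed as *dysplastic*, making the
sign convention deterministic) and the squared elemental Mahalanobis
distance $d^2 = \Delta^2 / ((\bar\sigma^2_1 + \bar\sigma^2_2)/2 +
\varepsilon)$. Each nucleus is then scored by weighted sums of its GLEM over
the two partitions of $\Delta$:

$$f^+ = \sum_{\Delta(i,j) > 0} d^2(i,j)\, P(i,j), \qquad
  f^- = \sum_{\Delta(i,j) < 0} d^2(i,j)\, P(i,j),$$

and each patient by the unweighted mean of the nucleus features over area
groups A1–A5 (plus $f^{\pm}$'s difference). Groups A0 and A6–A10 are
excluded from aggregation, so class statistics are only fitted for A1–A5 —
fitting the others would be dead computation. Nuclei whose area group has no
fitted statistics are dropped rather than imputed.

$\varepsilon = 10^{-8}$ handles matrix elements seen in only a handful of
nuclei: with both class variances zero and $\Delta \ne 0$ the weight becomes
$\Delta^2/\varepsilon$ instead of dividing by zero. Because the
single-feature discriminant is invariant to a common scaling of the weights
(a tested property), the absolute size of $\varepsilon$ does not affect
classification, only numerical hygiene. Per-case variances use the
divide-by-$n$ form; the choice is washed out by $\varepsilon$ and the step-2
averaging, and is recorded for reproducibility.

## DNA ploidy from integrated optical density

Per-nucleus DNA content is the integrated optical density
$\mathrm{IOD} = \sum_{\text{mask}} \log_{10}(I_\text{bg} / I_\text{pixel})$,
computed on the **original** grey depth (never on re-quantised images) so
densitometry and texture can never interact. IOD is invariant to a common
exposure factor and additive over the mask, both asserted to $10^{-9}$ in
the tests.

The per-patient histogram is scored by `ploidy_summary()`: the global mode
of a kernel-smoothed density of the IODs is taken as the 2c (G0/G1)
reference — the internal-reference calibration of the original instrument is
not reproducible from published material, and these monolayers carry a
dominant epithelial population, so the mode is the natural anchor; an
external reference IOD can be supplied instead. Secondary peaks (local
maxima above 5% of the main peak) are expressed as DNA indices; the rules
are a deliberately simplified, fully configurable reading of the consensus
cytometry guidelines:

* **aneuploid** — any peak with DNA index outside both [0.9, 1.1] and
  [1.9, 2.1], or more than 1% of nuclei above 2.5× the 2c scale (5cER);
* **tetraploid** — 4c-peak fraction above 10% without an aneuploid
  criterion;
* **diploid** — otherwise.

At least 100 nuclei are required for a call; patients below the limit get a
missing call, which the combined panel treats as ploidy-negative so the
patient is retained.

## Classification and evaluation

On a single feature, a two-class linear discriminant with pooled variance
and equal priors reduces to a threshold halfway between the class means
(with a pooled-variance offset when priors differ; priors are
config-exposed, and equal priors are the default because the reference
workflow reported plain correct-classification rates). Each of $f^+$, $f^-$
and $f^+ - f^-$ is fitted on the training patients; the feature with the
highest training CCR is kept (ties broken in that fixed order) and applied
unchanged to the test patients.

Evaluation reports sensitivity, specificity, CCR and the Pearson
chi-squared statistic of the 2×2 table without continuity correction;
percentages are kept unrounded with integer-rounded companions. The
combined panel calls a patient positive when texture-positive OR aneuploid;
the OR rule is inferred from the published combined table (its positives
are exactly the union of the two tests' positives) and is config-exposed.

## The synthetic cohort generator

No image galleries from the clinical study are deposited, so the package
ships a generator (`generate_cohort()`) whose defaults emulate the study
conditions: two groups, 1:1 random train/test split within each class,
1500 nuclei per case at 1024 grey levels, nuclear areas log-normal with
median ≈ 3000 px (sdlog 0.35, covering A1–A5 with ≥ 1% of nuclei each),
diploid-only DNA histograms in the non-dysplastic class versus 65% of
dysplastic patients carrying an aneuploid population (secondary peak at
3.4c, 2% of nuclei beyond 5c), S-phase as a uniform 2c–4c fill at 5%.

Each nucleus is an axis-aligned ellipse (eccentricity uniform on [0, 0.6];
shape is irrelevant to the GLEM beyond the mask). Chromatin is a Gaussian
random field — white noise convolved with a Gaussian kernel whose standard
deviation is the *correlation length* — mapped to a target contrast
(grey-level s.d., default 110) and superimposed on a mean intensity that is
bisected until the measured IOD is within 2% (typically 0.5%) of the target
drawn from the class's DNA-content mixture at a fixed 75 IOD-units-per-c
constant. Texture and ploidy are therefore independently controllable. All
randomness flows from one seed; identical configurations re-generate
byte-identical galleries.

No per-nucleus texture statistics for real Barrett's nuclei are published,
so the texture defaults (correlation length 6 px non-dysplastic vs 2 px
dysplastic at matched contrast) are chosen only to exercise the pipeline
with a class difference of realistic sign — dysplastic chromatin is the
more locally heterogeneous. The generator does **not** emulate overlapping
nuclei, doublets, cut cells, point-spread or shading; passing recovery
tests therefore demonstrate internal consistency of the method, not
performance on real slides, and the published clinical accuracies cannot be
reproduced without the undeposited images.

## Validation choices and known limitations

* The GLEM implementation is checked element-for-element ($10^{-12}$)
  against a brute-force per-pixel oracle; entropy closed forms, the
  partition-sum oracle, the two-step-averaging oracle and the chi-squared
  formula (against the generic contingency-table statistic) are all frozen
  in the test suite.
* Texture recovery is validated at 10 patients/class × 200 nuclei and the
  null behaviour at 20 patients/class × 30 nuclei over 20 seeds — sizes
  chosen to give stable binomial bands while keeping the suite quick to
  re-run.
* **Training CCR is optimistic by construction.** The $\Delta$ and $d^2$
  matrices are learned from the same training cases they are then used to
  classify; with thousands of matrix elements and tens of cases, the
  *resubstitution* CCR on identically generated classes averages around
  0.9 even though no class signal exists. The *independent test set* CCR
  under the same null is binomially consistent with 0.5, which is the
  correct no-signal behaviour and exactly why the train/test split is not
  optional in this design. Any reported training CCR should be read with
  this in mind.
* The ploidy rule set is a simplification: near-diploid aneuploidy hiding
  inside a broadened 2c peak (CV larger than the peak separation) is not
  resolvable by mode-anchored calibration, and S-phase estimation is out of
  scope.
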