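---
title: "Angular connectivity networks for pediatric epilepsy screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Angular connectivity networks for pediatric epilepsy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiFCN)
```

## The screening problem

Epilepsy diagnosis from routine scalp EEG normally requires long recordings
and expert visual review. epiFCN implements an unsupervised screening
pipeline that works on short, artifact-free EEG intervals: it quantifies how
strongly the 19 electrodes of the standard 10-20 montage co-vary, summarizes
each short window as a small functional connectivity network (FCN), and asks
whether a subject's windows look more like the weakly-coupled networks
typical of epilepsy or the strongly-coupled networks typical of controls —
without any training labels.

## The model, stage by stage

**Windowing.** Each recording is split by a moving window of 9 s with 4.5 s
overlap (`segmentRecording`). Window length is counted in seconds and
converted to samples per recording, so mixed sampling rates (200/500/512 Hz
in the reference cohort) yield the same window duration with different
sample counts. Intervals shorter than one window produce zero segments with
a warning rather than being padded: the connectivity formula below assumes a
full window, and partial windows would mix unequal effective bandwidths into
one feature distribution.

**Angular connectivity.** For channels $x_i$ and $x_j$ over a window of $N$
samples, connectivity is the angular distance

$$\theta_{ij} = \arccos\!\left(
  \frac{\sum_{n=1}^{N} x_i[n]\, x_j[n]}
       {\sqrt{\sum_n x_i^2[n]}\sqrt{\sum_n x_j^2[n]}}\right),$$

a modified cosine similarity: $0^\circ$ means proportional signals (maximal
connectivity), $90^\circ$ orthogonal signals (no linear association).
Because the metric depends only on the direction of the signal vectors it is
invariant to amplifier gain and to positive rescaling, which is what makes
mixed-rate, mixed-gain cohorts directly comparable with no resampling or
re-referencing. Two conventions exist in the literature for the sign of the
arccosine term; the package defaults to $\theta = \arccos(\cdot)$, under
which identical signals score $0^\circ$ — the convention consistent with
group mean angles below $90^\circ$ — and exposes the complementary form via
`convention = "literal"` in `pairwiseAngle`/`buildFCN`. The inner product is
used raw, not centered: `center = TRUE` turns the similarity into a Pearson
correlation for users who want the centered variant, and
`absolute = TRUE` folds angles into $[0^\circ, 90^\circ]$. All angles are
stored in degrees.

`buildFCN` assembles the symmetric, zero-diagonal $m \times m$ matrix of all
$\binom{m}{2}$ pairwise angles (171 unique values for the 19-electrode
montage). A flat (zero-norm) channel has no defined direction and raises an
error naming the channel.

**Graph features.** `toGraph` maps an FCN to two views: a binary graph
keeping edges with $\theta \le 45^\circ$ (the mid-point of connectivity
strength; configurable), and the complete weighted graph with the angle as
edge length. Seven statistics form the per-window feature vector
(`featureVector`), in this fixed order:

| feature | view | definition |
|---|---|---|
| ldg | binary | link density $2n_e / (n_n(n_n-1))$ |
| acc | weighted | mean over nodes of $1/\sum_j d(i,j)$, shortest-path distances in degrees |
| gcc | binary | transitivity: $3 \times$ triangles / connected triples |
| rcc | binary | rich club: $n_{e_k} / (n_{n_k}(n_{n_k}-1))$ over nodes of degree $> k$ |
| smg | binary | $\sum_{(u,v) \in E} \deg(u)\deg(v)$ |
| acg | weighted (default) | second-smallest Laplacian eigenvalue |
| eng | weighted (default) | $\sum_i \lvert \lambda_i \rvert$ of the adjacency |

Design choices worth stating explicitly:

* **acc** is classic closeness centrality — the reciprocal of the distance
  *sum* — not a sum of reciprocal distances. Only the former yields the
  $10^{-3}$ magnitude and control-greater-than-epilepsy direction that the
  feature is expected to show on 19-node graphs with edge lengths in
  degrees. A node that cannot reach some other node has an infinite distance
  sum and hence closeness exactly 0.
* **rcc** uses the quotient exactly as defined above, without a factor of 2;
  it is therefore half the edge density of the rich-club subgraph. The
  degree threshold $k$ defaults to $\lfloor n_n/2 \rfloor$ and is
  configurable; there is no canonical value for this statistic on 19-node
  FCNs.
* **acg/eng** default to the angle-weighted adjacency (magnitudes of
  hundreds for acg on 19-node graphs); `spectralMode = "binary"` and a
  `weightTransform` (degrees, radians, or cosine similarity) are available
  because the literature is not consistent about the weighting convention
  for spectral features on FCNs. Adjacencies are symmetric, so the spectrum
  is real and the "real component" qualifier is vacuous.
* Eigenvalues come from a dense symmetric eigensolver; an algebraic
  connectivity within $-10^{-9}$ of zero (numerical noise on a disconnected
  graph) is clamped to 0.

**Unsupervised labelling (phase I).** The feature vectors form a
$7 \times D$ matrix over all $D$ windows of all subjects. Features are
z-scored by default — they span roughly five orders of magnitude, and
unscaled PCA would be dominated by acg — then projected onto the leading
right singular direction (`firstPC`). The sign of the component is fixed by
requiring a positive loading on ldg (first retained feature as fallback) so
that scores are comparable across runs. Zero-variance features are dropped
with a warning before scaling; this happens routinely in regimes where the
binary graph is empty or complete for every window.

The 1-D scores are then fit with a two-component Gaussian mixture
(`fitGMM`) by EM: deterministic initialization at the means of the two
extreme quartiles, both variances at the overall variance, weights at 1/2;
variance floor $10^{-6}\,\mathrm{var}(x)$; convergence at $10^{-8}$ relative
log-likelihood improvement or 500 iterations. The log-likelihood trace is
stored and is non-decreasing — a property the test suite asserts on every
fit. The mixture is fit on the one-dimensional principal component scores:
the feature matrix could also be modelled multivariately, but the
one-component projection is the configuration the method was designed
around, and `firstPC` exposes the loadings so users can audit what the axis
measures. Windows are assigned to the component with the nearer mean (hard
nearest-mean labelling; ties go to component 1; posterior assignment is
available via `labelSegments(method = "posterior")`).

**Clinical identity of the clusters.** Clustering yields anonymous
components. `mapComponentsToClasses` names the component whose member
windows have the larger mean connectivity angle "epileptic": the epilepsy
group exhibits weaker coupling (larger angles) than controls, and this
directionality is the one substantive prior the unsupervised pipeline uses.
Equal component mean angles (or an empty component) are reported as
inconclusive clustering rather than silently broken.

**Subject decision (phase II).** A subject's epilepsy probability is the
fraction of their windows labelled epileptic, $E_s / D_s$
(`subjectProbability`); the display column rounds to the nearest integer
percent. The binary call applies a threshold of 0.5 (`classifySubject`):
any threshold in roughly $(0.25, 0.66]$ yields the same calls on the
reference per-subject table, and 0.5 is the natural midpoint.
`confusionMetrics` reports sensitivity, specificity, accuracy, PPV and NPV
in percent to one decimal. A linear-kernel SVM (`svmSupervised`) is included
as the supervised comparator for settings where a small annotated training
set exists.

## Group-level statistics

`groupMeanTest` compares the edge values of two group-mean FCNs with a
two-sided *pooled-variance* Student t-test — the pooled form is identified
by its degrees of freedom, $171 + 171 - 2 = 340$ for two 19-electrode
networks. `edgewiseTests` runs one such test per electrode pair across the
segments of each group; an edge is significant when its raw p-value falls
below the fixed threshold $10^{-5}$ (the operational "Bonferroni adjusted"
rule), with classical $\alpha/\text{pairs}$ division available via
`bonferroni = TRUE`. Segments enter these tests as independent observations;
segments from one subject are correlated, so the edgewise p-values are
anti-conservative at the subject level — this caveat is documented rather
than "fixed" because the method is defined on segments.
A pair with zero variance in both groups is untestable and is excluded from
the significance mask with a warning. `hemisphereDensity` counts strong
edges ($\theta \le 45^\circ$) with both endpoints left, both right, or one
in each hemisphere; midline electrodes (fz, cz, pz) are excluded from all
three counts by default since no standard assignment exists, with
`midline = "inter"` as the alternative.

## The synthetic cohort generator

No public EEG accession exists for the reference cohort, so `generateCohort`
provides the test-bed. Each channel of a synthetic recording is

$$x_c = a\, s_{\text{common}} + (1-a)\, s_{\text{region}(c)} + \varepsilon_c,$$

where $s_{\text{common}}$ is one shared latent source, $s_{\text{region}}$
is specific to the channel's region (left hemisphere, right hemisphere, or
midline), $\varepsilon_c$ is white noise, and the coupling $a$ is the only
quantity that differs between groups (0.8 control-like, 0.3
epilepsy-like, noise sd 1 by default). Group identity is deliberately *not*
encoded in amplitude: the angular metric is scale-invariant, so amplitude
differences would be invisible by construction and would test nothing.
Latent sources are band-limited (1–30 Hz, 4th-order Butterworth,
zero-phase) noise rather than sums of sinusoids, which avoids accidental
exact orthogonality between sources at commensurate frequencies. Default
cohort structure mirrors the reference study: 7 + 11 subjects, 90 s
recordings, sampling rates cycling over 200/500/512 Hz. Per-subject seeds
derive deterministically from the master seed, making cohorts
bit-reproducible.

Two properties of this regime are worth knowing when reading test output:

* With couplings 0.8 vs 0.3 and unit noise, expected mean angles are about
  $67^\circ$ (control) vs $80^\circ$ (epilepsy) — a $\ge 10^\circ$
  separation, but *both* above the $45^\circ$ binarization threshold, so the
  binary features (ldg, gcc, rcc, smg) are identically zero and are dropped
  by `firstPC` with a message; separation is carried by acc, acg and eng.
  Real EEG sits closer to the threshold and exercises all seven features.
* The expected mean angle is monotone *decreasing* in the coupling over the
  operating range $a \in [0.3, 1]$, which the property suite checks on a
  seeded grid. Below $a \approx 0.2$ monotonicity fails by a fraction of a
  degree: as $a \to 0$ the regional latent (weight $1-a$) dominates and
  *within*-region coherence rises again. The generator keeps the simple
  two-latent mixing form rather than reweighting it away.

What the generator does not emulate: interictal spikes, sleep architecture,
artifacts, volume conduction, or any head-model forward physics. Passing the
end-to-end recovery test therefore shows that the pipeline correctly turns
coupling differences into subject calls — not that it achieves any
particular accuracy on clinical EEG.

## Numerical and edge-case choices

* Cosine similarities are clamped to $[-1, 1]$ before the arccosine; FCNs
  are symmetrized as $(\Theta + \Theta^\top)/2$ to remove floating-point
  asymmetry.
* EM guards: variance floor as above; a component collapsing to zero total
  responsibility raises a fit error; fewer than 4 distinct score values is
  a fit error (the mixture is unidentifiable).
* Midpoint scores in nearest-mean labelling go to component 1 (documented
  tie-break).
* The EDF codec is 16-bit with one data record per second; round-trip
  precision is (physical range)/65535 per channel.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
exhaustive graph enumerations on 3–4 nodes plus 200 random weighted graphs
on 3–6 nodes against brute-force oracles; mixture recovery at $n = 500$;
ten full 18-subject, 90 s cohorts for end-to-end recovery; and a
1000-replicate, 20-pair null calibration of the edgewise tests. These sizes
give stable results at interactive runtimes; all scale linearly if users
want heavier replication.

## Known limitations

* The pipeline consumes signals as read: no artifact rejection, filtering,
  re-referencing or resampling. Heavily artifacted input will produce
  confident nonsense.
* Segment-level independence is assumed by the group statistics (see above).
* The two-component mixture presumes both classes are present in the
  analyzed pool; screening a single-group cohort will split some other
  source of variance and the mean-angle mapping rule may then be
  meaningless. The inconclusive-mapping error catches only the degenerate
  cases.
* Directed (effective) connectivity and frequency-domain coupling are out of
  scope; the FCN is undirected and time-domain by design.
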