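---
title: "Methods: fetal functional-connectome graph analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fetal functional-connectome graph analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fconn)
```

## Overview

`fconn` implements a complete resting-state functional-connectivity
analysis for the fetal brain. The pipeline runs

1. motion QC: framewise displacement, frame censoring, subject exclusion;
2. nuisance regression: noise-tissue principal components plus motion
   parameters and their temporal derivatives;
3. connectivity: pairwise Pearson correlation over retained frames,
   Fisher z-transform;
4. graph analysis: signed-weight modularity with Louvain consensus and
   fine-tuning, and eight nodal measures;
5. distance–strength profiling over 20 correlation bins;
6. cohort inference: gestational-age (GA) correlations (partial on
   flagged movement covariates), robust nodal regressions with BH-FDR,
   median-age-split group comparisons.

Because no fetal dataset of this kind is publicly deposited, the package
ships a synthetic cohort generator that reproduces the statistical
structure the analysis assumes and plants the developmental effects it is
meant to detect. The generator is first-class, tested code: the acceptance
suite demonstrates that the full pipeline recovers the planted truth.

## Motion QC

Framewise displacement at frame $t$ is the mean absolute backward
difference of the three parameters of each movement class,
$FD_t = \tfrac{1}{3}\sum_p |p_t - p_{t-1}|$, with $FD_1 = 0$ by
convention. Translational FD is in mm, rotational FD in radians; we do
not convert rotations to arc length because movement summaries are
conventionally reported in radians for fetal work. Censoring keys on
translational FD alone (the stability criterion is stated in mm);
rotational FD is reported by QC but does not drive censoring. Frames with
$FD < 1.5$ mm are retained; subjects with fewer than 90 retained volumes
are excluded. The 90-volume rule is applied to the final retained mask.
Censored frames' neighbours are not additionally removed. RMS is computed
per parameter about its own mean and then averaged within class — one
consistent reading of "RMS, averaged" conventions.

Welch two-sample t-tests compare the four movement summaries between the
younger (GA < 31 weeks) and older (GA ≥ 31 weeks) groups; any summary with
$p \le 0.05$ becomes a covariate which all global age analyses partial
out.

## Nuisance regression

The design contains the top-$k$ principal components of the noise-tissue
(white-matter/CSF surrogate) timeseries, the six rigid-body motion
parameters, and their backward-difference derivatives — $p = k + 12$
columns, all mean-centred, restricted to retained frames. $k$ defaults
to 3 in the reference pipeline driver (the generator simulates 3 shared
confound factors) and is configurable; component counts in this family of
pipelines are rarely reported, so the choice is exposed rather than
hidden. Regression is ordinary least squares per ROI with an intercept;
censoring precedes regression, so the design is estimated on exactly the
frames that enter connectivity. Rank-deficient designs drop collinear
columns with a warning. No band-pass filter stage is applied: the shared
signal of interest is generated (and in real data assumed) to live below
~0.1 Hz, and the regression leaves the passband untouched.

## Connectivity

Pearson correlations are computed across the concatenated retained
frames, ignoring segment boundaries. The Fisher transform
$z = \operatorname{atanh}(r)$ is applied off-diagonal; the diagonal is
stored as 0 and excluded from every downstream statistic, which avoids
$\operatorname{atanh}(1)$ and makes the "self-edge" convention explicit.
Degenerate pairs with $|r| = 1$ raise an error rather than propagate
infinities.

## Signed modularity

With $w^+ = \max(w, 0)$, $w^- = -\min(w, 0)$, strengths $s_i^\pm$, total
weights $v^\pm$ and chance terms $e^\pm_{ij} = s_i^\pm s_j^\pm / v^\pm$:

$$Q^* = \frac{1}{v^+}\sum_{ij}\left(w^+_{ij} - e^+_{ij}\right)
        \delta_{m_i m_j}
      - \frac{1}{v^+ + v^-}\sum_{ij}\left(w^-_{ij} - e^-_{ij}\right)
        \delta_{m_i m_j}.$$

This is the asymmetric signed form: positive within-module weight
contributes at full strength, negative within-module weight penalizes at
reduced strength $v^-/(v^+ + v^-)$, reflecting that positive edges carry
more information about module membership than negative ones. With no
negative weights the formula reduces exactly to weighted Newman
modularity (verified against an independent implementation in the test
suite).

Maximization is greedy two-phase Louvain: seeded random-order single-node
moves with exact $\Delta Q^*$ gains, then aggregation. The positive and
negative layers are aggregated separately so the objective is preserved
exactly across levels. Ties in the local move break toward the lowest
module index, making each run reproducible from its seed. Because the
heuristic varies slightly from run to run, 1000 seeded restarts are run
per subject by default and summarized by the partition "most consistently
identified across runs". Consistency is arbitrated among runs of maximal
quality: only partitions tying the best run's $Q^*$ (within $10^{-10}$)
are candidates, and among them the ARI-medoid — the partition maximizing
the multiplicity-weighted mean adjusted Rand similarity to the other
candidates — is selected. A pure frequency-based medoid was rejected
during development: on small noisy graphs the most frequent Louvain
attractor can be measurably suboptimal, and the whole point of the
restart ensemble is to optimize modularity, with consistency breaking
ties between equally good solutions. The selected partition is then
fine-tuned by deterministic
sweeps of single-node reassignments accepting only $Q^*$-increasing
moves; termination is guaranteed because $Q^*$ is bounded and strictly
increases. The result is never below the trivial single-module partition
($Q^* = 0$).

## Nodal measures

Eight measures per node under the subject's fine-tuned consensus
partition: positive and negative strength; positive and negative
participation coefficients $P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$
(the standard diversity form — verbal descriptions of participation as a
"fraction of edges" are looser than the formula, and we deliberately
implement the standard definition); and within/between-module strength
z-scores, where a node's summed sign-specific weight to its own (or all
other) modules is standardized against its module peers using the sample
(n−1) SD. Modules of size one, or with zero strength SD, yield z = 0 with
a logged message. "Between-module negative degree" is treated as
weighted strength, consistent with the within-module definition.

## Distance–strength profile

ROI centroids are in mm; distances are Euclidean. All $n(n-1)/2$ pairs
are assigned to 20 raw-correlation bins of width 0.1 spanning $[-1, 1]$,
left-closed/right-open with the final bin closed — a total and
unambiguous convention. Raw $r$ (not Fisher z) is binned because the bin
range is the natural range of $r$. Tail analyses rank pairs by distance
and take the longest/shortest $\lceil 5\% \rceil$; the group comparison
of tail strengths runs at α = 0.025. Distance cutoffs are computed per
subject and the cohort median is reported, since a pooled cutoff is not
well defined when parcellations are subject-specific.

## Cohort inference

Global effects (Q*, mean intermodular strength, correlation range) are
tested by Pearson correlation with GA, switching to partial correlation
(residualize both sides, df reduced by the covariate count) whenever
motion QC flagged movement covariates. Nodal effects use robust
regression — iteratively reweighted least squares with Tukey bisquare
weights at tuning constant 4.685 — because single-subject nodal measures
are outlier-prone at cohort sizes near 30; any M-estimator with
comparable breakdown would do, and the test suite asserts the
outlier-resistance property rather than a specific estimator brand. If
the robust scale estimate degenerates (a mostly-constant measure has MAD
zero), the fit falls back to OLS and is flagged as non-converged. FDR is
applied per measure family (8 families × n nodes), matching per-measure
reporting conventions; regional significance is additionally reportable
at a fixed nominal threshold, and both views are kept side by side rather
than merged. The exploratory hub follow-up restricts to regions outside
the hub's module in *every* subject and reports nominal p-values without
FDR, because it is a targeted post-hoc search, not a family of confirmatory
tests.

## The synthetic cohort generator

Per node $i$ in module $m(i)$:

$$x_i(t) = \sqrt{\lambda_w}\, f_{m(i)}(t)
         + \sqrt{\lambda_b(GA)}\, g(t)
         + \ell_i \sqrt{\lambda_{lr}(GA)}\, h(t)
         - \eta(GA)\,[i = \text{hub}] \sum_{m' \ne m(i)} f_{m'}(t)
         + \sum_k a_{ik} u_k(t)
         + \sigma_i \epsilon_i(t)$$

with all shared factors ($f$, $g$, $h$, $u$) low-pass filtered below
0.1 Hz and $\sigma_i$ completing each node to unit variance. The low-pass
structure is a 5-frame boxcar applied to white noise: at TR = 2 s the
first spectral null of a length-$L$ boxcar sits at $f_s/L = 0.1$ Hz, so
shared signal is confined to the band where resting-state coupling lives.

The defaults are the study conditions the pipeline targets: 30 subjects
spanning GA 19–39 weeks (median split at 31), 180–463 frames at TR = 2 s,
$\lambda_w = 0.25$ (within-module correlations ≈ 0.3, the regime in which
empirical fetal Q* ≈ 0.35 arises), $\lambda_b$ rising from 0.02 to 0.12
across the GA range (driving the modularity decline and intermodular
strengthening), hub loading $\eta$ rising to 0.4 (so the hub's
between-module edges turn measurably negative in older fetuses), and a
long-range factor reaching an 8 % variance share in the oldest fetuses on
a mutually distant 8-ROI subset. Which generative mechanism produces
long-range strengthening in the developing brain is not established; the
distant-subset shared factor is one admissible choice and is flagged as
such. The default cohort uses 60 ROIs in 4 modules rather than the
empirical ~149 ROIs: recovery behaviour is the same while every stage
runs comfortably at desk scale (the acceptance checks and the test suite
state the problem sizes they use).

Motion is a smooth random walk (translational steps of SD 0.03 mm)
plus Bernoulli repositioning events: at a spike frame the fetus jumps
2–6 mm per axis to a new position and stays, so exactly that frame's FD
exceeds the 1.5 mm threshold. The spike probability is 0.4 at the
mid-range GA and falls by 0.01/week (younger fetuses move more), which
yields ≈ 60 % retained frames on the default cohort and occasionally
pushes a young subject under the 90-volume exclusion — the regimes a
fetal QC stage must handle. Age effects are linear in GA throughout, the
simplest generator consistent with reporting linear correlations.
Centroids are sampled uniformly inside a 120 × 90 × 80 mm ellipsoid so
that inter-ROI distances reach the > 70 mm long-range regime.

Noise-tissue surrogates expose each confound factor through two noisy
channels, so aCompCor-style PCA can recover them; confound loadings have
random signs in $[0.05, 0.2]$ so shared noise inflates some pairwise
correlations without biasing the global mean.

What the generator does *not* emulate: image-domain artifacts, maternal
tissue, spatially structured (distance-dependent) noise, hemodynamic
response variability, non-linear developmental trajectories, and
coupling between motion and the BOLD signal beyond frame loss. Passing
tests therefore demonstrate that the pipeline's statistics recover
planted covariance structure under realistic sampling noise and frame
loss — not that they are robust to every artifact of real fetal fMRI.

## Parcellation

A simplified two-level spatially constrained clustering for voxel-level
inputs: the similarity graph connects only 6-adjacent voxels, weighted by
the Pearson correlation of their timeseries clipped at 0 (negative
adjacent-voxel similarity carries no information for a cut objective and
would break its normalization). Normalized cut is realized as normalized
spectral clustering — top-K eigenvectors of $D^{-1/2} A D^{-1/2}$,
row-normalized, clustered by seeded k-means (10 restarts). Spatial
adjacency is enforced structurally through the graph; any residual
discontiguous fragment after k-means is reassigned to the neighbouring
label with maximal similarity, so output parcels are contiguous by
construction. Group parcellation averages per-subject label-coincidence
weights on the shared adjacency and re-cuts at the same K; a single K is
used at both levels. A flood-fill audit (`drop_discontiguous()`) removes
any parcel whose members are not 6-connected, reporting what it removed.
Parcel-size evenness is checked softly (coefficient of variation of
sizes, logged not asserted) because spectral methods only approximately
balance cluster volumes.

## Numerical conventions and degenerate inputs

- Louvain move gains use exact $\Delta Q^*$ increments; acceptance
  threshold $10^{-12}$ avoids cycling on numerically tied moves.
- All RNG flows through one master seed; child seeds are derived by
  seeded sampling and stay below $2^{31} - 1$.
- Zero-variance ROIs error in correlation (they indicate a broken
  extraction), while zero-variance voxels in parcellation merely get
  zero-weight edges (they are common at mask borders).
- Constant nodal measures across a cohort yield a null robust-regression
  result (t = 0, p = 1) rather than an error; degenerate robust fits fall
  back to OLS with a non-convergence flag.
- Matrix TSV round-trips are validated for symmetry and label agreement
  on read, with the first offending entry reported.

## Known limitations

- The consensus medoid is computed over deduplicated run partitions;
  with very weak structure and many restarts the ARI matrix over unique
  partitions can grow large (cost is quadratic in their number).
- The module-matching assignment is exhaustive only up to 8 modules per
  side, greedy beyond — adequate for cortical module counts, not for
  fine parcel matching.
- The parcellation is a simplified realization of spatially constrained
  normalized-cut clustering, not a faithful reimplementation of any
  specific published toolchain.
- Group-level inference assumes one scan per subject; longitudinal or
  mixed-effects designs are out of scope.
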