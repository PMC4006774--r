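# fconn

Graph-theoretic analysis of fetal functional connectomes in R.

## The problem

Resting-state fMRI of the human fetus is dominated by two difficulties:
fetal movement is large and intermittent, and no deposited fetal
connectivity data exist at the scale needed to exercise an analysis
pipeline. `fconn` implements the full analysis chain used to study the
emergence of modular brain organization *in utero* — from motion-censored
ROI timeseries to signed-modularity, nodal hub metrics, distance–strength
profiles, and gestational-age (GA) inference — together with a synthetic
cohort generator that plants the developmental effects such a study looks
for, so that every stage is testable end to end without any download.

It is intended for researchers developing or validating fetal/neonatal
resting-state connectivity pipelines, and for anyone who needs a tested
reference implementation of signed-weight modularity with consensus
partitioning.

## The model

Connectivity is the Fisher-transformed Pearson correlation
\(z_{ij} = \mathrm{atanh}(r_{ij})\) between cleaned ROI timeseries
(motion-censored at framewise displacement < 1.5 mm, subjects with < 90
retained volumes excluded, aCompCor-style nuisance regression of
noise-tissue principal components plus the 6 rigid-body motion parameters
and their first derivatives).

Graphs are analyzed fully weighted and signed. With
\(w^\pm\) the positive/negative weight layers, \(s_i^\pm\) node strengths
and \(v^\pm\) total weights, signed modularity is

    Q* = (1/v+) Σ_ij (w+_ij − s+_i s+_j / v+) δ(m_i, m_j)
       − (1/(v+ + v−)) Σ_ij (w−_ij − s−_i s−_j / v−) δ(m_i, m_j)

maximized by seeded Louvain runs, summarized by a consensus (ARI-medoid
over restarts, 1000 by default) and refined by single-node fine-tuning.
Eight nodal measures are computed per subject: positive/negative strength,
positive/negative participation coefficient, and within/between-module
positive/negative strength z-scores. Cohort-level inference uses Pearson
(or motion-partialled) correlations with GA, robust (bisquare IRLS)
regression per node and measure with Benjamini–Hochberg FDR, Welch tests
for the median-age split (31 weeks), and 20-bin distance–strength
profiles with top/bottom-5 % connection-length comparisons at α = 0.025.

## Worked example

```r
library(fconn)

cohort <- generate_cohort(cohort_config(seed = 7))
res    <- analyze_cohort(cohort, n_consensus = 20, seed = 11)

res$global
#>                        effect   estimate         t           p  n
#> 1                q_star_vs_ga -0.5385955 -3.259465 0.003107728 30
#> 2 intermodular_strength_vs_ga  0.5774639  3.606616 0.001292503 30

mean(res$q_star); sd(res$q_star)
#> [1] 0.3266317
#> [1] 0.0544742

res$hub_node
#> [1] 1
subset(res$nodal_inference, effect == "between_neg_z" & node == 1)[, c("t", "q", "reject")]
#>          t            q reject
#> 421 6.7498 1.221381e-05   TRUE
```

The default generator plants three developmental effects; the analysis
recovers all three. Modularity Q* falls with GA (partial r = −0.54 after
controlling for the flagged movement covariates) while mean intermodular
strength rises (r = +0.58): with maturation the planted modules couple
more strongly into a whole-brain system. Node 1 — the planted
"posterior-cingulate-like" hub whose loading on every other module's
factor grows more negative with age — is the one FDR-significant node on
the between-module negative strength z-score (robust t = 6.7), and
`res$hub_followup` shows its edgewise connectivity to every out-of-module
region growing more negative with GA.

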