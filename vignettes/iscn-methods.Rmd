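---
title: "Individual structural covariance networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual structural covariance networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscn)
```

## The problem

Group-level structural covariance networks correlate regional morphometry
*across* subjects and therefore yield one network per cohort, with no handle
on individual variability. The intra-individual structural covariance
network (ISCN) instead assigns each subject their own graph: two brain
regions are strongly connected when they deviate from a healthy-control
norm *in the same way* within that subject (e.g. concurrent atrophy). This
package implements the full ISCN analysis chain for the standard 82-region
parcellation — 68 Desikan-Killiany cortical regions measured by mean
cortical thickness (mm) and 7 subcortical structures per hemisphere
measured by volume (mm³) — together with a synthetic-cohort generator so
that every stage is testable without access to patient MRI data.

## The model

**Normative model.** For each region $r$, ordinary least squares is fitted
on healthy controls only:

$$X_{sr} = \beta_{0r} + \beta_{1r}\,\mathrm{age}_s + \beta_{2r}\,\mathrm{sex}_s + \beta_{3r}\,\mathrm{ICV}_s + e_{sr},$$

and the residual mean $\mu_r$ (zero to numerical precision; retained
because the z-score is defined on residuals) and unbiased SD $\sigma_r$ are
recorded. Every subject — control, patient baseline, patient follow-up —
is then scored against this same model:

$$e_{sr} = X_{sr} - \hat X_{sr}, \qquad z_{sr} = \frac{e_{sr} - \mu_r}{\sigma_r}.$$

A positive $z$ means the measurement exceeds the covariate-adjusted
healthy expectation. Follow-up scans are z-scored against the baseline HC
model: no second control cohort exists in this design, and re-fitting the
norm at follow-up would absorb exactly the longitudinal change of interest.

**Similarity kernel.** Each subject's network is

$$w_{ij} = \exp\!\left(-(z_i - z_j)^2\right) \in (0, 1],$$

with $w_{ij} = 1$ iff $z_i = z_j$ and the diagonal excluded. Note two
properties that drive everything downstream: the kernel depends only on
*pairwise differences* of deviations (it is invariant to adding a constant
to all $z$), and it is sensitive to deviation *mismatch*, not to absolute
deviation level. A region that deviates idiosyncratically — differently
from the rest of the brain — loses similarity to all other nodes at once.

**Thresholding.** Weighted networks are binarized at each density $d$ of a
grid by keeping the $k = \lfloor d\,N(N-1)/2 \rfloor$ strongest
upper-triangle weights. Ties are broken by ascending $(i, j)$ pair index:
the choice is arbitrary but frozen, so results are bit-reproducible. The
default grid is 0.10–0.37 in steps of 0.01 (28 levels). A criteria-driven
mode is also provided (`determine_density_range(mode = "criteria")`) that
keeps the longest contiguous run of candidate densities at which every
subject's graph has >80% non-isolated nodes, best-partition modularity
> 0.3 and small-worldness $\sigma > 1$; the criteria are evaluated
per-subject (all must pass), with a fixed criterion seed. The fixed grid
is the default because the retention criteria themselves involve
stochastic quantities and a fixed grid makes cross-study comparison
straightforward.

**Graph metrics.** On each binary graph the package computes nodal degree
centrality, nodal efficiency, local efficiency, clustering and (Brandes)
betweenness normalized by $(N-1)(N-2)/2$, and global efficiency,
characteristic path length $L_p$, mean clustering $C_p$, modularity $Q$
(seeded Louvain with random-restart and a single-node-move/merge
refinement pass), and the small-world indices

$$\gamma = \frac{C_p}{\langle C_p^{\mathrm{rand}}\rangle},\quad
\lambda = \frac{L_p}{\langle L_p^{\mathrm{rand}}\rangle},\quad
\sigma = \gamma / \lambda,$$

where the reference ensemble consists of degree-preserving Maslov–Sneppen
double-edge-swap rewirings (default `m_refs = 100` references, `n_swaps =`
10 × edge count; both configurable — the reference counts are a
convention, not an identified quantity). Each metric's curve over the
density grid is summarised by its trapezoidal AUC. Disconnected graphs
use the usual conventions: efficiency terms take $1/\infty = 0$ and $L_p$
averages over reachable pairs only. The trapezoid rule (rather than a
step-sum) was chosen as the standard quadrature; on a uniform grid the two
differ by a near-constant factor that cancels in group contrasts.

**Inference.** Group contrasts (per-region morphometry; per-node metric
AUCs; global metric AUCs) use Freedman–Lane permutation: the outcome is
regressed on the nuisance covariates (age, sex) alone, reduced-model
residuals are permuted and re-added to the fitted values, and the group
$t$ statistic of the full model is recomputed; the two-sided p-value uses
the add-one convention $p = (\#\{|t^*| \ge |t|\} + 1)/(B + 1)$, so $p$ is
never 0 and never below $1/(B+1)$. The scheme was chosen because it keeps
the covariate effect fixed under the null; with no covariates it reduces
exactly to a plain label-permutation test (verified in the test suite).
Each family — one nodal metric × one comparison, the global metrics, the
morphometry regions — is Benjamini–Hochberg corrected separately (via
`stats::p.adjust`). Longitudinal change is tested by within-pair sign-flip
permutation of baseline/follow-up differences on the features significant
at baseline. Treatment response is the percent VAS change
$100\,(\mathrm{VAS}_{pre} - \mathrm{VAS}_{post})/\mathrm{VAS}_{pre}$,
oriented so larger = more relief, and is related to significant baseline
nodal AUCs by partial correlation adjusting age, sex and pain duration
(residual-on-residual Pearson, $t$ transform with $n - 2 - k$ degrees of
freedom). With the relief-positive orientation, a *negative* correlation
means patients with higher baseline centrality at the target node gain
less relief; the orientation is a convention and is exposed in the
outputs rather than hidden.

Morphometry contrasts are direct per-region value contrasts (thickness or
volume), not AUCs — an AUC over densities is meaningful only for graph
metrics. ICV can additionally be covaried in the morphometry family via
`include_icv_morphometry`; the default adjusts age and sex, matching the
covariates used for the network contrasts.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws, per subject,

$$X_{sr} = m_r + \text{covariate effects} + (f_s + \varepsilon_{sr})\,s_r,$$

where $m_r$ is a fixed per-region baseline mean, the covariate effects are
linear in age and sex (thickness) plus an ICV elasticity (volumes),
$f_s \sim N(0, 0.6)$ is a subject-level factor shared by all regions,
$\varepsilon_{sr} \sim N(0, 0.8)$ is independent regional noise (z-units),
and $s_r$ is the per-region residual scale (0.12 mm for thickness, 6% CV
for volumes). Patients additionally receive:

* a thickness reduction of `atrophy_effect` (default 0.15 mm) in the 12
  regions where the emulated study found patient cortical thinning;
* an independent deviation $\delta_s \sim N(0, \tau)$ at the target node
  (right pars triangularis), default $\tau = 2.5$ z-units. Decoupling —
  not a mean shift — is used because the similarity kernel responds to
  deviation mismatch: extra independent noise at one node lowers that
  node's similarity to every other node and hence its degree centrality
  and nodal efficiency, which is the mechanism the analysis is designed
  to detect. The default balances two competing design goals. Detection
  of the group contrast improves with $\tau$ and saturates near
  $\tau \approx 3.5$ (the target's weights are then effectively zero at
  the analysed densities for almost every patient) — but at saturation
  the *prognostic* signal disappears, because a correlation between
  baseline centrality and treatment response needs centrality to still
  vary across patients. $\tau = 2.5$ is the largest value at which the
  coupling remains graded: the group contrast is recovered under FDR in
  roughly half of simulated cohorts (comfortably at the shipped example
  seed) and the planted negative correlation is recovered at
  $r \approx -0.4$ to $-0.5$;
* percent VAS change generated with correlation `vas_link_strength`
  (default −0.6) to the subject's baseline target-node coupling
  ($-|\delta_s|$, standardized), truncated to [0, 100]. Patients whose
  target node is more decoupled (lower centrality) experience more
  relief, so the analysis recovers a negative partial correlation between
  baseline degree-centrality AUC and percent VAS change.

At follow-up both patient effects are multiplied by
$1 - \text{recovery\_fraction}$ (default 0.8: strong but partial
recovery); the per-region noise is redrawn (a second scan session) while
the shared factor, age, sex and ICV are kept (stable subject traits).

Demographics and clinical scores default to the emulated study's profile:
25 patients / 25 controls, patient age 48.38 ± 6.84 vs control age
46.35 ± 8.76 years, 12/25 male, VAS 6.25 ± 1.12 before treatment with a
mean percent change near 64%, pain duration 37.35 ± 16.54 months. The
planted effect sizes have no published counterparts; they were fixed once
so that the planted effects are detectable at n = 25/25 under FDR across
82 nodes, and they are configuration parameters, not claims about
patients.

Two deliberate limitations. First, the kernel's translation invariance
means the shared factor $f_s$ shapes the cross-subject covariance of
morphometry (as in real cohorts) but cancels exactly in every pairwise
$z_i - z_j$; the healthy network structure therefore comes from the noise
field, and real cortex — with spatially autocorrelated, hierarchically
organised deviations — will produce richer healthy topology than the
generator does. Second, the uniform atrophy shift makes the 12 thinned
regions deviate *together*, so they form a tight mutual-similarity block;
several of them gain degree in patients. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers planted effects of the
designed kind, not that real CNSP data would show the same side effects.

## Randomness and reproducibility

All randomness flows from one master seed through
`derive_seed(master, labels...)`, a fixed 31-bit hash: each subject, each
small-world reference, each permutation family and each modularity call
has its own derived stream. Consequences: the same configuration and seed
give byte-identical output tables, and enlarging a cohort leaves existing
subjects' data unchanged. Reference rewirings are generated by a
Mersenne-Twister stream inside the compiled core, seeded per reference, so
results do not depend on R's global RNG state.

## Numerical choices and degenerate inputs

* Residual SDs at numerical-noise scale (constant region across controls)
  are a fatal error, not a silent $z = \infty$.
* Edge-count rounding uses `floor`; ties in weights are broken by pair
  index (deterministic).
* An undefined metric value (edgeless graph modularity, path length with
  no reachable pairs) propagates as `NA` and flags the whole AUC rather
  than being interpolated.
* Permutation p-values use the add-one convention and are never 0;
  constant outcomes return $p = 1$ with a warning.
* Graphs that admit no rewiring (e.g. stars) return the input reference
  with a warning rather than looping forever.

## Problem sizes used by the shipped checks

The package's own validation runs at sizes chosen to exercise every code
path at desk scale: metric-engine equivalence against brute-force oracles
on every labeled connected graph with 3–5 nodes (770 graphs) plus seeded
random samples of 6–10-node graphs; permutation-test calibration over
1,000 null datasets at 999 permutations; and the end-to-end
parameter-recovery analysis on the default 25/25 cohort with the density
grid thinned to step 0.03 and `m_refs = 20` references per density. The
full-resolution grid (step 0.01, `m_refs = 100`) is the analysis default
and runs at about 2–3 s per subject.

One caveat worth knowing when applying the method to small cohorts: the
controls are z-scored *in-sample* (their residual SD is exactly the
$\sigma_r$ used to scale them) while patients are scored *out-of-sample*.
With very few controls the per-region $\hat\sigma_r$ estimation noise
makes patient deviation fields region-heteroscedastic relative to the
control fields, which measurably perturbs network statistics even for
patients drawn from the control distribution; in simulation the effect is
clearly visible at 8 controls and negligible at the 25-control study
scale. Group comparisons against very small normative cohorts should be
interpreted with this in mind.

## Known limitations

* Binary undirected graphs only; no weighted or directed variants, no
  rich-club/assortativity/hub statistics.
* The similarity kernel is the exponential-of-squared-difference form
  standard in the individual-network literature; alternatives (e.g.
  Gaussian kernels with bandwidth) are not implemented.
* The criteria-driven density range selection is quadratic in subjects ×
  densities and is the expensive path; the fixed grid is the default.
* No treatment-response classifier is included: with ~6/25
  non-responders a binary model cannot be trained or validated honestly,
  and the correlation analysis is the appropriate scope.
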