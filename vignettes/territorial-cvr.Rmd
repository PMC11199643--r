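---
title: "Estimating territorial cerebrovascular resistance on circle-of-Willis networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating territorial cerebrovascular resistance on circle-of-Willis networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowcvr)
```

## The model

Cerebrovascular resistance (CVR) is the Ohm's-law ratio between a
perfusion pressure gradient and the flow it drives. Globally,
`tCVR = (MAP - ICP) / Q_total` with `Q_total` the summed inflow of the
two internal carotid arteries (ICA) and the basilar artery (BA). Per
territory,

$$ R = \frac{P_{terr} - ICP}{Q_{terr}}, $$

where $Q_{terr}$ is the cycle-averaged flow in the artery feeding the
territory (MCA1, ACA2 or PCA2 of each hemisphere) and $P_{terr}$ is the
mean pressure at a cut plane 5 mm distal to that artery's origin on the
circle of Willis. Flows for every artery at once are what a 4D-flow-MRI
post-processing chain delivers (here emulated by the synthetic-data
layer, averaging 15 cross-sections per artery); the perfusion pressures
must be computed from a flow model.

`cowcvr` models the circle of Willis as a resistor network. Blood is an
incompressible Newtonian fluid ($\rho = 1060\ \mathrm{kg/m^3}$,
$\mu = 3.45\ \mathrm{mPa\,s}$), flow is steady, laminar and fully
developed with rigid no-slip walls, so each segment obeys the
Hagen–Poiseuille law $\Delta p = R_{seg} Q$ with
$R_{seg} = 8\mu L/(\pi r^4)$ for a uniform radius, and the analytic
integral $\frac{8\mu}{\pi}\frac{L}{3(r_p - r_d)}\left(r_d^{-3} -
r_p^{-3}\right)$ for a linear taper. Conservation of mass at every
junction then gives a linear nodal system (a weighted graph Laplacian)
solved exactly with one pressure reference per connected component.
Loops — the anterior communicating artery (ACoA) circuit — are resolved
by the solve itself, not by assumption.

**Fidelity gap.** A full 3D finite-element Navier–Stokes solve would
additionally capture junction and inertial (convective) losses and give
pressures averaged over genuine cut *planes*. At mean-flow conditions in
arteries of this calibre those losses are second order, and the
reduced-order model has the decisive advantage of being desk-verifiable:
every number in the test suite can be checked by hand reduction. The
substitution is the package's main stated limitation.

## Boundary-condition assembly

The circle of Willis is a ring: prescribing all measured flows around it
can contradict itself or underdetermine the interior. The pipeline
therefore splits the network into an **anterior** domain (ICAs, MCA1s,
ACA1s, ACA2s, ACoA) and a **posterior** domain (BA, PCA1s, PCA2s), each
posterior communicating artery (PCoA) being halved into two stumps whose
cut node is a boundary of both domains. Assembly rules, applied to the
measured flows:

* **PCoA role**: positive flow (anterior → posterior, the sign
  convention of the measurement set) makes the PCoA an outlet of the
  anterior domain and an inlet of the posterior one; negative flow the
  reverse; a missing PCoA contributes no boundary.
* **Inlet sums**: each ICA inlet is the sum of its side's measured MCA1,
  ACA1 and signed PCoA flows; the BA inlet is the sum of all PCA2
  outflows corrected by the signed PCoA flows. Mass conservation is
  therefore exact *by construction*, not by solver tolerance.
* **ACA2 adjustment**: measured ACA2 flows are rescaled by the common
  factor $s = (Q_{ACA1,L} + Q_{ACA1,R})/\sum Q_{ACA2}$ so the measured
  ACA1 flows are honoured. Proportional rescaling (rather than an
  additive split of the discrepancy) is chosen because it preserves
  zeros and cannot produce negative flows; whether the measured
  left/right ACA2 ratio should be preserved is not determined by the
  problem, and this choice is flagged as such.
* **Reference pressure**: the posterior domain pins MAP at the BA root.
  The anterior domain pins MAP at the contralateral ICA for stenotic
  subjects — reduced by the computed stenosis pressure drop when the
  contralateral stenosis is ≥ 50% (below 50% no correction is applied) —
  and at the ICA with the larger inlet flow for non-stenotic subjects
  (ties, a measure-zero event, break toward the left and are logged).

**Disconnected anterior domains.** Without an ACoA the anterior domain
separates into left and right components. A single reference and a
global ACA2 factor would leave one component floating and unbalanced, so
both rules are applied per connected component: each component's ICA
root receives MAP (minus its own ≥ 50% stenosis drop), and the ACA2
factor is computed per side. This is the only closure that keeps each
component balanced and preserves exact forward–inverse recovery.

One topological simplification: the PCoA take-off sits on the ICA just
proximal to the carotid terminus; in the lumped model the take-off and
the MCA1/ACA1 bifurcation collapse onto one node (zero-length offset).
This costs no resistance at mean-flow scale and keeps the complete
network at its natural 16 segments.

## Cut planes, duplicates, exclusions

Perfusion pressure is read 5 mm into each outflow artery, integrating
the (possibly tapered) per-length resistance analytically. With a PCoA
present the PCA plane sits on the PCA2, 5 mm from the PCoA junction;
with the PCoA absent it sits on the PCA path 5 mm from the BA
bifurcation, so the remaining PCA1 and the whole PCA2 are downstream of
the plane. For fetal-type PCAs (hypoplastic PCA1, enlarged PCoA — the
variant requires its ipsilateral PCoA) the PCoA-present rule applies and
the variant is flagged. Duplicated arteries (two MCA1 or two ACA2 on a
side) are parallel segments with duplicate indices and separate cut
planes; the territory value is the parallel combination
$1/\sum 1/R_i$ of its branch estimates. Territories with non-positive
flow or with perfusion pressure at or below ICP are flagged undefined
and excluded from aggregation — never silently valued — mirroring how
such territories are excluded in practice.

ICP enters as a single scalar counter-pressure shared by all
territories, defaulting to 11.6 mmHg (a healthy-elderly reference
value), overridable per subject. The unit boundary is centralised: the
solver works in mmHg, ml/s and mmHg·s/ml with one conversion constant
(1 mmHg = 133.322 Pa); the 160 ml/min hemodynamic-disturbance threshold
is the only ml/min quantity and is converted at the surface.

## The stenosis element

The separate high-fidelity stenosis simulation that a 3D pipeline would
run is represented by a semi-empirical two-term constriction law of the
Young–Tsai type:

$$ \Delta P = \underbrace{\frac{8 \mu L_t}{\pi r_t^4} Q}_{\text{viscous}}
  + \underbrace{K_t \frac{\rho}{2} \left(\frac{Q}{A_0}\right)^2
  \left(\frac{A_0}{A_t} - 1\right)^2}_{\text{expansion loss}} $$

with throat radius $r_t = r_0 (1 - d/100)$ from the NASCET degree $d$,
throat length $L_t$ (default 3 mm), and $K_t = 1.52$ (the classic
constriction-flow value, stored in the descriptor and overridable). The
expansion term is the standard Borda–Carnot form — equivalently
$K_t \frac{\rho}{2} u_t^2 (1 - A_t/A_0)^2$ with $u_t$ the throat
velocity — which reproduces simplified-Bernoulli-scale gradients (a
severe stenosis jetting at 4 m/s drops tens of mmHg). A degree-0
stenosis degenerates exactly to a straight Poiseuille segment. In the
forward model the element sits between the MAP source and the ICA root
and is quadratic in flow, so the solver resolves it by damped
fixed-point iteration on the effective resistance $\Delta P/Q$ to a
relative tolerance of $10^{-12}$ (deterministic; convergence in a few
iterations since the element is monotone).

In the inverse direction the estimation rule uses the stenosis only
through the reference-pressure correction on the contralateral side.
With an ipsilateral stenosis in the forward model and the reference on a
stenosis-free contralateral ICA, the anterior pressure field is still
exactly determined (flows plus one correct pressure), so recovery stays
exact; a *sub-50% contralateral* stenosis, which receives no correction
by the ≥ 50% rule, biases all anterior estimates downward by its
(small) drop — bounded and monotone in severity, documented rather than
asserted away.

## The synthetic cohort: what it emulates

The generator's defaults are the study conditions of a stroke/TIA
cohort with elderly controls:

* territorial resistances per hemisphere: MCA 33.8 ± 10.5, ACA
  59.0 ± 30.6, PCA 77.8 ± 21.3 mmHg·s/ml;
* MAP: patients 93 ± 12 mmHg, controls 102 ± 12 mmHg; ICP fixed at
  11.6 mmHg;
* ipsilateral stenosis degree 75 ± 12% (clamped to [50, 95]), with a
  9/29 chance of a contralateral stenosis of 67 ± 10%;
* anatomical variants per subject: each PCoA present with probability
  0.7, ACoA 0.95, fetal PCA 0.05 given its PCoA, duplicated ACA2 at
  4/48 and duplicated MCA1 at 1/48 per subject — frequencies consistent
  with anatomical series and with duplications being rare;
* per-segment geometric jitter of 5–8% (truncated normal) around the
  default geometry table;
* territorial volumes: per-hemisphere means MCA 240, ACA 160, PCA
  130 ml (SDs 28/22/18) under a subject-level scale factor with 9% SD,
  giving total brain volume ≈ 1065 ± 108 ml;
* measurement noise: each artery's reported flow is the mean of 15
  independent draws at 5% relative SD per cross-section. The 5% figure
  is a placeholder for unreported 4D-flow noise, exposed in the
  parameter list; noise is independent across arteries (no shared-scan
  covariance term), the simplest model absent evidence for more.

All positive-valued draws are truncated normals (± 4 SD and positive),
which avoids nonphysical values without materially changing moments.
What the generator does **not** emulate: segmentation error in the
vessel radii (which enters the real method through CTA), intra-subject
correlation of flow errors, pulsatility, and collateral pathways beyond
the circle of Willis. Passing recovery tests therefore demonstrates the
*consistency* of the inverse pipeline with its own forward physics, not
the accuracy of the method against ground truth in vivo.

The default geometry table (per-label lengths/radii: ICA 25 mm/2.0 mm,
MCA1 14/1.5, ACA1 13/1.2, ACA2 20/1.2, ACoA 3/0.7, BA 25/1.6, PCA1
8/1.1, PCA2 20/1.05, PCoA 15/0.7; fetal PCA1 0.5 mm and PCoA 1.1 mm) is
a packaged, editable stand-in for subject-specific segmentation, chosen
once from anatomical literature ranges.

## Cohort statistics

Group comparisons use Student's t-test (paired or unpaired) with a
Lilliefors normality diagnostic attached; identical groups give
$t = 0, p = 1$, and zero-variance comparisons fail with a structured
error. Intra/inter-territorial comparison families are Bonferroni
corrected; with $\alpha = 0.05$ over 18 tests the threshold
$0.05/18 = 0.00278$ is reported to one significant figure as 0.003.

The conductance–volume association is a REML linear mixed model:
conductance (1/R) as response, hemisphere class
(ipsilateral/contralateral/non-stenotic) as fixed factor, territorial
volume as covariate, and a random intercept per subject (a random
intercept only — the simplest structure consistent with repeated
territories per subject; treating the slope as random is not
identifiable at 6 records per subject). The volume covariate is
**grand-mean centred**, so the intercept is the expected conductance at
the cohort's mean territorial volume — with territorial conductances
averaging ≈ 0.022 ml/(mmHg·s), an uncentred intercept of that magnitude
would be inconsistent with any positive slope, so centring is the only
coherent reading and is applied symmetrically in the generator
(`generate_conductance_volume_cohort()`: conductance
$= 0.0224 + 1.84\times10^{-4}(V - \bar V) + b_i + \varepsilon$, subject
SD 0.003 and residual SD 0.005 ml/(mmHg·s), calibrated so the implied
slope standard error matches a printed CI half-width of
$\approx 10^{-5}$). Degenerate noise-free data (zero variance
components) fall back to the equivalent fixed-effects least-squares
fit, whose fixed-effect estimates coincide.

The inter-rater ICC is ICC(2,1) — two-way random effects, absolute
agreement, single rater — implemented directly from its ANOVA
decomposition,

$$ ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}, $$

with the standard F-based confidence interval, so that it remains an
independent oracle rather than a call into a package that might share
code with anything under test. Absolute agreement penalises constant
offsets between raters through $MS_C$; the test suite checks the value
against mean squares computed by `stats::aov`.

## Numerical choices

* Nodal system: dense symmetric solve with the reference node
  eliminated. Domains have at most ~20 nodes, so a dense factorisation
  is exact, fast and dependency-free; a sparse solver would add nothing
  at this size.
* Conservation residuals are recomputed from the returned flows (not
  from the factorisation) and are ≤ 10⁻⁹ ml/s in every converged solve;
  the forward/inverse consistency checks in the test suite run at
  10⁻⁶ relative and observe ~10⁻¹³.
* Tapered segments use the closed-form resistance integral everywhere,
  including partial (cut-window) integrals, so cut-plane pressures have
  no quadrature error.
* Determinism: every stochastic function takes a seed and restores the
  RNG state (`withr::with_seed`); the file pipeline writes a provenance
  header (package version, master seed, config hash) and identical
  config + seed give byte-identical payloads.
* Degenerate inputs: zero boundary flows give a uniform pressure field
  at the reference; empty networks have zero residual; a component
  without a pressure reference, a non-positive BA inflow, a non-positive
  ACA2 sum, or a constant volume covariate each fail with a structured,
  named error rather than a numeric surprise.

## Problem sizes used in the checks

The packaged verification uses 100 subjects per anatomical variant for
noiseless recovery (tolerance 10⁻⁶ relative), 500 subjects at 5% noise
for the error/bias summaries, 100 random anatomies for conservation,
200 replicates of a 46-subject × 6-record cohort for mixed-model slope
recovery and CI coverage, and a 100-subject cohort for the summary
statistics — sizes chosen so the full suite completes in a couple of
minutes on a single core while keeping Monte-Carlo error well below the
tolerances being asserted.

## Known limitations

Beyond the reduced-order fidelity gap: the anterior and posterior
domains are solved independently with their own references (no attempt
to reconcile them into one global field); MAP is taken at the BA for the
posterior domain, which is reasonable only in the absence of posterior
stenoses; territorial volumes are synthetic inputs, so volume–territory
mapping fidelity is outside the model; and no velocity fields, wall
shear stress or pulsatile quantities are produced.
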