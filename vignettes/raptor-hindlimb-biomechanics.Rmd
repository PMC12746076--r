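---
title: "Methods: raptor hindlimb lever mechanics and tendon tensile analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raptor hindlimb lever mechanics and tendon tensile analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raptormech)
```

This vignette documents the models implemented in `raptormech`, their
assumptions, the tunable parameters that matter, and the design choices made
where the design was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The dorsiflexion lever model

Ankle dorsiflexion in raptorial birds is modelled as a quasi-static
third-class lever. The m. tibialis cranialis inserts on a tubercle of the
dorsal tarsometatarsus at distance FA (the inlever) from the intertarsal
joint; prey resistance acts at distance RA (the outlever), taken as the full
tarsometatarsus length. With a prey item of mass $m$, the resistance of prey
is $RP = mg$ (we fix $g = 9.81\ \mathrm{m\,s^{-2}}$, configurable), and

$$F = \frac{RP \cdot RA}{FA}, \qquad MA = \frac{FA}{RA}.$$

Assumptions: single joint, no acceleration (the prey is lifted
quasi-statically), no muscle architecture (pennation, PCSA) — the outputs
are the forces the geometry *demands*, not what the animal can produce.
Arms are stored in meters; `geometry_from_morphometrics()` converts from
millimetre skeletal metrics (RA from tarsometatarsus length, FA from
tubercle distance).

**Torque conventions.** `required_torque()` offers two conventions because
both circulate in the comparative literature. The default,
`"muscle-outlever"`, multiplies the required muscle force by the outlever,
$\tau = F \cdot RA = RP \cdot RA / MA$; this is the convention used in the
reference tables the package reproduces and it preserves the qualitative
result that high-MA (strigid) limbs need less torque for the same prey. The
`"joint"` convention is the standard moment balance $\tau = RP \cdot RA
\;(= F \cdot FA)$, provided for cross-checks; the two differ by the factor
$1/MA$. The convention in effect is recorded in every demo manifest.

## 2. Morphometric summaries and group comparisons

Specimen series (about ten skeletons per species) are summarized into a
representative individual by the arithmetic mean and sample SD ($n-1$) of
each metric. Derived ratios — the aspect ratio (length / midpoint width)
and the proportional tubercle position (tubercle distance / length) — are
computed **from the averaged metrics**, not as means of per-specimen
ratios; the two differ under between-specimen variation and the
representative-individual convention is the one used throughout.

Group differences between accipitrids and strigids use the Mann–Whitney
U test (`mann_whitney_u()`), on the convention $U = \#\{x_i > y_j\}$ plus
half-ties, alongside the orientation-free $W = \min(U,\ n_1 n_2 - U)$.
P-values come from `stats::wilcox.test`: exact (distribution of U over all
label assignments) for small tie-free samples, tie-corrected normal
approximation otherwise. The test suite verifies the exact path against a
brute-force enumeration over all $\binom{n_1+n_2}{n_1}$ assignments for
every $n_1, n_2 \le 6$. The unit of analysis (species-representative values
vs pooled specimens) is an explicit choice in `compare_groups()`; with
three focal species per family only the species level is meaningful.
Normality and homoscedasticity screening is out of scope: the pipeline
takes nonparametric testing as given for the focal comparisons.

## 3. The synthetic tendon model

The cyclic tensile stage needs traces with *known* material properties. The
generator uses a constitutive family chosen so that every quantity the
processing pipeline estimates has a closed form:

* loading (rising) curve: $\sigma_{up}(\varepsilon) = a(e^{b\varepsilon}-1)$ —
  strictly increasing and convex, i.e. the J-shape with a toe region;
* unloading (falling) curve: $\sigma_{down}(\varepsilon) =
  \sigma_m(\varepsilon/\varepsilon_{max})^q$ with
  $\sigma_m = \sigma_{up}(\varepsilon_{max})$.

The rising area is $A_{up} = a\left((e^{b\varepsilon_{max}}-1)/b -
\varepsilon_{max}\right)$ and the falling area
$\sigma_m\varepsilon_{max}/(q+1)$, so setting

$$q = \frac{\sigma_m \varepsilon_{max}}{r\,A_{up}} - 1$$

makes the analytic falling/rising area ratio equal the requested resilience
$r$ exactly. Two feasibility constraints are enforced at construction:
$q \ge 1$, and the unloading curve must not cross above the loading curve
(checked on a 1000-point grid). For strongly J-shaped loading curves the
crossing constraint binds first: e.g. with $b = 20$ resiliences above about
0.85 are rejected as physically unrepresentable in this family — a real
hysteresis loop cannot self-intersect.

**Trace synthesis.** Displacement runs `n_cycles` (default 5) triangular
ramps from 0 to $\varepsilon_{max} L_0$ at 50 mm/min, sampled at 50 Hz,
matching the incremental cyclic protocol; load is
$\sigma(\varepsilon) A_0$ plus a constant pre-tension offset and i.i.d.
Gaussian noise. The sampling grid is chosen so a sample falls **exactly**
on every apex and trough (grid spacing is the nominal period adjusted by at
most one part in the per-leg sample count): peak/trough detection is then
deterministic and the tests need no fuzzy matching. Defaults
($a = 0.5$ MPa, $b = 20$, $\varepsilon_{max} = 0.10$, $A_0 = 5$ mm²,
$L_0 = 15$ mm, $r = 0.75$) give peak stresses ($\approx 3.2$ MPa),
late-region moduli ($\approx 53$ MPa) and resiliences in the middle of the
ranges observed for raptor hindlimb tendons at the 10% increment, and the
0.001 N / 0.01 mm instrument resolutions are far below the default noise
floor. Sub-0.1 N pre-tension and 0.01–0.05 N noise are typical of a zeroed
100 N gauge; the defaults exercise both.

**What the generator does not emulate:** viscoelastic rate dependence,
creep, and the cycle-to-cycle modulus drift seen in real cyclic tests
(moduli highest in cycle 2, lowest in cycle 4). The synthetic model is
cycle-stationary by design, so passing recovery tests show the *processing*
is correct, not that real tendons are stationary. Real traces also show
slack-length artefacts and clamp slippage that the generator does not
model; `segment_cycles()` fails loudly rather than repairing such traces.

## 4. The trace-processing pipeline

`segment_cycles()` finds displacement apexes (local maxima separated by at
least half the nominal period), the troughs between them, and
rising/falling index ranges; finding a number of apexes different from the
expected cycle count is an error with diagnostics, never a silent repair.
The apex sample is assigned to the **rising** segment (tie-break
convention); the falling stress–strain *curve* is nevertheless anchored at
the apex point so the hysteresis loop closes — integrating the falling
curve from the next sample instead would discard the top slice of the
falling area (about 4% at 50 Hz and $\varepsilon_{max} = 0.10$) and bias
every resilience estimate low by several times the recovery tolerance the
pipeline is validated to.

The remaining rules, in pipeline order:

* **Zero offset** (`zero_load_offset()`): mean of the load at the trough
  sample of each of the last three cycles. We read "the three lowest values
  of the three last cycle troughs" as one value per trough; taking minima
  over wider windows would bias the offset low under noise (the minimum of
  $k$ Gaussian samples sits $\sim\sqrt{2\log k}$ SDs below the mean). The
  alternative reading — the three lowest samples anywhere in the trace — is
  available as `zero_rule = "lowest-three"`.
* **Final load** (`final_leg_load()`): mean of the per-cycle peak loads of
  cycles 2–4, minus the offset. Cycle 1 is a pre-stress cycle; cycle 5 is
  excluded so that "the three highest recorded loads" and "peaks of cycles
  2–4" coincide.
* **Stress/strain**: engineering definitions $\sigma = F_t/A_0$ (N/mm² ≡
  MPa), $\varepsilon = \delta/L_0$; both invariant to unit-consistent
  rescaling.
* **Regional moduli** (`region_moduli()`): the rising curve is split into
  three contiguous regions of equal *sample count* (remainders to earlier
  regions; strain-span splitting is available as
  `region_rule = "equal-span"` — the two differ only under nonuniform
  sampling). In each region the ordinary least-squares slope (with
  intercept, equal weights) over the central five points is the modulus;
  regions shorter than five points use all their points (minimum 2) and are
  flagged degraded. The late-region slope is the peak-modulus candidate.
* **Areas and resilience** (`loop_areas_resilience()`): trapezoidal
  integration (`pracma::trapz`) of both curves over their strain supports,
  sign-corrected; resilience = falling / rising.
* **Aggregation** (`aggregate_tendon_results()`): species modulus is the
  mean of the six late-region slopes (2 legs × cycles 2–4), species
  resilience the mean of the six per-cycle values, species load the mean of
  the leg loads, species stress the species load over the mean
  cross-sectional area. Reported SDs are across the pooled six cycle×leg
  values (whether published SDs are across cycles, legs or both is not
  stated anywhere we can check, so the choice is documented rather than
  inferred).

Validation is by parameter recovery: across a 20-seed sweep at
$\le 0.02$ N noise, per-trace resilience must come back within $\pm 0.02$
of the generator's analytic value (observed errors are an order of
magnitude smaller), the late-region modulus must match an OLS oracle
computed from the closed-form curve *on the identical five strain values*
within 1% averaged over the sweep (per-cycle noise on a five-point slope is
itself ~2% SD, so the per-cycle comparison would be a test of the noise,
not the code), the zero offset must recover the injected pre-tension within
four standard errors of its three-trough mean, and the toe < early < late
ordering must hold on every trace.

## 5. Phylogenetic comparative statistics

Implemented from first principles (tree I/O and pruning are delegated to
`ape`, which is also what a practitioner would use):

* `phylo_vcv()` builds the Brownian variance–covariance matrix by
  accumulating each edge length onto all tip pairs descending from it;
  $C_{ij}$ is the shared root-to-MRCA path length. Trees are taken as
  rooted at their representation's root node, so star trees and basal
  polytomies are valid (a star tree of depth $t$ gives $C = tI$). The
  test suite checks the construction against an explicit path-walk oracle
  on random trees.
* `lambda_transform()` multiplies off-diagonal entries by
  $\lambda \in [0,1]$. The upper bound is fixed at 1: values above 1 are
  only defined tree-by-tree and nothing in the intended use requires them.
* `pagel_lambda_ml()` maximizes the profile likelihood of
  $y \sim \mathcal{N}(\mu\mathbf{1},\ \sigma^2 C(\lambda))$, with $\mu$ and
  $\sigma^2$ profiled analytically by GLS and $\lambda$ optimized by a
  0.01-step grid plus local refinement (`stats::optimize`, tol $10^{-8}$);
  the grid guards against the multimodal profiles that pure local search
  can fall into. A flat profile (range $< 10^{-8}$, e.g. any star tree)
  sets `identifiable = FALSE`. Constant traits are rejected as degenerate.
* `pgls_anova_rrpp()` / `pgls_manova_rrpp()` whiten data and design by the
  symmetric inverse square root of $C$ (eigendecomposition;
  near-singular $C$ is an error, not a warning), fit by OLS on the
  whitened scale, and test by randomization of *reduced-model*
  (intercept-only) residuals — the default residual-randomization scheme;
  full-model residual permutation is deliberately not offered. P-values
  use the add-one convention $(1 + \#\{F^* \ge F\})/(N+1)$, so $p > 0$
  always and the null distribution of $p$ is uniform on its achievable
  grid (which makes the type-I calibration below exact in expectation).
  The MANOVA statistic is the trace-form (Goodall-style) ratio of summed
  model to summed residual sums of squares; Wilks/Pillai forms are out of
  scope. With $C = I$ the ANOVA reduces to the classical one-way F exactly
  (asserted to $10^{-10}$), and with one trait column the MANOVA equals
  the ANOVA at identical seeds.

Validation is again by simulation, since the original 62-species trait
table and pruned tree are not bundled: mean ML $\hat\lambda > 0.9$ on
Brownian data (64-tip balanced tree, 50 replicates — matching the
high-signal regime reported for raptor limb traits), null rejection rate
$0.05 \pm 0.02$ at $\alpha = 0.05$ (500 simulations × 199 permutations;
199 keeps the achievable p-grid aligned with $\alpha$ while staying inside
the suite's time budget), and signal destruction by tip permutation
(median $\hat\lambda < 0.2$).

## 6. Problem sizes, determinism and degenerate inputs

Every stochastic function takes an explicit `seed`; there is no hidden
global state, and two runs at the same seed are identical (asserted for
the full demo). Simulation sizes used by the tests and the acceptance
script — 20-seed tensile sweeps, 50 lambda replicates at 64 tips, 500 null
simulations at 199 permutations, 100 random trees for the VCV oracle —
were chosen so the whole validation runs in well under a minute while
keeping Monte-Carlo error comfortably inside each tolerance (e.g. the
type-I rate has SE $\approx 0.01$ at 500 simulations against a $\pm 0.02$
band).

Degenerate inputs fail loudly by design: monotone or constant displacement
traces raise segmentation errors; fewer than 3 (offset) or 4 (final load)
cycles are errors; regions with under two points, non-positive areas,
empty samples, mixed-species summaries, unknown tips and non-positive
lengths/areas all abort with informative messages. Single-specimen and
single-leg inputs are allowed but flagged.

## 7. Known limitations

* The lever model is quasi-static and single-joint; it says nothing about
  what muscle force the animal can actually generate.
* The tendon model has no viscoelasticity, damage or cycle drift; recovery
  tests validate the estimator, not tendon physiology.
* The Mann–Whitney exact path refuses ties (falls back to the corrected
  normal approximation), as is standard.
* Lambda estimation on very small trees (the 6-tip demo) is close to
  unidentifiable; the profile is returned so users can see how flat it is.
* The species-level group comparison on three species per family has a
  minimum achievable two-sided exact p of 0.1; significance claims at that
  sample size rest on the statistic (complete separation, $W = 0$), not
  the p-value.
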