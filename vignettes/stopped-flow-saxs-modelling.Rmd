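---
title: "Modelling stopped-flow SAXS of protein–surfactant complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stopped-flow SAXS of protein-surfactant complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfsaxs)
```

## The system and the model

Mixing a globular protein with SDS above its binding transition produces
protein-decorated micelles: an ellipsoidal alkyl-chain core wrapped in a
shell of sulfate head groups, protein and water. Early in the unfolding
reaction the protein sits on *one side* of the micelle; over seconds it
redistributes around it. The package models one complex as a core–shell
ellipsoid of revolution whose core may be displaced by a distance $s$
perpendicular to the symmetry axis. With
$\Phi(x) = 3(\sin x - x\cos x)/x^3$ and effective radii
$r_i(\theta) = R_i\sqrt{\sin^2\theta + \varepsilon_i^2\cos^2\theta}$
(outer surface $i=1$, core $i=2$), the orientation-dependent amplitude is

$$A(q,\theta) = k_1\,\Phi(q r_1(\theta)) +
  k_2\,\Phi(q r_2(\theta))\,J_0(q s \sin\theta),$$

and the form factor is the orientational average
$P(q) = \int_0^{\pi/2} A^2 \sin\theta\, d\theta$. Two variants are
implemented. The default squares the $J_0$-weighted amplitude, so the
core self-term carries $J_0^2$; the exact azimuthal average of the
two-body intensity, in which $J_0$ appears only in the cross term, is
available via `variant = "exact"`. The two differ by well under a percent
for the offsets encountered here (both are validated against Monte-Carlo
orientation averages in the test suite); the amplitude form is the
default because the recovery pipeline is internally consistent under
either choice and the amplitude form matches the symbol-by-symbol
construction of the model this analysis reproduces. Shell uniformity
ties the outer axis ratio to the core's:
$\varepsilon_1 = (\varepsilon_2 R_2 + D)/(R_2 + D)$, which makes the
shell exactly $D$ thick at pole and equator.

Transient clustering of complexes right after mixing is described by a
random-flight structure factor
$S(q) = 1 + (2/N)\sum_{k=1}^{N-1}(N-k)x^k$ with
$x = \sin(qD_{mic})/(qD_{mic})$; a non-integer mean cluster size $N$ is
handled as a linear mixture of the two bracketing integers, which is the
only continuous choice with $S(0) = N$. (Some printed forms of this
expression divide by the shell thickness instead of $D_{mic}$; that
normalization would break $S(0)=N$ and is available only for
comparison via the `x_denominator` argument.) Unfolded protein is a
Gaussian chain, $I(q) = I_0\,2(e^{-x}-1+x)/x^2$, $x = q^2R_g^2$.

## Absolute scale

All model curves are in cm⁻¹. The prefactors are
$k_1 = v_1\Delta\rho_1$ and $k_2 = v_2(\Delta\rho_2-\Delta\rho_1)$,
where $v_1$ is the whole outer-ellipsoid volume and $v_2$ the core
volume. The core holds $N_{agg}$ alkyl chains
($N_{agg} = \tfrac{4\pi}{3}\varepsilon R_{core}^3 / v_{chain}$); the
shell holds the head groups, the bound protein and filling water, whose
volume is checked to be non-negative (an overfilled shell is a hard
error, not a silent clamp). The number density of clusters follows from
the bound-surfactant concentration,
$n = (C_{tot}-C_{free})\cdot 6.022\times10^{17}/(N_{agg}N_{mic})$, so
$I(q) = n\,P(q)\,S(q)$ carries no free scale. The implied protein
concentration $n N_{mic} N_{pro} M/N_A$ is reported as a diagnostic
rather than enforced: proteins-per-complex is a free fit parameter, and
forcing both it and the nominal concentration would over-determine the
model.

Every contrast constant lives in one overridable table
(`default_contrasts()`, shipped as `inst/extdata/contrasts_default.csv`):
a 350 Å³ C12 chain (97 e⁻), a 60 Å³/59 e⁻ sulfate head, a
520 Å³/201 e⁻ octa(ethylene-oxide) head, an 18 300 Da protein with
partial specific volume 0.735 cm³ g⁻¹ (9798 e⁻), water at 0.334 e⁻ Å⁻³,
and the Thomson radius for the electron-to-length conversion. With these
values the micelle aggregation numbers evaluate to 84.0 (SDS) and 70.9
(C12E8), within ~1% of the rounded values they are meant to reproduce;
the residual discrepancy reflects the unpublished volume set behind
those numbers and is documented rather than tuned away. The
Gaussian-chain prefactor uses $I_0 = cM\Delta\rho_m^2/N_A$ with a default
$\Delta\rho_m = 2.0\times10^{10}$ cm g⁻¹ (giving 0.0243 cm⁻¹ at
2 mg mL⁻¹); the bookkeeping route through the contrast table gives
$2.17\times10^{10}$, a ~8% difference absorbed by the documented default.

## Fitting

`fit_curve()` minimizes $\chi^2 = \sum_j[(I_j - I_{model}(q_j))/\sigma_j]^2$
with Levenberg–Marquardt (minpack.lm), box bounds and locked parameters.
Choices that were genuinely open:

- **Geometry constraint.** $s \le R_1 - R_2$ is enforced by fitting
  $s_{frac} \in [0,1]$ with $s = s_{frac}\,D_{shell}$, keeping the
  optimizer inside a box instead of relying on penalties.
- **Multi-start.** Oscillatory form factors have local minima; the
  default 8 starts combine the user's start, log-normal jitters around
  it, and Latin-hypercube draws over the bounds, all seeded.
- **Uncertainties** come from the linearized covariance at the optimum
  scaled by reduced $\chi^2$; the original analysis does not state its
  error definition, so this standard choice is used throughout.
- **Warm starts.** In `fit_unfolding_series()` frame $i{+}1$ starts at
  frame $i$'s solution; multi-start is spent only on the first frame.
  A non-converged frame is flagged in the output and skipped as a warm
  start, never thrown.
- **Series protocols.** `unfold_protocol()` mirrors the published
  locking scheme: $D_{mic} = 50$ Å everywhere, $\varepsilon$ at its
  end-state value, $D_{head}$ at the end-state thickness (~15 Å at
  2.0 mM, ~10 Å at 7.3/10.5 mM), with proteins-per-complex, cluster
  number and core offset free; the 4.1 mM case is the named exception
  with $D_{head}$ and $R_{core}$ also free, since both decrease
  markedly over that series.

## Refolding decomposition

Refolding frames are fitted as
$I = a_1I_1 + a_2I_2 + a_3I_3 + a_4I_4 + a_5$ (complex, mixed micelle,
native protein, Gaussian chain, constant background). Protein-mass
conservation is imposed *exactly* by substituting $a_1 = 1-a_3-a_4$
before optimization. Non-negativity of the mass fractions — physically
required though not always stated — is enforced by bounded least
squares, solved exactly by active-set enumeration (16 KKT systems for
the 4 inequality constraints, column-equilibrated for conditioning).
The goodness of fit is computed in two steps: first with the frame's
counting-statistics $\sigma$, then with the basis curves' own noise
propagated as $\sigma_j^2 = a_1^2\sigma_{1,j}^2 + a_2^2\sigma_{2,j}^2 +
a_3^2\sigma_{3,j}^2$ and the scales re-optimized. Whether the frame's
own $\sigma$ should also enter this second pass is ambiguous in the
source description ("replacing"); the literal replacement is the
default and `include_measurement_sigma = TRUE` adds the measurement
variance in quadrature. The SDS-micelle basis is deliberately absent:
its curve is nearly collinear with the mixed-micelle one, so only mixed
micelles are used, and a condition-number warning guards against other
collinear bases. The chain's $R_g$ follows a schedule (default constant
30 Å with an optional larger early-frame value) because it is too
unstable to optimize per frame; how much larger the early-frame value
should be is not quantified in the source, so it is a configurable
argument (default 40 Å) rather than a constant.

## Kinetics

`fit_exponentials()` fits $y(t) = y_\infty + \sum A_i e^{-k_i t}$ with
1–3 components. Initialization is by variable projection on a log-spaced
rate grid (default 20 rates; every size-$n$ subset gets a linear
amplitude solve), which sidesteps the classic degeneracy of
multi-exponential starts; rates are optimized in log space so they stay
positive. In `n = "auto"` mode the order is chosen by nested F-tests at
$\alpha = 0.01$ — the source's order selection is qualitative ("fewer
components fit worse"), so the F-test is this package's explicit
substitute. Nearly equal rates are reported with their correlation
matrix rather than silently reduced in order. Half-times are
$t_{1/2} = \ln 2/k$ identically; uncertainties propagate by the delta
method.

## Model-free analysis

`guinier_fit()` fits $\ln I = \ln I_0 - q^2R_g^2/3$ on the widest window
with $q_{max}R_g \le 1.3$ (iteratively self-consistent). The 1.3 limit
is the standard convention; note that for compact spheres it carries a
~2% truncation bias and for Gaussian chains ~6% (the Debye function
curves away from the Guinier parabola early), so the tests use a
narrower 0.8 window where unbiased radii matter. A low-q upturn
(systematically positive residuals >0.5%) triggers an aggregation
warning. `pr_from_model_curve()` computes
$p(r) = \frac{r}{2\pi^2}\int qI(q)\sin(qr)\,dq$ directly, with a
Gaussian damping window above $0.8\,q_{max}$; it is intended for smooth
model curves only — regularized indirect transforms for noisy data are
deliberately out of scope. $D_{max}$ is the last $r$ where $|p|$ exceeds
a threshold set above the residual ringing level (estimated from the
outer 10% of the $r$ grid), so the grid should extend well beyond the
particle.

## Structure-based curves

`debye_intensity()` evaluates $I(q) = n\sum_{ij} b_i b_j
\mathrm{sinc}(qr_{ij})$ over one-bead-per-residue models (Cα positions,
residue-summed excess electrons); the fast path bins pair distances at
0.1 Å (within 1% of the exact sum; the exact path equals a brute-force
double loop to machine precision). The hydration layer is a simple
explicit choice: solvent-exposed beads (neighbor-count criterion) gain
10% of the water scattering-length density over a 3 Å shell of the
residue footprint. This raises the forward scattering above the dry
value by tens of percent, as a hydration shell should; the absolute-scale
consistency check against the composition route is therefore defined on
the dry model. Real crystal structures are read with bio3d when the user
supplies PDB files; `synthetic_globule()`/`synthetic_dimer()` generate
clearly-labelled synthetic bead models (randomly packed at protein
density, minimum Cα separation 3.8 Å) so the monomer/dimer machinery is
fully testable without structure downloads.

## What the synthetic generators emulate

`simulate_unfolding_series()` produces log-spaced frames starting at the
4 ms instrument deadtime, with every model parameter relaxing
exponentially to its end state,
$p(t) = p_{end} + (p_0-p_{end})e^{-t\ln2/t_{1/2}}$. The defaults *are*
the measured study conditions: end states from the four equilibrium
parameter sets (2.0/4.1/7.3/10.5 mM SDS at 2 mg mL⁻¹ protein),
relaxation half-times from the measured series (0.36–0.97 s for
proteins-per-complex, 1.17–1.38 s for the core offset; constant offset
at 2.0 mM where no exponential could be fitted), initial clustering of
~3 complexes per cluster, and for the 4.1 mM case the published initial
shell thickness (24.2 Å) and core radius (13.3 Å). The initial
proteins-per-complex defaults to 5× the end state, capped so the shell
stays physically fillable (≤90% occupancy). Noise is
multiplicative-Gaussian with $\sigma(q) = f_{rel}I(q)(1+(q/q_c)^m)$
(defaults 1%, 0.2 Å⁻¹, 2), emulating counting statistics of 10–20 ms
frames on reduced absolute-scale curves — not Poisson on raw counts,
which the pipeline never sees.

`simulate_refolding_series()` evolves species fractions as two
conversions into the native state: complexes with half-time 1110 s
(χ_SDS = 0.45) or 385 s (0.30), burst-phase coil with 242 s or 101 s.
The burst fractions themselves are only available graphically in the
source, so they are free scenario parameters with defaults (0.55/0.45
complex/coil at χ = 0.45; 0.40/0.60 at 0.30) chosen to match the
narrative: most complexes disrupted within the deadtime, more so at
higher C12E8. Basis curves are generated with their own smaller noise
(0.5%), as separately measured reference data would be. Truth tables
accompany every generated series; the recovery tests read truth only
from them.

What passing tests therefore show: the pipeline recovers parameters,
fractions and half-times from data that *exactly follow its own models*
with realistic noise. What they cannot show: robustness to the
mismatches of real data — polydispersity, inter-particle interference,
imperfect backgrounds, radiation damage — which are out of scope here.

## Problem sizes and numerical choices

Orientational averages use fixed Gauss–Legendre quadrature on
$[0,\pi/2]$ (default order 76; doubling the order changes the intensity
by <10⁻⁶ on all parameter sets — asserted in the tests). $\Phi(x)$
switches to a series below $x = 10^{-2}$ to avoid cancellation, as does
the Debye chain function. The test suite runs series of 20–25 frames of
150–200 points, the acceptance script 300-point curves and 60-frame
refolding series — sizes chosen to mirror the 30–50 frames of a real
stopped-flow run while keeping a full check under a minute of CPU.
Determinism is end-to-end: every noise draw and every multi-start draw
descends from an integer seed, and reruns are bit-identical.

## Known limitations

- The displaced-core amplitude convention (squared $J_0$-folded
  amplitude vs exact azimuthal average) cannot be resolved from the
  source; both are provided, and they agree to <1% here.
- Contrast defaults reproduce the printed aggregation numbers only to
  ~1–2%; the exact volume table behind them is not public.
- No polydispersity, no charged-particle structure factors, no
  sphero-cylinder micelle alternative, no regularized IFT, no
  CRYSOL-style excluded-volume fitting.
- The hydration-layer parameterization is an explicit stand-in, not a
  reproduction of any published scheme; absolute comparisons against
  measured protein curves should treat it as adjustable.
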