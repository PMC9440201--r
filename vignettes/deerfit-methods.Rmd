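---
title: "Models and methods behind deerfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deerfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerfit)
```

`deerfit` analyses four-pulse DEER decays measured on spin-labelled pairs
of a membrane transporter under several conditions at once, and estimates
the pK and Hill coefficient of the pH-coupled conformational transition
from the fitted state populations. This vignette documents the models,
their assumptions, the defaults, and the numerical choices, so that a user
can judge what a given fit does and does not establish.

## The forward model

A normalized dipolar evolution trace is modelled as

$$V(t) = B(t)\,\bigl[(1-\Delta) + \Delta \int K(t,r)\,P(r)\,dr\bigr],$$

the standard factorization into an intermolecular background and the
intramolecular form factor at modulation depth $\Delta$.

**Kernel.** $K(t,r)=\int_0^1 \cos[(1-3u^2)\,\omega_d(r)\,t]\,du$ with
$\omega_d = 2\pi D/r^3$, $D = 52.04$ MHz nm³ — the orientation-averaged
point-dipole kernel for a nitroxide pair, with ideal (complete) pump
excitation. Orientation selection and excitation-bandwidth effects are
deliberately excluded: Q-band measurements on nitroxides at the usual
offsets are well approximated by the powder average, and the global fit
would absorb small deviations into the component widths. The powder
integral is evaluated by Gauss–Legendre quadrature whose node count grows
with the largest dipolar phase ($n = \max(301,\ \lceil 0.75 \times 3\,
\omega_d(r_{\min})\,t_{\max}\rceil$)); on the default grid this keeps the
kernel within $\sim 10^{-10}$ of a $10^6$-point Riemann reference
everywhere in $t \in [0,6]$ µs, $r \in [1.5,8]$ nm. Kernels are cached per
(time axis, grid).

**Background.** $B(t) = \exp(-\kappa t^{d/3})$, a stretched exponential
with rate $\kappa \ge 0$ (µs$^{-d/3}$) and effective dimensionality $d \in
[2, 3.5]$. $d = 3$ is a homogeneous three-dimensional spin bath and is the
default; $d$ is held fixed at 3 during fitting unless `fit_dims = TRUE`
frees it per trace. Fitting $\kappa$ per trace while fixing $d$ reflects
that rate changes (e.g. the markedly steeper decays of clustered nanodiscs
at acidic pH) are identifiable from typical trace lengths, whereas $d$ and
$\kappa$ are strongly correlated and freeing both often degrades the
conditioning of the fit without changing $P(r)$.

**Units.** Time in µs, distances in nm, frequencies in MHz; the default
distance grid is 1.5–8.0 nm in 0.02 nm steps. Structure coordinates are Å
(PDB convention) and converted exactly by ×0.1 at the interface.

**Noise.** Additive white Gaussian noise on $V$; no phase error, dead-time
or ESEEM artifacts (experimental preprocessing is upstream of this
package). The signal-to-noise convention used throughout is
SNR $= \Delta/\sigma_{\text{noise}}$, i.e. noise measured against the
modulated amplitude; the default generator noise of 0.006 with
$\Delta = 0.3$ corresponds to SNR 50.

## Global Gaussian-mixture analysis

$P(r) = \sum_{k=1}^{K} a_k\, \mathcal N(r_{0k}, \sigma_k)$, renormalized
on the grid. In a global fit across conditions, centers and widths are
**shared** — conformer geometry does not depend on pH or membrane mimetic
— while populations are free per condition and $(\Delta, \kappa)$ are free
per trace. Each trace is one condition. The objective is the plain sum of
per-trace squared residuals.

*Parameterization.* Populations use a softmax transform (per condition,
$K-1$ free parameters), so normalization $\sum_k a_{ck} = 1$ holds by
construction and box constraints never bind on populations. Bounds:
$r_0$ within the grid, $\sigma \in [0.05, 1.5]$ nm, $\Delta \in
[0.02, 0.8]$, $\kappa \in [0, 25]$.

*Optimization.* Levenberg–Marquardt (`minpack.lm`) with a multi-start
schedule: two deterministic starts (centers evenly spaced over the grid,
and over the 2.5–5.5 nm window where nitroxide pairs typically fall) plus
seeded jittered restarts (8 starts total by default), a 30-iteration
screening pass, and full refinement of the three best candidates.
Components are reported sorted by center; the softmax parameters are
remapped so the canonical ordering is exact, making results invariant to
the internal component labelling. When scanning $K$, each fit is
additionally warm-started from the $K-1$ solution with its widest
component split in two — this resolves the common local optimum in which
a single broad Gaussian masquerades as two overlapping states.

*Model selection.* BIC on the concatenated residuals,
$\sum_c n_c \log(\mathrm{RSS}_c/n_c) + p \log \sum_c n_c$, with the
per-trace noise variance estimated from the fit; ties break toward
smaller $K$. BIC's parsimony matches the small component counts (1–3)
typical of transporter DEER data; AICc is available via
`criterion = "aicc"`. The full criterion table is retained in the result
so the margin of the selection is always inspectable.

*Uncertainty.* The parameter covariance is $(J_w^\top J_w)^{-1}$ with the
Jacobian of noise-weighted residuals evaluated at the solution. Pointwise
2σ bands on $P(r)$ use first-order (delta-method) propagation,
$\mathrm{sd}[P(r)] = \sqrt{g(r)^\top \Sigma\, g(r)}$ with $g = \partial
P/\partial\theta$, lower bound clipped at zero. Because $P(r)$ does not
depend on background parameters directly, including or excluding them
from $\Sigma$ changes the delta-method band only through correlations; a
seeded parametric bootstrap (`method = "bootstrap"`), which refits
simulated traces and therefore propagates background uncertainty in full,
is provided both as a cross-check and as the fallback advised when the
covariance is singular. In simulation the delta-method band's mean
pointwise coverage of the true $P(r)$ sits near its nominal 95% (the
acceptance script measures it over 200 replicates).

## pH titrations

Populations of a tracked state across pH are fit with the generalized
Hill curve

$$f(\mathrm{pH}) = f_\mathrm{base} + \frac{f_\mathrm{acid}-f_\mathrm{base}}
{1 + 10^{\,n\,(\mathrm{pH}-\mathrm{p}K)}},$$

the standard parameterization in which a single-site
(Henderson–Hasselbalch) equilibrium is exactly the $n = 1$ member. The
midpoint property $f(\mathrm pK) = (f_\mathrm{acid}+f_\mathrm{base})/2$
holds by construction. Plateaus are free by default (the sampled pH range
rarely reaches both asymptotes, and pinning them at 0/1 would bias the
pK); $n$ can be fixed with `fix_n = 1` when independent protonation is
assumed. Weights are inverse-variance from the per-point 2σ population
uncertainties; equal weights reduce exactly to the unweighted fit.
Replacing $f$ by $1-f$ (tracking the complementary state) flips the
plateaus and leaves pK and $n$ unchanged. Series without a transition in
range (population spread < 0.02) are rejected as unidentifiable rather
than fitted.

`titrate_from_fits()` assembles the series from global-fit results using
`state_population()`, which also propagates the softmax covariance into a
2σ uncertainty per point.

## Structure-based distance prediction

A deliberately simple accessible-volume label model stands in for rotamer
library calculations: candidate unpaired-electron positions are drawn at a
fixed tether length $L = 7$ Å from CB, uniformly within a 90° cone about
the CA→CB axis (2000 samples), and rejected if they come within 2.5 Å of
any heavy atom outside the labelled residue. Survivors carry uniform
weights — in an accessible-volume model with hard-sphere exclusion the
Boltzmann weighting at room temperature reduces to uniform weights over
unclashed positions. Multi-model structures pool per-model clouds with
equal model weights. The azimuthal sampling frame is anchored to the
residue's own N/CA/CB atoms, so clouds are exactly equivariant under
rigid-body motion of the structure (a tested invariant). The predicted
$P(r)$ is the weighted pairwise-distance histogram, linearly binned (each
distance splits its weight between flanking grid points, which preserves
the mean) and Gaussian-smoothed (default 0.05 nm). Agreement with an
experimental distribution is scored by the overlap coefficient
$\int \min(P_1, P_2)\,dr \in [0,1]$.

This model reproduces the location and breadth of label clouds well
enough for assigning distance components to conformations; it does not
reproduce rotamer-library energetics, chain dihedral preferences, or
label–surface interactions, so quantitative agreement with full rotamer
calculations is not expected and not claimed.

## Collective variables, salt bridges, restraints

The α angle (intracellular opening) is measured at the center of mass of
the extracellular half of the whole protein, between the centers of mass
of the intracellular halves of the N- and C-domains; β is the symmetric
extracellular angle. Domains are split into halves at the sequence
midpoint by default ("two equal segments"; odd counts put the extra
residue in the first half), with a `by-z` alternative splitting at the
median CA z-coordinate for structures oriented with the membrane normal
along z — the choice matters only if the termini do not alternate sides.
Centers of mass are all-atom and mass-weighted by default; CA-only and
unweighted variants are provided since conventions differ between
analysis codes (for equal-mass selections the two coincide, a tested
property).

Salt bridges are tracked as the per-frame minimum over donor side-chain
nitrogens (NE/NH1/NH2/NZ) × acceptor carboxylate oxygens
(OD1/OD2/OE1/OE2), with a centered, edge-truncated moving average and a
formed fraction below a 4.0 Å cutoff — the conventional salt-bridge
criterion; the cutoff is a parameter. Frames with missing side-chain
atoms become error entries and are excluded from averages.

Restraint energies use the harmonic form $E = \sum_i \tfrac12 k_i
(d_i - d_i^{\rm target})^2$ with $k$ in kcal/mol/Å² and distances
converted to Å. Whether a quoted force constant means $\tfrac12 k x^2$ or
$k x^2$ is a perennial ambiguity; the ½k convention is the default and
`half_k = FALSE` switches to the other, so either bookkeeping can be
reproduced.

## The synthetic-data generators

`generate_deer_dataset()` emulates the measured situation: a two-state
equilibrium whose state-A weight follows the Hill curve in pH, each state
a sum of Gaussians, traces composed with the forward model and white
noise. Defaults are the study conditions: states at 3.0 nm (closed,
acid-favoured) and 4.5 nm (open, base-favoured) with σ = 0.3 nm,
populations shifting 0.8 → 0.2 across pH 4 → 9 (pK 7.6, n = 1, the
intracellular transition of a proton-coupled transporter), Δ = 0.3,
κ = 0.2, 3 µs traces with 300 points, SNR 50. The
`steep_acid_background` flag multiplies κ by 3 for nanodisc traces at
pH ≤ 4.5, mirroring the reversible nanodisc clustering seen at acidic pH.
All generators are pure functions of (spec, seed): sub-seeds are derived
deterministically per condition, and every generator returns a
ground-truth record sufficient to score recovery without re-deriving
anything.

What the generators do *not* emulate — orientation selection, dead-time
artifacts, phase noise, ESEEM, correlated baseline drifts, non-Gaussian
distance components, exchange broadening — bounds what passing tests
show: recovery results demonstrate the estimator is correct and
well-calibrated under the stated model, not that the model is complete
for every measured decay. For real data the fit diagnostics (residuals
vs. noise estimate, criterion table, low-modulation flags) are the
relevant guards.

## Numerical choices and degenerate inputs

- Trapezoidal quadrature on the distance grid throughout; distributions
  are renormalized to unit trapezoidal integral (tolerance 1e-6).
- Traces whose fitted modulation depth lands on its lower bound are
  flagged with a low-modulation warning: a near-pure background carries
  essentially no distance information and the fitted $P(r)$ is then
  unconstrained.
- Singular covariances (e.g. exactly overlapping components) produce an
  error advising the bootstrap band rather than a silently inflated band.
- Component selectors by center window must match exactly one component;
  0 or >1 matches are errors naming the window, and in titration assembly
  the offending pH is named.
- Ties: model-selection ties break toward smaller K; odd-length sequence
  splits put the extra residue in the first half; moving averages truncate
  the window at the edges.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulation sizes — 50 bimodal
datasets for recovery/selection, 200 replicates for band coverage, 30
seeded datasets (7 pH points each) for end-to-end pK recovery, a 20×20
(t, r) grid against a $10^6$-point Riemann oracle for the kernel — were
chosen to make Monte-Carlo error comfortably smaller than the tolerances
being checked while keeping a full run in the minutes range on a single
core.

## Known limitations

- One trace per condition; replicate decays for the same condition must
  currently be fitted as separate conditions (their populations will agree
  within uncertainty, which is itself a useful consistency check).
- No Tikhonov or other model-free inversion: the package is built around
  the Gaussian-mixture hypothesis, and badly multimodal or highly skewed
  distributions will be summarized, not resolved.
- No global fits across *different* spin pairs, and no joint fit of the
  titration directly to the traces (populations are estimated per pH,
  then fitted; the two-stage procedure is what the uncertainty weighting
  reflects).
- The label model's fixed tether and hard clash cutoff ignore label
  flexibility differences between buried and exposed sites.
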