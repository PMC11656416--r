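---
title: "pKa of NMR-invisible acids from a single pH-gradient experiment: models, choices, limitations"
author: "gradpka"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gradpka)
```

## The measurement model

The method determines the acid dissociation constant and total
concentration of an acidic analyte without ever observing it. A basic
indicator diffuses along the tube; each chemical-shift-imaging slice is an
independent equilibrium between the analyte, the indicator, strong co-ions
and water. Two observables per slice — the indicator chemical shift and its
integral relative to an inert reference — yield three derived quantities:

1. **pH** from the shift. With limiting shifts $\delta_H$ (protonated) and
   $\delta_L$ (deprotonated),
   $$\mathrm{pH} = \mathrm{p}K_{a,0} + \Delta z^2\, A f(I) +
     \log_{10}\frac{\delta_H-\delta_{obs}}{\delta_{obs}-\delta_L},
     \qquad f(I)=\frac{\sqrt I}{1+\sqrt I}-0.3I,$$
   the Davies form of the ionic-strength correction with $A=0.509$ at
   298 K. $\Delta z^2$ is the difference of squared charges between the
   protonated and deprotonated indicator (+1 for nitrogenous bases, −1 for
   carboxylates); the sign convention follows from
   $\mathrm{p}K_a^{mixed} = \mathrm{p}K_{a,0} + A f(I)\,\Delta z^2$ for
   constants written with concentrations of the conjugate pair and the
   H$^+$ activity. The ratio form handles both shift orientations
   (formate moves downfield on protonation, the others upfield).

2. **Indicator concentration** from per-proton integral ratios against the
   reference compound, times a calibrated correction factor.

3. **$\kappa$**, the concentration of protons transferred from the
   analyte: protons sitting on the indicator plus free protons,
   $\kappa = f_H C_{ind} + 10^{-\mathrm{pH}}/\gamma_1(I)$. The free-proton
   term matters for low-p$K_a$ analytes (phosphoric acid). $\kappa$ is
   deliberately kept in this two-term form; the hydroxide the indicator
   draws from water is neglected, consistent with the low basicity of the
   indicators. The residual effect of that neglect is quantified below.

$\kappa$ obeys $\kappa = C K_a/(K_a + a_H)$ with $a_H = 10^{-\mathrm{pH}}$,
so $1/\kappa$ is linear in $a_H$ with intercept $1/C$ and slope
$1/(K_a C)$.

### Assumptions

- The analyte concentration is homogeneous along the tube; analyte
  migration (observed experimentally for some polyelectrolytes) is not
  modelled.
- Indicator protonation from water is negligible in the working range.
- DSS referencing (0 ppm) has been applied upstream.
- The Davies expression is adequate (ionic strengths up to ~0.1 M here;
  the expression is conventionally trusted to ~0.5 M). No ion pairing, no
  temperature dependence.
- $K_w = 10^{-14}$, with no activity correction applied to water's
  autoionization — hydroxide is a spectator in the working range pH 1–10.

## The speciation oracle

`solve_speciation()` is an exact charge-balance solver: mass-action laws
for every dissociable site (successive mixed constants, multiprotic acids
site-wise), the indicator's conjugate acid, strong monovalent co-ions, and
water. It exists so that every shortcut in the measurement model can be
checked against a computation that makes none. The central identity — that
$\kappa$ measured from the indicator equals the deprotonated-analyte
concentration (plus hydroxide) — is a rearranged charge balance and is
verified to sub-nanomolar agreement in the tests.

Numerics: the root in $[\mathrm{H^+}]$ is bracketed in $[10^{-14}, 1]$ M
(monotone charge function), bisected 60 times on the log scale, then
polished by damped Newton steps with a numerical derivative; the returned
charge residual is below $10^{-12}$ M. With activity corrections on, the
ionic strength is iterated to a fixed point; the loop stops at
$|\Delta \mathrm{pH}| < 10^{-12}$ — far tighter than needed for pH itself —
so that bookkeeping identities downstream hold to $10^{-9}$ M. Degenerate
inputs (negative concentrations, unbracketed roots) raise errors that name
the offending slice.

Setting `Kw = 0` and `use_activity = FALSE` turns the solver into the
ideal-solution textbook model; the tests use this mode to compare against
the closed-form monoprotic quadratic (which also omits water) at
$|\Delta \mathrm{pH}| < 10^{-8}$, and a cubic `polyroot` oracle including
water against the default mode. The quadratic genuinely disagrees with the
water-including model by ~0.02 pH at the weak-and-dilute corner
(p$K_a$ 10, 1 mM), which is why the comparison is made like-for-like.

## Fitting: two design choices that matter

**Per-slice activity adjustment (default `activity = "per_slice"`).** The
mixed constant in the titration relation depends on $I$, and $I$ varies
along the tube by up to two orders of magnitude with the indicator
concentration. Fitting raw $a_H$ and back-correcting the fitted constant at
the median $I$ (the `"median"` option) leaves a curvature bias we measured
at ~0.08 p$K_a$ units and 18% in $C$ for the boric-acid configuration —
far larger than the noise floor. Replacing the regressor by
$\tilde a_H = a_H\,10^{A f(I_i)\Delta z^2_{analyte}}$ makes the relation
exactly linear in the *thermodynamic* constant, eliminating the bias at the
cost of needing the analyte's site charge change $\Delta z^2_{analyte}$
(−1 neutral acids, +1 cationic acids, −3 for the second phosphate
dissociation). Noise-free round trips then recover the generating
p$K_{a,0}$ to better than 0.001 and $C$ to ~0.3% (the residue being the
neglected hydroxide term, visible only for the highest-pH configurations).

**Variance-stabilized weights (default `weights = "kappa2"`).** The
reciprocal transform maps multiplicative noise on $\kappa$ into noise on
$1/\kappa$ whose standard deviation scales as $1/\kappa$ — across a tube
$1/\kappa$ spans one to two decades, so the near-equivalence-point slices
can carry residual variances $10^4$ times larger than the well-buffered
ones. Plain unweighted regression then occasionally returns estimates off
by a full pH unit, or a negative intercept (a negative concentration).
This is precisely the classical failure of double-reciprocal
(Lineweaver–Burk) plots, and the classical remedy applies: weights
proportional to $\kappa^2$. Across 12 seeds × 9 benchmark analytes at the
default noise, the maximum $|\Delta \mathrm{p}K_a|$ was 0.13 weighted
versus 0.73 unweighted. `weights = "none"` reproduces the plain regression
line. On noise-free data all options coincide.

The nonlinear route (`fit_nonlinear()`, Levenberg–Marquardt on the
untransformed relation, started from the linear estimates) is the
cross-check: on noise-free monoprotic data the two routes agree to
$10^{-4}$ p$K_a$ units.

Confidence intervals are t-based (n−2 df) with delta-method propagation to
$C = 1/\mathrm{intercept}$ and $\mathrm{p}K_a = -\log_{10}(a/b)$; the
propagation is documented as approximate for intercepts near zero.
Site-per-molecule ratios are returned unrounded; rounding happens only in
reports.

## The simulator and what it does (not) emulate

`tube_system()`/`simulate_tube()` forward-model the experiment: an erfc
diffusion profile $C(h) = C_0\,\mathrm{erfc}(h/2\sqrt{Dt})$ from the tube
base (or from the top for the dense-liquid layering geometry), exact
per-slice equilibria via the oracle, shifts via the inverted pH relation,
integrals encoding the indicator concentration through the reference
ratio, and seeded Gaussian noise.

Defaults and why:

- **Geometry**: 64 slices × 0.41 mm (26.2 mm active region), offset 5 mm
  from the base — the standard CSI raster for a 5 mm tube.
- **Diffusion**: $D = 10^{-9}\,\mathrm{m^2/s}$ (typical small molecule in
  water), $t = 3.6\times 10^4$ s. The erfc profile is a simple stand-in for
  the gradient-development model used to time real experiments — it
  reproduces the monotone shape, not the source kinetics. With these
  values the indicator concentration falls ~2000-fold across the active
  region, so the usable pH window is fully traversed.
- **Source concentration**: chosen automatically so the slice nearest the
  source sits 0.3 units past the top of the indicator window (capped at
  1.5 M); this mirrors how solid-base deposits of a few mg equilibrate to
  a few hundred mM locally.
- **Noise**: shift sd 0.002 ppm, integral relative sd 2% — representative
  of a 500 MHz spectrometer with 4-scan CSI rows; both configurable, both
  honoured bitwise under a fixed seed.
- **Co-ions**: counter-ions of salt-form analytes (Cl⁻ of glycine·HCl,
  NH₃OHCl, NH₄Cl; Na⁺ of NaH₂PO₄) and the 0.2 mM Na-DSS reference enter
  the ionic strength and charge balance; carboxylate indicators bring
  their Na⁺ slice by slice.

What passing simulated tests does **not** show about real data: lineshape
and water-suppression artefacts, B₀/B₁ inhomogeneity, convection,
indicator self-association, temperature drift of limiting shifts, and
analyte migration along the gradient are all outside the generator. The
simulator validates the *inference chain*, not the spectroscopy.

`simulate_calibration()`/`calibrate_limits()` reproduce the limiting-shift
procedure: in a tube of 0.01 M strong acid, $\kappa$ is known, so the
protonated fraction at each slice follows from the known indicator p$K_a$
and the slice equilibrium, and regressing $\delta_{obs}$ on $f_H$ yields
$\delta_L$ (intercept) and $\delta_H$ (intercept + slope). Noise-free, the
recovery is exact to machine precision; at default noise, limits are
recovered within 0.01 ppm across 50 seeds. Where the base is in large
excess the measured $\kappa$ exceeds the acid concentration by exactly the
hydroxide drawn from water (up to ~4 µM for 2-MI) — the tests assert this
identity rather than pretending $\kappa$ is perfectly constant.

## Validity filtering

Slices are rejected, with logged reasons, when the shift sits at or beyond
a limiting value, when the indicator protonated fraction leaves
[0.05, 0.95] (a shift-margin version of the rule that pH read more than
about one unit from the indicator p$K_a$ is unreliable), when the pH falls
outside the indicator's tabulated window, or when $\kappa \le 0$. Fewer
than three surviving slices is an error, not a fit.

## Known limitations

- **Extrapolating configurations under-cover.** When the analyte p$K_a$
  lies inside the indicator window (phosphoric acid with triazole,
  4-cyanophenol with 2-MI) the 95% CI covers the truth at the nominal rate
  (measured 93–94% over 200 noisy replicates). When the analyte p$K_a$
  sits just outside the window (boric acid, ammonium with 2-MI) the fit
  extrapolates, shift noise enters the regressor, and coverage drops to
  ~80%. Treat CIs for such pairings as optimistic; choosing an indicator
  within ~1 unit of the expected p$K_a$ avoids the regime.
- **Multi-site analytes get one effective p$K_a$.** A two-site acid bends
  the reciprocal plot (systematic residual curvature) and the fitted value
  lands between the site constants; no multi-site fit is attempted.
- **The hydroxide term is neglected in $\kappa$** (by construction of the
  two-term formula); for configurations reaching pH 9+ this leaves a
  ~0.3% downward-compatible bias in $C$ and ~0.001 in p$K_a$.
- The composition context used for the ionic-strength estimate is
  whatever the user declares; for a truly unknown analyte the estimate
  rests on the indicator and declared co-ions alone. With nothing declared
  at all, the estimate is zero and the plain conversion applies.
- Problem sizes in the test suite — 64-slice tubes, 200-replicate
  coverage runs, 50-seed calibration sweeps, 12-seed benchmark sweeps —
  were chosen as the smallest sets that make the statistical assertions
  stable.
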