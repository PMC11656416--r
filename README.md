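# gradpka

Determination of the acid dissociation constant (pKa) and total
concentration of acidic species that are **invisible to NMR** — polymers
with broad resonances, proteins, inorganic oxyacids, exchangeable-proton
compounds — from a *single* ¹H chemical shift imaging (CSI) experiment on a
pH gradient.

## The idea

A small basic **indicator** (2-methylimidazole, 2,6-lutidine, acetate,
formate or 1,2,4-triazole) diffuses along a 5 mm NMR tube containing the
analyte solution, creating a smooth pH gradient. Each 0.41 mm CSI slice
yields one spectrum, from which two numbers are read:

- the **indicator chemical shift** δ_obs, which interpolates between the
  protonated limit δ_H and deprotonated limit δ_L and gives the slice pH:

      pH = pKa,0 + Δz² · A·(√I/(1+√I) − 0.3·I)
                 + log₁₀((δ_H − δ_obs)/(δ_obs − δ_L))

  where Δz² is the change in squared charge on protonation (+1 nitrogenous,
  −1 carboxylate), A = 0.509 at 298 K and I is the ionic strength;

- the **indicator integral**, which against an inert integral reference of
  known concentration gives the local indicator concentration C_indicator.

The concentration of protons the analyte has surrendered at that slice is

    κ = f_H · C_indicator + [H⁺]_free ,    f_H = (δ_obs − δ_L)/(δ_H − δ_L)

and obeys the titration relation κ = C_analyte·K_a/(K_a + 10^−pH), whose
reciprocal form

    1/κ = 1/C_analyte + (1/(K_a·C_analyte)) · 10^−pH

is a straight line in 10^−pH: the intercept gives C_analyte, the
intercept/slope ratio gives K_a. The analyte itself is never observed.

The package implements the full chain — an exact charge-balance speciation
solver (the internal oracle), shift↔pH conversion with self-consistent
Davies ionic-strength correction, the slice pipeline with validity
filtering, linear (variance-stabilized) and nonlinear fits with 95%
confidence intervals, limiting-shift calibration against a strong-acid
gradient, and a forward simulator of the whole experiment so every stage is
testable without a spectrometer.

## Worked example

Simulate a boric-acid tube (10 mM, literature pKa,0 9.19, 2-MI indicator)
with realistic noise (0.002 ppm on shifts, 2% on integrals), then analyze
it as experimental data would be:

```r
library(gradpka)

sc  <- benchmark_scenario("boric_acid", seed = 1)
sim <- simulate_tube(sc$sys)

pts <- build_points(sim$peaks, sc$sys$ind, sc$sys$ref, sim$comp)
pts
#> slice_points: 48 retained, 16 rejected (indicator 2-MI)
#> frac_protonated outside retained range   pH outside indicator window
#>                                      2                            14
#>   pH 7.06-8.97, median I 0.001337 M

fit_linear(pts, dz2_analyte = sc$dz2_analyte)
#> pKa fit (linear route, 48 points):
#>   pKa,0      9.236 +/- 0.073 (95% CI)
#>   C_analyte  0.01121 +/- 0.0016 M
#>   R^2 0.9900, mixed pKa 9.219 at median I 0.001337 M
```

The fitted pKa,0 (9.24 ± 0.07) recovers the generating value 9.19 within
its confidence interval, and the concentration (11.2 ± 1.6 mM) the true
10 mM. Slices whose shift sits too close to a limiting value or whose pH
falls outside the indicator's usable window (7–9 for 2-MI) are rejected
with logged reasons, never silently.

Protein quantities follow from the same fit. For a protein at 3.8 mg/mL
and 21 kDa with a fitted acid-site concentration of 2.38 ± 0.24 mM:

```r
s <- sites_per_molecule(2.38e-3, protein_molarity(3.8, 21000), 0.24e-3)
#> sites: 13.2 +/- 1.3   (i.e. 13 +/- 1 acidic sites per molecule)
```

Limiting shifts are calibrated against a tube of 0.01 M strong acid, where
κ is known to equal the acid concentration:

```r
ind <- get_indicator("acetate")
cal <- calibrate_limits(simulate_calibration(ind, 0.01, seed = 2), ind, 0.01)
#> limiting shifts: delta_H 2.0829 +/- 0.0008, delta_L 1.9060 +/- 0.0020 ppm
```

## Command line

A thin dispatcher is installed under `inst/cli/gradpka`:

```sh
gradpka simulate  --scenario scenario.json --out-prefix run1
gradpka analyze   --peaks run1_peaks.csv --config config.json [--nonlinear]
gradpka calibrate --peaks cal_peaks.csv --kappa 0.01 --config config.json
```

Configs are flat JSON (`schema_version`, indicator/reference names or full
definitions, optional composition); scenario configs must carry a `seed`.

## The methods vignette

`vignettes/gradient-pka.Rmd` documents the model and its assumptions, the
speciation oracle, the choice of variance-stabilized weighting and
per-slice activity adjustment, what the simulator does and does not
emulate, and known limitations.
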