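# Ready-made simulation scenarios for the nine benchmark analytes, each at
# its literature thermodynamic pKa and stated concentration (10 mM, except
# phosphoric acid at 60 mM), paired with the indicator whose pKa lies
# within about 2 units. Salt-form analytes contribute their counter-ion to
# the ionic strength and charge balance; the 0.2 mM Na-DSS shift reference
# is included as a strong ion pair. The lutidine scenario diffuses from the
# top (the dense-liquid layering geometry).

benchmark_defs <- function() {
  list(
    glycine_hcl = list(
      acid = acid_species("glycine.HCl", c(2.35, 9.78), 0.010, 1L),
      ind = "1,2,4-triazole", site = 1L, anions = 0.010),
    h3po4 = list(
      acid = acid_species("H3PO4", c(2.16, 7.21, 12.35), 0.060, 0L),
      ind = "1,2,4-triazole", site = 1L),
    nah2po4 = list(
      acid = acid_species("H3PO4", c(2.16, 7.21, 12.35), 0.010, 0L),
      ind = "2-MI", site = 2L, cations = 0.010),
    cyanophenol4 = list(
      acid = acid_species("4-cyanophenol", 7.95, 0.010, 0L),
      ind = "2-MI", site = 1L),
    boric_acid = list(
      acid = acid_species("boric acid", 9.19, 0.010, 0L),
      ind = "2-MI", site = 1L),
    nh3ohcl = list(
      acid = acid_species("NH3OHCl", 5.94, 0.010, 1L),
      ind = "2,6-lutidine", site = 1L, anions = 0.010, top = TRUE),
    nh4cl = list(
      acid = acid_species("NH4Cl", 9.24, 0.010, 1L),
      ind = "2-MI", site = 1L, anions = 0.010),
    benzoic_acid = list(
      acid = acid_species("benzoic acid", 4.20, 0.010, 0L),
      ind = "acetate", site = 1L),
    glycolic_acid = list(
      acid = acid_species("glycolic acid", 3.89, 0.010, 0L),
      ind = "formate", site = 1L)
  )
}

#' Names of the packaged benchmark scenarios
#' @return Character vector.
#' @export
benchmark_scenarios <- function() names(benchmark_defs())

#' Build a packaged benchmark scenario
#'
#' @param name One of [benchmark_scenarios()].
#' @param seed Noise seed.
#' @param noise_shift_sd,noise_integral_rel_sd Noise levels (defaults
#'   0.002 ppm and 2%).
#' @param ... Further overrides passed to [tube_system()].
#' @return List of class `pka_scenario`: `name`, `sys` (a [tube_system()]),
#'   `pKa_true` (literature pKa,0 of the probed site), `dz2_analyte`
#'   (charge change of that site, for the fit back-correction), `site`.
#' @export
benchmark_scenario <- function(name, seed = 1L, noise_shift_sd = 0.002,
                               noise_integral_rel_sd = 0.02, ...) {
  defs <- benchmark_defs()
  if (!name %in% names(defs))
    stop(sprintf("unknown scenario '%s'; packaged scenarios are: %s",
                 name, paste(names(defs), collapse = ", ")), call. = FALSE)
  d <- defs[[name]]
  dss <- 2e-4
  sys <- tube_system(
    analyte = d$acid, ind = get_indicator(d$ind),
    source_from_top = isTRUE(d$top),
    strong_cations = dss + (if (is.null(d$cations)) 0 else d$cations),
    strong_anions = dss + (if (is.null(d$anions)) 0 else d$anions),
    noise_shift_sd = noise_shift_sd,
    noise_integral_rel_sd = noise_integral_rel_sd,
    seed = seed, ...)
  structure(
    list(name = name, sys = sys, pKa_true = d$acid$pKa0[d$site],
         dz2_analyte = site_dz2(d$acid$z0, d$site), site = d$site),
    class = "pka_scenario")
}
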