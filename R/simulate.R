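# Forward simulation of a complete gradient experiment. A basic indicator
# diffuses from a solid deposit at the tube base (or a layer floated on
# top) into the analyte solution; each 0.41 mm CSI slice is an independent
# acid-base equilibrium solved exactly by solve_speciation(); the observed
# shift follows from the slice pH and the integrals encode the indicator
# concentration, with seeded Gaussian noise on both. Ground truth is kept
# alongside so every pipeline stage can be checked without experimental
# data.
#
# The concentration profile is a semi-infinite-medium diffusion solution,
# C(h) = C0 * erfc(h / (2 sqrt(D t))). This is a deliberately simple
# stand-in for the gradient-development model used to time real
# experiments; it produces the same qualitative monotone profile without
# modelling the source dissolution kinetics.

erfc_ <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

#' Describe a simulated gradient tube
#'
#' @param analyte An [acid_species()], or `NULL` for an analyte-free tube
#'   (calibration).
#' @param ind The diffusing basic [indicator()].
#' @param source_conc Source concentration `C0` (mol/L) at the boundary.
#'   `NULL` (default) chooses it automatically so that the slice nearest
#'   the source sits just past the top of the indicator's pH window
#'   (+0.3 units), ensuring the window is traversed inside the active
#'   region; capped at 1.5 M.
#' @param D Diffusion coefficient (m^2/s); 1e-9 is typical of small
#'   molecules in water.
#' @param t Elapsed diffusion time (s). The default 3.6e4 s (10 h) makes
#'   the indicator concentration fall by roughly three orders of magnitude
#'   across the 26 mm active region, so both window edges are exercised.
#' @param n_slices Number of CSI slices (64).
#' @param slice_thickness Slice thickness (mm, 0.41; 64 x 0.41 = 26.2 mm
#'   active region).
#' @param active_region_offset Distance (mm) from the tube base (the
#'   source boundary) to the bottom of the NMR-active region; accounts for
#'   the solid deposit and glass beads.
#' @param source_from_top Logical; `TRUE` simulates a dense-liquid base
#'   layered on top of the solution (the 2,6-lutidine geometry) as
#'   diffusion from the top boundary.
#' @param column_height Liquid column height (mm), the top boundary
#'   position when `source_from_top`.
#' @param strong_cations,strong_anions Strong monovalent co-ion
#'   concentrations (mol/L), e.g. Cl- of salt-form analytes and the DSS/Na+
#'   shift reference. The counter-ion of carboxylate indicators is added
#'   automatically slice by slice.
#' @param ref The [reference_compound()] present in the solution.
#' @param noise_shift_sd Gaussian noise sd on the observed shift (ppm);
#'   default 0.002.
#' @param noise_integral_rel_sd Relative Gaussian noise sd on integrals;
#'   default 0.02.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param use_activity Apply Davies corrections in the slice equilibria.
#' @param Kw Water autoionization product used by the slice equilibria
#'   (`1e-14`; `0` disables autoionization for algebraic checks).
#' @return Object of class `tube_system`.
#' @export
tube_system <- function(analyte = NULL, ind, source_conc = NULL,
                        D = 1e-9, t = 3.6e4, n_slices = 64L,
                        slice_thickness = 0.41,
                        active_region_offset = 5,
                        source_from_top = FALSE, column_height = NULL,
                        strong_cations = 2e-4, strong_anions = 2e-4,
                        ref = packaged_references()$dioxane,
                        noise_shift_sd = 0.002,
                        noise_integral_rel_sd = 0.02, seed = 1L,
                        use_activity = TRUE, Kw = 1e-14) {
  stopifnot(inherits(ind, "nmr_indicator"),
            inherits(ref, "reference_compound"))
  if (!is.null(analyte)) stopifnot(inherits(analyte, "acid_species"))
  if (t <= 0) stop("elapsed time t must be > 0", call. = FALSE)
  stopifnot(D > 0, n_slices >= 3, slice_thickness > 0,
            strong_cations >= 0, strong_anions >= 0)
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  if (is.null(column_height))
    column_height <- active_region_offset + n_slices * slice_thickness + 5
  sys <- structure(
    list(analyte = analyte, ind = ind, source_conc = source_conc,
         D = D, t = t, n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness,
         active_region_offset = active_region_offset,
         source_from_top = source_from_top,
         column_height = column_height,
         strong_cations = strong_cations, strong_anions = strong_anions,
         ref = ref, noise_shift_sd = noise_shift_sd,
         noise_integral_rel_sd = noise_integral_rel_sd,
         seed = as.integer(seed), use_activity = use_activity,
         Kw = Kw, integral_scale = 1000),
    class = "tube_system")
  if (is.null(sys$source_conc)) sys$source_conc <- auto_source_conc(sys)
  sys
}

slice_heights <- function(sys)
  sys$active_region_offset +
  (seq_len(sys$n_slices) - 0.5) * sys$slice_thickness

# distance from the diffusion source to a height above the tube base
source_distance <- function(sys, height_mm) {
  if (sys$source_from_top) sys$column_height - height_mm else height_mm
}

#' Diffusion concentration profile of the indicator
#'
#' `C(h) = C0 * erfc(x / (2 sqrt(D t)))` with `x` the distance (mm) from
#' the source boundary; monotone non-increasing away from the source and
#' equal to `C0` at the source.
#'
#' @param sys A [tube_system()].
#' @param height_mm Height(s) above the tube base (mm), `>= 0`.
#' @return Indicator concentration (mol/L).
#' @export
gradient_profile <- function(sys, height_mm) {
  stopifnot(inherits(sys, "tube_system"))
  if (sys$t <= 0) stop("elapsed time t must be > 0", call. = FALSE)
  if (any(height_mm < 0)) stop("height must be >= 0", call. = FALSE)
  x <- source_distance(sys, height_mm) * 1e-3
  x[x < 0] <- 0
  sys$source_conc * erfc_(x / (2 * sqrt(sys$D * sys$t)))
}

# indicator concentration needed to hold the slice nearest the source just
# past the top of the pH window, scaled back to the source boundary
auto_source_conc <- function(sys, target_overshoot = 0.3, cap = 1.5) {
  target <- sys$ind$pH_window[2] + target_overshoot
  acids <- if (is.null(sys$analyte)) list() else list(sys$analyte)
  ph_at <- function(C_ind) {
    extra_na <- if (sys$ind$dz2 == -1L) C_ind else 0
    solve_speciation(acids, sys$ind, C_ind,
                     strong_cations = sys$strong_cations + extra_na,
                     strong_anions = sys$strong_anions,
                     use_activity = sys$use_activity, Kw = sys$Kw)$pH
  }
  f <- function(lc) ph_at(10^lc) - target
  hi <- log10(cap)
  C_star <- if (f(hi) < 0) {
    warning(sprintf(
      "source concentration capped at %.2g M; pH window top not reached",
      cap), call. = FALSE)
    cap
  } else 10^stats::uniroot(f, c(-6, hi), tol = 1e-10)$root
  h0 <- slice_heights(sys)
  h0 <- if (sys$source_from_top) max(h0) else min(h0)
  u <- source_distance(sys, h0) * 1e-3 / (2 * sqrt(sys$D * sys$t))
  min(C_star / erfc_(u), cap / erfc_(u))
}

#' Simulate a full gradient experiment
#'
#' Per slice: indicator concentration from the diffusion profile at the
#' slice mid-height, exact equilibrium via [solve_speciation()], observed
#' shift via [shift_from_ph()] at the slice pH and ionic strength,
#' integrals scaled so the indicator:reference per-proton ratio encodes the
#' indicator concentration (including the reference's correction factor),
#' then seeded Gaussian noise. Ground truth is returned alongside.
#'
#' @param sys A [tube_system()].
#' @return Object of class `tube_simulation`: `peaks` (the peak-table
#'   data.frame consumed by [build_points()]), `truth` (data.frame
#'   `height_mm, pH_true, C_ind_true_M, kappa_true_M, I_true_M,
#'   f_H_true, released_true_M`), `states` (list of `speciation_state`),
#'   `sys`, and `comp` (the [composition()] for downstream analysis).
#' @export
simulate_tube <- function(sys) {
  stopifnot(inherits(sys, "tube_system"))
  h <- slice_heights(sys)
  C_ind <- gradient_profile(sys, h)
  acids <- if (is.null(sys$analyte)) list() else list(sys$analyte)
  states <- vector("list", sys$n_slices)
  for (i in seq_len(sys$n_slices)) {
    extra_na <- if (sys$ind$dz2 == -1L) C_ind[i] else 0
    states[[i]] <- tryCatch(
      solve_speciation(acids, sys$ind, C_ind[i],
                       strong_cations = sys$strong_cations + extra_na,
                       strong_anions = sys$strong_anions,
                       use_activity = sys$use_activity, Kw = sys$Kw),
      error = function(e)
        stop(sprintf("slice %d (%.2f mm): %s", i, h[i],
                     conditionMessage(e)), call. = FALSE))
  }
  pH <- vapply(states, `[[`, numeric(1), "pH")
  I <- vapply(states, `[[`, numeric(1), "I")
  f_H <- vapply(states, `[[`, numeric(1), "frac_protonated")
  H <- vapply(states, `[[`, numeric(1), "H")
  released <- vapply(states, protons_released, numeric(1), acids)
  delta_true <- shift_from_ph(pH, sys$ind, if (sys$use_activity) I else 0)
  kappa_true <- f_H * C_ind + H

  s <- sys$integral_scale
  int_ref_true <- s * sys$ref$n_protons * sys$ref$conc
  int_ind_true <- s * sys$ind$n_protons * C_ind /
    sys$ref$correction_factor
  noisy <- withr::with_seed(sys$seed, {
    n <- sys$n_slices
    list(delta = delta_true + stats::rnorm(n, 0, sys$noise_shift_sd),
         ind = int_ind_true *
           (1 + stats::rnorm(n, 0, sys$noise_integral_rel_sd)),
         ref = rep(int_ref_true, n) *
           (1 + stats::rnorm(n, 0, sys$noise_integral_rel_sd)))
  })
  structure(
    list(peaks = data.frame(height_mm = h, delta_obs_ppm = noisy$delta,
                            integral_indicator = noisy$ind,
                            integral_reference = noisy$ref),
         truth = data.frame(height_mm = h, pH_true = pH,
                            C_ind_true_M = C_ind,
                            kappa_true_M = kappa_true, I_true_M = I,
                            f_H_true = f_H, released_true_M = released),
         states = states, sys = sys,
         comp = composition(acids, sys$strong_cations, sys$strong_anions)),
    class = "tube_simulation")
}

#' @export
print.tube_simulation <- function(x, ...) {
  cat(sprintf(
    "tube_simulation: %d slices, indicator %s (C0 %.3g M), pH %.2f-%.2f\n",
    x$sys$n_slices, x$sys$ind$name, x$sys$source_conc,
    min(x$truth$pH_true), max(x$truth$pH_true)))
  invisible(x)
}

#' Write a simulation as peak-table and ground-truth CSVs
#'
#' @param sim A `tube_simulation`.
#' @param prefix Output path prefix; writes `<prefix>_peaks.csv` and
#'   `<prefix>_truth.csv`.
#' @return The two paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "tube_simulation"))
  p1 <- paste0(prefix, "_peaks.csv"); p2 <- paste0(prefix, "_truth.csv")
  utils::write.csv(sim$peaks, p1, row.names = FALSE)
  utils::write.csv(
    sim$truth[c("height_mm", "pH_true", "C_ind_true_M", "kappa_true_M")],
    p2, row.names = FALSE)
  invisible(c(peaks = p1, truth = p2))
}

#' Simulate a limiting-shift calibration tube
#'
#' A homogeneous strong-acid solution (fully dissociated, so the
#' proton-transfer concentration kappa equals the acid concentration
#' everywhere) with a gradient of the indicator. Feeding the result to
#' [calibrate_limits()] recovers the limiting shifts.
#'
#' @param ind The [indicator()] being calibrated (its limiting shifts are
#'   the ground truth the simulation encodes).
#' @param strong_acid_conc HCl concentration (mol/L), default 0.01.
#' @param source_conc Indicator source concentration; default five acid
#'   equivalents at the nearest slice, which spreads the protonated
#'   fraction widely across the tube.
#' @param ... Further arguments to [tube_system()].
#' @return A `tube_simulation` with `kappa_known` set.
#' @export
simulate_calibration <- function(ind, strong_acid_conc = 0.01,
                                 source_conc = NULL, ...) {
  if (!(strong_acid_conc > 0))
    stop("strong_acid_conc must be > 0", call. = FALSE)
  sys <- tube_system(analyte = NULL, ind = ind, source_conc = 1, ...,
                     strong_cations = 0, strong_anions = strong_acid_conc)
  if (is.null(source_conc)) {
    h0 <- slice_heights(sys)
    h0 <- if (sys$source_from_top) max(h0) else min(h0)
    u <- source_distance(sys, h0) * 1e-3 / (2 * sqrt(sys$D * sys$t))
    source_conc <- 5 * strong_acid_conc / erfc_(u)
  }
  sys$source_conc <- source_conc
  sim <- simulate_tube(sys)
  sim$kappa_known <- strong_acid_conc
  sim
}

#' Limiting shifts from a known-kappa calibration gradient
#'
#' In a strong-acid tube the proton-transfer concentration is known, so the
#' protonated fraction of the indicator at each slice is
#' `f_H = (kappa_known - [H+]_free) / C_indicator`, with `[H+]_free`
#' obtained by solving the strong-acid/indicator equilibrium at the slice's
#' indicator concentration (only the indicator pKa is needed, not its
#' shifts). A linear regression of the observed shift on `f_H` then yields
#' `delta_L` (intercept) and `delta_H` (intercept + slope).
#'
#' @param peaks Peak-table data.frame (or a `tube_simulation`).
#' @param ind [indicator()] supplying `pKa0`, `dz2` and `n_protons`; its
#'   limiting shifts are not used.
#' @param kappa_known Strong-acid concentration (mol/L).
#' @param ref The [reference_compound()] (taken from the simulation when a
#'   `tube_simulation` is given).
#' @param use_activity Apply Davies corrections in the slice equilibria.
#' @return List of class `shift_calibration`: `delta_H`, `delta_L`, their
#'   95% CI half-widths, `n`, `f_range`.
#' @export
calibrate_limits <- function(peaks, ind, kappa_known, ref = NULL,
                             use_activity = TRUE) {
  if (inherits(peaks, "tube_simulation")) {
    if (is.null(ref)) ref <- peaks$sys$ref
    peaks <- peaks$peaks
  }
  stopifnot(inherits(ind, "nmr_indicator"),
            inherits(ref, "reference_compound"), kappa_known > 0)
  C_ind <- indicator_concentration(peaks$integral_indicator,
                                   peaks$integral_reference, ind, ref)
  f <- H <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    extra_na <- if (ind$dz2 == -1L) C_ind[i] else 0
    st <- solve_speciation(list(), ind, C_ind[i],
                           strong_cations = extra_na,
                           strong_anions = kappa_known,
                           use_activity = use_activity)
    H[i] <- st$H
    f[i] <- (kappa_known - st$H + st$OH) / C_ind[i]
  }
  ok <- f > 0 & f < 1
  if (!any(ok))
    stop(paste0("calibration impossible: protonated fraction outside ",
                "(0, 1) at every slice"), call. = FALSE)
  if (diff(range(f[ok])) < 0.05 || all(f[ok] > 0.95))
    warning(sprintf(
      "calibration ill-conditioned: f_H spans only %.3f-%.3f",
      min(f[ok]), max(f[ok])), call. = FALSE)
  d <- peaks$delta_obs_ppm[ok]
  fit <- stats::lm(d ~ f[ok])
  cf <- unname(stats::coef(fit)); V <- stats::vcov(fit)
  tq <- stats::qt(0.975, max(sum(ok) - 2, 1))
  structure(
    list(delta_L = cf[1], delta_H = cf[1] + cf[2],
         ci95_delta_L = tq * sqrt(V[1, 1]),
         ci95_delta_H = tq * sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2]),
         n = sum(ok), f_range = range(f[ok])),
    class = "shift_calibration")
}

#' @export
print.shift_calibration <- function(x, ...) {
  cat(sprintf(paste0("limiting shifts: delta_H %.4f +/- %.4f, ",
                     "delta_L %.4f +/- %.4f ppm (%d slices, f_H %.2f-%.2f)\n"),
              x$delta_H, x$ci95_delta_H, x$delta_L, x$ci95_delta_L,
              x$n, x$f_range[1], x$f_range[2]))
  invisible(x)
}

#' Synthesize a 1D slice spectrum (demo)
#'
#' Lorentzian lines for the indicator, the integral reference and DSS with
#' areas proportional to concentration times proton count. Purely a
#' demonstration of what a slice spectrum looks like; the pipeline consumes
#' integrals directly.
#'
#' @param C_indicator Indicator concentration (mol/L).
#' @param delta_obs Indicator line position (ppm).
#' @param ind An [indicator()].
#' @param ref A [reference_compound()].
#' @param ref_shift Reference line position (ppm; 3.75 for dioxane).
#' @param dss_conc DSS concentration (mol/L, 9 protons at 0 ppm).
#' @param linewidth_hz Full width at half maximum (Hz).
#' @param larmor_mhz Spectrometer frequency (MHz).
#' @param ppm Grid of chemical shifts; default -1 to 10.5 ppm in steps of
#'   2e-4.
#' @return data.frame `ppm, intensity`, plus attribute `areas` (declared
#'   line areas in concentration x proton units).
#' @export
synthesize_spectrum <- function(C_indicator, delta_obs, ind, ref,
                                ref_shift = 3.75, dss_conc = 2e-4,
                                linewidth_hz = 1, larmor_mhz = 500.21,
                                ppm = seq(-1, 10.5, by = 2e-4)) {
  w <- linewidth_hz / larmor_mhz  # FWHM in ppm
  lorentz <- function(x0, area)
    area / pi * (w / 2) / ((ppm - x0)^2 + (w / 2)^2)
  areas <- c(indicator = C_indicator * ind$n_protons,
             reference = ref$conc * ref$n_protons,
             DSS = dss_conc * 9)
  intensity <- lorentz(delta_obs, areas["indicator"]) +
    lorentz(ref_shift, areas["reference"]) +
    lorentz(0, areas["DSS"])
  structure(data.frame(ppm = ppm, intensity = intensity), areas = areas)
}
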