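# Forward simulator: diffusion profile, determinism, bookkeeping,
# round-trip recovery, limiting-shift calibration, spectrum demo.

test_that("diffusion profile has the erfc special values and shape", {
  sys <- tube_system(acid_species("HA", 4.76, 0.01),
                     get_indicator("acetate"), source_conc = 0.1,
                     active_region_offset = 0, seed = 1)
  expect_equal(gradient_profile(sys, 0), 0.1)
  h_star <- 2 * sqrt(sys$D * sys$t) * 1e3  # mm
  expect_equal(gradient_profile(sys, h_star), 0.1 * 0.15729921,
               tolerance = 1e-6)
  expect_lt(gradient_profile(sys, 1e4), 1e-12)
  h <- seq(0, 30, by = 0.5)
  expect_true(all(diff(gradient_profile(sys, h)) < 0))
  expect_error(gradient_profile(sys, -1), "height")
  expect_error(tube_system(NULL, get_indicator("acetate"), 0.1, t = 0,
                           seed = 1), "t must be > 0")
})

test_that("a fixed seed reproduces the simulation bitwise", {
  sc <- benchmark_scenario("glycolic_acid", seed = 42)
  sim1 <- simulate_tube(sc$sys)
  sim2 <- simulate_tube(sc$sys)
  expect_identical(sim1$peaks, sim2$peaks)
  sc2 <- benchmark_scenario("glycolic_acid", seed = 43)
  expect_false(identical(simulate_tube(sc2$sys)$peaks, sim1$peaks))
})

test_that("proton bookkeeping: indicator + free H - OH equals the
           deprotonated analyte at every slice", {
  for (nm in c("boric_acid", "benzoic_acid", "h3po4")) {
    nf <- noisefree_sim(nm)
    sim <- nf$sim
    lhs <- vapply(seq_along(sim$states), function(i) {
      st <- sim$states[[i]]
      st$frac_protonated * sim$truth$C_ind_true_M[i] + st$H - st$OH
    }, numeric(1))
    extra <- sim$sys$strong_anions - sim$sys$strong_cations
    expect_lt(max(abs(lhs - extra - sim$truth$released_true_M)), 1e-9)
  }
})

test_that("noise-free simulation round-trips to the generating parameters", {
  nf <- noisefree_sim("benzoic_acid")
  pr <- run_pipeline(nf$sim, nf$sc$dz2_analyte)
  expect_lt(abs(pr$fit$pKa0_fit - nf$sc$pKa_true), 0.01)
  expect_lt(abs(pr$fit$C_analyte_fit - nf$sc$sys$analyte$conc) /
              nf$sc$sys$analyte$conc, 0.01)
})

test_that("with ideal-solution settings the reciprocal plot is exactly
           collinear", {
  # activity machinery and autoionization off: kappa = C*Ka/(Ka + aH)
  # holds identically, so the linear relation is exact
  benz <- acid_species("benzoic", 4.20, 0.01)
  sys <- tube_system(benz, get_indicator("acetate"), seed = 9,
                     strong_cations = 0, strong_anions = 0,
                     noise_shift_sd = 0, noise_integral_rel_sd = 0,
                     use_activity = FALSE, Kw = 0)
  sim <- simulate_tube(sys)
  pts <- build_points(sim$peaks, sys$ind, sys$ref, sim$comp,
                      use_activity = FALSE)
  f <- stats::lm(inv_kappa ~ aH, data = pts$points)
  expect_lt(max(abs(stats::residuals(f))) / mean(pts$points$inv_kappa),
            1e-9)
})

test_that("pH profile is monotone along the tube, including the
           top-source geometry", {
  nf <- noisefree_sim("boric_acid")
  expect_true(all(diff(nf$sim$truth$pH_true) < 0))
  top <- noisefree_sim("nh3ohcl")  # lutidine layered on top
  expect_true(all(diff(top$sim$truth$pH_true) > 0))
})

test_that("limiting-shift calibration round-trips exactly without noise", {
  for (nm in c("acetate", "2-MI")) {
    ind <- get_indicator(nm)
    sim <- simulate_calibration(ind, 0.01, seed = 3, noise_shift_sd = 0,
                                noise_integral_rel_sd = 0)
    # kappa is constant at the acid concentration up to the protons the
    # indicator draws from water where the base is in large excess (OH-)
    OH <- vapply(sim$states, `[[`, numeric(1), "OH")
    expect_lt(max(abs(sim$truth$kappa_true_M - 0.01 - OH)), 1e-9)
    expect_lt(max(abs(sim$truth$kappa_true_M - 0.01)), 1e-5)
    cal <- calibrate_limits(sim, ind, 0.01)
    expect_lt(abs(cal$delta_H - ind$delta_H), 1e-3)
    expect_lt(abs(cal$delta_L - ind$delta_L), 1e-3)
  }
})

test_that("noisy calibration stays within 0.01 ppm across seeds", {
  ind <- get_indicator("acetate")
  errs <- vapply(1:50, function(s) {
    sim <- simulate_calibration(ind, 0.01, seed = 700 + s)
    cal <- calibrate_limits(sim, ind, 0.01)
    max(abs(cal$delta_H - ind$delta_H), abs(cal$delta_L - ind$delta_L))
  }, numeric(1))
  expect_lt(max(errs), 0.01)
})

test_that("a gradient too weak to deprotonate the indicator is flagged as
           ill-conditioned", {
  ind <- get_indicator("2-MI")
  expect_warning(
    calibrate_limits(
      simulate_calibration(ind, 0.01, source_conc = 5e-4, seed = 2,
                           noise_shift_sd = 0, noise_integral_rel_sd = 0),
      ind, 0.01),
    "ill-conditioned")
})

test_that("synthetic spectra integrate to the declared areas", {
  ind <- get_indicator("2-MI")
  ref <- packaged_references()$dioxane
  sp <- synthesize_spectrum(5e-3, 7.1, ind, ref)
  areas <- attr(sp, "areas")
  dx <- diff(sp$ppm[1:2])
  win <- function(x0, half = 1) {
    sel <- abs(sp$ppm - x0) <= half
    sum(sp$intensity[sel]) * dx
  }
  expect_equal(win(7.1), unname(areas["indicator"]), tolerance = 1e-3)
  expect_equal(win(3.75), unname(areas["reference"]), tolerance = 1e-3)
  # indicator and reference lines are resolved: a valley exists between
  mid <- sp$intensity[abs(sp$ppm - 5.4) < 0.1]
  expect_lt(max(mid), 1e-3 * max(sp$intensity))
  # integral ratio reproduces the concentration encoding
  C_back <- (win(7.1) / ind$n_protons) / (win(3.75) / ref$n_protons) *
    ref$conc
  expect_equal(C_back, 5e-3, tolerance = 1e-3)
})
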