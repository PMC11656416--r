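# pKa/C estimation: linear and nonlinear routes, CIs, protein quantities.

test_that("exact titration points are recovered algebraically", {
  pts <- exact_points(Ka = 1e-5, C = 0.01, aH = c(1e-4, 1e-5, 1e-6))
  for (w in c("kappa2", "none")) {
    # suppressed: R's "essentially perfect fit" note on exact data
    f <- suppressWarnings(fit_linear(pts, weights = w))
    expect_equal(f$slope, 1e7, tolerance = 1e-9)
    expect_equal(f$intercept, 100, tolerance = 1e-9)
    expect_equal(f$pKa0_fit, 5, tolerance = 1e-9)
    expect_equal(f$C_analyte_fit, 0.01, tolerance = 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-12)
    expect_lt(f$ci95_pKa, 1e-6)
  }
  fn <- suppressWarnings(fit_nonlinear(pts))
  expect_equal(fn$pKa0_fit, 5, tolerance = 1e-7)
  expect_equal(fn$C_analyte_fit, 0.01, tolerance = 1e-7)
})

test_that("degenerate fits fail informatively", {
  pts <- exact_points(1e-5, 0.01, c(1e-4, 1e-5, 1e-6))
  expect_error(fit_linear(pts[1:2, ]), "insufficient data")
  flat <- pts; flat$kappa_M <- 5e-3; flat$inv_kappa <- 200
  expect_error(fit_linear(flat), "no titration")
  expect_error(fit_nonlinear(flat), "no titration")
  # decreasing 1/kappa with aH: negative slope
  neg <- pts; neg$inv_kappa <- rev(neg$inv_kappa)
  expect_error(fit_linear(neg), "no titration")
  narrow <- exact_points(1e-5, 0.01, c(1e-5, 1.5e-5, 2e-5))
  ws <- testthat::capture_warnings(fit_linear(narrow))
  expect_true(any(grepl("factor", ws)))
})

test_that("linear and nonlinear routes agree on noise-free gradients", {
  nf <- noisefree_sim("benzoic_acid")
  pr <- run_pipeline(nf$sim, nf$sc$dz2_analyte)
  fnl <- fit_nonlinear(pr$pts, nf$sc$dz2_analyte)
  expect_lt(abs(pr$fit$pKa0_fit - fnl$pKa0_fit), 1e-4)
  expect_lt(abs(pr$fit$C_analyte_fit - fnl$C_analyte_fit) /
              pr$fit$C_analyte_fit, 1e-3)
})

test_that("confidence intervals cover the truth in most noisy replicates", {
  # a well-posed configuration: the analyte pKa lies inside the indicator
  # window, so the fit interpolates; extrapolating configurations (analyte
  # pKa beyond the window, e.g. boric acid with 2-MI) have optimistic CIs,
  # a known property discussed in the methods vignette
  sc <- benchmark_scenario("h3po4", seed = 1)
  sys <- sc$sys
  hits <- logical(200)
  for (r in seq_along(hits)) {
    sys$seed <- 20000 + r
    sim <- simulate_tube(sys)
    f <- tryCatch(
      suppressWarnings(run_pipeline(sim, sc$dz2_analyte)$fit),
      error = function(e) NULL)
    hits[r] <- !is.null(f) &&
      abs(f$pKa0_fit - sc$pKa_true) <= f$ci95_pKa
  }
  expect_gte(mean(hits), 0.90)  # measured 0.935
})

test_that("CI half-widths shrink roughly as 1/sqrt(n points)", {
  ratios <- vapply(1:5, function(s) {
    # same 26.2 mm active region sampled 4x more finely
    sc_lo <- benchmark_scenario("benzoic_acid", seed = 500 + s,
                             n_slices = 32L, slice_thickness = 0.82)
    sc_hi <- benchmark_scenario("benzoic_acid", seed = 500 + s,
                             n_slices = 128L, slice_thickness = 0.205)
    f_lo <- run_pipeline(simulate_tube(sc_lo$sys), sc_lo$dz2_analyte)$fit
    f_hi <- run_pipeline(simulate_tube(sc_hi$sys), sc_hi$dz2_analyte)$fit
    f_lo$ci95_pKa / f_hi$ci95_pKa
  }, numeric(1))
  # fourfold more slices: expect roughly a twofold tighter CI on average
  expect_gt(mean(ratios), 1.3)
  expect_lt(mean(ratios), 4)
})

test_that("a two-site acid bends the reciprocal plot and yields an
           effective pKa between the site values", {
  two <- acid_species("two-site", c(4.3, 5.3), 0.005, 0L)
  sys <- tube_system(two, get_indicator("acetate"), seed = 11,
                     noise_shift_sd = 0, noise_integral_rel_sd = 0)
  sim <- simulate_tube(sys)
  pts <- build_points(sim$peaks, sys$ind, sys$ref, sim$comp)
  f <- fit_linear(pts)
  expect_gt(f$pKa0_fit, 4.3)
  expect_lt(f$pKa0_fit, 5.3)
  # systematic curvature: residual sign flips from the ends to the middle
  r <- f$residuals[order(pts$points$aH)]; n <- length(r)
  mid <- sign(mean(r[(n %/% 3):(2 * n %/% 3)]))
  expect_true(sign(r[1]) == sign(r[n]) && sign(r[1]) == -mid)
  # and the fit is visibly worse than a one-site analyte's
  mono <- noisefree_sim("benzoic_acid")
  f1 <- run_pipeline(mono$sim, mono$sc$dz2_analyte)$fit
  expect_gt(f1$r_squared, 0.99999)
  expect_lt(f$r_squared, 0.999)
})

test_that("protein molarity and acidic-site counts follow the worked
           arithmetic", {
  pm <- protein_molarity(3.8, 21000)
  expect_equal(pm, 1.81e-4, tolerance = 1e-2)
  expect_equal(protein_molarity(21, 21000), 1e-3)
  expect_error(protein_molarity(0, 21000), "> 0")
  s <- sites_per_molecule(2.38e-3, pm, ci95_C = 0.24e-3)
  expect_equal(s$sites, 13.1, tolerance = 5e-3)
  expect_equal(round(s$sites), 13)
  expect_equal(round(s$ci95), 1)
  expect_equal(sites_per_molecule(1e-3, 1e-3)$sites, 1)
  expect_error(sites_per_molecule(2.38e-3, 0), "> 0")
})

test_that("fit reports serialize the essentials", {
  pts <- exact_points(1e-5, 0.01, 10^seq(-6, -4, by = 0.5))
  rep <- fit_report(suppressWarnings(fit_linear(pts)),
                    data.frame(height_mm = 1, reason = "pH outside window"))
  expect_named(rep, c("method", "pKa0", "pKa0_ci95", "C_analyte_M",
                      "C_ci95", "r_squared", "n_points", "rejected"))
  expect_equal(rep$rejected[[1]]$reason, "pH outside window")
  expect_equal(rep$n_points, 5)
})
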