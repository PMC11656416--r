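# Core model: Davies activity correction and the exact speciation solver.

test_that("Davies log-gamma matches the closed form and scales with z^2", {
  expect_identical(davies_log_gamma(1, 0), 0)
  # sqrt(0.01)/(1.1) - 0.003 = 0.0879091; x 0.509
  expect_equal(davies_log_gamma(1, 0.01), -0.509 * 0.0879091,
               tolerance = 1e-6)
  expect_equal(davies_log_gamma(-1, 0.01), davies_log_gamma(1, 0.01))
  expect_equal(davies_log_gamma(2, 0.01), 4 * davies_log_gamma(1, 0.01))
  expect_error(davies_log_gamma(1, -0.001), "ionic strength")
})

test_that("solver reproduces pure water and strong acid exactly", {
  expect_equal(solve_speciation(use_activity = FALSE)$pH, 7, tolerance = 1e-9)
  expect_equal(solve_speciation()$pH, 7, tolerance = 1e-3)
  s <- solve_speciation(strong_anions = 0.01, use_activity = FALSE)
  expect_equal(s$pH, 2, tolerance = 1e-9)
})

test_that("solver matches the monoprotic closed-form quadratic (no water)", {
  # the quadratic [H] = (-Ka + sqrt(Ka^2 + 4 Ka C))/2 neglects
  # autoionization, so the comparison disables it in the solver too
  for (pKa in c(2, 4.76, 7, 10)) {
    for (C in c(1e-3, 1e-2, 0.1)) {
      Ka <- 10^(-pKa)
      Hq <- (-Ka + sqrt(Ka^2 + 4 * Ka * C)) / 2
      s <- solve_speciation(acid_species("HA", pKa, C),
                            use_activity = FALSE, Kw = 0)
      expect_lt(abs(s$pH + log10(Hq)), 1e-8)
    }
  }
})

test_that("solver with water matches an independent cubic-root oracle", {
  # full monoprotic charge balance H^3 + Ka H^2 - (Ka C + Kw) H - Ka Kw = 0
  for (pKa in c(4.76, 8, 10)) {
    for (C in c(1e-3, 5e-2)) {
      Ka <- 10^(-pKa)
      r <- polyroot(c(-Ka * 1e-14, -(Ka * C + 1e-14), Ka, 1))
      H <- Re(r[abs(Im(r)) < 1e-20 & Re(r) > 0])
      s <- solve_speciation(acid_species("HA", pKa, C),
                            use_activity = FALSE)
      expect_lt(abs(s$pH + log10(max(H))), 1e-8)
    }
  }
})

test_that("charge-balance residual is below 1e-12 M at the returned state", {
  mi <- get_indicator("2-MI")
  cases <- list(
    solve_speciation(acid_species("boric", 9.19, 0.01), mi, 0.05),
    solve_speciation(acid_species("H3PO4", c(2.16, 7.21, 12.35), 0.06,
                                  0L),
                     get_indicator("1,2,4-triazole"), 0.2),
    solve_speciation(acid_species("NH4", 9.24, 0.01, 1L), mi, 0.03,
                     strong_anions = 0.01),
    solve_speciation(list(), get_indicator("acetate"), 0.02,
                     strong_cations = 0.02, strong_anions = 0.01))
  for (s in cases) expect_lt(abs(s$charge_residual), 1e-12)
})

test_that("pH responds monotonically to added base and acid", {
  mi <- get_indicator("2-MI")
  bor <- acid_species("boric", 9.19, 0.01)
  ph_base <- vapply(c(0, 1e-3, 5e-3, 2e-2, 0.1),
                    function(C) solve_speciation(bor, mi, C)$pH,
                    numeric(1))
  expect_true(all(diff(ph_base) > 0))
  ph_acid <- vapply(c(0, 1e-3, 5e-3, 2e-2),
                    function(C) solve_speciation(
                      acid_species("boric", 9.19, C), mi, 0.02)$pH,
                    numeric(1))
  expect_true(all(diff(ph_acid) < 0))
})

test_that("activity-corrected pH converges to the uncorrected one as I -> 0", {
  # for a strong acid the on/off difference is exactly the Davies term
  # A f(I), so it must fall monotonically to zero on dilution
  d_of <- function(C) abs(
    solve_speciation(strong_anions = C)$pH -
      solve_speciation(strong_anions = C, use_activity = FALSE)$pH)
  ds <- vapply(10^-(1:6), d_of, numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_gt(ds[1], 0.05)
  expect_lt(ds[6], 1e-3)
})

test_that("multiprotic speciation tracks successive deprotonation", {
  h3 <- acid_species("H3PO4", c(2.16, 7.21, 12.35), 0.01, 0L)
  s <- solve_speciation(h3, get_indicator("2-MI"), 0.03,
                        strong_cations = 0.01)
  sp <- s$species$H3PO4
  expect_length(sp, 4)
  expect_equal(sum(sp), 0.01, tolerance = 1e-12)
  # near pH 7.2 the mono- and di-anion dominate
  expect_gt(sp[2] + sp[3], 0.0099)
  expect_equal(protons_released(s, h3),
               sum((0:3) * sp), tolerance = 1e-15)
})
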