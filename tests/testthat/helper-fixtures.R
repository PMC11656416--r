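# Shared fixtures: everything is generated in code, nothing is stored.

# a noise-free benchmark scenario simulation (memoised per test file run)
noisefree_sim <- local({
  cache <- list()
  function(name, seed = 1) {
    key <- paste(name, seed)
    if (is.null(cache[[key]])) {
      sc <- benchmark_scenario(name, seed = seed, noise_shift_sd = 0,
                               noise_integral_rel_sd = 0)
      cache[[key]] <<- list(sc = sc, sim = simulate_tube(sc$sys))
    }
    cache[[key]]
  }
})

# points lying exactly on the titration relation kappa = C*Ka/(Ka + aH),
# with zero ionic strength so every activity scheme is the identity
exact_points <- function(Ka, C, aH) {
  kappa <- C * Ka / (Ka + aH)
  data.frame(height_mm = seq_along(aH), pH = -log10(aH),
             ionic_strength_M = 0, C_indicator_M = NA_real_,
             kappa_M = kappa, inv_kappa = 1 / kappa, aH = aH,
             frac_protonated = NA_real_)
}

run_pipeline <- function(sim, dz2, ...) {
  pts <- build_points(sim$peaks, sim$sys$ind, sim$sys$ref, sim$comp, ...)
  list(pts = pts, fit = fit_linear(pts, dz2))
}
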