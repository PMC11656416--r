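# Exact acid-base speciation: the brute-force oracle against which the
# shift->pH->kappa pipeline is checked. Solves the charge balance
#   [H+] + cations - [OH-] - anions + sum(acid species charges) = 0
# with mass-action laws for every dissociable site, the indicator's
# conjugate acid, and water. Constants are "mixed" (concentrations of the
# conjugate pair, activity of H+); with use_activity on they are corrected
# from the thermodynamic pKa0 via the Davies expression and the ionic
# strength is iterated to self-consistency.

# per-site charge change (protonated^2 - deprotonated^2) for site i of an
# acid whose fully protonated form has charge z0
site_dz2 <- function(z0, i) (z0 - i + 1)^2 - (z0 - i)^2

# distribution of an acid over its n+1 protonation states at H+ activity aH.
# Returns list(alpha = fractions, z = charges), most protonated first.
acid_alphas <- function(acid, aH, I = 0, use_activity = TRUE, A = 0.509) {
  n <- length(acid$pKa0)
  pKm <- acid$pKa0
  if (use_activity)
    pKm <- pKm + davies_f(I, A) * site_dz2(acid$z0, seq_len(n))
  # [A_k]/[A_0] = prod(K_i)/aH^k  =>  log10 = -sum(pKm_1..k) - k*log10(aH)
  lx <- c(0, cumsum(-pKm) - seq_len(n) * log10(aH))
  lx <- lx - max(lx)
  x <- 10^lx
  list(alpha = x / sum(x), z = acid$z0 - 0:n)
}

# indicator protonated fraction and species charges at H+ activity aH
indicator_state <- function(ind, aH, I = 0, use_activity = TRUE, A = 0.509) {
  pKm <- ind$pKa0
  if (use_activity) pKm <- pKm + davies_f(I, A) * ind$dz2
  K <- 10^(-pKm)
  f <- aH / (aH + K)
  zH <- if (ind$dz2 == 1L) 1L else 0L
  list(f = f, zH = zH, zL = zH - 1L, pKa_mixed = pKm)
}

#' Solve the acid-base equilibrium of a slice
#'
#' Returns the unique hydrogen-ion concentration satisfying charge balance
#' for a mixture of acids, a basic indicator, strong monovalent co-ions and
#' water. The root is found by bisection on `log10[H+]` over the bracket
#' `[1e-14, 1]` M followed by a Newton polish; with `use_activity = TRUE`
#' the ionic strength is iterated to a fixed point (`|dpH| < 1e-9`).
#'
#' This solver is deliberately assumption-free (no proton bookkeeping
#' shortcuts) so that it can serve as the independent oracle for the
#' indicator-based pipeline: the proton-transfer concentration measured from
#' the indicator must agree with the deprotonated-analyte concentration this
#' solver returns.
#'
#' @param acids List of [acid_species()] (possibly empty).
#' @param ind Optional [indicator()] acting as the base, at concentration
#'   `C_indicator`.
#' @param C_indicator Indicator concentration (mol/L).
#' @param strong_cations,strong_anions Strong monovalent co-ion
#'   concentrations (mol/L). For carboxylate indicators added as sodium
#'   salts the caller must include the Na+ at `C_indicator` (the simulator
#'   and pipeline do this automatically).
#' @param use_activity Correct mixed constants via [davies_log_gamma()] and
#'   iterate the ionic strength self-consistently.
#' @param Kw Water autoionization product (default `1e-14`; no activity
#'   correction is applied to Kw itself, adequate in the working range
#'   pH 1-10). `Kw = 0` disables autoionization, which is occasionally
#'   useful for algebraic cross-checks.
#' @param A Debye-Hueckel constant.
#' @param max_iter Maximum ionic-strength iterations.
#' @return List of class `speciation_state` with elements `pH` (from the
#'   H+ activity when `use_activity`, otherwise concentration), `aH`, `H`,
#'   `OH`, `I`, `frac_protonated` (indicator), `species` (per-acid
#'   concentration vectors, most protonated first), `charge_residual`,
#'   `iterations`.
#' @export
solve_speciation <- function(acids = list(), ind = NULL, C_indicator = 0,
                             strong_cations = 0, strong_anions = 0,
                             use_activity = TRUE, Kw = 1e-14, A = 0.509,
                             max_iter = 100L) {
  if (inherits(acids, "acid_species")) acids <- list(acids)
  stopifnot(all(vapply(acids, inherits, logical(1), "acid_species")))
  if (C_indicator > 0 && is.null(ind))
    stop("C_indicator > 0 requires an indicator definition", call. = FALSE)
  if (C_indicator < 0 || strong_cations < 0 || strong_anions < 0)
    stop("concentrations must be >= 0", call. = FALSE)

  charge <- function(H, I) {
    aH <- if (use_activity) gamma1(I, A) * H else H
    res <- H + strong_cations - strong_anions
    if (Kw > 0) res <- res - Kw / H
    for (a in acids) {
      if (a$conc == 0) next
      st <- acid_alphas(a, aH, I, use_activity, A)
      res <- res + a$conc * sum(st$alpha * st$z)
    }
    if (C_indicator > 0) {
      st <- indicator_state(ind, aH, I, use_activity, A)
      res <- res + C_indicator * (st$f * st$zH + (1 - st$f) * st$zL)
    }
    res
  }

  solve_at_I <- function(I) {
    lo <- -14; hi <- 0
    flo <- charge(10^lo, I); fhi <- charge(10^hi, I)
    if (flo > 0 || fhi < 0)
      stop(sprintf(paste0("speciation root not bracketed in [1e-14, 1] M ",
                          "(residuals %.3g at 1e-14, %.3g at 1)"), flo, fhi),
           call. = FALSE)
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (charge(10^mid, I) > 0) hi <- mid else lo <- mid
    }
    H <- 10^((lo + hi) / 2)
    # Newton polish with a numerical derivative to drive the residual to
    # machine level
    for (k in 1:6) {
      r <- charge(H, I)
      if (abs(r) < 1e-15) break
      dH <- H * 1e-7
      dr <- (charge(H + dH, I) - r) / dH
      if (!is.finite(dr) || dr <= 0) break
      step <- r / dr
      if (abs(step) >= H) break
      H <- H - step
    }
    H
  }

  ionic_strength <- function(H, I) {
    aH <- if (use_activity) gamma1(I, A) * H else H
    tot <- H + (if (Kw > 0) Kw / H else 0) + strong_cations + strong_anions
    for (a in acids) {
      if (a$conc == 0) next
      st <- acid_alphas(a, aH, I, use_activity, A)
      tot <- tot + a$conc * sum(st$alpha * st$z^2)
    }
    if (C_indicator > 0) {
      st <- indicator_state(ind, aH, I, use_activity, A)
      tot <- tot + C_indicator * (st$f * st$zH^2 + (1 - st$f) * st$zL^2)
    }
    tot / 2
  }

  I <- 0; iter <- 0L
  H <- solve_at_I(I)
  if (use_activity) {
    pH_old <- -log10(gamma1(I, A) * H)
    repeat {
      iter <- iter + 1L
      I <- ionic_strength(H, I)
      H <- solve_at_I(I)
      pH_new <- -log10(gamma1(I, A) * H)
      # converge well past the 1e-9 pH guarantee so that downstream
      # bookkeeping identities hold to sub-nanomolar level
      if (abs(pH_new - pH_old) < 1e-12) break
      if (iter >= max_iter)
        stop(sprintf(
          "ionic-strength iteration did not converge in %d steps (dpH %.2g)",
          max_iter, abs(pH_new - pH_old)), call. = FALSE)
      pH_old <- pH_new
    }
  } else {
    I <- ionic_strength(H, 0)
  }

  aH <- if (use_activity) gamma1(I, A) * H else H
  species <- lapply(acids, function(a) {
    st <- acid_alphas(a, aH, I, use_activity, A)
    stats::setNames(a$conc * st$alpha,
                    paste0(a$name, "_", seq_along(st$alpha) - 1L, "dep"))
  })
  names(species) <- vapply(acids, `[[`, character(1), "name")
  f_ind <- if (C_indicator > 0)
    indicator_state(ind, aH, I, use_activity, A)$f else NA_real_
  structure(
    list(pH = -log10(aH), aH = aH, H = H,
         OH = if (Kw > 0) Kw / H else 0, I = I,
         frac_protonated = f_ind, species = species,
         charge_residual = charge(H, I), iterations = iter),
    class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("speciation: pH %.4f, I %.4g M, charge residual %.2g M\n",
              x$pH, x$I, x$charge_residual))
  invisible(x)
}

#' Deprotonated-analyte concentration of a solved state
#'
#' Total concentration of protons released by the acids: for each acid,
#' `conc * sum(k * alpha_k)` over its deprotonation states. This is the
#' quantity the indicator-based kappa measurement estimates.
#'
#' @param state A `speciation_state`.
#' @param acids The acids passed to [solve_speciation()].
#' @return mol/L of transferred (released) protons.
#' @export
protons_released <- function(state, acids) {
  if (inherits(acids, "acid_species")) acids <- list(acids)
  tot <- 0
  for (a in acids) {
    sp <- state$species[[a$name]]
    if (is.null(sp)) sp <- a$conc * acid_alphas(a, state$aH, state$I)$alpha
    tot <- tot + sum((seq_along(sp) - 1L) * sp)
  }
  tot
}
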