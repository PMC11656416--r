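# Estimation of pKa,0 and C_analyte from slice points.
#
# The titration relation kappa = C * Ka / (Ka + 10^-pH) (Ka mixed) has the
# linear form
#   1/kappa = 1/C + (1 / (Ka * C)) * 10^-pH ,
# so ordinary least squares of 1/kappa on aH = 10^-pH gives
# C = 1/intercept and Ka = intercept/slope without any nonlinear iteration.
# The nonlinear route fits the same model directly and serves as a
# cross-check.
#
# Because the mixed constant Ka depends on the ionic strength, which varies
# along the tube with the indicator concentration, the regressor is by
# default activity-adjusted point by point:
#   aH_adj = aH * 10^(A * f(I_i) * dz2_analyte)
# turns the relation into 1/kappa = 1/C + aH_adj / (Ka0 * C) with the
# *thermodynamic* constant, exactly linear even when I varies. The simpler
# textbook alternative (fit raw aH, back-correct the fitted constant at the
# median I) is available as activity = "median" but leaves a curvature bias
# when I spans a wide range.

points_frame <- function(points) {
  if (inherits(points, "slice_points")) points <- points$points
  need <- c("aH", "inv_kappa", "kappa_M", "ionic_strength_M")
  stopifnot(is.data.frame(points), all(need %in% names(points)))
  points
}

# activity-adjusted regressor and the post-fit correction for each scheme
adjust_aH <- function(df, activity, dz2_analyte, A) {
  switch(activity,
         per_slice = df$aH *
           10^(davies_f(df$ionic_strength_M, A) * dz2_analyte),
         median = df$aH,
         none = df$aH,
         stop("activity must be 'per_slice', 'median' or 'none'",
              call. = FALSE))
}

back_correct <- function(pKa_fit, activity, dz2_analyte, I_med, A) {
  switch(activity,
         per_slice = pKa_fit,  # already thermodynamic
         median = pKa_fit - davies_f(I_med, A) * dz2_analyte,
         none = pKa_fit)
}

#' Linear-route estimate of pKa,0 and analyte concentration
#'
#' @param points A `slice_points` object from [build_points()] or its
#'   `points` data.frame.
#' @param dz2_analyte Difference of squared charges (protonated minus
#'   deprotonated) of the analyte site being titrated: -1 for neutral acids
#'   releasing an anion (the default), +1 for cationic acids (ammonium,
#'   glycinium), -3 for the second phosphate dissociation. Controls the
#'   ionic-strength correction that converts the fitted constant to pKa,0.
#' @param activity How to handle the ionic-strength dependence of the mixed
#'   constant: `"per_slice"` (default) activity-adjusts the regressor point
#'   by point so the fitted constant is directly thermodynamic;
#'   `"median"` fits raw `aH` and back-corrects at the median ionic
#'   strength; `"none"` reports the mixed constant unchanged.
#' @param weights `"kappa2"` (default) weights each point by `kappa^2`,
#'   the variance-stabilizing choice for a reciprocal transform under
#'   multiplicative kappa noise (exactly the remedy long recommended for
#'   double-reciprocal enzyme plots); `"none"` is the plain unweighted
#'   regression line. Both coincide on noise-free data.
#' @param A Debye-Hueckel constant.
#' @return Object of class `pka_fit`: `pKa0_fit`, `C_analyte_fit` (mol/L),
#'   `ci95_pKa`, `ci95_C` (95% half-widths, t-distribution with n-2 df,
#'   delta-method propagation), `r_squared`, `n_points`, `method`,
#'   `residuals` (on the 1/kappa scale), plus the raw `slope`, `intercept`,
#'   `pKa_mixed` and `I_median`.
#' @export
fit_linear <- function(points, dz2_analyte = -1L,
                       activity = c("per_slice", "median", "none"),
                       weights = c("kappa2", "none"), A = 0.509) {
  activity <- match.arg(activity)
  weights <- match.arg(weights)
  df <- points_frame(points)
  n <- nrow(df)
  if (n < 3) stop("insufficient data: need >= 3 points, got ", n,
                  call. = FALSE)
  spread <- max(df$aH) / min(df$aH)
  if (spread < 3)
    warning(sprintf(
      "aH spans only a factor of %.2f (< 3); fit poorly conditioned",
      spread), call. = FALSE)
  df$aH_adj <- adjust_aH(df, activity, dz2_analyte, A)
  df$.w <- if (weights == "kappa2") df$kappa_M^2 else rep(1, n)
  fit <- stats::lm(inv_kappa ~ aH_adj, data = df, weights = .w)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (b <= 0)
    stop(sprintf(paste0("no titration: 1/kappa does not increase with ",
                        "10^-pH (slope %.3g)"), b), call. = FALSE)
  if (a <= 0)
    stop(sprintf(paste0("unphysical fit: intercept %.3g <= 0 (implies ",
                        "negative analyte concentration); slope %.3g, ",
                        "R^2 %.3f"), a, b, summary(fit)$r.squared),
         call. = FALSE)
  V <- stats::vcov(fit)
  tq <- stats::qt(0.975, n - 2)
  C <- 1 / a
  Ka <- a / b
  var_C <- V[1, 1] / a^4
  var_K <- Ka^2 * (V[1, 1] / a^2 + V[2, 2] / b^2 - 2 * V[1, 2] / (a * b))
  var_pK <- var_K / (Ka * log(10))^2
  I_med <- stats::median(df$ionic_strength_M)
  pKa_raw <- -log10(Ka)
  pKa0 <- back_correct(pKa_raw, activity, dz2_analyte, I_med, A)
  structure(
    list(pKa0_fit = pKa0,
         C_analyte_fit = C,
         ci95_pKa = tq * sqrt(max(var_pK, 0)),
         ci95_C = tq * sqrt(max(var_C, 0)),
         r_squared = summary(fit)$r.squared,
         n_points = n, method = "linear",
         residuals = unname(stats::residuals(fit)),
         slope = b, intercept = a,
         pKa_mixed = pKa0 + davies_f(I_med, A) * dz2_analyte,
         I_median = I_med, dz2_analyte = dz2_analyte,
         activity = activity, weights = weights,
         aH = df$aH_adj, inv_kappa = df$inv_kappa),
    class = "pka_fit")
}

#' Nonlinear-route estimate of pKa,0 and analyte concentration
#'
#' Levenberg-Marquardt least squares of `kappa = C*Ka/(Ka + aH)` over
#' `(pKa, C)`, started from the linear fit when it succeeds (otherwise from
#' the median pH and the maximum kappa). Confidence intervals come from the
#' parameter covariance at the optimum.
#'
#' @inheritParams fit_linear
#' @return A `pka_fit` with `method = "nonlinear"`; residuals are on the
#'   kappa scale.
#' @export
fit_nonlinear <- function(points, dz2_analyte = -1L,
                          activity = c("per_slice", "median", "none"),
                          A = 0.509) {
  activity <- match.arg(activity)
  df <- points_frame(points)
  n <- nrow(df)
  if (n < 3) stop("insufficient data: need >= 3 points, got ", n,
                  call. = FALSE)
  if (diff(range(df$kappa_M)) <= 1e-12 * max(df$kappa_M))
    stop("no titration: kappa shows no pH dependence", call. = FALSE)
  df$aH_adj <- adjust_aH(df, activity, dz2_analyte, A)
  lin <- tryCatch(
    suppressWarnings(fit_linear(df, dz2_analyte, activity, A = A)),
    error = function(e) NULL)
  start <- if (!is.null(lin))
    list(pKm = if (activity == "per_slice") lin$pKa0_fit
         else lin$pKa_mixed,
         C = lin$C_analyte_fit)
  else
    list(pKm = stats::median(df$pH), C = max(df$kappa_M))
  fit <- tryCatch(
    minpack.lm::nlsLM(kappa_M ~ C * 10^(-pKm) / (10^(-pKm) + aH_adj),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("nonlinear fit failed: ", conditionMessage(e),
           if (!is.null(lin)) sprintf(
             " (linear-route fallback: pKa0 %.3f, C %.4g M)",
             lin$pKa0_fit, lin$C_analyte_fit) else "",
           call. = FALSE))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  tq <- stats::qt(0.975, n - 2)
  I_med <- stats::median(df$ionic_strength_M)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((df$kappa_M - mean(df$kappa_M))^2)
  pKa0 <- back_correct(unname(cf["pKm"]), activity, dz2_analyte, I_med, A)
  structure(
    list(pKa0_fit = pKa0,
         C_analyte_fit = unname(cf["C"]),
         ci95_pKa = tq * sqrt(V["pKm", "pKm"]),
         ci95_C = tq * sqrt(V["C", "C"]),
         r_squared = 1 - sum(res^2) / ss_tot,
         n_points = n, method = "nonlinear",
         residuals = res,
         pKa_mixed = pKa0 + davies_f(I_med, A) * dz2_analyte,
         I_median = I_med, dz2_analyte = dz2_analyte,
         activity = activity,
         aH = df$aH_adj, inv_kappa = df$inv_kappa),
    class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("pKa fit (%s route, %d points):\n", x$method, x$n_points))
  cat(sprintf("  pKa,0      %.3f +/- %.3f (95%% CI)\n",
              x$pKa0_fit, x$ci95_pKa))
  cat(sprintf("  C_analyte  %.4g +/- %.2g M\n", x$C_analyte_fit, x$ci95_C))
  cat(sprintf("  R^2 %.4f, mixed pKa %.3f at median I %.4g M\n",
              x$r_squared, x$pKa_mixed, x$I_median))
  invisible(x)
}

#' Plot 1/kappa against 10^-pH with the regression line
#'
#' @param x A `pka_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pka_fit <- function(x, ...) {
  graphics::plot(x$aH, x$inv_kappa, xlab = expression(10^-pH),
                 ylab = expression(1 / kappa ~ "(L/mol)"),
                 main = sprintf("pKa,0 = %.2f +/- %.2f, C = %.3g M",
                                x$pKa0_fit, x$ci95_pKa, x$C_analyte_fit),
                 ...)
  if (x$method == "linear")
    graphics::abline(x$intercept, x$slope, col = "red3")
  else {
    aa <- seq(min(x$aH), max(x$aH), length.out = 200)
    K <- 10^(-x$pKa_mixed)
    graphics::lines(aa, (K + aa) / (K * x$C_analyte_fit), col = "red3")
  }
  invisible(x)
}

#' Molar protein concentration from mass concentration
#'
#' @param mass_conc Mass concentration (mg/mL, i.e. g/L).
#' @param mw Molecular weight (Da, g/mol).
#' @return mol/L.
#' @export
protein_molarity <- function(mass_conc, mw) {
  if (!is.numeric(mass_conc) || !is.numeric(mw) || any(mass_conc <= 0) ||
      any(mw <= 0))
    stop("mass concentration and molecular weight must be > 0",
         call. = FALSE)
  mass_conc / mw
}

#' Acidic sites per molecule
#'
#' Ratio of the fitted total concentration of acidic sites to the molar
#' protein concentration, with the 95% CI of the fitted concentration
#' propagated. The ratio is returned unrounded; round only for reporting.
#'
#' @param C_analyte Fitted acid-site concentration (mol/L).
#' @param protein_mol Protein molarity (mol/L), e.g. [protein_molarity()].
#' @param ci95_C 95% half-width of `C_analyte` (mol/L).
#' @return List with `sites` and `ci95`.
#' @export
sites_per_molecule <- function(C_analyte, protein_mol, ci95_C = 0) {
  if (!(C_analyte > 0) || !(protein_mol > 0))
    stop("concentrations must be > 0", call. = FALSE)
  list(sites = C_analyte / protein_mol, ci95 = ci95_C / protein_mol)
}

#' Fit report as a plain list (JSON-ready)
#'
#' @param fit A `pka_fit`.
#' @param rejected Optional rejection log data.frame from [build_points()].
#' @return Named list matching the report schema
#'   `{method, pKa0, pKa0_ci95, C_analyte_M, C_ci95, r_squared, n_points,
#'     rejected}`.
#' @export
fit_report <- function(fit, rejected = NULL) {
  stopifnot(inherits(fit, "pka_fit"))
  list(method = fit$method,
       pKa0 = fit$pKa0_fit, pKa0_ci95 = fit$ci95_pKa,
       C_analyte_M = fit$C_analyte_fit, C_ci95 = fit$ci95_C,
       r_squared = fit$r_squared, n_points = fit$n_points,
       rejected = if (is.null(rejected) || nrow(rejected) == 0) list()
       else lapply(seq_len(nrow(rejected)), function(i)
         list(height_mm = rejected$height_mm[i],
              reason = rejected$reason[i])))
}
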