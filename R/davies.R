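#' Davies activity coefficient (log10)
#'
#' Single-ion activity coefficient from the Davies modification of the
#' extended Debye-Hueckel law,
#' \deqn{\log_{10}\gamma_z = -A z^2 \left(\frac{\sqrt I}{1+\sqrt I} - 0.3 I\right)}
#' valid to roughly I = 0.5 M. `A` = 0.509 at 298 K in water.
#'
#' @param z Integer ion charge.
#' @param I Ionic strength (mol/L), `>= 0`.
#' @param A Debye-Hueckel constant (default 0.509, water at 298 K).
#' @return log10 of the activity coefficient (dimensionless, <= 0).
#' @export
davies_log_gamma <- function(z, I, A = 0.509) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("ionic strength must be finite and >= 0", call. = FALSE)
  -A * z^2 * davies_f(I, 1)
}

# shared Davies ionic-strength function f(I) = sqrt(I)/(1+sqrt(I)) - 0.3 I,
# optionally premultiplied; kept separate so the pH and speciation code can
# apply the dz2-signed correction without double negation
davies_f <- function(I, A = 0.509) {
  s <- sqrt(I)
  A * (s / (1 + s) - 0.3 * I)
}

# activity coefficient (plain, |z| = 1) used to convert H+ activity to
# concentration
gamma1 <- function(I, A = 0.509) 10^(-davies_f(I, A))
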