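#' Define a basic NMR pH indicator
#'
#' An indicator is a weak base whose \sup{1}H chemical shift interpolates
#' between a fully protonated limit `delta_H` and a fully deprotonated limit
#' `delta_L`, so that the observed shift reports the local pH. `dz2` is the
#' difference of squared charges between the protonated and deprotonated
#' forms (+1 for nitrogenous bases such as imidazoles, -1 for carboxylate
#' anions added as their sodium salts); it controls the sign of the
#' ionic-strength correction applied to the indicator pKa.
#'
#' @param name Indicator name.
#' @param pKa0 Thermodynamic pKa (zero ionic strength) of the conjugate acid.
#' @param delta_H Limiting chemical shift of the protonated form (ppm).
#' @param delta_L Limiting chemical shift of the deprotonated form (ppm).
#'   `delta_H` may be larger or smaller than `delta_L`; both orientations
#'   occur in practice (formate shifts downfield on protonation).
#' @param dz2 Integer, difference of squared charges (protonated minus
#'   deprotonated form); must be -1 or +1 for the packaged indicators.
#' @param n_protons Number of protons contributing to the monitored integral.
#' @param pH_window Length-2 numeric, the usable pH range `(lo, hi)`.
#'   Outside this window the shift is too close to a limit for the pH to be
#'   read reliably.
#' @return An object of class `nmr_indicator`.
#' @export
indicator <- function(name, pKa0, delta_H, delta_L, dz2, n_protons,
                      pH_window) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.numeric(pKa0), length(pKa0) == 1L, is.finite(pKa0))
  if (!is.numeric(delta_H) || !is.numeric(delta_L) || delta_H == delta_L)
    stop("limiting shifts delta_H and delta_L must differ", call. = FALSE)
  if (!dz2 %in% c(-1L, 1L))
    stop("dz2 must be -1 (carboxylate-type) or +1 (nitrogenous)",
         call. = FALSE)
  stopifnot(n_protons >= 1)
  pH_window <- sort(as.numeric(pH_window))
  if (length(pH_window) != 2L || pKa0 < pH_window[1] || pKa0 > pH_window[2])
    stop("pH_window must be a (lo, hi) pair containing pKa0", call. = FALSE)
  structure(
    list(name = name, pKa0 = pKa0, delta_H = delta_H, delta_L = delta_L,
         dz2 = as.integer(dz2), n_protons = as.integer(n_protons),
         pH_window = pH_window),
    class = "nmr_indicator")
}

#' @export
print.nmr_indicator <- function(x, ...) {
  cat(sprintf("NMR pH indicator '%s': pKa0 %.2f, dH %.3f ppm, dL %.3f ppm,\n",
              x$name, x$pKa0, x$delta_H, x$delta_L))
  cat(sprintf("  dz2 %+d, %d proton(s), pH window %.1f-%.1f\n",
              x$dz2, x$n_protons, x$pH_window[1], x$pH_window[2]))
  invisible(x)
}

#' Packaged indicators
#'
#' The five basic indicators shipped with the package, spanning pH 1-9:
#' 2-methylimidazole (2-MI), 2,6-lutidine, acetate, formate and
#' 1,2,4-triazole, each with its literature thermodynamic pKa, limiting
#' shifts, charge change and usable pH window.
#'
#' @return Named list of [indicator()] objects.
#' @export
packaged_indicators <- function() {
  list(
    "2-MI" = indicator("2-MI", 7.96, 7.270, 6.958, +1L, 2L, c(7, 9)),
    "2,6-lutidine" = indicator("2,6-lutidine", 6.75, 2.707, 2.456, +1L, 6L,
                               c(6, 8)),
    "acetate" = indicator("acetate", 4.76, 2.083, 1.906, -1L, 3L,
                          c(3.5, 5.5)),
    "formate" = indicator("formate", 3.75, 8.266, 8.441, -1L, 1L,
                          c(2.5, 4.5)),
    "1,2,4-triazole" = indicator("1,2,4-triazole", 2.45, 9.193, 8.352, +1L,
                                 2L, c(1, 3))
  )
}

#' Look up a packaged indicator by name
#'
#' @param name One of `names(packaged_indicators())`.
#' @return An `nmr_indicator`.
#' @export
get_indicator <- function(name) {
  inds <- packaged_indicators()
  if (!name %in% names(inds))
    stop(sprintf("unknown indicator '%s'; packaged indicators are: %s",
                 name, paste(names(inds), collapse = ", ")), call. = FALSE)
  inds[[name]]
}

#' Define an acidic analyte
#'
#' Represents an acid with one or more dissociable protons by its
#' thermodynamic pKa values (successive, strictly increasing), total
#' concentration and the charge of the fully protonated form. The charge
#' fixes the Davies correction applied to each site's mixed constant: site
#' i releases a proton from a species of charge `z0 - i + 1`.
#'
#' @param name Analyte name.
#' @param pKa0 Numeric vector of thermodynamic pKa values, one per site,
#'   strictly increasing.
#' @param conc Total concentration (mol/L).
#' @param charge_fully_protonated Integer charge of the fully protonated
#'   species (0 for neutral acids, +1 for e.g. ammonium or glycinium).
#' @return Object of class `acid_species`.
#' @export
acid_species <- function(name, pKa0, conc, charge_fully_protonated = 0L) {
  stopifnot(is.numeric(pKa0), length(pKa0) >= 1L, all(is.finite(pKa0)))
  if (length(pKa0) > 1L && any(diff(pKa0) <= 0))
    stop("pKa0 values must be strictly increasing", call. = FALSE)
  if (!is.numeric(conc) || conc < 0)
    stop("total concentration must be >= 0", call. = FALSE)
  structure(
    list(name = name, pKa0 = as.numeric(pKa0), conc = as.numeric(conc),
         z0 = as.integer(charge_fully_protonated)),
    class = "acid_species")
}

#' Define an integral-reference compound
#'
#' An inert compound of known concentration whose integral converts the
#' indicator integral into a concentration. The correction factor absorbs
#' relaxation/saturation differences between reference and indicator and is
#' calibrated once against a solution of known base concentration.
#'
#' @param name Compound name.
#' @param conc Concentration in the analyte solution (mol/L).
#' @param n_protons Protons contributing to the reference integral.
#' @param correction_factor Dimensionless calibration factor (near 1).
#' @return Object of class `reference_compound`.
#' @export
reference_compound <- function(name, conc, n_protons,
                               correction_factor = 1) {
  stopifnot(conc > 0, n_protons >= 1, correction_factor > 0)
  structure(
    list(name = name, conc = as.numeric(conc),
         n_protons = as.integer(n_protons),
         correction_factor = as.numeric(correction_factor)),
    class = "reference_compound")
}

#' Packaged integral references
#'
#' Dioxane and DMSO at 0.01 % v/v as shipped in the stock solutions, with
#' synthetic correction factors representative of a calibrated setup.
#'
#' @return Named list of [reference_compound()] objects.
#' @export
packaged_references <- function() {
  list(
    dioxane = reference_compound("dioxane", 1.17e-3, 8L, 1.03),
    DMSO = reference_compound("DMSO", 1.41e-3, 6L, 0.97)
  )
}

#' Describe the ionic composition surrounding the analyte
#'
#' Collects everything the pipeline needs to estimate the ionic strength of
#' a slice: the acids present, strong (fully dissociated, monovalent)
#' co-ions such as Na+ or Cl- from salt-form analytes, and the DSS chemical
#' shift reference. The indicator's own counter-ion (Na+ for carboxylate
#' indicators) is added automatically slice by slice.
#'
#' @param acids List of [acid_species()] (may be empty when the analyte is
#'   unknown; the ionic strength is then estimated from the indicator and
#'   strong ions alone).
#' @param strong_cations,strong_anions Concentrations (mol/L) of monovalent
#'   strong co-ions.
#' @return Object of class `ion_composition`.
#' @export
composition <- function(acids = list(), strong_cations = 0,
                        strong_anions = 0) {
  if (inherits(acids, "acid_species")) acids <- list(acids)
  stopifnot(all(vapply(acids, inherits, logical(1), "acid_species")),
            strong_cations >= 0, strong_anions >= 0)
  structure(list(acids = acids, strong_cations = strong_cations,
                 strong_anions = strong_anions),
            class = "ion_composition")
}

#' Load an indicator or analyte definition from JSON
#'
#' JSON configs are flat objects with a `schema_version` field. An indicator
#' entry may be a packaged name (string) or a full definition with fields
#' `name, pKa0, delta_H, delta_L, dz2, n_protons, pH_window`.
#'
#' @param x A string (packaged name) or a named list parsed from JSON.
#' @return An `nmr_indicator`.
#' @export
indicator_from_config <- function(x) {
  if (is.character(x) && length(x) == 1L) return(get_indicator(x))
  if (!is.list(x)) stop("indicator config must be a name or an object",
                        call. = FALSE)
  need <- c("name", "pKa0", "delta_H", "delta_L", "dz2", "n_protons",
            "pH_window")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("indicator config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  indicator(x$name, x$pKa0, x$delta_H, x$delta_L, x$dz2, x$n_protons,
            unlist(x$pH_window))
}

#' @rdname indicator_from_config
#' @export
reference_from_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    refs <- packaged_references()
    if (!x %in% names(refs))
      stop(sprintf("unknown reference '%s'; packaged references are: %s",
                   x, paste(names(refs), collapse = ", ")), call. = FALSE)
    return(refs[[x]])
  }
  need <- c("name", "conc", "n_protons")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("reference config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  reference_compound(x$name, x$conc, x$n_protons,
                     if (is.null(x$correction_factor)) 1
                     else x$correction_factor)
}

#' @rdname indicator_from_config
#' @export
acid_from_config <- function(x) {
  need <- c("name", "pKa0", "conc")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("acid config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  acid_species(x$name, unlist(x$pKa0), x$conc,
               if (is.null(x$charge_fully_protonated)) 0L
               else x$charge_fully_protonated)
}
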