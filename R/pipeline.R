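# Slice-wise reduction: peak table -> (10^-pH, 1/kappa) points ready for
# the linear fit. Each CSI slice contributes the indicator shift (-> pH),
# the indicator/reference integral ratio (-> C_indicator) and from these the
# concentration of protons transferred from the analyte,
#   kappa = f_H * C_indicator + [H+]_free,
# where [H+]_free = 10^-pH / gamma1(I) converts the H+ activity to a
# concentration. The free-proton term matters for low-pKa analytes.

#' Indicator concentration from integrals
#'
#' Per-proton integral ratio against an inert reference compound of known
#' concentration, times its calibrated correction factor.
#'
#' @param integral_indicator,integral_reference Peak integrals (arbitrary
#'   units, same scale); vectorized.
#' @param ind An [indicator()].
#' @param ref A [reference_compound()].
#' @return Indicator concentration (mol/L).
#' @export
indicator_concentration <- function(integral_indicator, integral_reference,
                                    ind, ref) {
  stopifnot(inherits(ind, "nmr_indicator"),
            inherits(ref, "reference_compound"))
  bad <- which(!(integral_indicator > 0) | !(integral_reference > 0))
  if (length(bad))
    stop("nonpositive integral in slice(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  (integral_indicator / ind$n_protons) /
    (integral_reference / ref$n_protons) * ref$conc * ref$correction_factor
}

#' Proton-transfer concentration of a slice (kappa)
#'
#' kappa is the concentration of protons the acidic analyte has given up at
#' a slice: protons now sitting on the indicator plus those free in
#' solution. The free-proton term `10^-pH / gamma1(I)` becomes significant
#' for low-pKa analytes where the working pH is low.
#'
#' @param C_indicator Indicator concentration (mol/L).
#' @param frac_protonated Protonated fraction of the indicator (0-1).
#' @param pH Slice pH (so `10^-pH` is the H+ activity).
#' @param I Ionic strength used to convert H+ activity to concentration.
#' @param A Debye-Hueckel constant.
#' @return kappa (mol/L); vectorized.
#' @export
proton_transfer <- function(C_indicator, frac_protonated, pH, I = 0,
                            A = 0.509) {
  if (any(C_indicator <= 0))
    stop("C_indicator must be > 0", call. = FALSE)
  frac_protonated * C_indicator + 10^(-pH) / gamma1(I, A)
}

#' Read a per-slice peak table
#'
#' CSV with header `height_mm, delta_obs_ppm, integral_indicator,
#' integral_reference`, one row per slice, comma-separated with
#' dot-decimals.
#'
#' @param path File path.
#' @return data.frame with the four columns, numeric.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse peak table ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  need <- c("height_mm", "delta_obs_ppm", "integral_indicator",
            "integral_reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("peak table ", path, " has no rows", call. = FALSE)
  for (cl in need) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v)))
      stop(sprintf("peak table %s: non-numeric '%s' at data line(s) %s",
                   path, cl, paste(which(is.na(v)), collapse = ", ")),
           call. = FALSE)
    df[[cl]] <- v
  }
  df[need]
}

#' Derive fit-ready slice points from a peak table
#'
#' Runs the full per-slice reduction: indicator concentration from
#' integrals, self-consistent pH and ionic strength from the shift, kappa,
#' and validity filtering. Rejection is logged, never silent; slices are
#' dropped when the shift is at or beyond a limiting value, the protonated
#' fraction falls outside `f_limits` (too close to a limit for a reliable
#' pH), the pH lies outside the indicator's usable window, or kappa is not
#' positive.
#'
#' @param peaks data.frame as returned by [read_peak_table()] (or a path).
#' @param ind An [indicator()].
#' @param ref A [reference_compound()].
#' @param comp An [composition()] describing the analyte and strong co-ions
#'   entering the ionic strength (default: indicator only).
#' @param f_limits Retained range of the indicator protonated fraction;
#'   the default `c(0.05, 0.95)` implements the rule that pH read more than
#'   about one unit from the indicator pKa is unreliable.
#' @param A Debye-Hueckel constant.
#' @param use_activity Apply the Davies ionic-strength machinery (the
#'   self-consistent I loop and the activity-to-concentration conversion in
#'   kappa). `FALSE` treats I as zero throughout, matching data simulated
#'   with `use_activity = FALSE`.
#' @param Kw Water autoionization product used in the ionic-strength
#'   estimate.
#' @return Object of class `slice_points`: list with `points` (data.frame
#'   `height_mm, pH, ionic_strength_M, C_indicator_M, kappa_M, inv_kappa,
#'   aH, frac_protonated`), `rejected` (data.frame `height_mm, reason`),
#'   `ind`, `ref`.
#' @export
build_points <- function(peaks, ind, ref, comp = composition(),
                         f_limits = c(0.05, 0.95), A = 0.509,
                         use_activity = TRUE, Kw = 1e-14) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  stopifnot(inherits(ind, "nmr_indicator"),
            inherits(ref, "reference_compound"),
            inherits(comp, "ion_composition"))
  if (nrow(peaks) < 3)
    stop("need at least 3 slice measurements", call. = FALSE)
  bad <- which(!(peaks$integral_indicator > 0) |
                 !(peaks$integral_reference > 0))
  if (length(bad))
    stop("nonpositive integral in slice(s) ",
         paste(bad, collapse = ", "), call. = FALSE)

  C_ind <- indicator_concentration(peaks$integral_indicator,
                                   peaks$integral_reference, ind, ref)
  lo <- min(ind$delta_H, ind$delta_L); hi <- max(ind$delta_H, ind$delta_L)

  pts <- vector("list", nrow(peaks))
  rej <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    h <- peaks$height_mm[i]; d <- peaks$delta_obs_ppm[i]
    if (d <= lo || d >= hi) {
      rej[[i]] <- data.frame(height_mm = h,
                             reason = "shift at or beyond limiting value")
      next
    }
    pr <- if (use_activity) ph_selfconsistent(d, ind, C_ind[i], comp, A,
                                              Kw = Kw)
    else ph_from_shift(d, ind, 0, A)
    if (pr$frac_protonated < f_limits[1] ||
        pr$frac_protonated > f_limits[2]) {
      rej[[i]] <- data.frame(height_mm = h,
                             reason = "frac_protonated outside retained range")
      next
    }
    if (!pr$in_window) {
      rej[[i]] <- data.frame(height_mm = h,
                             reason = "pH outside indicator window")
      next
    }
    I_i <- if (use_activity) pr$I_used else 0
    k <- proton_transfer(C_ind[i], pr$frac_protonated, pr$pH,
                         if (use_activity) I_i else 0, A)
    if (!(k > 0)) {
      rej[[i]] <- data.frame(height_mm = h, reason = "kappa not positive")
      next
    }
    pts[[i]] <- data.frame(height_mm = h, pH = pr$pH,
                           ionic_strength_M = pr$I_used,
                           C_indicator_M = C_ind[i], kappa_M = k,
                           inv_kappa = 1 / k, aH = 10^(-pr$pH),
                           frac_protonated = pr$frac_protonated)
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  rejected <- do.call(rbind, rej[!vapply(rej, is.null, logical(1))])
  if (is.null(rejected))
    rejected <- data.frame(height_mm = numeric(), reason = character())
  if (is.null(points) || nrow(points) < 3)
    stop(sprintf(paste0("insufficient data: %d retained slice(s) after ",
                        "filtering (need >= 3); rejections: %s"),
                 if (is.null(points)) 0L else nrow(points),
                 paste(unique(rejected$reason), collapse = "; ")),
         call. = FALSE)
  structure(list(points = points, rejected = rejected, ind = ind,
                 ref = ref),
            class = "slice_points")
}

#' @export
print.slice_points <- function(x, ...) {
  cat(sprintf("slice_points: %d retained, %d rejected (indicator %s)\n",
              nrow(x$points), nrow(x$rejected), x$ind$name))
  if (nrow(x$rejected))
    print(table(x$rejected$reason))
  cat(sprintf("  pH %.2f-%.2f, median I %.4g M\n",
              min(x$points$pH), max(x$points$pH),
              stats::median(x$points$ionic_strength_M)))
  invisible(x)
}

#' Write derived slice points as CSV
#'
#' @param x A `slice_points` object or its `points` data.frame.
#' @param path Output path.
#' @export
write_points_csv <- function(x, path) {
  df <- if (inherits(x, "slice_points")) x$points else x
  utils::write.csv(
    df[c("height_mm", "pH", "ionic_strength_M", "C_indicator_M", "kappa_M",
         "inv_kappa", "aH")],
    path, row.names = FALSE)
  invisible(path)
}
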