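# Cyclodextrin-mediated lipid-exchange design and zeta-potential-based
# asymmetry validation.

#' Donor-specific exchange constants
#'
#' Empirical constants for the cyclodextrin-lipid exchange formula:
#' 292 for PC, PG and PS donation and 150 for PE donation.
#'
#' @param donor species name (e.g. "DMPG") or headgroup class
#'   ("PC", "PG", "PS", "PE").
#' @return numeric constant K.
#' @export
donor_exchange_constant <- function(donor) {
  head <- toupper(donor)
  if (grepl("P[CGS]$", head)) return(292)
  if (grepl("PE$", head)) return(150)
  stop("no exchange constant known for donor '", donor,
       "'; supply K explicitly")
}

#' Plan a single-round cyclodextrin lipid exchange
#'
#' Computes the donor lipid concentration `Cd` and the methyl
#' beta-cyclodextrin concentration `Cm` required to reach a target
#' outer-leaflet donor fraction by one round of outside-only exchange:
#' \deqn{Cd = a \cdot Ca \cdot asym / (1 - asym)}
#' \deqn{Cm = n \cdot Cd + (Cd \cdot K) / n}
#' where `a` is the fraction of acceptor lipid accessible to exchange
#' (~0.5 for LUVs), `n` the CD-lipid complex stoichiometry (4) and `K`
#' the donor-specific constant. The formula is applied exactly as printed,
#' in the caller's concentration units: `K` is quoted with irregular units
#' in the source protocols yet enters linearly, so no unit conversion is
#' attempted. The CD-lipid saturation level (70%) is recorded as metadata
#' only; it was absorbed into `K` empirically and has no separate role in
#' the arithmetic.
#'
#' @param Ca acceptor lipid concentration (mM), > 0.
#' @param target_asym desired outer-leaflet donor fraction in [0, 1).
#'   Practical exchanges reach about 0.5; values above 0.55 warn.
#' @param a accessible (outer-leaflet) lipid fraction, default 0.5.
#' @param donor donor species or headgroup class used to look up `K`.
#' @param K exchange constant; overrides the `donor` lookup when given.
#' @param n CD-lipid complex stoichiometry, default 4.
#' @param saturation CD-lipid saturation fraction, metadata only.
#' @return An object of class `exchange_plan` with elements `Ca`, `Cd`,
#'   `Cm`, `target_asym`, `a`, `K`, `n`, `saturation`.
#' @export
#' @examples
#' plan_exchange(Ca = 40, target_asym = 1/3, donor = "DMPG")
plan_exchange <- function(Ca, target_asym, a = 0.5, donor = "DMPC",
                          K = NULL, n = 4, saturation = 0.70) {
  if (!is.finite(Ca) || Ca <= 0) stop("'Ca' must be a positive concentration")
  if (!is.finite(target_asym) || target_asym < 0)
    stop("'target_asym' must be non-negative")
  if (target_asym >= 1)
    stop("'target_asym' must be < 1 (a leaflet cannot exceed 100% donor)")
  if (target_asym > 0.55)
    warning("target asymmetry above ~0.55 is beyond the validated range ",
            "of single-round exchange")
  if (!(a > 0 && a < 1)) stop("'a' must lie strictly between 0 and 1")
  if (n <= 0) stop("'n' must be a positive stoichiometry")
  if (is.null(K)) K <- donor_exchange_constant(donor)
  if (K < 0) stop("'K' must be non-negative")

  Cd <- a * Ca * target_asym / (1 - target_asym)
  Cm <- if (Cd == 0) 0 else n * Cd + (Cd * K) / n
  structure(list(Ca = Ca, Cd = Cd, Cm = Cm, target_asym = target_asym,
                 a = a, donor = donor, K = K, n = n,
                 saturation = saturation),
            class = "exchange_plan")
}

#' @export
print.exchange_plan <- function(x, ...) {
  cat("Cyclodextrin exchange plan\n")
  cat(sprintf("  acceptor Ca  : %.4g mM\n", x$Ca))
  cat(sprintf("  donor Cd     : %.4g mM (%s, K = %g, n = %g)\n",
              x$Cd, x$donor, x$K, x$n))
  cat(sprintf("  MbetaCD Cm   : %.4g (printed-formula units)\n", x$Cm))
  cat(sprintf("  target outer-leaflet donor fraction: %.3f (a = %.2f)\n",
              x$target_asym, x$a))
  cat(sprintf("  CD-lipid saturation (metadata): %.0f%%\n",
              100 * x$saturation))
  invisible(x)
}

#' Outer-leaflet donor fraction from the total donor fraction
#'
#' Under single-round, outside-only exchange all donor lipid resides in
#' the outer leaflet, so the outer-leaflet donor fraction is the measured
#' whole-liposome donor fraction divided by the accessible fraction `a`.
#' A total fraction of 0.25 at a = 0.5 therefore reads out as 0.50 (50%)
#' outer-leaflet donor content.
#'
#' @param total_donor_fraction whole-liposome donor mole fraction in [0, a].
#' @param a accessible (outer-leaflet) lipid fraction, default 0.5.
#' @return outer-leaflet donor fraction, clipped to [0, 1].
#' @export
#' @examples
#' outer_leaflet_fraction(0.25, a = 0.5)  # 0.5
outer_leaflet_fraction <- function(total_donor_fraction, a = 0.5) {
  if (!(a > 0 && a < 1)) stop("'a' must lie strictly between 0 and 1")
  if (any(total_donor_fraction < 0))
    stop("'total_donor_fraction' must be non-negative")
  if (any(total_donor_fraction > a + 1e-12))
    stop("total donor fraction exceeds the accessible fraction: ",
         "inconsistent with outside-only exchange (implies inner-leaflet donor)")
  pmin(pmax(total_donor_fraction / a, 0), 1)
}

#' Bin measured asymmetry to the nearest 10%
#'
#' Measured outer-leaflet fractions are grouped to the nearest 10%
#' (+/- 3%) for analysis; samples farther than 3 percentage points from
#' any bin centre are excluded, returned as `NA`.
#'
#' @param measured_fraction numeric vector of fractions in [0, 1].
#' @param bin_width bin spacing, default 0.10.
#' @param tol maximal distance from a bin centre, default 0.03.
#' @return numeric vector of bin centres; `NA` marks excluded samples.
#' @export
#' @examples
#' bin_asymmetry(c(0.48, 0.44, 0.30))  # 0.5, NA, 0.3
bin_asymmetry <- function(measured_fraction, bin_width = 0.10, tol = 0.03) {
  if (any(measured_fraction < 0 | measured_fraction > 1))
    stop("'measured_fraction' must lie in [0, 1]")
  centre <- round(measured_fraction / bin_width) * bin_width
  out <- ifelse(abs(measured_fraction - centre) <= tol + 1e-12, centre,
                NA_real_)
  round(out, 10)
}

#' Theoretical zeta-potential asymmetry line
#'
#' Couples a symmetric-liposome calibration (zeta potential as a function
#' of whole-liposome charged-lipid fraction) to the accessible fraction
#' `a`, yielding the theoretical zeta expected for an asymmetric liposome
#' whose donor lipid is confined to the outer leaflet. The calibration is
#' a table of (fraction, zeta_mV) points interpolated piecewise-linearly;
#' it must be monotone, and evaluation outside its range is an error.
#'
#' @param calibration data.frame with columns `fraction` and `zeta_mV`.
#' @param a accessible fraction, default 0.5.
#' @param margin relative tolerance band on the predicted zeta magnitude,
#'   default 0.10 (the 10% shaded band around the line).
#' @return An object of class `asymmetry_line`.
#' @export
asymmetry_line <- function(calibration, a = 0.5, margin = 0.10) {
  stopifnot(is.data.frame(calibration),
            all(c("fraction", "zeta_mV") %in% names(calibration)))
  if (margin < 0) stop("'margin' must be non-negative")
  if (!(a > 0 && a < 1)) stop("'a' must lie strictly between 0 and 1")
  cal <- calibration[order(calibration$fraction), ]
  if (anyDuplicated(cal$fraction)) stop("calibration fractions must be distinct")
  dz <- diff(cal$zeta_mV)
  if (!(all(dz >= 0) || all(dz <= 0)))
    stop("calibration must be monotone in zeta")
  structure(list(calibration = cal, a = a, margin = margin),
            class = "asymmetry_line")
}

# evaluate the symmetric calibration; extrapolation is an error
sym_zeta <- function(line, fraction) {
  cal <- line$calibration
  if (any(fraction < min(cal$fraction) - 1e-12 |
          fraction > max(cal$fraction) + 1e-12))
    stop("fraction outside the calibrated range [",
         min(cal$fraction), ", ", max(cal$fraction), "]")
  stats::approx(cal$fraction, cal$zeta_mV, xout = fraction,
                rule = 1, ties = "ordered")$y
}

#' Classify a liposome on the theoretical asymmetry line
#'
#' Compares a measured zeta potential against two predictions from the
#' symmetric calibration: the symmetric prediction at the total
#' charged-lipid fraction, and the asymmetric prediction at
#' `total_fraction / a` (all donor in the outer leaflet). A measurement
#' within the relative `margin` band of exactly one prediction takes that
#' label; both or neither matching yields "indeterminate".
#'
#' @param line an [asymmetry_line()].
#' @param total_fraction whole-liposome donor fraction.
#' @param zeta_measured measured zeta potential (mV).
#' @return list with `label` ("asymmetric", "symmetric" or
#'   "indeterminate"), predicted values and the margin band half-widths.
#' @export
classify_on_asymmetry_line <- function(line, total_fraction, zeta_measured) {
  stopifnot(inherits(line, "asymmetry_line"))
  if (total_fraction / line$a > 1 + 1e-12)
    stop("total_fraction / a exceeds 1: no valid outer-leaflet composition")
  z_sym <- sym_zeta(line, total_fraction)
  z_asym <- sym_zeta(line, min(total_fraction / line$a, 1))
  band_sym <- line$margin * abs(z_sym)
  band_asym <- line$margin * abs(z_asym)
  eps <- 1e-9 * (1 + abs(zeta_measured))   # interpolation round-off guard
  hit_sym <- abs(zeta_measured - z_sym) <= band_sym + eps
  hit_asym <- abs(zeta_measured - z_asym) <= band_asym + eps
  label <- if (hit_asym && !hit_sym) "asymmetric"
           else if (hit_sym && !hit_asym) "symmetric"
           else "indeterminate"
  list(label = label, zeta_sym = z_sym, zeta_asym = z_asym,
       band_sym = band_sym, band_asym = band_asym,
       zeta_measured = zeta_measured)
}
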