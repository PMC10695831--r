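# Curve-level analysis: absorbance deconvolution, linear calibration,
# laurdan generalized polarization and melting midpoints, folded-fraction
# readouts.

#' Deconvolute an absorbance spectrum into reference components
#'
#' Finds the non-negative scale factors of the supplied reference spectra
#' (e.g. unlabelled liposomes and fluorophore alone) that minimize the sum
#' of squared differences between the reconvoluted and raw spectra over
#' the measured wavelength range (300-600 nm in the standard assay).
#' References measured on a different wavelength grid are linearly
#' resampled onto the raw grid; scales are constrained non-negative
#' because they represent physical concentrations.
#'
#' @param raw data.frame with columns `wavelength_nm` (strictly
#'   increasing) and `absorbance`.
#' @param references named list of reference spectra in the same format.
#' @return An object of class `deconvolution`: `concentrations` (named
#'   non-negative scales), `residual_ss`, `reconvoluted` (data.frame) and
#'   an `ill_conditioned` flag set when references are nearly collinear.
#' @export
deconvolute_spectrum <- function(raw, references) {
  check_spectrum(raw)
  if (!length(references)) stop("need at least one reference spectrum")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  lambda <- raw$wavelength_nm
  R <- vapply(references, function(ref) {
    check_spectrum(ref)
    if (min(ref$wavelength_nm) > min(lambda) + 1e-9 ||
        max(ref$wavelength_nm) < max(lambda) - 1e-9)
      stop("reference does not cover the raw wavelength range")
    stats::approx(ref$wavelength_nm, ref$absorbance, xout = lambda)$y
  }, numeric(length(lambda)))
  R <- as.matrix(R)
  ill <- FALSE
  if (ncol(R) > 1) {
    s <- svd(R)$d
    ill <- s[length(s)] <= 1e-10 * s[1]
    if (ill) warning("reference spectra are nearly linearly dependent; ",
                     "component scales are poorly determined")
  }
  fit <- pracma::lsqnonneg(R, raw$absorbance)
  scales <- setNames(as.numeric(fit$x), names(references))
  recon <- as.numeric(R %*% fit$x)
  structure(list(
    concentrations = scales,
    residual_ss = sum((recon - raw$absorbance)^2),
    reconvoluted = data.frame(wavelength_nm = lambda, absorbance = recon),
    ill_conditioned = ill
  ), class = "deconvolution")
}

check_spectrum <- function(sp) {
  if (!all(c("wavelength_nm", "absorbance") %in% names(sp)))
    stop("spectrum needs columns 'wavelength_nm' and 'absorbance'")
  if (any(diff(sp$wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  invisible(sp)
}

#' Ordinary least-squares calibration line with inverse prediction
#'
#' Fits y = intercept + slope * x to calibration standards (e.g. an
#' anthrone absorbance series against known MbetaCD concentrations) and
#' returns an inverse-prediction function mapping a measured response
#' back to concentration.
#'
#' @param x,y numeric vectors of standard concentrations and responses.
#' @return list with `slope`, `intercept`, `fit` (the `lm` object) and
#'   `inverse(y)`.
#' @export
#' @examples
#' cal <- linear_calibration(x = seq(0, 200, 25), y = 0.002 * seq(0, 200, 25))
#' cal$inverse(0.2)  # 100
linear_calibration <- function(x, y) {
  if (length(unique(x)) < 2) stop("need at least two distinct x values")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope == 0) stop("calibration slope is zero; inverse prediction undefined")
  list(slope = slope, intercept = intercept, fit = fit,
       inverse = function(y_meas) (y_meas - intercept) / slope)
}

#' Laurdan generalized polarization
#'
#' GP = (I440 - I490) / (I440 + I490), the standard ratiometric readout
#' of laurdan emission reporting the lipid phase.
#'
#' @param I440,I490 emission intensities at 440 and 490 nm (vectorized).
#' @return numeric GP values in [-1, 1].
#' @export
#' @examples
#' gp_value(0.6, 0.4)  # 0.2
gp_value <- function(I440, I490) {
  total <- I440 + I490
  if (any(total <= 0)) stop("I440 + I490 must be positive")
  (I440 - I490) / total
}

#' Lipid melting midpoint from a GP-vs-temperature curve
#'
#' Determines the gel-fluid transition temperature as the extremum of the
#' numerical first differential of GP with respect to temperature
#' (central differences), refined by quadratic interpolation through the
#' extremum and its two neighbours. A curve whose derivative never rises
#' above the noise floor (estimated robustly from second differences)
#' raises a no-transition error: a straight or flat GP trace carries no
#' transition.
#'
#' @param temperature strictly increasing temperatures (degrees C).
#' @param gp GP values, same length, or a data.frame with columns
#'   `temp_C` and `gp` passed as the first argument.
#' @return list with `tm` (degrees C), `peak_derivative` (GP per degree C)
#'   and the interior derivative table.
#' @export
melting_midpoint <- function(temperature, gp = NULL) {
  if (is.data.frame(temperature)) {
    gp <- temperature$gp
    temperature <- temperature$temp_C
  }
  n <- length(temperature)
  if (n < 5) stop("need at least 5 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  idx <- 2:(n - 1)
  d <- (gp[idx + 1] - gp[idx - 1]) / (temperature[idx + 1] - temperature[idx - 1])
  tmid <- temperature[idx]

  # noise floor on the derivative from second differences of GP
  h <- stats::median(diff(temperature))
  d2 <- diff(gp, differences = 2)
  sigma_gp <- stats::mad(d2, center = 0) / sqrt(6)
  sigma_d <- sigma_gp * sqrt(2) / (2 * h)

  dc <- d - stats::median(d)
  peak <- which.max(abs(dc))
  floor_abs <- 1e-6 * max(1, abs(stats::median(d)))
  if (abs(dc[peak]) <= 5 * sigma_d + floor_abs)
    stop("no transition detected: GP derivative never exceeds the noise floor")

  tm <- tmid[peak]
  if (peak > 1 && peak < length(d)) {
    # quadratic vertex through the extremum and neighbours (uniform or not)
    x <- tmid[(peak - 1):(peak + 1)]
    yv <- d[(peak - 1):(peak + 1)]
    co <- stats::coef(stats::lm(yv ~ x + I(x^2)))
    if (is.finite(co[3]) && co[3] != 0) {
      vertex <- -co[2] / (2 * co[3])
      if (vertex >= x[1] && vertex <= x[3]) tm <- vertex
    }
  }
  list(tm = unname(tm), peak_derivative = d[peak],
       derivative = data.frame(temp_C = tmid, dgp_dT = d))
}

#' Folded protein fraction from standard readouts
#'
#' Two modes: `"trp_ratio"` linearly interpolates the sample's 335/350 nm
#' tryptophan fluorescence intensity ratio between an unfolded reference
#' (fraction 0) and a folded reference (fraction 1), clipped to [0, 1];
#' `"gel_monomer"` computes folded / (folded + unfolded) from cold
#' SDS-PAGE monomer band densities.
#'
#' @param mode `"trp_ratio"` or `"gel_monomer"`.
#' @param ratio,ratio_folded,ratio_unfolded 335/350 ratios for the sample
#'   and the folded/unfolded references (trp_ratio mode).
#' @param folded,unfolded monomer band densities (gel mode).
#' @return folded fraction in [0, 1].
#' @export
#' @examples
#' folded_fraction("gel_monomer", folded = 30, unfolded = 10)  # 0.75
folded_fraction <- function(mode = c("trp_ratio", "gel_monomer"),
                            ratio = NULL, ratio_folded = NULL,
                            ratio_unfolded = NULL,
                            folded = NULL, unfolded = NULL) {
  mode <- match.arg(mode)
  if (mode == "gel_monomer") {
    if (is.null(folded) || is.null(unfolded))
      stop("gel mode needs 'folded' and 'unfolded' band densities")
    if (any(folded < 0) || any(unfolded < 0))
      stop("band densities must be non-negative")
    if (any(folded + unfolded == 0))
      stop("folded and unfolded densities cannot both be zero")
    return(folded / (folded + unfolded))
  }
  if (is.null(ratio) || is.null(ratio_folded) || is.null(ratio_unfolded))
    stop("trp_ratio mode needs 'ratio', 'ratio_folded' and 'ratio_unfolded'")
  if (ratio_folded == ratio_unfolded)
    stop("degenerate calibration: folded and unfolded reference ratios are equal")
  frac <- (ratio - ratio_unfolded) / (ratio_folded - ratio_unfolded)
  pmin(pmax(frac, 0), 1)
}
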