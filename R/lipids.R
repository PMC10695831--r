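#' Built-in lipid species table
#'
#' Reference properties for the lipid species supported throughout the
#' package: headgroup charge (elementary charges per lipid), gel-fluid
#' transition temperature Tm (degrees Celsius) and a cholesterol flag.
#' DMPC/DMPG have Tm of ~24 and 23 degrees C and charges 0 and -1; DMPS and
#' DMPE have Tm of 35 and 50 degrees C. Cholesterol carries no Tm and is
#' handled separately by the featurizer.
#'
#' @return A data.frame with columns `name`, `headgroup_charge`,
#'   `tm_celsius`, `is_cholesterol`.
#' @export
#' @examples
#' lipid_species()
lipid_species <- function() {
  data.frame(
    name = c("DMPC", "DMPG", "DMPE", "DMPS", "POPC", "POPG", "cholesterol"),
    headgroup_charge = c(0, -1, 0, -1, 0, -1, 0),
    tm_celsius = c(24, 23, 50, 35, -2, -2, NA_real_),
    is_cholesterol = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Leaflet composition
#'
#' A named vector of mole fractions (mol/mol) over lipid species,
#' validated to be non-negative and to sum to 1.
#'
#' @param fractions named numeric vector of mole fractions.
#' @return An object of class `leaflet_composition`.
#' @export
#' @examples
#' leaflet_composition(c(DMPC = 0.75, DMPG = 0.25))
leaflet_composition <- function(fractions) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("'fractions' must be a named vector of mole fractions")
  if (any(fractions < 0)) stop("mole fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(fractions)), ")")
  structure(fractions, class = "leaflet_composition")
}

#' Liposome composition with distinct leaflets
#'
#' @param inner,outer leaflet compositions (see [leaflet_composition()]).
#' @param accessible_fraction fraction of total lipid residing in the outer,
#'   exchange-accessible leaflet. ~0.5 for large unilamellar vesicles.
#' @return An object of class `liposome_composition`.
#' @export
liposome_composition <- function(inner, outer, accessible_fraction = 0.5) {
  if (!inherits(inner, "leaflet_composition")) inner <- leaflet_composition(inner)
  if (!inherits(outer, "leaflet_composition")) outer <- leaflet_composition(outer)
  if (!(accessible_fraction > 0 && accessible_fraction < 1))
    stop("'accessible_fraction' must lie strictly between 0 and 1")
  structure(list(inner = inner, outer = outer,
                 accessible_fraction = accessible_fraction),
            class = "liposome_composition")
}

#' Total (whole-liposome) mole fractions of a liposome composition
#'
#' @param x a `liposome_composition`.
#' @return named numeric vector of whole-liposome mole fractions.
#' @export
total_fractions <- function(x) {
  stopifnot(inherits(x, "liposome_composition"))
  a <- x$accessible_fraction
  species <- union(names(x$inner), names(x$outer))
  inner <- setNames(rep(0, length(species)), species)
  outer <- inner
  inner[names(x$inner)] <- as.numeric(x$inner)
  outer[names(x$outer)] <- as.numeric(x$outer)
  (1 - a) * inner + a * outer
}
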