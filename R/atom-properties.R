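#' Elemental property table used for descriptor weighting
#'
#' Per-element constants consumed by the autocorrelation and Burden-matrix
#' descriptors: Sanderson electronegativity (dimensionless), static atomic
#' polarizability (cubic Angstrom), first ionization energy (eV) and atomic
#' number. Sanderson electronegativities follow the scale tabulated in
#' Todeschini & Consonni, *Handbook of Molecular Descriptors*; polarizabilities
#' and ionization energies are the CRC Handbook free-atom values. The table is
#' a package constant so every computed descriptor is reproducible offline.
#'
#' @return A data frame with one row per element and columns
#'   \code{element}, \code{electronegativity}, \code{polarizability},
#'   \code{ionization}, \code{atomic_number}.
#' @examples
#' atom_property_table()
#' @export
atom_property_table <- function() .atom_props

.atom_props <- data.frame(
  element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
              "Se", "Br", "I"),
  electronegativity = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000,
                        2.138, 2.515, 2.957, 3.475, 3.014, 3.219, 2.778),
  polarizability = c(0.667, 3.030, 1.760, 1.100, 0.802, 0.557,
                     5.380, 3.630, 2.900, 2.180, 3.770, 3.050, 5.350),
  ionization = c(13.598, 8.298, 11.260, 14.534, 13.618, 17.423,
                 8.151, 10.487, 10.360, 12.968, 9.752, 11.814, 10.451),
  atomic_number = c(1L, 5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L,
                    34L, 35L, 53L),
  stringsAsFactors = FALSE
)

.weight_schemes <- c("electronegativity", "polarizability", "ionization",
                     "atomic_number")

# single-letter scheme codes used in canonical descriptor names
.scheme_codes <- c(e = "electronegativity", p = "polarizability",
                   i = "ionization", Z = "atomic_number")

#' Per-atom property weights for a molecular graph
#'
#' Looks up, for every heavy atom of a molecular graph, one of the elemental
#' properties in [atom_property_table()]. With \code{relative = TRUE} values
#' are divided by carbon's value, the convention used by the Burden-matrix
#' diagonal ("relative first ionization potential" and friends).
#'
#' @param g A [molecular_graph()].
#' @param scheme One of \code{"electronegativity"}, \code{"polarizability"},
#'   \code{"ionization"}, \code{"atomic_number"}.
#' @param relative Divide by the carbon value? Default \code{FALSE}.
#' @return Numeric vector, one weight per heavy atom, in atom order.
#' @examples
#' g <- parse_smiles("CCO")
#' atom_weights(g, "atomic_number")            # 6 6 8
#' atom_weights(g, "electronegativity", TRUE)  # 1 1 1.33...
#' @export
atom_weights <- function(g, scheme = c("electronegativity", "polarizability",
                                       "ionization", "atomic_number"),
                         relative = FALSE) {
  stopifnot(inherits(g, "molecular_graph"))
  scheme <- match.arg(scheme)
  tab <- .atom_props
  idx <- match(g$atoms$element, tab$element)
  if (anyNA(idx)) {
    bad <- unique(g$atoms$element[is.na(idx)])
    stopf("element(s) %s of compound '%s' not covered by the property table",
          paste(bad, collapse = ", "), g$id, class = "plqsar_unknown_element")
  }
  w <- tab[[scheme]][idx]
  if (relative) w <- w / tab[[scheme]][tab$element == "C"]
  w
}
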