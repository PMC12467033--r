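#' Compound registry and unit conversion
#'
#' Inhibitor dosing is usually reported in mass concentration (ug/mL) while
#' binding constants (Ka, L/mol) require molar concentration.  A compound
#' registry maps compound names to molecular weights so the two scales can be
#' interconverted.
#'
#' @name compound-registry
NULL

#' Build a compound registry
#'
#' @param name Character vector of unique compound identifiers.
#' @param molecular_weight Numeric vector of molecular weights, g/mol
#'   (positive).
#' @param notes Optional character vector of free-text notes.
#' @return A data frame of class `"compound_registry"`.
#' @export
#' @examples
#' reg <- compound_registry(c("drugA", "drugB"), c(500, 750))
compound_registry <- function(name, molecular_weight, notes = NA_character_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("compound names must be unique")
  molecular_weight <- as.numeric(molecular_weight)
  if (any(!is.finite(molecular_weight)) || any(molecular_weight <= 0))
    stop("molecular_weight must be positive and finite")
  structure(data.frame(name = name, molecular_weight = molecular_weight,
                       notes = rep_len(as.character(notes), length(name)),
                       stringsAsFactors = FALSE),
            class = c("compound_registry", "data.frame"))
}

#' Default porphyrin registry
#'
#' Molecular weights of the six porphyrin inhibitors, computed from their
#' molecular formulas: TAPP = tetrakis(4-aminophenyl)porphyrin (C44H34N8),
#' THPP = tetrakis(4-hydroxyphenyl)porphyrin (C44H30N4O4), TCPP =
#' tetrakis(4-carboxyphenyl)porphyrin (C48H30N4O8), and the metalated
#' M-TCPP species as TCPP minus two pyrrolic hydrogens plus the metal.
#'
#' @return A `"compound_registry"` with six rows.
#' @export
#' @examples
#' default_porphyrin_registry()
default_porphyrin_registry <- function() {
  compound_registry(
    name = c("TAPP", "THPP", "TCPP", "Fe-TCPP", "Ni-TCPP", "Cu-TCPP"),
    molecular_weight = c(674.81, 678.77, 790.80, 844.60, 847.45, 852.33),
    notes = c("C44H34N8", "C44H30N4O4", "C48H30N4O8",
              "C48H28FeN4O8", "C48H28NiN4O8", "C48H28CuN4O8"))
}

lookup_mw <- function(compound, registry) {
  if (is.numeric(compound)) {  # direct molecular weight
    if (compound <= 0) stop("molecular weight must be positive")
    return(compound)
  }
  i <- match(compound, registry$name)
  if (is.na(i))
    stop(sprintf("unknown compound '%s' (not in registry)", compound))
  registry$molecular_weight[i]
}

#' Convert mass concentration to molar concentration
#'
#' `convert_concentration()` maps ug/mL to mol/L via the molecular weight;
#' `convert_concentration_back()` is its exact inverse.
#'
#' @param value Concentration in ug/mL (or mol/L for the inverse).
#' @param compound Compound name looked up in `registry`, or a molecular
#'   weight in g/mol given directly.
#' @param registry A [compound_registry()]; defaults to
#'   [default_porphyrin_registry()].
#' @return Concentration in mol/L (respectively ug/mL).
#' @export
#' @examples
#' convert_concentration(10, "TAPP")      # mol/L
#' convert_concentration(1000, 1000)      # 1e-3 mol/L for MW 1000
convert_concentration <- function(value, compound,
                                  registry = default_porphyrin_registry()) {
  mw <- lookup_mw(compound, registry)
  value * 1e-3 / mw
}

#' @rdname convert_concentration
#' @export
convert_concentration_back <- function(value, compound,
                                       registry = default_porphyrin_registry()) {
  mw <- lookup_mw(compound, registry)
  value * mw * 1e3
}
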