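#' Electron equivalents from elemental composition
#'
#' Computes the degree of reduction of a compound, i.e. the number of
#' electrons released by its complete oxidation to CO2 and H2O, from the
#' atom counts of its neutral (acid) form: `4*C + H - 2*O` mol electrons
#' per mol compound. CO2 is the zero reference; H2 carries 2 electrons.
#'
#' @param c_atoms,h_atoms,o_atoms non-negative atom counts per molecule
#'   (vectorised; recycled to common length).
#' @return mol electrons per mol compound (numeric vector).
#' @examples
#' electron_equivalents(3, 6, 3)  # lactic acid: 12
#' electron_equivalents(0, 2, 0)  # H2: 2
#' @export
electron_equivalents <- function(c_atoms, h_atoms, o_atoms) {
  n <- max(length(c_atoms), length(h_atoms), length(o_atoms))
  c_atoms <- rep_len(c_atoms, n)
  h_atoms <- rep_len(h_atoms, n)
  o_atoms <- rep_len(o_atoms, n)
  if (any(c_atoms < 0 | h_atoms < 0 | o_atoms < 0))
    stop("atom counts must be non-negative")
  if (any(c_atoms + h_atoms + o_atoms == 0))
    stop("atom counts must not all be zero")
  ee <- 4 * c_atoms + h_atoms - 2 * o_atoms
  if (any(ee < 0))
    stop("negative electron equivalents: compounds more oxidized than the ",
         "CO2/H2O reference are unsupported")
  ee
}

#' Compound registry
#'
#' Loads the table of compounds known to the package (short-chain
#' carboxylic acids in their neutral acid form, alcohols, H2, CO2, CH4)
#' and derives electron and carbon equivalents by the degree-of-reduction
#' rule. Users may supply their own table with identical columns to
#' extend or override the packaged one.
#'
#' @param file optional path to a CSV with columns
#'   `name, c_atoms, h_atoms, o_atoms, molar_mass`; defaults to the
#'   packaged table.
#' @return data.frame with the input columns plus `electron_equiv` and
#'   `carbon_equiv`.
#' @export
compound_registry <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "compounds.csv", package = "electroferm",
                        mustWork = TRUE)
  reg <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "c_atoms", "h_atoms", "o_atoms", "molar_mass")
  if (!all(need %in% names(reg)))
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  reg$name <- tolower(reg$name)
  reg$electron_equiv <- electron_equivalents(reg$c_atoms, reg$h_atoms, reg$o_atoms)
  reg$carbon_equiv <- reg$c_atoms
  reg
}

#' Look up one compound
#'
#' @param name compound name (case-insensitive).
#' @param registry a registry from [compound_registry()].
#' @return one-row data.frame.
#' @export
get_compound <- function(name, registry = compound_registry()) {
  i <- match(tolower(name), registry$name)
  if (is.na(i)) stop("unknown compound: ", name)
  registry[i, , drop = FALSE]
}

#' Convert a molar rate to a mass rate
#'
#' @param rate molar production rate, mM per day.
#' @param compound compound name.
#' @param registry a registry from [compound_registry()].
#' @return mass rate in g per L per day (neutral-acid molar mass basis).
#' @examples
#' mm_to_mass_rate(5.9, "propionate")  # 0.44 g/L/d
#' @export
mm_to_mass_rate <- function(rate, compound, registry = compound_registry()) {
  if (any(!is.finite(rate))) stop("rate must be finite")
  cmp <- get_compound(compound, registry)
  rate * cmp$molar_mass / 1000
}

#' Carbon and electron content of an amount of compound
#'
#' @param amount mmol of compound (non-negative).
#' @param compound compound name.
#' @param registry a registry from [compound_registry()].
#' @return named numeric vector `c(mmol_c = , mmol_e = )`.
#' @examples
#' mmol_to_carbon_and_electrons(12.2, "lactate")  # 36.6 C, 146.4 e-
#' @export
mmol_to_carbon_and_electrons <- function(amount, compound,
                                         registry = compound_registry()) {
  if (any(amount < 0)) stop("amount must be non-negative")
  cmp <- get_compound(compound, registry)
  c(mmol_c = amount * cmp$carbon_equiv, mmol_e = amount * cmp$electron_equiv)
}
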