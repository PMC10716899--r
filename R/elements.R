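# Element reference data: symbols, atomic numbers, covalent radii (Angstrom,
# Cordero et al. 2008 single-bond values) and standard atomic masses (u).
# Covers the elements that occur in biomolecular and common small-molecule
# systems; extend the table to support exotic species.

.element_table <- local({
  df <- data.frame(
    symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
               "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
               "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Se", "Br", "I"),
    number = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
               11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
               25L, 26L, 27L, 28L, 29L, 30L, 34L, 35L, 53L),
    r_cov = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
              1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
              1.39, 1.32, 1.26, 1.24, 1.32, 1.22, 1.20, 1.20, 1.39),
    mass = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
             18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974,
             32.06, 35.45, 39.948, 39.098, 40.078, 54.938, 55.845,
             58.933, 58.693, 63.546, 65.38, 78.971, 79.904, 126.90),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$symbol
  df
})

#' Look up properties of a chemical element
#'
#' @param symbol Character vector of element symbols (case-sensitive,
#'   e.g. `"Na"`).
#' @return For `element_mass()` and `covalent_radius()`, a numeric vector
#'   (`NA` for unknown symbols); for `is_known_element()`, a logical vector;
#'   for `atomic_number()`, an integer vector.
#' @examples
#' element_mass(c("C", "O"))
#' covalent_radius("H")
#' @export
element_mass <- function(symbol) {
  .element_table$mass[match(symbol, .element_table$symbol)]
}

#' @rdname element_mass
#' @export
covalent_radius <- function(symbol) {
  .element_table$r_cov[match(symbol, .element_table$symbol)]
}

#' @rdname element_mass
#' @export
atomic_number <- function(symbol) {
  .element_table$number[match(symbol, .element_table$symbol)]
}

#' @rdname element_mass
#' @export
is_known_element <- function(symbol) {
  !is.na(match(symbol, .element_table$symbol))
}

# Canonicalise capitalisation ("CL" -> "Cl"); returns NA for non-elements.
normalize_element_symbol <- function(symbol) {
  cand <- paste0(toupper(substr(symbol, 1L, 1L)),
                 tolower(substr(symbol, 2L, nchar(symbol))))
  ifelse(is_known_element(cand), cand, NA_character_)
}

# Residue-name sets used by the selection builtins.  The standard 20 amino
# acids plus common protonation/termination variants; water residue names
# from the usual MD force-field conventions.
.amino_acid_names <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "CYM", "ASH", "GLH",
  "LYN", "ACE", "NME", "NMA"
)

.water_names <- c("HOH", "SOL", "WAT", "TIP3", "TIP4", "SPC")

is_amino_acid <- function(resname) toupper(resname) %in% .amino_acid_names

is_water_resname <- function(resname) toupper(resname) %in% .water_names
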