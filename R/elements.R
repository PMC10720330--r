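# Periodic-table lookups used across the package. Symbols indexed by nuclear
# charge Z = 1..86; standard atomic weights (u), IUPAC 2021 abridged values.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

.element_masses <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
  145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
  174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
  204.38, 207.2, 208.98, 209, 210, 222
)

symbol_to_z <- function(symbols) {
  z <- match(symbols, .element_symbols)
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  z
}

z_to_symbol <- function(z) {
  if (any(z < 1L | z > length(.element_symbols))) {
    stop("nuclear charge out of supported range [1, ", length(.element_symbols), "]",
      call. = FALSE
    )
  }
  .element_symbols[z]
}

#' Atomic masses for element symbols
#'
#' Standard atomic weights in unified atomic mass units, looked up by chemical
#' symbol. Used by the mass-weighted radius of gyration.
#'
#' @param symbols Character vector of element symbols (e.g. `c("C", "H")`).
#' @return Numeric vector of masses (u), same length as `symbols`.
#' @export
#' @examples
#' atomic_masses(c("H", "C", "O"))
atomic_masses <- function(symbols) {
  .element_masses[symbol_to_z(symbols)]
}

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula (element symbols each followed by an
#' optional integer count) into per-element atom counts.
#'
#' @param formula A single string such as `"C24H42O21"`.
#' @return A named integer vector mapping element symbol to count; `sum()` of
#'   it is the total atom count.
#' @export
#' @examples
#' parse_formula("C24H42O21") # stachyose: 87 atoms
#' sum(parse_formula("C22H32O2")) # DHA: 56 atoms
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  formula <- trimws(formula)
  if (!nzchar(formula)) stop("empty formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
    sub("^[A-Za-z]+", "", tokens), "1"
  ))
  symbol_to_z(syms) # validates symbols
  out <- tapply(counts, factor(syms, levels = unique(syms)), sum)
  setNames(as.integer(out), names(out))
}

# Expand a formula into the per-atom symbol vector, element blocks in
# formula order (C24H42O21 -> 24 C, then 42 H, then 21 O).
formula_to_symbols <- function(formula) {
  counts <- parse_formula(formula)
  rep(names(counts), counts)
}
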