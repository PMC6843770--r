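# Standard atomic weights (amu) for the elements routinely seen in
# biomolecular structures.  Masses are assigned from the element, never read
# from coordinate files (PDB/GRO carry no masses).
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA_ = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, ZN = 65.38, SE = 78.971,
  BR = 79.904, I = 126.904
)

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of atomic masses in amu.
#' @examples
#' element_mass(c("C", "N", "P"))
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

# Infer the element symbol from an atom name when the coordinate file does
# not provide one.  Hydrogens may be named like "H", "HG1", "1HB", "HO2'".
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[0-9'*\"]", "", trimws(atom_name)))
  vapply(nm, function(x) {
    if (x == "") return("C")
    two <- substr(x, 1, 2)
    if (two %in% c("MG", "ZN", "CL", "FE", "MN", "SE", "BR")) return(two)
    one <- substr(x, 1, 1)
    if (one %in% c("H", "C", "N", "O", "P", "S", "F", "K", "I", "D")) return(one)
    one
  }, character(1), USE.NAMES = FALSE)
}
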