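# Element tables used across the geometry and superposition code.

# Standard atomic masses (u), sufficient for protein + water systems.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, SE = 78.971, F = 18.998, CL = 35.45,
  BR = 79.904, I = 126.904, `NA` = 22.990, K = 39.098, MG = 24.305,
  CA = 40.078, MN = 54.938, FE = 55.845, ZN = 65.38, CU = 63.546
)

# van der Waals radii (Angstrom) after Bondi (1964), with the Rowland &
# Taylor value for H; these are the radii commonly used for solvent
# accessibility calculations on proteins.
.vdw_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  `NA` = 2.27, K = 2.75, MG = 1.73, CA = 2.31, MN = 2.05, FE = 2.05,
  ZN = 1.39, CU = 1.40
)

# The twenty standard amino acids (three-letter, upper case).
.standard_aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.aa3_to_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# Residue names treated as solvent water in hydrogen-bond bookkeeping.
.water_resnames <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "H2O", "SPC")

#' van der Waals radii table
#'
#' Per-element van der Waals radii (in Angstrom) used by [sasa()]. The values
#' follow the Bondi compilation with the commonly used 1.20 A radius for
#' hydrogen.
#'
#' @return A named numeric vector of radii keyed by upper-case element symbol.
#' @export
#' @examples
#' vdw_radii()[c("C", "N", "O")]
vdw_radii <- function() .vdw_radii

#' Standard atomic masses
#'
#' Masses (in unified atomic mass units) used for mass-weighted quantities
#' such as the radius of gyration.
#'
#' @return A named numeric vector of masses keyed by upper-case element symbol.
#' @export
atomic_masses <- function() .atomic_masses

# Infer element symbols from PDB atom names when the element column is
# blank. Handles the common protein/water cases: a leading digit is
# stripped (e.g. "1HG1"), two-letter metals occupy columns 13-14.
.infer_element <- function(elety, elesy = NULL) {
  out <- toupper(trimws(elesy %||% rep("", length(elety))))
  need <- is.na(out) | out == ""
  if (any(need)) {
    nm <- toupper(gsub("^[0-9']+", "", trimws(elety[need])))
    first <- substr(nm, 1, 1)
    two <- substr(nm, 1, 2)
    guess <- ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "MN", "FE", "SE", "CU"),
      two, first
    )
    out[need] <- guess
  }
  out
}
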