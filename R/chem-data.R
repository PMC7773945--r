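# Element-level constants used across the descriptor pipeline.

# Standard atomic weights (IUPAC 2021 abridged), g/mol.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971,
  Br = 79.904, Kr = 83.798, Rb = 85.468, Sr = 87.62, Mo = 95.95, Ag = 107.87,
  Cd = 112.41, Sn = 118.71, Sb = 121.76, I = 126.90, Xe = 131.29, Cs = 132.91,
  Ba = 137.33, W = 183.84, Pt = 195.08, Au = 196.97, Hg = 200.59, Pb = 207.2
)

# Bondi van der Waals radii (Angstrom); used by the grid-probe pocket volume.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90
)
.VDW_DEFAULT <- 1.70

# Default metal set for the 2.1 A ligand-contact filter: common biologically
# relevant PDB metals (configurable in filter_metal_contacts()).
.DEFAULT_METALS <- c("Li", "Na", "K", "Mg", "Ca", "Mn", "Fe", "Co", "Ni",
                     "Cu", "Zn", "Cd", "Hg")

# Default valences for implicit-hydrogen inference on neutral atoms.
.STANDARD_VALENCES <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                        Br = 1, I = 1, B = 3, Si = 4)

# Gas constant in kcal/(mol K), as used in dG = -RT ln K.
.R_KCAL <- 1.9872e-3

# The fixed 20-feature schema: 6 ligand + 14 pocket descriptors.
.LIGAND_FEATURES <- c("MASS", "D", "A", "logP", "MR", "W")
.POCKET_FEATURES <- c("PMR.Arom", "PMR.NonArom", "PlogP.Arom",
                      "PlogP.NonArom", "PD.AmideNH", "PD.KRHIP", "PD.KNQ",
                      "PD.WH", "PD.TSYDE", "PA.AmideO", "PA.DE",
                      "PA.NQTSDHEH", "PA.YH", "PVol")
.ALL_FEATURES <- c(.LIGAND_FEATURES, .POCKET_FEATURES)
.DONOR_GROUPS <- c("PD.AmideNH", "PD.KRHIP", "PD.KNQ", "PD.WH", "PD.TSYDE")
.ACCEPTOR_GROUPS <- c("PA.AmideO", "PA.DE", "PA.NQTSDHEH", "PA.YH")

#' Standard atomic weight of an element
#'
#' @param element Character vector of element symbols (case-normalised).
#' @return Numeric vector of atomic weights in g/mol.
#' @keywords internal
atomic_weight <- function(element) {
  el <- normalize_element(element)
  w <- .ATOMIC_WEIGHTS[el]
  if (anyNA(w)) {
    stop("unknown element(s): ", paste(unique(el[is.na(w)]), collapse = ", "))
  }
  unname(w)
}

vdw_radius <- function(element) {
  el <- normalize_element(element)
  r <- .VDW_RADII[el]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# "CL" -> "Cl", "fe" -> "Fe"
normalize_element <- function(element) {
  el <- as.character(element)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}
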