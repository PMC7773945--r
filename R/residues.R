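# Amino-acid reference data for the pocket descriptors: residue topology
# templates (used to type atoms with the Wildman-Crippen scheme without
# needing hydrogens in the input PDB) and the donor/acceptor group mapping
# table behind the nine hydrogen-bonding pocket features.

# Aromatic residue set used to split PMR / PlogP.
.AROMATIC_RESIDUES <- c("PHE", "TRP", "TYR", "HIS", "HID", "HIE", "HIP")

# Protonation-variant aliases resolve to a base template.
.RESIDUE_ALIASES <- c(HID = "HIS", HIE = "HIS", HIP = "HIS",
                      ASH = "ASP", GLH = "GLU", LYN = "LYS", CYX = "CYS",
                      MSE = "MET")

# Template definitions. Atoms: name, element, number of attached hydrogens,
# formal charge. Bonds: name pairs with order (4 = aromatic). The backbone
# (N, CA, C, O) is shared; side chains are listed per residue. Physiological
# protonation: Asp-/Glu- carboxylates, Lys+/Arg+, neutral His with the
# proton on NE2.
.SIDE_CHAINS <- list(
  GLY = list(atoms = NULL, bonds = NULL),
  ALA = list(atoms = list(c("CB", "C", 3, 0)), bonds = list(c("CA", "CB", 1))),
  VAL = list(atoms = list(c("CB", "C", 1, 0), c("CG1", "C", 3, 0),
                          c("CG2", "C", 3, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG1", 1),
                          c("CB", "CG2", 1))),
  LEU = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 1, 0),
                          c("CD1", "C", 3, 0), c("CD2", "C", 3, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD1", 1), c("CG", "CD2", 1))),
  ILE = list(atoms = list(c("CB", "C", 1, 0), c("CG1", "C", 2, 0),
                          c("CG2", "C", 3, 0), c("CD1", "C", 3, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG1", 1),
                          c("CB", "CG2", 1), c("CG1", "CD1", 1))),
  PRO = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 2, 0),
                          c("CD", "C", 2, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD", 1), c("CD", "N", 1))),
  PHE = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 0, 0),
                          c("CD1", "C", 1, 0), c("CD2", "C", 1, 0),
                          c("CE1", "C", 1, 0), c("CE2", "C", 1, 0),
                          c("CZ", "C", 1, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD1", 4), c("CD1", "CE1", 4),
                          c("CE1", "CZ", 4), c("CZ", "CE2", 4),
                          c("CE2", "CD2", 4), c("CD2", "CG", 4))),
  TYR = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 0, 0),
                          c("CD1", "C", 1, 0), c("CD2", "C", 1, 0),
                          c("CE1", "C", 1, 0), c("CE2", "C", 1, 0),
                          c("CZ", "C", 0, 0), c("OH", "O", 1, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD1", 4), c("CD1", "CE1", 4),
                          c("CE1", "CZ", 4), c("CZ", "CE2", 4),
                          c("CE2", "CD2", 4), c("CD2", "CG", 4),
                          c("CZ", "OH", 1))),
  TRP = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 0, 0),
                          c("CD1", "C", 1, 0), c("CD2", "C", 0, 0),
                          c("NE1", "N", 1, 0), c("CE2", "C", 0, 0),
                          c("CE3", "C", 1, 0), c("CZ2", "C", 1, 0),
                          c("CZ3", "C", 1, 0), c("CH2", "C", 1, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD1", 4), c("CD1", "NE1", 4),
                          c("NE1", "CE2", 4), c("CE2", "CD2", 4),
                          c("CD2", "CG", 4), c("CD2", "CE3", 4),
                          c("CE3", "CZ3", 4), c("CZ3", "CH2", 4),
                          c("CH2", "CZ2", 4), c("CZ2", "CE2", 4))),
  SER = list(atoms = list(c("CB", "C", 2, 0), c("OG", "O", 1, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "OG", 1))),
  THR = list(atoms = list(c("CB", "C", 1, 0), c("OG1", "O", 1, 0),
                          c("CG2", "C", 3, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "OG1", 1),
                          c("CB", "CG2", 1))),
  CYS = list(atoms = list(c("CB", "C", 2, 0), c("SG", "S", 1, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "SG", 1))),
  MET = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 2, 0),
                          c("SD", "S", 0, 0), c("CE", "C", 3, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "SD", 1), c("SD", "CE", 1))),
  ASN = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 0, 0),
                          c("OD1", "O", 0, 0), c("ND2", "N", 2, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "OD1", 2), c("CG", "ND2", 1))),
  GLN = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 2, 0),
                          c("CD", "C", 0, 0), c("OE1", "O", 0, 0),
                          c("NE2", "N", 2, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD", 1), c("CD", "OE1", 2),
                          c("CD", "NE2", 1))),
  ASP = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 0, 0),
                          c("OD1", "O", 0, 0), c("OD2", "O", 0, -1)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "OD1", 2), c("CG", "OD2", 1))),
  GLU = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 2, 0),
                          c("CD", "C", 0, 0), c("OE1", "O", 0, 0),
                          c("OE2", "O", 0, -1)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD", 1), c("CD", "OE1", 2),
                          c("CD", "OE2", 1))),
  LYS = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 2, 0),
                          c("CD", "C", 2, 0), c("CE", "C", 2, 0),
                          c("NZ", "N", 3, 1)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD", 1), c("CD", "CE", 1),
                          c("CE", "NZ", 1))),
  ARG = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 2, 0),
                          c("CD", "C", 2, 0), c("NE", "N", 1, 0),
                          c("CZ", "C", 0, 0), c("NH1", "N", 2, 1),
                          c("NH2", "N", 2, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "CD", 1), c("CD", "NE", 1),
                          c("NE", "CZ", 1), c("CZ", "NH1", 2),
                          c("CZ", "NH2", 1))),
  HIS = list(atoms = list(c("CB", "C", 2, 0), c("CG", "C", 0, 0),
                          c("ND1", "N", 0, 0), c("CD2", "C", 1, 0),
                          c("CE1", "C", 1, 0), c("NE2", "N", 1, 0)),
             bonds = list(c("CA", "CB", 1), c("CB", "CG", 1),
                          c("CG", "ND1", 4), c("ND1", "CE1", 4),
                          c("CE1", "NE2", 4), c("NE2", "CD2", 4),
                          c("CD2", "CG", 4)))
)

# Build an ACE/NME-capped template molgraph for one residue; returns the
# molgraph plus the index of each named heavy atom of the residue proper.
residue_template <- function(resid) {
  base <- if (resid %in% names(.RESIDUE_ALIASES)) .RESIDUE_ALIASES[[resid]]
          else resid
  sc <- .SIDE_CHAINS[[base]]
  if (is.null(sc)) stop("no template for residue ", resid)
  n_h <- if (base == "PRO") 0L else 1L
  ca_h <- if (base == "GLY") 2L else 1L
  atoms <- list(
    c("ACE_CH3", "C", 3, 0), c("ACE_C", "C", 0, 0), c("ACE_O", "O", 0, 0),
    c("N", "N", n_h, 0), c("CA", "C", ca_h, 0), c("C", "C", 0, 0),
    c("O", "O", 0, 0), c("NME_N", "N", 1, 0), c("NME_CH3", "C", 3, 0))
  bonds <- list(
    c("ACE_CH3", "ACE_C", 1), c("ACE_C", "ACE_O", 2), c("ACE_C", "N", 1),
    c("N", "CA", 1), c("CA", "C", 1), c("C", "O", 2), c("C", "NME_N", 1),
    c("NME_N", "NME_CH3", 1))
  atoms <- c(atoms, sc$atoms)
  bonds <- c(bonds, sc$bonds)

  nm <- vapply(atoms, `[`, character(1), 1)
  el <- vapply(atoms, `[`, character(1), 2)
  nh <- as.integer(vapply(atoms, `[`, character(1), 3))
  ch <- as.integer(vapply(atoms, `[`, character(1), 4))

  # expand explicit hydrogens
  all_el <- el; all_ch <- ch
  hpar <- integer(0)
  for (i in seq_along(nm)) {
    if (nh[i] > 0L) {
      all_el <- c(all_el, rep("H", nh[i]))
      all_ch <- c(all_ch, rep(0L, nh[i]))
      hpar <- c(hpar, rep(i, nh[i]))
    }
  }
  bmat <- do.call(rbind, lapply(bonds, function(b)
    c(match(b[1], nm), match(b[2], nm), as.integer(b[3]))))
  if (length(hpar)) {
    hidx <- length(nm) + seq_along(hpar)
    bmat <- rbind(bmat, cbind(hpar, hidx, 1L))
  }
  m <- molgraph(all_el, bonds = bmat, charges = all_ch, name = resid)
  list(mol = m, heavy_names = nm, heavy_idx = seq_along(nm))
}

.residue_crippen_cache <- new.env(parent = emptyenv())

#' Per-atom Wildman-Crippen contributions for standard residues
#'
#' For each supported residue type, the contribution of every heavy atom by
#' PDB atom name, with the contributions of its attached (template)
#' hydrogens folded in. This makes the pocket logP/MR sums well defined on
#' hydrogen-free crystal structures. Computed once per session from
#' ACE/NME-capped template graphs.
#'
#' @param resid Three-letter residue name (HID/HIE/HIP, ASH/GLH, LYN, CYX
#'   and MSE resolve to their base templates).
#' @return data.frame with columns atom_name, element, logp, mr; NULL for
#'   unsupported residue names.
#' @export
residue_crippen <- function(resid) {
  base <- if (resid %in% names(.RESIDUE_ALIASES)) .RESIDUE_ALIASES[[resid]]
          else resid
  if (!base %in% names(.SIDE_CHAINS)) return(NULL)
  hit <- .residue_crippen_cache[[base]]
  if (!is.null(hit)) return(hit)
  tpl <- residue_template(base)
  m <- tpl$mol
  types <- crippen_atom_types(m)
  idx <- match(types, .CRIPPEN$type)
  lp <- .CRIPPEN$logp[idx]; mr <- .CRIPPEN$mr[idx]
  nb <- mol_neighbors(m)
  nheavy <- length(tpl$heavy_names)
  out <- data.frame(atom_name = tpl$heavy_names,
                    element = m$elements[tpl$heavy_idx],
                    logp = lp[tpl$heavy_idx], mr = mr[tpl$heavy_idx],
                    stringsAsFactors = FALSE)
  # fold hydrogens onto parents
  for (h in which(m$elements == "H")) {
    p <- nb[[h]][1]
    if (p <= nheavy) {
      out$logp[p] <- out$logp[p] + lp[h]
      out$mr[p] <- out$mr[p] + mr[h]
    }
  }
  keep <- !grepl("^(ACE|NME)_", out$atom_name)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  assign(base, out, envir = .residue_crippen_cache)
  out
}

#' Donor/acceptor group mapping table for pocket atoms
#'
#' Maps (residue, atom name) to one of the five donor groups and one of the
#' four acceptor groups behind the nine hydrogen-bonding pocket
#' descriptors. Backbone amide N (except proline) maps to the Amide-NH
#' donor group and backbone O to the Amide-O acceptor group for every
#' residue type, including unknown ones. Within each family (donor,
#' acceptor) the groups are disjoint at the atom level; an atom such as a
#' serine hydroxyl oxygen may appear in both a donor and an acceptor group.
#'
#' Group conventions: lysine NZ belongs to the positively charged donor
#' group only; neutral histidine donates through NE2 (heteroaromatic donor
#' group) and accepts through ND1 (aromatic acceptor group), with HID
#' reversing the two and HIP placing both ring nitrogens in the positively
#' charged donor group; protonated Asp/Glu (ASH/GLH) move their hydroxyl
#' oxygen into the hydroxyl donor group while the carbonyl oxygen counts as
#' a neutral non-aromatic acceptor.
#'
#' @return data.frame with columns resid, atom_name, donor_group,
#'   acceptor_group (NA when the atom is not in a group of that family).
#' @export
donor_acceptor_map <- function() {
  rows <- list(
    c("SER", "OG",  "PD.TSYDE", "PA.NQTSDHEH"),
    c("THR", "OG1", "PD.TSYDE", "PA.NQTSDHEH"),
    c("TYR", "OH",  "PD.TSYDE", "PA.YH"),
    c("ASP", "OD1", NA, "PA.DE"),
    c("ASP", "OD2", NA, "PA.DE"),
    c("GLU", "OE1", NA, "PA.DE"),
    c("GLU", "OE2", NA, "PA.DE"),
    c("ASH", "OD1", NA, "PA.NQTSDHEH"),
    c("ASH", "OD2", "PD.TSYDE", NA),
    c("GLH", "OE1", NA, "PA.NQTSDHEH"),
    c("GLH", "OE2", "PD.TSYDE", NA),
    c("ASN", "OD1", NA, "PA.NQTSDHEH"),
    c("ASN", "ND2", "PD.KNQ", NA),
    c("GLN", "OE1", NA, "PA.NQTSDHEH"),
    c("GLN", "NE2", "PD.KNQ", NA),
    c("LYS", "NZ",  "PD.KRHIP", NA),
    c("ARG", "NE",  "PD.KRHIP", NA),
    c("ARG", "NH1", "PD.KRHIP", NA),
    c("ARG", "NH2", "PD.KRHIP", NA),
    c("HIS", "ND1", NA, "PA.YH"),
    c("HIS", "NE2", "PD.WH", NA),
    c("HIE", "ND1", NA, "PA.YH"),
    c("HIE", "NE2", "PD.WH", NA),
    c("HID", "ND1", "PD.WH", NA),
    c("HID", "NE2", NA, "PA.YH"),
    c("HIP", "ND1", "PD.KRHIP", NA),
    c("HIP", "NE2", "PD.KRHIP", NA),
    c("TRP", "NE1", "PD.WH", NA))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("resid", "atom_name", "donor_group", "acceptor_group")
  out
}
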