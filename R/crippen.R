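# Wildman-Crippen atomic contribution scheme for logP and molar
# refractivity (MR). The contribution values are the published constants
# (Wildman & Crippen 1999, J Chem Inf Comput Sci 39:868); the atom typer
# below is a procedural classifier over the molgraph representation covering
# the organic subset relevant to drug-like ligands and protein residues.

.CRIPPEN <- local({
  tab <- rbind(
    c("C1",  0.1441,  2.503),  c("C2",  0.0000,  2.433),
    c("C3", -0.2035,  2.753),  c("C4", -0.2051,  2.731),
    c("C5", -0.2783,  5.007),  c("C6",  0.1551,  3.513),
    c("C7",  0.0017,  3.888),  c("C8",  0.08452, 2.464),
    c("C9", -0.1444,  2.412),  c("C10", -0.0516, 2.488),
    c("C11", 0.1193,  2.582),  c("C12", -0.0967, 2.576),
    c("C13", -0.5443, 4.041),  c("C14", 0.0000,  3.257),
    c("C15", 0.2450,  3.564),  c("C16", 0.1980,  3.180),
    c("C17", 0.0000,  3.104),  c("C18", 0.1581,  3.350),
    c("C19", 0.2955,  4.346),  c("C20", 0.2713,  3.904),
    c("C21", 0.1360,  3.509),  c("C22", 0.4619,  4.067),
    c("C23", 0.5437,  3.853),  c("C24", 0.1893,  2.673),
    c("C25", -0.8186, 3.135),  c("C26", 0.2640,  4.305),
    c("C27", 0.2148,  2.693),  c("CS",  0.08129, 3.243),
    c("H1",  0.1230,  1.057),  c("H2", -0.2677,  1.395),
    c("H3",  0.2142,  0.9627), c("H4",  0.2980,  1.805),
    c("HS",  0.1125,  1.112),
    c("N1", -1.0190,  2.262),  c("N2", -0.7096,  2.173),
    c("N3", -1.0270,  2.827),  c("N4", -0.5188,  3.000),
    c("N5",  0.08387, 1.757),  c("N6",  0.1836,  2.428),
    c("N7", -0.3187,  1.839),  c("N8", -0.4458,  2.819),
    c("N9",  0.01508, 1.725),  c("N10", -1.9500, 0.000),
    c("N11", -0.3239, 2.202),  c("N12", -1.1190, 0.000),
    c("N13", -0.3396, 0.2604), c("N14", 0.2887,  3.359),
    c("NS", -0.4806,  2.134),
    c("O1",  0.1552,  1.080),  c("O2", -0.2893,  0.8238),
    c("O3", -0.0684,  1.085),  c("O4", -0.4195,  1.182),
    c("O5",  0.0335,  3.367),  c("O6", -0.3339,  0.7774),
    c("O7", -1.1890,  0.000),  c("O8",  0.1788,  3.135),
    c("O9", -0.1526,  0.000),  c("O10", 0.1129,  0.2215),
    c("O11", 0.4833,  0.389),  c("O12", -1.3260, 0.000),
    c("OS", -0.1188,  0.6865),
    c("F",   0.4202,  1.108),  c("Cl",  0.6895,  5.853),
    c("Br",  0.8456,  8.927),  c("I",   0.8857, 14.02),
    c("Hal", -2.9960, 0.000),
    c("P",   0.8612,  6.920),
    c("S1",  0.6482,  7.591),  c("S2", -0.0024,  7.365),
    c("S3",  0.6237,  6.691),
    c("Me1", -0.3808, 5.754),  c("Me2", -0.0025, 0.000)
  )
  data.frame(type = tab[, 1], logp = as.numeric(tab[, 2]),
             mr = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
})

.HETERO_SET <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
.ME1_SET <- c("Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
              "B", "Al", "Ga", "In", "Tl", "Si", "Ge", "Sn", "Pb",
              "As", "Sb", "Bi", "Se", "Te", "Po")
.ME2_SET <- c("Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
              "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
              "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg")

#' Wildman-Crippen atom types
#'
#' Assign every atom (explicit hydrogens included) one of the published
#' Wildman-Crippen contribution classes. Implicit hydrogens inferred from
#' standard valences are typed through \code{\link{crippen_contributions}},
#' which folds their contribution onto the parent atom.
#'
#' @param mol A \code{molgraph}.
#' @return Character vector of type labels (e.g. "C1", "O9", "NS").
#' @export
crippen_atom_types <- function(mol) {
  n <- n_atoms(mol)
  nb <- mol_neighbors(mol)
  el <- mol$elements
  arom <- mol$aromatic
  chg <- mol$charges
  b <- mol$bonds

  # per-atom double/triple bond partners
  dbl <- vector("list", n); trp <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    if (b[k, 3] == 2L) {
      dbl[[b[k, 1]]] <- c(dbl[[b[k, 1]]], b[k, 2])
      dbl[[b[k, 2]]] <- c(dbl[[b[k, 2]]], b[k, 1])
    } else if (b[k, 3] == 3L) {
      trp[[b[k, 1]]] <- c(trp[[b[k, 1]]], b[k, 2])
      trp[[b[k, 2]]] <- c(trp[[b[k, 2]]], b[k, 1])
    }
  }
  nH_expl <- vapply(nb, function(v) sum(el[v] == "H"), integer(1))
  nH <- nH_expl + implicit_hydrogens(mol)
  nbh <- lapply(nb, function(v) v[el[v] != "H"])

  vapply(seq_len(n), function(i) {
    heavy_nb <- nbh[[i]]
    switch(el[i],
      "H" = type_hydrogen(i, nb, dbl, el, arom),
      "C" = type_carbon(i, heavy_nb, dbl[[i]], trp[[i]], nH[i], el, arom),
      "N" = type_nitrogen(i, heavy_nb, dbl[[i]], trp[[i]], nH[i], chg[i],
                          el, arom),
      "O" = type_oxygen(i, heavy_nb, dbl[[i]], nH[i], chg[i], el, arom,
                        dbl, nbh),
      "S" = if (arom[i]) "S3" else
        if (chg[i] != 0 ||
            any(el[dbl[[i]]] %in% c("N", "O", "P", "S"))) "S2" else "S1",
      "P" = "P",
      "F" = if (chg[i] == 0) "F" else "Hal",
      "Cl" = if (chg[i] == 0) "Cl" else "Hal",
      "Br" = if (chg[i] == 0) "Br" else "Hal",
      "I" = if (chg[i] == 0) "I" else "Hal",
      type_other(el[i], chg[i]))
  }, character(1))
}

type_other <- function(e, chg) {
  if (e %in% c("Li", "Na", "K", "Rb", "Cs") && chg > 0) return("Hal")
  if (e %in% .ME1_SET) return("Me1")
  if (e %in% .ME2_SET) return("Me2")
  "CS"  # carbon default absorbs anything unclassifiable
}

type_hydrogen <- function(i, nb, dbl, el, arom) {
  p <- nb[[i]][1]
  if (is.na(p)) return("HS")
  pe <- el[p]
  if (pe %in% c("C", "H")) return("H1")
  if (pe == "N") return("H3")
  if (pe == "O") {
    onb <- nb[[p]][el[nb[[p]]] != "H"]
    if (any(el[onb] == "N")) return("H3")              # H-O-N
    if (any(el[onb] %in% c("O", "S"))) return("H4")    # peroxide/H-O-S
    for (c_at in onb[el[onb] == "C"]) {
      if (any(el[dbl[[c_at]]] %in% c("C", "N", "O", "S")))
        return("H4")                                   # acid/enol H
    }
    return("H2")                                       # alcohol, phenol
  }
  "H2"  # [#1][!C;!N;!O]
}

type_carbon <- function(i, heavy_nb, di, ti, nH, el, arom) {
  if (arom[i]) {
    # substituent = neighbour that is not aromatic-ring partner
    sub <- heavy_nb[!arom[heavy_nb]]
    if (nH >= 1L && length(sub) == 0L) return("C18")
    if (length(sub) == 0L) {
      # all-aromatic neighbours: fused (3 ring partners) C19 or biaryl C20
      return(if (length(heavy_nb) >= 3L) "C19" else "C18")
    }
    s <- sub[1]
    se <- el[s]
    if (se == "F") return("C14")
    if (se == "Cl") return("C15")
    if (se == "Br") return("C16")
    if (se == "I") return("C17")
    if (s %in% di && se %in% c("C", "N", "O")) return("C25")  # exocyclic =
    if (se == "C") return("C21")
    if (se == "N") return("C22")
    if (se == "O") return("C23")
    if (se == "S") return("C24")
    return("C13")
  }
  # aliphatic
  if (length(ti) > 0L && any(el[ti] != "H")) return("C7")
  if (length(di) > 0L) {
    dpart <- di[el[di] != "H"]
    if (length(dpart)) {
      dp <- dpart[1]
      if (el[dp] == "C") {
        if (arom[dp]) return("C26")                 # [C]=c
        if (any(arom[heavy_nb])) return("C26")      # vinyl on aryl
        return("C6")
      }
      return("C5")                                  # C = heteroatom
    }
  }
  # sp3
  if (any(arom[heavy_nb])) {
    if (nH >= 3L) {
      ar <- heavy_nb[arom[heavy_nb]][1]
      return(if (el[ar] == "C") "C8" else "C9")
    }
    if (nH == 2L) return("C10")
    if (nH == 1L) return("C11")
    return("C12")
  }
  if (any(el[heavy_nb] %in% .HETERO_SET)) {
    return(if (nH >= 2L) "C3" else "C4")
  }
  if (any(!(el[heavy_nb] %in% c("C", "H")))) return("C27")
  if (nH >= 2L || length(heavy_nb) <= 1L) return("C1")
  if (length(heavy_nb) + nH >= 4L) return("C2")
  "CS"
}

type_nitrogen <- function(i, heavy_nb, di, ti, nH, chg, el, arom) {
  di <- di[el[di] != "H"]; ti <- ti[el[ti] != "H"]
  if (arom[i]) return(if (chg > 0) "N12" else "N11")
  if (chg > 0) {
    if (nH >= 1L) return("N10")
    if (length(ti)) return("N14")
    return("N13")
  }
  if (chg < 0) return("N14")
  if (length(ti)) return("N9")
  if (length(di)) {
    return(if (nH >= 1L) "N5" else "N6")
  }
  has_ar <- any(arom[heavy_nb])
  if (nH >= 2L) return(if (has_ar) "N3" else "N1")
  if (nH == 1L) return(if (has_ar) "N4" else "N2")
  if (has_ar) return("N8")
  if (length(heavy_nb) >= 3L) return("N7")
  "NS"
}

type_oxygen <- function(i, heavy_nb, di, nH, chg, el, arom, dbl, nbh) {
  di <- di[el[di] != "H"]
  if (arom[i]) return("O1")
  if (chg < 0) {
    if (any(el[heavy_nb] == "N")) return("O5")
    if (any(el[heavy_nb] == "S")) return("O6")
    # carboxylate: O- on a carbon that is double-bonded to another O
    for (c_at in heavy_nb[el[heavy_nb] == "C"]) {
      if (any(el[dbl[[c_at]]] == "O")) return("O12")
    }
    return("O7")
  }
  if (nH >= 1L) return("O2")
  if (length(di)) {
    dp <- di[1]
    if (arom[dp]) return("O8")
    if (el[dp] %in% c("N", "O")) return("O5")
    if (el[dp] == "S") return("O6")
    if (el[dp] == "C") {
      # classify by the carbonyl carbon's other substituents
      csub <- setdiff(nbh[[dp]], i)
      csub_el <- el[csub]
      if (any(arom[csub])) return("O10")
      nonC <- csub[!(csub_el %in% c("C", "H"))]
      if (length(nonC) >= 2L) return("O11")
      return("O9")
    }
    return("OS")
  }
  if (length(heavy_nb) >= 2L) {
    return(if (any(arom[heavy_nb])) "O4" else "O3")
  }
  "OS"
}

#' Wildman-Crippen logP and molar refractivity
#'
#' Sum of atomic contributions over all atoms, with implicit hydrogens
#' (inferred from standard valences) contributing as hydrogen atoms typed by
#' their parent. Additive over disconnected components.
#'
#' @param mol A \code{molgraph}.
#' @return Named list with elements \code{logP} (unitless) and \code{MR}
#'   (cm^3/mol).
#' @examples
#' benzene <- molgraph(rep("C", 6),
#'                     bonds = cbind(1:6, c(2:6, 1), c(1, 2, 1, 2, 1, 2)))
#' crippen_contributions(benzene)
#' @export
crippen_contributions <- function(mol) {
  if (n_atoms(mol) == 0L) stop("empty molecule")
  nb <- mol_neighbors(mol)
  types <- crippen_atom_types(mol)
  idx <- match(types, .CRIPPEN$type)
  logp <- sum(.CRIPPEN$logp[idx])
  mr <- sum(.CRIPPEN$mr[idx])

  # implicit hydrogens: type each as a hydrogen attached to its parent
  impH <- implicit_hydrogens(mol)
  if (any(impH > 0L)) {
    for (i in which(impH > 0L)) {
      htype <- type_implicit_h(i, mol, nb)
      k <- match(htype, .CRIPPEN$type)
      logp <- logp + impH[i] * .CRIPPEN$logp[k]
      mr <- mr + impH[i] * .CRIPPEN$mr[k]
    }
  }
  list(logP = logp, MR = mr)
}

type_implicit_h <- function(parent, mol, nb) {
  el <- mol$elements
  pe <- el[parent]
  if (pe == "C") return("H1")
  if (pe == "N") return("H3")
  if (pe == "O") {
    onb <- nb[[parent]][el[nb[[parent]]] != "H"]
    if (any(el[onb] == "N")) return("H3")
    if (any(el[onb] %in% c("O", "S"))) return("H4")
    b <- mol$bonds
    for (c_at in onb[el[onb] == "C"]) {
      dpart <- c(b[b[, 1] == c_at & b[, 3] == 2L, 2],
                 b[b[, 2] == c_at & b[, 3] == 2L, 1])
      if (any(el[dpart] %in% c("C", "N", "O", "S"))) return("H4")
    }
    return("H2")
  }
  "H2"
}
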