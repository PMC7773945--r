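# The six ligand descriptors (MASS, D, A, logP, MR, W) and the geometric
# quantity maxD that sizes the pocket-selection spheres.

#' Molecular weight
#'
#' Sum of standard atomic weights over all atoms, counting implicit
#' hydrogens inferred from standard valences when explicit hydrogens are
#' absent.
#'
#' @param mol A \code{molgraph}.
#' @return Molecular weight in g/mol.
#' @export
molecular_weight <- function(mol) {
  sum(atomic_weight(mol$elements)) +
    sum(implicit_hydrogens(mol)) * .ATOMIC_WEIGHTS[["H"]]
}

#' Hydrogen-bond donor and acceptor counts
#'
#' Donor atoms (not hydrogens) are counted: D = number of N or O atoms
#' carrying at least one hydrogen (explicit or implicit). A = number of N
#' or O atoms, excluding nitro-group nitrogens and oxygens and excluding
#' aromatic N that carries a hydrogen (pyrrole-type, whose lone pair is
#' part of the ring system).
#'
#' @param mol A \code{molgraph}.
#' @return Named integer vector c(D = ..., A = ...).
#' @examples
#' # ethanol: the hydroxyl O is both donor and acceptor
#' m <- molgraph(c("C", "C", "O"), bonds = rbind(c(1, 2, 1), c(2, 3, 1)))
#' hbond_counts(m)
#' @export
hbond_counts <- function(mol) {
  el <- mol$elements
  nH <- hydrogen_counts(mol)
  no <- which(el %in% c("N", "O"))
  if (!length(no)) return(c(D = 0L, A = 0L))
  nitro <- nitro_atoms(mol)
  D <- sum(nH[no] >= 1L & !(no %in% nitro))
  acc <- vapply(no, function(i) {
    if (i %in% nitro) return(FALSE)
    if (mol$aromatic[i] && el[i] == "N" && nH[i] >= 1L) return(FALSE)
    TRUE
  }, logical(1))
  c(D = as.integer(D), A = as.integer(sum(acc)))
}

# indices of N and O atoms belonging to nitro groups: N bonded to two O
# of which at least one by a double bond (covers charged and uncharged forms)
nitro_atoms <- function(mol) {
  el <- mol$elements
  nb <- mol_neighbors(mol)
  b <- mol$bonds
  out <- integer(0)
  for (i in which(el == "N")) {
    o_nb <- nb[[i]][el[nb[[i]]] == "O"]
    # only terminal oxygens (bonded to this N alone)
    o_nb <- o_nb[vapply(o_nb, function(o)
      sum(el[nb[[o]]] != "H") == 1L, logical(1))]
    if (length(o_nb) >= 2L) {
      has_dbl <- any(apply(b, 1, function(r)
        r[3] == 2L && ((r[1] == i && r[2] %in% o_nb) ||
                       (r[2] == i && r[1] %in% o_nb))))
      chg_pair <- mol$charges[i] > 0L && any(mol$charges[o_nb] < 0L)
      if (has_dbl || chg_pair) out <- c(out, i, o_nb)
    }
  }
  unique(out)
}

#' Wiener topological index
#'
#' Sum over unordered heavy-atom pairs of the shortest-path length in bond
#' counts; hydrogens are excluded. For a disconnected heavy-atom graph the
#' within-component sums are added and a warning is emitted.
#'
#' @param mol A \code{molgraph}.
#' @return Integer Wiener index.
#' @examples
#' butane <- molgraph(rep("C", 4), bonds = cbind(1:3, 2:4, 1))
#' wiener_index(butane)  # 10
#' @export
wiener_index <- function(mol) {
  g <- heavy_graph(mol)
  d <- igraph::distances(g)
  if (any(is.infinite(d))) {
    warning("disconnected heavy-atom graph: Wiener index summed within components")
    d[is.infinite(d)] <- 0
  }
  as.integer(round(sum(d) / 2))
}

#' Maximum atom distance from the centre of mass (maxD)
#'
#' The mass-weighted centre of mass is taken over all atoms present; maxD
#' is the largest Euclidean distance from any atom to it. maxD sets the
#' radius of the pocket-selection spheres.
#'
#' @param mol A \code{molgraph} with coordinates.
#' @return maxD in Angstrom.
#' @export
max_distance <- function(mol) {
  if (is.null(mol$coords)) stop("molecule has no coordinates")
  w <- atomic_weight(mol$elements)
  com <- colSums(mol$coords * w) / sum(w)
  sqrt(max(colSums((t(mol$coords) - com)^2)))
}

#' Mass-weighted centre of mass of a molecule
#' @param mol A \code{molgraph} with coordinates.
#' @return Numeric length-3 point in Angstrom.
#' @export
mol_center_of_mass <- function(mol) {
  if (is.null(mol$coords)) stop("molecule has no coordinates")
  w <- atomic_weight(mol$elements)
  colSums(mol$coords * w) / sum(w)
}

#' The six ligand descriptors
#'
#' MASS (g/mol), hydrogen-bond donor and acceptor atom counts (D, A),
#' Wildman-Crippen logP and molar refractivity (MR, cm^3/mol) and the
#' Wiener index (W). maxD is returned alongside (attribute of the pocket
#' geometry, not one of the six model features). Multi-component inputs
#' (salts) are reduced to their largest component first.
#'
#' @param mol A \code{molgraph}.
#' @param salt_strip Reduce to the largest heavy-atom component first
#'   (default TRUE).
#' @return Named numeric vector with elements MASS, D, A, logP, MR, W and
#'   maxD (NA when the molecule has no coordinates).
#' @export
ligand_descriptors <- function(mol, salt_strip = TRUE) {
  if (salt_strip) {
    g <- heavy_graph(mol)
    if (igraph::components(g)$no > 1L) mol <- largest_component(mol)
  }
  da <- hbond_counts(mol)
  cr <- crippen_contributions(mol)
  c(MASS = molecular_weight(mol),
    D = as.numeric(da[["D"]]), A = as.numeric(da[["A"]]),
    logP = cr$logP, MR = cr$MR,
    W = as.numeric(wiener_index(mol)),
    maxD = if (is.null(mol$coords)) NA_real_ else max_distance(mol))
}
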