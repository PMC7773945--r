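#' Molecular graph of a small molecule
#'
#' The substrate of all ligand descriptors: element symbols, optional 3D
#' coordinates, formal charges, aromaticity flags and a bond list. Bonds are
#' stored undirected (each pair once, i < j) with integer orders; order 4
#' denotes an aromatic bond as in SDF V2000.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric n x 3 matrix of coordinates in Angstrom, or NULL for
#'   a coordinate-free graph (all descriptors except maxD are coordinate-free).
#' @param bonds Integer matrix with columns i, j, order (1-based atom indices).
#' @param charges Integer vector of formal charges (default all 0).
#' @param aromatic Logical vector of per-atom aromaticity flags. If NULL,
#'   aromaticity is perceived from rings of the bond graph.
#' @param name Identifier string.
#' @return An object of class \code{molgraph}.
#' @examples
#' # ethanol, heavy atoms only
#' m <- molgraph(c("C", "C", "O"),
#'               coords = cbind(c(0, 1.5, 2.2), 0, 0),
#'               bonds = rbind(c(1, 2, 1), c(2, 3, 1)))
#' n_atoms(m)
#' @export
molgraph <- function(elements, coords = NULL, bonds = NULL, charges = NULL,
                     aromatic = NULL, name = "mol") {
  elements <- normalize_element(elements)
  n <- length(elements)
  if (n == 0L) stop("empty molecule")
  if (!any(elements != "H")) stop("molecule must contain at least one heavy atom")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("coords must be an n x 3 matrix")
    if (!all(is.finite(coords))) stop("coordinates must be finite")
    dimnames(coords) <- NULL
  }
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2) bonds <- cbind(bonds, 1L)
    storage.mode(bonds) <- "integer"
    if (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))
      stop("bond atom indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    # store each undirected bond once with i < j
    ij <- t(apply(bonds[, 1:2, drop = FALSE], 1, sort))
    bonds <- cbind(ij, bonds[, 3])
    bonds <- bonds[!duplicated(bonds[, 1:2, drop = FALSE]), , drop = FALSE]
  }
  colnames(bonds) <- c("i", "j", "order")
  if (is.null(charges)) charges <- integer(n)
  charges <- as.integer(charges)
  if (length(charges) != n) stop("charges length mismatch")
  m <- structure(
    list(elements = elements, coords = coords, bonds = bonds,
         charges = charges, aromatic = logical(n), name = as.character(name)),
    class = "molgraph")
  if (is.null(aromatic)) {
    m$aromatic <- perceive_aromaticity(m)
  } else {
    if (length(aromatic) != n) stop("aromatic length mismatch")
    m$aromatic <- as.logical(aromatic)
  }
  m
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s: %d atoms (%d heavy), %d bonds%s\n",
              x$name, n_atoms(x), sum(x$elements != "H"), nrow(x$bonds),
              if (is.null(x$coords)) ", no coordinates" else ""))
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param mol A \code{molgraph}.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

# adjacency list: integer indices of neighbours per atom
mol_neighbors <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b[k, 1]]] <- c(nb[[b[k, 1]]], b[k, 2])
    nb[[b[k, 2]]] <- c(nb[[b[k, 2]]], b[k, 1])
  }
  nb
}

# per-atom bond orders aligned with mol_neighbors(); aromatic order-4 bonds
# are counted as order 1.5 for valence purposes
mol_bond_orders <- function(mol) {
  n <- n_atoms(mol)
  bo <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    o <- b[k, 3]
    ov <- if (o == 4L) 1.5 else as.numeric(o)
    bo[[b[k, 1]]] <- c(bo[[b[k, 1]]], ov)
    bo[[b[k, 2]]] <- c(bo[[b[k, 2]]], ov)
  }
  bo
}

#' Implicit hydrogen counts
#'
#' Hydrogens implied by standard valences (C4, N3, O2, S2, P3, halogens 1)
#' for atoms without a full complement of explicit neighbours. Formal charge
#' adjusts the target valence by +charge for N and P and -|charge| for O and
#' S (so N+ carries 4 bonds, O- carries 1). Aromatic ring bonds count 1.5;
#' the per-ring-atom sum is rounded down before subtraction.
#'
#' @param mol A \code{molgraph}.
#' @return Integer vector of implicit H counts per atom.
#' @export
implicit_hydrogens <- function(mol) {
  bo <- mol_bond_orders(mol)
  n <- n_atoms(mol)
  out <- integer(n)
  for (i in seq_len(n)) {
    el <- mol$elements[i]
    if (el == "H") next
    v <- .STANDARD_VALENCES[el]
    if (is.na(v)) next                       # metals etc.: no implicit H
    ch <- mol$charges[i]
    if (el %in% c("N", "P")) v <- v + ch
    if (el %in% c("O", "S")) v <- v - abs(ch)
    used <- sum(bo[[i]])
    # aromatic atom with two 1.5 bonds has used 3; floor() keeps pyrrole N
    # (three ring/substituent bonds summing 4) from going negative
    out[i] <- max(0L, as.integer(v - floor(used + 1e-9)))
    # aromatic carbons in a ring carry exactly one H unless substituted
    if (mol$aromatic[i] && el == "C") out[i] <- min(out[i], 1L)
  }
  out
}

#' Total hydrogen count attached to each atom (explicit + implicit)
#' @param mol A \code{molgraph}.
#' @return Integer vector.
#' @export
hydrogen_counts <- function(mol) {
  nb <- mol_neighbors(mol)
  expl <- vapply(nb, function(v) sum(mol$elements[v] == "H"), integer(1))
  expl + implicit_hydrogens(mol)
}

#' Perceive aromatic rings
#'
#' A lightweight perception sufficient for drug-like molecules: a ring of
#' size 5 or 6 is marked aromatic when every ring atom is C, N, O or S and
#' each carbon either carries an explicit aromatic (order 4) ring bond or
#' participates in exactly one double bond, while heteroatoms may contribute
#' a lone pair (two single ring bonds, pyrrole/furan-like) or one double
#' bond (pyridine-like). Fused systems are handled ring by ring.
#'
#' @param mol A \code{molgraph} (aromatic flags ignored).
#' @return Logical per-atom vector.
#' @export
perceive_aromaticity <- function(mol) {
  n <- n_atoms(mol)
  out <- logical(n)
  b <- mol$bonds
  if (nrow(b) == 0L) return(out)
  # explicit aromatic bonds decide immediately
  ar4 <- b[b[, 3] == 4L, , drop = FALSE]
  out[unique(c(ar4[, 1], ar4[, 2]))] <- TRUE

  heavy <- which(mol$elements != "H")
  bh <- b[mol$elements[b[, 1]] != "H" & mol$elements[b[, 2]] != "H", ,
          drop = FALSE]
  if (nrow(bh) == 0L) return(out)
  g <- igraph::graph_from_edgelist(cbind(match(bh[, 1], heavy),
                                         match(bh[, 2], heavy)),
                                   directed = FALSE)
  # double-bond partner count per atom
  dbl <- b[b[, 3] == 2L, , drop = FALSE]
  ndbl <- tabulate(c(dbl[, 1], dbl[, 2]), nbins = n)

  rings <- find_rings(g, max_size = 6L)
  for (ring in rings) {
    ring_atoms <- heavy[ring]
    if (length(ring_atoms) < 5L) next
    ok <- TRUE
    for (a in ring_atoms) {
      el <- mol$elements[a]
      if (!(el %in% c("C", "N", "O", "S"))) { ok <- FALSE; break }
      if (el == "C") {
        if (ndbl[a] != 1L && !out[a]) { ok <- FALSE; break }
      } else if (el %in% c("O", "S")) {
        if (ndbl[a] != 0L) { ok <- FALSE; break }   # lone-pair donor only
      }
      # N: either pyridine-like (1 double) or pyrrole-like (0 doubles) - ok
    }
    if (ok) out[ring_atoms] <- TRUE
  }
  out
}

# minimal cycle basis up to max_size, as lists of vertex indices of g
find_rings <- function(g, max_size = 6L) {
  rings <- list()
  for (e in igraph::E(g)) {
    ends <- igraph::ends(g, e, names = FALSE)
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = ends[1], to = ends[2],
                             output = "vpath")$vpath[[1]])
    if (length(sp) >= 3L && length(sp) <= max_size) {
      v <- sort(as.integer(sp))
      key <- paste(v, collapse = "-")
      if (is.null(rings[[key]])) rings[[key]] <- as.integer(sp)
    }
  }
  unname(rings)
}

# heavy-atom subgraph as igraph, vertices in heavy-atom order
heavy_graph <- function(mol) {
  heavy <- which(mol$elements != "H")
  b <- mol$bonds
  bh <- b[b[, 1] %in% heavy & b[, 2] %in% heavy, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(bh)) {
    g <- igraph::add_edges(g, rbind(match(bh[, 1], heavy),
                                    match(bh[, 2], heavy)))
  }
  g
}

#' Largest connected component of the heavy-atom graph
#'
#' Salt-strip step: descriptors of multi-component inputs (e.g. salts) are
#' computed on the largest heavy-atom component; hydrogens attached to the
#' retained heavy atoms are kept. Ties broken by total atomic weight then by
#' lowest atom index.
#'
#' @param mol A \code{molgraph}.
#' @return A \code{molgraph} restricted to the largest component.
#' @export
largest_component <- function(mol) {
  heavy <- which(mol$elements != "H")
  g <- heavy_graph(mol)
  comp <- igraph::components(g)$membership
  sizes <- tapply(atomic_weight(mol$elements[heavy]), comp, sum)
  keep_comp <- as.integer(names(sizes)[which.max(sizes)])
  keep_heavy <- heavy[comp == keep_comp]
  nb <- mol_neighbors(mol)
  keep_h <- which(mol$elements == "H" &
                  vapply(nb, function(v) any(v %in% keep_heavy), logical(1)))
  keep <- sort(c(keep_heavy, keep_h))
  subset_molgraph(mol, keep)
}

subset_molgraph <- function(mol, keep) {
  idx <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds
  bk <- b[b[, 1] %in% keep & b[, 2] %in% keep, , drop = FALSE]
  bk[, 1] <- idx[bk[, 1]]; bk[, 2] <- idx[bk[, 2]]
  molgraph(mol$elements[keep],
           coords = if (is.null(mol$coords)) NULL else
             mol$coords[keep, , drop = FALSE],
           bonds = bk, charges = mol$charges[keep],
           aromatic = mol$aromatic[keep], name = mol$name)
}
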