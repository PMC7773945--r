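# Pocket selection and the 14 protein descriptors. The pocket is defined
# pose-invariantly: a sphere at an assumed binding-site centre whose radius
# derives from the query ligand's maxD alone. Residues contribute logP/MR
# sums (aromatic vs non-aromatic residues separately) when their centre of
# mass lies within maxD + 0.9 A; individual atoms contribute hydrogen-bond
# donor/acceptor counts within maxD + 3.0 A. All residue-derived values are
# scaled by 1/maxD; the grid-probe pocket volume (PVol) is reported
# unscaled.

#' Select the putative binding pocket
#'
#' Residues are selected when their (mass-weighted, present-atom) centre of
#' mass lies within maxD + \code{res_ext} of the centre; protein atoms for
#' donor/acceptor counting are selected within maxD + \code{atom_ext}.
#' Boundaries are inclusive. Hetero atoms are never part of the protein
#' selections but any hetero heavy atom (non-water) inside the residue
#' sphere raises a cofactor diagnostic flag.
#'
#' @param protein A \code{protstruct}.
#' @param center Numeric length-3 point (Angstrom).
#' @param maxD Ligand maxD in Angstrom (> 0).
#' @param res_ext,atom_ext Sphere extensions in Angstrom (defaults 0.9 and
#'   3.0).
#' @return An object of class \code{pocket_selection}: residue table with
#'   COM distances, atom table, the centre and radii, and a
#'   \code{cofactor} flag.
#' @export
select_pocket <- function(protein, center, maxD, res_ext = 0.9,
                          atom_ext = 3.0) {
  stopifnot(length(center) == 3, is.finite(center))
  if (!is.finite(maxD) || maxD <= 0) stop("maxD must be positive")
  a <- protein$atoms
  if (nrow(a) == 0L) stop("empty protein")
  pa <- a[!a$hetero & a$element != "H", , drop = FALSE]
  if (nrow(pa) == 0L) stop("protein has no polymer atoms")

  d <- sqrt((pa$x - center[1])^2 + (pa$y - center[2])^2 +
            (pa$z - center[3])^2)
  atoms_hb <- pa[d <= maxD + atom_ext, , drop = FALSE]

  key <- paste(pa$chain, pa$resno, pa$resid, sep = "|")
  w <- atomic_weight(pa$element)
  comx <- tapply(pa$x * w, key, sum) / tapply(w, key, sum)
  comy <- tapply(pa$y * w, key, sum) / tapply(w, key, sum)
  comz <- tapply(pa$z * w, key, sum) / tapply(w, key, sum)
  dres <- sqrt((comx - center[1])^2 + (comy - center[2])^2 +
               (comz - center[3])^2)
  sel <- names(dres)[dres <= maxD + res_ext]
  parts <- do.call(rbind, strsplit(sel, "|", fixed = TRUE))
  residues_com <- if (length(sel)) {
    data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
               resid = parts[, 3], com_dist = unname(dres[sel]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = character(0), resno = integer(0),
               resid = character(0), com_dist = numeric(0))
  }
  if (nrow(residues_com) == 0L && nrow(atoms_hb) == 0L)
    warning("empty pocket selection: all descriptors will be zero")

  het <- a[a$hetero & a$element != "H" &
           !(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  cof <- FALSE
  if (nrow(het)) {
    dh <- sqrt((het$x - center[1])^2 + (het$y - center[2])^2 +
               (het$z - center[3])^2)
    cof <- any(dh <= maxD + res_ext)
  }
  structure(list(center = as.numeric(center), maxD = maxD,
                 res_ext = res_ext, atom_ext = atom_ext,
                 residues_com = residues_com, atoms_hb = atoms_hb,
                 protein = protein, cofactor = cof),
            class = "pocket_selection")
}

#' @export
print.pocket_selection <- function(x, ...) {
  cat(sprintf("<pocket_selection> maxD %.2f A: %d residues (r <= %.2f), %d atoms (r <= %.2f)%s\n",
              x$maxD, nrow(x$residues_com), x$maxD + x$res_ext,
              nrow(x$atoms_hb), x$maxD + x$atom_ext,
              if (x$cofactor) " [cofactor in pocket]" else ""))
  invisible(x)
}

#' Raw residue-derived pocket values (pre-scaling)
#'
#' The 13 residue-derived quantities: Wildman-Crippen MR and logP sums over
#' pocket residues split into aromatic (PHE/TRP/TYR/HIS) and non-aromatic
#' residues, and the nine donor/acceptor group counts over pocket atoms per
#' the shipped mapping table. Residue types without a template contribute
#' only backbone counts (with a warning).
#'
#' @param selection A \code{pocket_selection}.
#' @return Named numeric vector of 13 values (unscaled).
#' @export
residue_group_descriptors <- function(selection) {
  out <- stats::setNames(numeric(13), setdiff(.POCKET_FEATURES, "PVol"))

  res <- selection$residues_com
  if (nrow(res)) {
    pa <- selection$protein$atoms
    pa <- pa[!pa$hetero & pa$element != "H", , drop = FALSE]
    unknown <- character(0)
    for (k in seq_len(nrow(res))) {
      tab <- residue_crippen(res$resid[k])
      atoms_k <- pa[pa$chain == res$chain[k] & pa$resno == res$resno[k] &
                    pa$resid == res$resid[k], , drop = FALSE]
      if (is.null(tab)) { unknown <- c(unknown, res$resid[k]); next }
      hit <- match(atoms_k$atom_name, tab$atom_name)
      lp <- sum(tab$logp[hit], na.rm = TRUE)
      mr <- sum(tab$mr[hit], na.rm = TRUE)
      if (res$resid[k] %in% .AROMATIC_RESIDUES) {
        out["PMR.Arom"] <- out["PMR.Arom"] + mr
        out["PlogP.Arom"] <- out["PlogP.Arom"] + lp
      } else {
        out["PMR.NonArom"] <- out["PMR.NonArom"] + mr
        out["PlogP.NonArom"] <- out["PlogP.NonArom"] + lp
      }
    }
    if (length(unknown))
      warning("no residue template for: ",
              paste(unique(unknown), collapse = ", "),
              " (backbone-only contribution)")
  }

  ah <- selection$atoms_hb
  if (nrow(ah)) {
    # backbone groups apply to every residue type; proline N has no H
    out["PD.AmideNH"] <- sum(ah$atom_name == "N" & ah$resid != "PRO")
    out["PA.AmideO"] <- sum(ah$atom_name == "O")
    map <- donor_acceptor_map()
    mk <- paste(map$resid, map$atom_name, sep = "|")
    ak <- paste(ah$resid, ah$atom_name, sep = "|")
    hit <- match(ak, mk)
    don <- map$donor_group[hit[!is.na(hit)]]
    acc <- map$acceptor_group[hit[!is.na(hit)]]
    for (g in setdiff(.DONOR_GROUPS, "PD.AmideNH"))
      out[g] <- sum(don == g, na.rm = TRUE)
    for (g in setdiff(.ACCEPTOR_GROUPS, "PA.AmideO"))
      out[g] <- sum(acc == g, na.rm = TRUE)
  }
  out
}

#' Grid-probe pocket volume
#'
#' Volume of the solvent-accessible part of the sphere of radius maxD
#' around the centre: grid points inside the sphere count when they lie
#' farther than (vdW radius + probe) from every protein heavy atom. A
#' documented stand-in for cavity-analysis tools; converges to analytic
#' values as the grid spacing shrinks.
#'
#' @param protein A \code{protstruct} (hetero atoms excluded).
#' @param center Length-3 centre (Angstrom).
#' @param maxD Sphere radius in Angstrom.
#' @param grid Grid spacing in Angstrom (default 0.5).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @return Volume in cubic Angstrom.
#' @export
pocket_volume <- function(protein, center, maxD, grid = 0.5, probe = 1.4) {
  if (!is.finite(grid) || grid <= 0) stop("grid spacing must be positive")
  if (!is.finite(maxD) || maxD <= 0) stop("maxD must be positive")
  ax <- seq(center[1] - maxD, center[1] + maxD, by = grid)
  ay <- seq(center[2] - maxD, center[2] + maxD, by = grid)
  az <- seq(center[3] - maxD, center[3] + maxD, by = grid)
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  r2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2
  pts <- pts[r2 <= maxD^2, , drop = FALSE]
  if (nrow(pts) == 0L) return(0)

  a <- protein$atoms
  a <- a[!a$hetero & a$element != "H", , drop = FALSE]
  if (nrow(a)) {
    rad <- vdw_radius(a$element) + probe
    # only atoms whose exclusion sphere can reach the pocket sphere
    da <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 +
               (a$z - center[3])^2)
    near <- which(da <= maxD + rad)
    free <- rep(TRUE, nrow(pts))
    for (k in near) {
      d2 <- (pts[, 1] - a$x[k])^2 + (pts[, 2] - a$y[k])^2 +
        (pts[, 3] - a$z[k])^2
      free <- free & d2 > rad[k]^2
      if (!any(free)) break
    }
    n_free <- sum(free)
  } else {
    n_free <- nrow(pts)
  }
  n_free * grid^3
}

#' The 14 pocket descriptors
#'
#' The 13 residue-derived values scaled by 1/maxD plus the unscaled pocket
#' volume PVol. Depends on the query ligand only through maxD and the
#' supplied centre (pose invariance).
#'
#' @param protein A \code{protstruct}.
#' @param center Length-3 binding-site centre (typically the reference
#'   ligand's centre of mass).
#' @param maxD Query ligand maxD in Angstrom.
#' @param res_ext,atom_ext Sphere extensions (0.9, 3.0 A).
#' @param grid,probe Pocket-volume grid spacing and probe radius.
#' @return Named numeric vector of 14 descriptors.
#' @export
pocket_descriptors <- function(protein, center, maxD, res_ext = 0.9,
                               atom_ext = 3.0, grid = 0.5, probe = 1.4) {
  sel <- select_pocket(protein, center, maxD, res_ext, atom_ext)
  raw <- residue_group_descriptors(sel)
  out <- c(raw / maxD,
           PVol = pocket_volume(protein, center, maxD, grid, probe))
  out[.POCKET_FEATURES]
}
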