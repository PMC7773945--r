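# Structure and affinity IO: PDB proteins via bio3d, ligands via
# ChemmineR/ChemmineOB, affinity tables as CSV, complex assembly and the
# metal-contact dataset filter.

#' Read a protein structure from a PDB file
#'
#' All ATOM records are kept; HETATM records are retained with a hetero
#' flag. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken alphabetically by altLoc id). Only the first
#' MODEL of a multi-model file is read.
#'
#' @param path Path to a PDB file.
#' @return An object of class \code{protstruct}: a list with an
#'   \code{atoms} data.frame (record, atom_name, element, x, y, z, resid,
#'   chain, resno, occupancy, hetero) and the source path.
#' @export
read_protein <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms in PDB file: ", path)
  # altLoc resolution: highest occupancy, ties alphabetical
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "|")
  occ <- ifelse(is.na(a$o), 1, a$o)
  alt <- ifelse(is.na(a$alt) | a$alt == "", " ", a$alt)
  ord <- order(key, -occ, alt)
  a <- a[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(as.integer(rownames(a))), , drop = FALSE]

  elem <- a$elesy
  missing_el <- is.na(elem) | elem == ""
  if (any(missing_el)) {
    # infer from the atom name: strip digits/primes, take leading letters
    nm <- gsub("[0-9']", "", a$elety[missing_el])
    elem[missing_el] <- substr(nm, 1, 1)
  }
  atoms <- data.frame(
    record = a$type,
    atom_name = a$elety,
    element = normalize_element(elem),
    x = a$x, y = a$y, z = a$z,
    resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in PDB file: ", path)
  structure(list(atoms = atoms, path = path), class = "protstruct")
}

#' @export
print.protstruct <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[!a$hetero, c("chain", "resno", "resid")]))
  cat(sprintf("<protstruct> %d atoms (%d hetero), %d residues, chains: %s\n",
              nrow(a), sum(a$hetero), nres,
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Write a protein structure to PDB
#' @param protein A \code{protstruct}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protein <- function(protein, path) {
  a <- protein$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(a[, c("x", "y", "z")])),
                   type = a$record, resno = a$resno, resid = a$resid,
                   chain = a$chain, elety = a$atom_name, o = a$occupancy,
                   elesy = toupper(a$element))
  invisible(path)
}

#' Residue table of a protein structure
#'
#' One row per (chain, resno, resid) among non-hetero residues.
#' @param protein A \code{protstruct}.
#' @return data.frame with columns chain, resno, resid.
#' @export
protein_residues <- function(protein) {
  a <- protein$atoms[!protein$atoms$hetero, , drop = FALSE]
  unique(a[, c("chain", "resno", "resid")])
}

# SDF charge codes (field 4 of the atom block) to formal charges
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

sdf_to_molgraph <- function(sdf, name = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) stop("empty molecule in SDF")
  elements <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  charges <- .SDF_CHARGE[as.character(ab[, "C6"])]
  charges[is.na(charges)] <- 0L
  bonds <- if (is.null(bb) || nrow(bb) == 0L) NULL else
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  if (is.null(name)) {
    name <- tryCatch(unname(ChemmineR::header(sdf)["Molecule_Name"]),
                     error = function(e) "mol")
    if (is.na(name) || !nzchar(name)) name <- "mol"
  }
  molgraph(elements, coords = coords, bonds = bonds, charges = charges,
           name = name)
}

#' Read ligand molecules
#'
#' @param path Path to an SDF, MOL2, PDB or SMILES file (one SMILES plus
#'   optional name per line). MOL2 and SMILES are converted through Open
#'   Babel (ChemmineOB); SMILES input is given a deterministic 3D embedding
#'   so that maxD is defined.
#' @param format One of "sdf", "mol2", "pdb", "smiles"; guessed from the
#'   file extension by default.
#' @return A list of \code{molgraph} objects.
#' @export
read_ligands <- function(path, format = c("auto", "sdf", "mol2", "pdb",
                                          "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     pdb = "pdb", smi = "smiles", smiles = "smiles",
                     txt = "smiles",
                     stop("cannot guess ligand format from extension: ", ext))
  }
  if (format == "sdf") {
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
    return(lapply(seq_along(sdfs), function(i) sdf_to_molgraph(sdfs[[i]])))
  }
  if (format == "mol2") {
    txt <- ChemmineOB::convertFormat("MOL2", "SDF",
                                     paste(readLines(path), collapse = "\n"))
    tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(tmp))
    writeLines(txt, tmp)
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    return(lapply(seq_along(sdfs), function(i) sdf_to_molgraph(sdfs[[i]])))
  }
  if (format == "pdb") {
    p <- read_protein(path)
    a <- p$atoms
    # a ligand PDB has no bond table; connectivity by distance is out of
    # scope here, so bonds are inferred through Open Babel
    txt <- ChemmineOB::convertFormat("PDB", "SDF",
                                     paste(readLines(path), collapse = "\n"))
    tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(tmp))
    writeLines(txt, tmp)
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    return(lapply(seq_along(sdfs), function(i) sdf_to_molgraph(sdfs[[i]])))
  }
  # SMILES
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) smiles_to_molgraph(ln))
}

#' Build a molecular graph from a SMILES string
#'
#' Conversion and 3D embedding go through Open Babel; the embedding is
#' deterministic for a given input, which makes maxD reproducible.
#'
#' @param smiles A SMILES string, optionally followed by a name.
#' @param gen3d Embed 3D coordinates (default TRUE; needed only for maxD
#'   and pocket selection).
#' @return A \code{molgraph}.
#' @export
smiles_to_molgraph <- function(smiles, gen3d = TRUE) {
  parts <- strsplit(trimws(smiles), "[ \t]+")[[1]]
  smi <- parts[1]
  nm <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else smi
  opts <- if (gen3d) data.frame(names = "gen3D", args = "") else NULL
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, " ", nm, "\n"),
                              options = opts),
    error = function(e) stop("SMILES conversion failed for '", smi, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!nzchar(txt)) stop("SMILES conversion produced no molecule: ", smi)
  tmp <- tempfile(fileext = ".sdf"); on.exit(unlink(tmp))
  writeLines(txt, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  sdf_to_molgraph(sdfs[[1]], name = nm)
}

#' Write ligands to an SDF (V2000) file
#' @param mols A \code{molgraph} or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ligands <- function(mols, path) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  con <- file(path, "w"); on.exit(close(con))
  for (m in mols) writeLines(molgraph_to_sdf_text(m), con)
  invisible(path)
}

molgraph_to_sdf_text <- function(mol) {
  n <- n_atoms(mol)
  co <- if (is.null(mol$coords)) matrix(0, n, 3) else mol$coords
  chg_code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L, `-1` = 5L,
                `-2` = 6L, `-3` = 7L)
  lines <- c(mol$name, " raspdplus", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n, nrow(mol$bonds)))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                              co[i, 1], co[i, 2], co[i, 3], mol$elements[i],
                              chg_code[as.character(mol$charges[i])]))
  }
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b[k, 1], b[k, 2],
                              b[k, 3]))
  }
  chg <- which(mol$charges != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, mol$charges[chg]),
                                    collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

#' Convert an experimental affinity to binding free energy
#'
#' dG = -R T ln(1/K) = R T ln K with R = 1.9872e-3 kcal/(mol K), so that a
#' dissociation-type constant of 1 M maps to 0 and stronger binders (small
#' K) get more negative dG. Dissociation constants, inhibition constants
#' and IC50 values are treated identically.
#'
#' @param value Affinity in molar units (must be > 0).
#' @param type One of "Kd", "Ki", "IC50" (informational; all treated alike).
#' @param temperature Temperature in Kelvin, default 298.15.
#' @return Binding free energy in kcal/mol.
#' @examples
#' affinity_to_dG(1e-9)   # a 1 nM binder, about -12.3 kcal/mol
#' @export
affinity_to_dG <- function(value, type = c("Kd", "Ki", "IC50"),
                           temperature = 298.15) {
  type <- match.arg(type)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("affinity value must be positive and finite")
  .R_KCAL * temperature * log(value)
}

.UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Read an affinity table
#'
#' CSV with columns id, value, unit (M, mM, uM, nM, pM) and type (Kd, Ki,
#' IC50). Values are converted to molar. When one id carries several
#' measurements, precedence is Kd > Ki > IC50, then the smallest value.
#'
#' @param path CSV path.
#' @param temperature Kelvin, for the dG conversion.
#' @return data.frame with columns id, K (molar), type, dG (kcal/mol).
#' @export
read_affinities <- function(path, temperature = 298.15) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "value", "unit", "type")
  if (!all(need %in% names(d)))
    stop("affinity table must have columns: ", paste(need, collapse = ", "))
  fac <- .UNIT_FACTORS[d$unit]
  if (anyNA(fac)) stop("unknown unit(s): ",
                       paste(unique(d$unit[is.na(fac)]), collapse = ", "))
  d$K <- d$value * fac
  pref <- match(d$type, c("Kd", "Ki", "IC50"))
  if (anyNA(pref)) stop("affinity type must be Kd, Ki or IC50")
  d <- d[order(d$id, pref, d$K), , drop = FALSE]
  d <- d[!duplicated(d$id), , drop = FALSE]
  d$dG <- vapply(seq_len(nrow(d)), function(i)
    affinity_to_dG(d$K[i], d$type[i], temperature), numeric(1))
  rownames(d) <- NULL
  d[, c("id", "K", "type", "dG")]
}

#' Metal-contact dataset filter
#'
#' Complexes whose ligand lies within \code{cutoff} of a metal ion are
#' excluded from training data, since metal coordination is not modelled by
#' the descriptors. Distances are between atom centres; the boundary is
#' exclusive (an atom at exactly the cutoff keeps the complex).
#'
#' @param protein A \code{protstruct}; metals are sought among its hetero
#'   atoms.
#' @param ligand A \code{molgraph} with coordinates (all ligand atoms are
#'   considered).
#' @param cutoff Distance cutoff in Angstrom (default 2.1).
#' @param metals Character vector of metal element symbols.
#' @return TRUE to keep the complex, FALSE to discard it.
#' @export
filter_metal_contacts <- function(protein, ligand, cutoff = 2.1,
                                  metals = .DEFAULT_METALS) {
  if (is.null(ligand$coords)) stop("ligand has no coordinates")
  a <- protein$atoms
  met <- a[a$hetero & a$element %in% metals, c("x", "y", "z"), drop = FALSE]
  if (nrow(met) == 0L) return(TRUE)
  lig <- ligand$coords
  for (k in seq_len(nrow(met))) {
    d2 <- (lig[, 1] - met[k, 1])^2 + (lig[, 2] - met[k, 2])^2 +
      (lig[, 3] - met[k, 3])^2
    if (any(d2 < cutoff^2)) return(FALSE)
  }
  TRUE
}

#' Assemble protein-ligand complex records
#'
#' Pairs each ligand with the protein, attaches dG from the affinity table
#' (matching on ligand name), and applies the metal-contact filter.
#'
#' @param protein A \code{protstruct}.
#' @param ligands List of \code{molgraph}s.
#' @param affinities Optional data.frame from \code{\link{read_affinities}}.
#' @param metal_cutoff Angstrom; set to 0 to disable the filter.
#' @param metals Metal element set.
#' @return List of complex records (protein, ligand, dG, id, kept flag).
#' @export
assemble_complexes <- function(protein, ligands, affinities = NULL,
                               metal_cutoff = 2.1,
                               metals = .DEFAULT_METALS) {
  lapply(ligands, function(lig) {
    dG <- NA_real_
    if (!is.null(affinities)) {
      hit <- match(lig$name, affinities$id)
      if (!is.na(hit)) dG <- affinities$dG[hit]
    }
    keep <- if (metal_cutoff > 0 && !is.null(lig$coords))
      filter_metal_contacts(protein, lig, metal_cutoff, metals) else TRUE
    list(protein = protein, ligand = lig, dG = dG, id = lig$name,
         kept = keep)
  })
}
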