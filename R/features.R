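# Assembly of the 20-feature table from complexes.

#' Feature vector for one protein-ligand complex
#'
#' The six ligand descriptors plus the 14 pocket descriptors computed at
#' the given binding-site centre with the ligand's own maxD. The centre
#' defaults to the ligand's centre of mass (training usage, where the
#' ligand is crystallographic); in screening, pass the reference centre.
#'
#' @param protein A \code{protstruct}.
#' @param ligand A \code{molgraph} with coordinates.
#' @param center Optional length-3 binding-site centre; default ligand COM.
#' @param ... Passed to \code{\link{pocket_descriptors}}.
#' @return Named numeric vector of 20 features.
#' @export
complex_features <- function(protein, ligand, center = NULL, ...) {
  ld <- ligand_descriptors(ligand)
  maxd <- ld[["maxD"]]
  if (is.na(maxd)) stop("ligand has no coordinates; maxD undefined")
  if (is.null(center)) center <- mol_center_of_mass(ligand)
  pd <- pocket_descriptors(protein, center, maxd, ...)
  c(ld[.LIGAND_FEATURES], pd)
}

#' Feature table from assembled complexes
#'
#' @param complexes List of complex records from
#'   \code{\link{assemble_complexes}}; records failing the metal filter are
#'   dropped.
#' @param ... Passed to \code{\link{complex_features}}.
#' @return data.frame with id, the 20 features and dG.
#' @export
feature_table <- function(complexes, ...) {
  complexes <- Filter(function(cx) isTRUE(cx$kept), complexes)
  if (!length(complexes)) stop("no complexes left after filtering")
  rows <- lapply(complexes, function(cx)
    c(complex_features(cx$protein, cx$ligand, ...), dG = cx$dG))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(id = vapply(complexes, `[[`, character(1), "id"), out)
  rownames(out) <- NULL
  out
}
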