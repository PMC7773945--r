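# Virtual screening: pose-invariant scoring of a ligand library against a
# fixed binding-site centre, enrichment factors, and union ensembles.

#' Score a ligand library against one binding site
#'
#' For each query ligand the six ligand descriptors are computed, then the
#' 14 pocket descriptors at the fixed centre using that ligand's own maxD,
#' and each fitted method's fold-model predictions (one replicate) are
#' averaged into a predicted dG. Lower (more negative) dG ranks better.
#' Featurization failures flag and skip the molecule rather than aborting
#' the screen.
#'
#' @param fit A \code{raspd} fit with stored models, trained on the
#'   standard 20-feature schema.
#' @param protein A \code{protstruct}.
#' @param ligands List of \code{molgraph}s with coordinates.
#' @param center Length-3 binding-site centre (e.g. the co-crystallised
#'   reference ligand's centre of mass via
#'   \code{\link{mol_center_of_mass}}).
#' @param methods Methods to score with (default: all fitted).
#' @param replicate Replicate whose fold models are averaged (default 1).
#' @param ... Passed to \code{\link{pocket_descriptors}}.
#' @return data.frame of class \code{screen_result}: id, ok flag, one
#'   predicted-dG column per method, and per-method rank columns
#'   (rank 1 = most negative dG).
#' @export
screen_library <- function(fit, protein, ligands, center,
                           methods = NULL, replicate = 1L, ...) {
  if (is.null(methods)) methods <- fit$methods
  ids <- vapply(ligands, function(m) m$name, character(1))
  feats <- lapply(ligands, function(lig) {
    tryCatch(complex_features(protein, lig, center = center, ...),
             error = function(e) {
               warning("featurization failed for '", lig$name, "': ",
                       conditionMessage(e))
               NULL
             })
  })
  ok <- !vapply(feats, is.null, logical(1))
  out <- data.frame(id = ids, ok = ok, stringsAsFactors = FALSE)
  Xok <- do.call(rbind, feats[ok])
  for (m in methods) {
    sc <- rep(NA_real_, length(ligands))
    if (any(ok))
      sc[ok] <- predict.raspd(fit, Xok, method = m, replicate = replicate)
    out[[paste0("dG_", m)]] <- sc
    rk <- rep(NA_integer_, length(ligands))
    rk[ok] <- rank(sc[ok], ties.method = "first")
    out[[paste0("rank_", m)]] <- rk
  }
  class(out) <- c("screen_result", class(out))
  out
}

#' Enrichment factor at a library fraction
#'
#' The top \code{ceiling(fraction/100 * n)} molecules by score (lower =
#' better, ties broken by stable id order) are selected; EF is the active
#' fraction in the selection divided by the active fraction in the whole
#' library.
#'
#' @param scores Numeric scores, lower is better (predicted dG).
#' @param actives Logical vector marking known actives.
#' @param fraction Selection percentage in (0, 100].
#' @param ids Optional molecule ids for the tie-break (default index
#'   order).
#' @return List of class \code{enrichment_result}: fraction, EF,
#'   n_selected, n_active_selected, n_total, n_active_total.
#' @examples
#' enrichment_factor(c(-9, -8, -7, -6), c(TRUE, TRUE, FALSE, FALSE), 50)
#' @export
enrichment_factor <- function(scores, actives, fraction, ids = NULL) {
  stopifnot(length(scores) == length(actives))
  if (fraction <= 0 || fraction > 100) stop("fraction must be in (0, 100]")
  n <- length(scores)
  n_act <- sum(actives)
  if (n_act == 0L) stop("no active molecules in the library")
  if (is.null(ids)) ids <- seq_len(n)
  n_sel <- ceiling(fraction / 100 * n)
  ord <- order(scores, ids)
  sel <- ord[seq_len(n_sel)]
  n_act_sel <- sum(actives[sel])
  structure(list(fraction = fraction,
                 EF = (n_act_sel / n_sel) / (n_act / n),
                 n_selected = n_sel, n_active_selected = n_act_sel,
                 n_total = n, n_active_total = n_act,
                 selected = sort(ids[sel])),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("EF(%g%%) = %.3f  [%d/%d actives in top %d of %d]\n",
              x$fraction, x$EF, x$n_active_selected, x$n_active_total,
              x$n_selected, x$n_total))
  invisible(x)
}

.UNION_PRESETS <- list(
  union = c("lr", "knn", "lsvr", "svr", "rf", "erf", "dnn"),
  union_wo_knn = c("lr", "lsvr", "svr", "rf", "erf", "dnn"),
  union_top3 = c("lr", "lsvr", "svr"))

#' Union ensemble selection and enrichment
#'
#' Takes the union of the per-method top-fraction sets and computes the
#' enrichment factor on the union (with n_selected = |union|). Presets:
#' "union" (all methods present), "union_wo_knn", and "union_top3"
#' ({lr, lsvr, svr}).
#'
#' @param result A \code{screen_result} from \code{\link{screen_library}}.
#' @param actives Logical vector aligned with \code{result$id} (or a
#'   character vector of active ids).
#' @param fraction Selection percentage per method.
#' @param methods Preset name or explicit character vector of methods.
#' @return List: the selected ids, per-method top sets, and an
#'   \code{enrichment_result} for the union.
#' @export
union_selection <- function(result, actives, fraction,
                            methods = "union") {
  score_cols <- grep("^dG_", names(result), value = TRUE)
  avail <- sub("^dG_", "", score_cols)
  if (is.character(methods) && length(methods) == 1L &&
      methods %in% names(.UNION_PRESETS))
    methods <- intersect(.UNION_PRESETS[[methods]], avail)
  if (!length(methods)) stop("no methods to combine")
  missing <- setdiff(methods, avail)
  if (length(missing)) stop("methods not in screen result: ",
                            paste(missing, collapse = ", "))
  if (is.character(actives)) actives <- result$id %in% actives
  ok <- result$ok
  ids <- result$id[ok]
  act <- actives[ok]
  n_sel <- ceiling(fraction / 100 * length(ids))
  tops <- lapply(methods, function(m) {
    sc <- result[[paste0("dG_", m)]][ok]
    ids[order(sc, ids)[seq_len(n_sel)]]
  })
  names(tops) <- methods
  sel <- sort(unique(unlist(tops)))
  n_act_sel <- sum(act[ids %in% sel])
  ef <- structure(list(fraction = fraction,
                       EF = (n_act_sel / length(sel)) /
                         (sum(act) / length(ids)),
                       n_selected = length(sel),
                       n_active_selected = n_act_sel,
                       n_total = length(ids), n_active_total = sum(act),
                       selected = sel),
                  class = "enrichment_result")
  list(selected = sel, per_method = tops, enrichment = ef)
}
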