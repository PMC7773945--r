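# End-to-end pipeline wiring: prepare -> featurize -> train -> importance
# -> screen -> enrich, with a materialised config echoed beside every run.

#' Default run configuration
#'
#' Every tunable of the pipeline with its default: sphere extensions
#' (0.9 / 3.0 A), metal cutoff (2.1 A), volume grid and probe, nested-CV
#' settings, hyperparameter grids, seed and ensemble preset.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(res_ext = 0.9, atom_ext = 3.0, metal_cutoff = 2.1,
       metals = .DEFAULT_METALS, grid = 0.5, probe = 1.4,
       methods = c("lr", "knn", "lsvr", "svr", "rf", "erf"),
       replicates = 10L, test_frac = 0.125, inner_folds = 6L,
       grids = default_grids(), seed = 1L, n_shuffles = 5L,
       ensemble = "union", fractions = c(1, 5, 10),
       qf3_variant = "consonni")
}

merge_config <- function(config) {
  base <- default_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

#' Run the full pipeline on one target
#'
#' Reads a protein, a ligand library and optionally affinities; filters
#' metal contacts; builds the 20-column feature table; trains the nested
#' cross-validation ensemble; computes permutation importances; and, when
#' a screening library is given, scores it and reports enrichment factors
#' for each preset fraction. All outputs (feature CSV, metric CSV,
#' importance CSV, ranks CSV, enrichment CSV, resolved config JSON) are
#' written into \code{out_dir}.
#'
#' @param protein_path PDB file of the target.
#' @param ligand_path Training ligand file (SDF/MOL2/SMILES).
#' @param affinity_path CSV of affinities (id, value, unit, type).
#' @param screen_path Optional library to screen.
#' @param actives Optional character vector (or file of ids, one per line)
#'   of known actives within the screening library.
#' @param out_dir Output directory (created).
#' @param config Partial configuration list; merged over
#'   \code{\link{default_config}}.
#' @return Invisibly, a list with the fit, feature table and screen/
#'   enrichment results.
#' @export
run_pipeline <- function(protein_path, ligand_path, affinity_path = NULL,
                         screen_path = NULL, actives = NULL,
                         out_dir = "raspd_run", config = list()) {
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg[setdiff(names(cfg), "grids")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  message("[prepare] reading structures")
  protein <- read_protein(protein_path)
  ligands <- read_ligands(ligand_path)
  aff <- if (!is.null(affinity_path)) read_affinities(affinity_path)
  cx <- assemble_complexes(protein, ligands, aff,
                           metal_cutoff = cfg$metal_cutoff,
                           metals = cfg$metals)
  message(sprintf("[prepare] %d complexes, %d kept by metal filter",
                  length(cx), sum(vapply(cx, `[[`, logical(1), "kept"))))

  message("[featurize] computing 20 descriptors per complex")
  tab <- feature_table(cx, res_ext = cfg$res_ext, atom_ext = cfg$atom_ext,
                       grid = cfg$grid, probe = cfg$probe)
  utils::write.csv(tab, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  fit <- NULL
  if (!all(is.na(tab$dG)) && nrow(tab) >= 48L) {
    message("[train] nested cross-validation")
    fit <- raspd(dG ~ . - id, tab, methods = cfg$methods,
                 replicates = cfg$replicates, test_frac = cfg$test_frac,
                 inner_folds = cfg$inner_folds, grids = cfg$grids,
                 seed = cfg$seed, qf3_variant = cfg$qf3_variant)
    utils::write.csv(fit$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)

    message("[importance] permutation importances on the test split")
    ti <- fit$reps[[1]]$test_idx
    best <- fit$metrics$method[which.min(fit$metrics$RMSE)]
    w <- fit$reps[[1]]$methods[[best]]$models[[1]]
    imp <- permutation_importance(w, tab[ti, fit$features], tab$dG[ti],
                                  n_shuffles = cfg$n_shuffles,
                                  seed = cfg$seed)
    utils::write.csv(imp, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
  }

  screen <- NULL; enrich <- NULL
  if (!is.null(screen_path) && !is.null(fit)) {
    message("[screen] scoring library")
    lib <- read_ligands(screen_path)
    center <- mol_center_of_mass(ligands[[1]])
    screen <- screen_library(fit, protein, lib, center,
                             res_ext = cfg$res_ext,
                             atom_ext = cfg$atom_ext, grid = cfg$grid,
                             probe = cfg$probe)
    utils::write.csv(screen, file.path(out_dir, "ranks.csv"),
                     row.names = FALSE)
    if (!is.null(actives)) {
      if (length(actives) == 1L && file.exists(actives))
        actives <- readLines(actives)
      enrich <- do.call(rbind, lapply(cfg$fractions, function(f) {
        u <- union_selection(screen, actives, f, methods = cfg$ensemble)
        data.frame(fraction = f, EF = u$enrichment$EF,
                   n_selected = u$enrichment$n_selected,
                   n_active_selected = u$enrichment$n_active_selected)
      }))
      utils::write.csv(enrich, file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE)
    }
  }
  message("[done] outputs in ", out_dir)
  invisible(list(config = cfg, features = tab, fit = fit, screen = screen,
                 enrichment = enrich))
}
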