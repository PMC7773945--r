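# Synthetic fixtures: a small library of hand-checkable ligand graphs, toy
# protein pockets built from idealised residue templates, and feature
# tables with planted statistical structure. Every expected value shipped
# alongside a fixture is computed by an independent brute-force path
# (breadth-first-search Wiener, hand-tabulated donor/acceptor counts,
# analytic volumes), never by the descriptor code under test.

#' Fixture ligand library
#'
#' About ten small molecules with known graphs and 3D coordinates chosen
#' so that Wiener, donor/acceptor and mass values are hand-checkable:
#' methane, ethanol, benzene, n-butane, cyclohexane, acetamide, an
#' aspirin-like fused fixture and three seeded random carbon trees.
#'
#' @param seed Seed for the random-tree members.
#' @return Named list of \code{molgraph}s.
#' @export
fixture_ligands <- function(seed = 11L) {
  hex <- function(r) cbind(r * cos(seq(0, 5) * pi / 3),
                           r * sin(seq(0, 5) * pi / 3), 0)
  out <- list(
    methane = molgraph("C", coords = matrix(0, 1, 3), name = "methane"),
    ethanol = molgraph(c("C", "C", "O"),
                       coords = rbind(c(0, 0, 0), c(1.52, 0, 0),
                                      c(2.0, 1.3, 0)),
                       bonds = rbind(c(1, 2, 1), c(2, 3, 1)),
                       name = "ethanol"),
    benzene = molgraph(rep("C", 6), coords = hex(1.39),
                       bonds = cbind(1:6, c(2:6, 1), 4L), name = "benzene"),
    butane = molgraph(rep("C", 4),
                      coords = cbind((0:3) * 1.3, c(0, 0.8, 0, 0.8), 0),
                      bonds = cbind(1:3, 2:4, 1L), name = "butane"),
    cyclohexane = molgraph(rep("C", 6), coords = hex(1.53),
                           bonds = cbind(1:6, c(2:6, 1), 1L),
                           name = "cyclohexane"),
    acetamide = molgraph(c("C", "C", "O", "N"),
                         coords = rbind(c(0, 0, 0), c(1.5, 0, 0),
                                        c(2.1, 1.05, 0), c(2.2, -1.2, 0)),
                         bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
                         name = "acetamide"),
    # aspirin-like fused fixture: salicylate ester skeleton, heavy atoms
    aspirin = molgraph(
      c(rep("C", 6), "C", "O", "O", "O", "C", "O", "C"),
      coords = rbind(hex(1.39),
                     c(2.78, 0, 0),       # carboxyl C on ring atom 1
                     c(3.4, 1.1, 0),      # =O
                     c(3.4, -1.1, 0),     # -OH
                     c(0.7, 2.4, 0),      # ester O on ring atom 2
                     c(1.4, 3.6, 0),      # ester carbonyl C
                     c(2.6, 3.7, 0),      # =O
                     c(0.6, 4.85, 0)),    # methyl
      bonds = rbind(cbind(1:6, c(2:6, 1), 4L),
                    c(1, 7, 1), c(7, 8, 2), c(7, 9, 1),
                    c(2, 10, 1), c(10, 11, 1), c(11, 12, 2), c(11, 13, 1)),
      name = "aspirin")
  )
  set.seed(seed)
  for (k in 1:3) {
    n <- sample(5:9, 1)
    # random tree: node i attaches to a uniform earlier node
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1),
                           integer(1)))
    out[[paste0("tree", k)]] <- molgraph(
      rep("C", n), coords = matrix(stats::rnorm(n * 3, sd = 2), n, 3),
      bonds = cbind(2:n, parent[-1], 1L), name = paste0("tree", k))
  }
  out
}

# Independent oracle: Wiener index by brute-force breadth-first search over
# the heavy-atom adjacency (no igraph).
bfs_wiener <- function(mol) {
  heavy <- which(mol$elements != "H")
  nb <- mol_neighbors(mol)
  total <- 0L
  for (s in heavy) {
    dist <- rep(-1L, n_atoms(mol)); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (mol$elements[w] != "H" && dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    total <- total + sum(dist[heavy][dist[heavy] > 0L])
  }
  as.integer(total / 2L)
}

# Idealised residue coordinate templates for toy pockets (backbone + side
# chain, heavy atoms; origin near the residue centroid). Crude but
# clash-free geometry with ~1.4-1.5 A bonds.
.RESIDUE_XYZ <- list(
  GLY = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0)),
  ALA = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06)),
  SER = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06), OG = c(0.10, -2.26, -0.84)),
  ASP = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06), CG = c(0.05, -2.36, -0.86),
              OD1 = c(-1.11, -2.60, -0.50), OD2 = c(0.86, -3.28, -1.05)),
  ASN = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06), CG = c(0.05, -2.36, -0.86),
              OD1 = c(-1.11, -2.60, -0.50), ND2 = c(0.86, -3.32, -1.10)),
  LYS = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06), CG = c(0.05, -2.38, -0.85),
              CD = c(0.67, -3.34, -1.86), CE = c(0.21, -4.77, -1.65),
              NZ = c(0.82, -5.71, -2.63)),
  PHE = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06), CG = c(0.05, -2.36, -0.90),
              CD1 = c(-1.19, -2.76, -1.38), CD2 = c(0.85, -3.30, -0.26),
              CE1 = c(-1.62, -4.08, -1.25), CE2 = c(0.43, -4.62, -0.13),
              CZ = c(-0.81, -5.01, -0.62)),
  HIS = rbind(N = c(-1.46, 0.00, 0), CA = c(0.00, 0.00, 0),
              C = c(0.73, 1.27, 0), O = c(1.96, 1.27, 0),
              CB = c(0.51, -0.94, -1.06), CG = c(0.05, -2.33, -0.89),
              ND1 = c(-1.17, -2.83, -1.17), CD2 = c(0.78, -3.41, -0.46),
              CE1 = c(-1.26, -4.14, -0.99), NE2 = c(-0.08, -4.56, -0.51))
)

# Hand-tabulated donor/acceptor group expectations per residue (within the
# atom sphere): independent of donor_acceptor_map().
.RESIDUE_DA_EXPECT <- list(
  GLY = c(PD.AmideNH = 1, PA.AmideO = 1),
  ALA = c(PD.AmideNH = 1, PA.AmideO = 1),
  SER = c(PD.AmideNH = 1, PA.AmideO = 1, PD.TSYDE = 1, PA.NQTSDHEH = 1),
  ASP = c(PD.AmideNH = 1, PA.AmideO = 1, PA.DE = 2),
  ASN = c(PD.AmideNH = 1, PA.AmideO = 1, PD.KNQ = 1, PA.NQTSDHEH = 1),
  LYS = c(PD.AmideNH = 1, PA.AmideO = 1, PD.KRHIP = 1),
  PHE = c(PD.AmideNH = 1, PA.AmideO = 1),
  HIS = c(PD.AmideNH = 1, PA.AmideO = 1, PD.WH = 1, PA.YH = 1)
)

random_rotation <- function() {
  # QR-based uniform random rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a toy protein-ligand complex with known descriptor expectations
#'
#' Places idealised residue templates so that each residue's heavy-atom
#' centre of mass sits at a stated distance from the pocket centre (the
#' origin), in seeded random orientations, and pairs them with a fixture
#' ligand. The returned expectations are computed by independent
#' brute-force oracles: BFS Wiener index, hand-tabulated donor/acceptor
#' counts, and the analytic sphere volume when the pocket is empty.
#'
#' @param ligand Name of a \code{\link{fixture_ligands}} member.
#' @param recipe data.frame with columns resid (residue type) and
#'   com_dist (Angstrom from the centre); may have zero rows.
#' @param seed Integer seed controlling orientations and placement
#'   directions.
#' @param out_dir If non-NULL, a PDB (pocket) and SDF (ligand) file pair
#'   is written there.
#' @param clash_tol Minimum allowed distance between atoms of different
#'   residues (error below it).
#' @return List: protein (\code{protstruct}), ligand (\code{molgraph}),
#'   center, expected (list of expected descriptor values), paths.
#' @export
make_toy_complex <- function(ligand = "ethanol",
                             recipe = data.frame(resid = "GLY",
                                                 com_dist = 5),
                             seed = 11L, out_dir = NULL, clash_tol = 1.5) {
  lig <- fixture_ligands(seed)[[ligand]]
  if (is.null(lig)) stop("unknown fixture ligand: ", ligand)
  set.seed(seed)

  atoms <- NULL
  if (nrow(recipe)) {
    # well-spread fixed directions, randomly rotated as a whole
    base_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1),
                       c(1, 1, 1) / sqrt(3), c(-1, -1, 1) / sqrt(3))
    if (nrow(recipe) > nrow(base_dirs))
      stop("at most ", nrow(base_dirs), " residues per toy pocket")
    dirs <- base_dirs[seq_len(nrow(recipe)), , drop = FALSE] %*%
      random_rotation()
    for (k in seq_len(nrow(recipe))) {
      rn <- toupper(recipe$resid[k])
      xyz <- .RESIDUE_XYZ[[rn]]
      if (is.null(xyz)) stop("no coordinate template for residue ", rn)
      el <- normalize_element(ifelse(substr(rownames(xyz), 1, 1) %in%
                                       c("N", "O", "S"),
                                     substr(rownames(xyz), 1, 1), "C"))
      w <- atomic_weight(el)
      # try orientations until the residue sits clash-free
      placed <- NULL
      for (try in 1:50) {
        rot <- random_rotation()
        xyzr <- xyz %*% rot
        com <- colSums(xyzr * w) / sum(w)
        cand <- sweep(xyzr, 2, com) +
          matrix(rep(dirs[k, ] * recipe$com_dist[k], each = nrow(xyz)),
                 ncol = 3)
        if (is.null(atoms) || nrow(atoms) == 0L) { placed <- cand; break }
        prev <- as.matrix(atoms[, c("x", "y", "z")])
        d2 <- outer(rowSums(cand^2), rowSums(prev^2), "+") -
          2 * cand %*% t(prev)
        dmin <- sqrt(max(0, min(d2)))
        if (dmin >= clash_tol) { placed <- cand; break }
      }
      if (is.null(placed))
        stop("infeasible geometry: inter-residue clash below ", clash_tol,
             " A for residue ", k, " (", rn, ")")
      atoms <- rbind(atoms, data.frame(
        record = "ATOM", atom_name = rownames(xyz), element = el,
        x = placed[, 1], y = placed[, 2], z = placed[, 3],
        resid = rn, chain = "A", resno = k, occupancy = 1, hetero = FALSE,
        stringsAsFactors = FALSE))
    }
  } else {
    atoms <- data.frame(record = character(0), atom_name = character(0),
                        element = character(0), x = numeric(0),
                        y = numeric(0), z = numeric(0), resid = character(0),
                        chain = character(0), resno = integer(0),
                        occupancy = numeric(0), hetero = logical(0))
  }
  protein <- structure(list(atoms = atoms, path = NA_character_),
                       class = "protstruct")

  # ---- expectations by independent oracles ----
  w <- atomic_weight(lig$elements)
  com <- colSums(lig$coords * w) / sum(w)
  maxd <- sqrt(max(rowSums(sweep(lig$coords, 2, com)^2)))
  da_exp <- stats::setNames(numeric(9), c(.DONOR_GROUPS, .ACCEPTOR_GROUPS))
  if (nrow(recipe)) {
    for (k in seq_len(nrow(recipe))) {
      e <- .RESIDUE_DA_EXPECT[[toupper(recipe$resid[k])]]
      # atoms count within maxD + 3; residue COM at com_dist, template
      # extent < 5 A, so only include when the whole residue is inside
      if (recipe$com_dist[k] + 5 <= maxd + 3)
        da_exp[names(e)] <- da_exp[names(e)] + e
    }
  }
  expected <- list(
    ligand_mass = sum(atomic_weight(lig$elements)) +
      sum(implicit_hydrogens(lig)) * 1.008,
    wiener = bfs_wiener(lig),
    maxD = maxd,
    donor_acceptor_raw_lower_bound = da_exp,
    empty_pocket_volume = if (nrow(recipe) == 0L)
      4 / 3 * pi * maxd^3 else NA_real_)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ppath <- file.path(out_dir, paste0("pocket_", seed, ".pdb"))
    lpath <- file.path(out_dir, paste0(lig$name, "_", seed, ".sdf"))
    if (nrow(atoms)) write_protein(protein, ppath) else
      writeLines("END", ppath)
    write_ligands(lig, lpath)
    paths <- c(protein = ppath, ligand = lpath)
  }
  list(protein = protein, ligand = lig, center = c(0, 0, 0),
       expected = expected, paths = paths)
}

#' Synthetic feature table with planted signal
#'
#' Generates \code{n} rows on the exact 20-feature schema with plausible
#' marginal ranges (positive counts, logP/MR scales), a linear target
#' with optional interaction terms, and Gaussian noise:
#' dG = intercept + Z beta + interactions + eps, where Z holds centred and
#' scaled features so beta is expressed in effect per standard deviation.
#'
#' @param n Number of rows (>= 48).
#' @param beta Named numeric vector of coefficients over feature names;
#'   default places moderate weight on MR, MASS, PA.AmideO, PlogP.NonArom
#'   (mirroring which features carry signal in real data).
#' @param interactions List of list(features = c(f1, f2), coef = x) terms
#'   applied to the scaled features.
#' @param noise_sd Noise standard deviation in kcal/mol (default 1).
#' @param intercept Mean dG (default -7).
#' @param scaled If FALSE, beta applies to raw feature columns instead of
#'   scaled ones (useful for exact linear-recovery tests).
#' @param seed Integer seed.
#' @return List: table (data.frame id + 20 features + dG), beta,
#'   interactions, noise_sd.
#' @export
make_feature_table <- function(n = 600L, beta = NULL, interactions = list(),
                               noise_sd = 1, intercept = -7,
                               scaled = TRUE, seed = 1L) {
  if (n < 48L) stop("n must be at least 48")
  set.seed(seed)
  mass <- stats::rlnorm(n, log(350), 0.35)
  X <- data.frame(
    MASS = mass,
    D = stats::rpois(n, 2),
    A = stats::rpois(n, 4),
    logP = stats::rnorm(n, 2.5, 1.5),
    MR = mass / 3.6 + stats::rnorm(n, 0, 8),
    W = round(mass^1.35 / 3 + stats::rnorm(n, 0, 150)),
    PMR.Arom = stats::rgamma(n, 2, rate = 0.25),
    PMR.NonArom = stats::rgamma(n, 8, rate = 0.4),
    PlogP.Arom = stats::rnorm(n, 1.5, 0.8),
    PlogP.NonArom = stats::rnorm(n, -1, 1.2),
    PD.AmideNH = stats::rgamma(n, 4, rate = 2),
    PD.KRHIP = stats::rgamma(n, 1.5, rate = 3),
    PD.KNQ = stats::rgamma(n, 1.5, rate = 3),
    PD.WH = stats::rgamma(n, 1, rate = 4),
    PD.TSYDE = stats::rgamma(n, 2, rate = 3),
    PA.AmideO = stats::rgamma(n, 4, rate = 2),
    PA.DE = stats::rgamma(n, 1.5, rate = 3),
    PA.NQTSDHEH = stats::rgamma(n, 2, rate = 3),
    PA.YH = stats::rgamma(n, 1, rate = 4),
    PVol = stats::runif(n, 150, 1500))
  X$W <- pmax(X$W, 1)
  if (is.null(beta))
    beta <- c(MR = -1.2, MASS = -0.4, PA.AmideO = -0.8,
              PlogP.NonArom = -0.5)
  bad <- setdiff(names(beta), names(X))
  if (length(bad)) stop("unknown feature(s) in beta: ",
                        paste(bad, collapse = ", "))
  Z <- if (scaled) scale(as.matrix(X)) else as.matrix(X)
  y <- rep(intercept, n)
  y <- y + drop(Z[, names(beta), drop = FALSE] %*% beta)
  for (it in interactions) {
    f <- it$features
    if (!all(f %in% names(X))) stop("unknown interaction feature(s)")
    y <- y + it$coef * Z[, f[1]] * Z[, f[2]]
  }
  y <- y + stats::rnorm(n, 0, noise_sd)
  tab <- cbind(data.frame(id = sprintf("syn%04d", seq_len(n)),
                          stringsAsFactors = FALSE), X, dG = y)
  list(table = tab, beta = beta, interactions = interactions,
       noise_sd = noise_sd)
}
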