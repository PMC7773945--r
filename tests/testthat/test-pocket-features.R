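# Single-atom "residues" let the selection boundaries be placed exactly.
atom_row <- function(name, el, pos, resid, resno) {
  data.frame(record = "ATOM", atom_name = name, element = el,
             x = pos[1], y = pos[2], z = pos[3], resid = resid,
             resno = resno, stringsAsFactors = FALSE)
}

test_that("sphere boundaries select residues by COM and atoms independently", {
  maxd <- 5
  p <- protstruct_from_atoms(rbind(
    atom_row("N", "N", c(maxd + 0.5, 0, 0), "GLY", 1),   # inside res sphere
    atom_row("N", "N", c(0, maxd + 1.0, 0), "GLY", 2),   # outside res, in atom
    atom_row("N", "N", c(0, 0, maxd + 3.1), "GLY", 3)))  # outside both
  sel <- select_pocket(p, c(0, 0, 0), maxd)
  expect_equal(sel$residues_com$resno, 1L)
  expect_setequal(sel$atoms_hb$resno, c(1L, 2L))
})

test_that("boundaries are inclusive and selections grow monotonically with maxD", {
  p <- protstruct_from_atoms(rbind(
    atom_row("N", "N", c(5.9, 0, 0), "GLY", 1),
    atom_row("N", "N", c(8.0, 0, 0), "GLY", 2)))
  sel <- select_pocket(p, c(0, 0, 0), 5)
  # residue sphere radius is exactly 5.9: the boundary residue is kept
  expect_equal(sel$residues_com$resno, 1L)
  # atom sphere radius is exactly 8.0: the boundary atom is kept too
  expect_setequal(sel$atoms_hb$resno, c(1L, 2L))
  # growing maxD never drops anything
  prev_res <- integer(0); prev_at <- integer(0)
  for (md in c(2, 4, 6, 8, 10)) {
    s <- suppressWarnings(select_pocket(p, c(0, 0, 0), md))
    expect_true(all(prev_res %in% s$residues_com$resno))
    expect_true(all(prev_at %in% s$atoms_hb$resno))
    prev_res <- s$residues_com$resno; prev_at <- s$atoms_hb$resno
  }
})

test_that("a lone glycine contributes only backbone donor/acceptor counts", {
  tc <- make_toy_complex("aspirin", data.frame(resid = "GLY", com_dist = 2),
                         seed = 3)
  sel <- select_pocket(tc$protein, tc$center, max_distance(tc$ligand))
  raw <- residue_group_descriptors(sel)
  expect_equal(raw[["PD.AmideNH"]], 1)
  expect_equal(raw[["PA.AmideO"]], 1)
  side <- setdiff(names(raw), c("PD.AmideNH", "PA.AmideO", "PMR.NonArom",
                                "PlogP.NonArom"))
  expect_true(all(raw[side] == 0))
  expect_true(raw[["PMR.NonArom"]] > 0)   # glycine is non-aromatic
  expect_equal(raw[["PMR.Arom"]], 0)
})

test_that("an aspartate pocket counts two carboxylate acceptors", {
  tc <- make_toy_complex("aspirin", data.frame(resid = "ASP", com_dist = 2),
                         seed = 5)
  sel <- select_pocket(tc$protein, tc$center, max_distance(tc$ligand))
  raw <- residue_group_descriptors(sel)
  expect_equal(raw[["PA.DE"]], 2)
  expect_equal(raw[["PA.AmideO"]], 1)
  expect_equal(raw[["PD.AmideNH"]], 1)
  expect_equal(raw[["PD.TSYDE"]], 0)
})

test_that("histidine and serine map to heteroaromatic and hydroxyl groups", {
  tc <- make_toy_complex("aspirin",
                         data.frame(resid = c("HIS", "SER"),
                                    com_dist = c(2, 3)), seed = 8)
  sel <- select_pocket(tc$protein, tc$center, max_distance(tc$ligand))
  raw <- residue_group_descriptors(sel)
  expect_equal(raw[["PD.WH"]], 1)        # His NE2
  expect_equal(raw[["PA.YH"]], 1)        # His ND1
  expect_equal(raw[["PD.TSYDE"]], 1)     # Ser OG donates
  expect_equal(raw[["PA.NQTSDHEH"]], 1)  # Ser OG accepts
  expect_true(raw[["PMR.Arom"]] > 0)     # His counts as aromatic residue
})

test_that("empty selections give zero descriptors with a warning", {
  p <- protstruct_from_atoms(atom_row("N", "N", c(50, 0, 0), "GLY", 1))
  expect_warning(sel <- select_pocket(p, c(0, 0, 0), 3), "empty")
  raw <- residue_group_descriptors(sel)
  expect_true(all(raw == 0))
})

test_that("unknown residue types contribute backbone counts only, with warning", {
  p <- protstruct_from_atoms(rbind(
    atom_row("N", "N", c(2, 0, 0), "XYZ", 1),
    atom_row("O", "O", c(0, 2, 0), "XYZ", 1)))
  sel <- select_pocket(p, c(0, 0, 0), 5)
  expect_warning(raw <- residue_group_descriptors(sel), "template")
  expect_equal(raw[["PD.AmideNH"]], 1)
  expect_equal(raw[["PA.AmideO"]], 1)
  expect_equal(raw[["PMR.NonArom"]], 0)
})

test_that("donor and acceptor groups are disjoint within each family", {
  map <- donor_acceptor_map()
  key <- paste(map$resid, map$atom_name)
  expect_false(any(duplicated(key)))   # one row per atom: one group/family
  expect_true(all(is.na(map$donor_group) |
                  map$donor_group %in% c("PD.KRHIP", "PD.KNQ", "PD.WH",
                                         "PD.TSYDE")))
  expect_true(all(is.na(map$acceptor_group) |
                  map$acceptor_group %in% c("PA.DE", "PA.NQTSDHEH",
                                            "PA.YH")))
})

test_that("pocket volume approaches analytic values", {
  empty <- protstruct_from_atoms(atom_row("N", "N", c(100, 0, 0), "GLY", 1))
  r <- 5
  v <- pocket_volume(empty, c(0, 0, 0), r, grid = 0.25)
  expect_equal(v, 4 / 3 * pi * r^3, tolerance = 0.02)

  # wall of atoms whose exclusion zone fills the z < 0 half-space
  xy <- expand.grid(x = seq(-9, 9, by = 1), y = seq(-9, 9, by = 1))
  rad <- vdw <- 1.55 + 1.4   # N vdW + probe
  wall <- protstruct_from_atoms(data.frame(
    record = "ATOM", atom_name = "N", element = "N",
    x = xy$x, y = xy$y, z = -rad, resid = "GLY", resno = seq_len(nrow(xy)),
    stringsAsFactors = FALSE))
  vh <- pocket_volume(wall, c(0, 0, 0), r, grid = 0.25)
  expect_equal(vh, 0.5 * 4 / 3 * pi * r^3, tolerance = 0.05)

  # dense slab everywhere: essentially no free volume
  xyz <- expand.grid(x = seq(-6, 6, 2), y = seq(-6, 6, 2), z = seq(-6, 6, 2))
  slab <- protstruct_from_atoms(data.frame(
    record = "ATOM", atom_name = "N", element = "N",
    x = xyz$x, y = xyz$y, z = xyz$z, resid = "GLY",
    resno = seq_len(nrow(xyz)), stringsAsFactors = FALSE))
  expect_lt(pocket_volume(slab, c(0, 0, 0), r, grid = 0.5),
            0.02 * 4 / 3 * pi * r^3)
  expect_error(pocket_volume(empty, c(0, 0, 0), r, grid = 0))
})

test_that("halving the volume grid changes the estimate by less than 5%", {
  tc <- make_toy_complex("aspirin",
                         data.frame(resid = c("GLY", "PHE"),
                                    com_dist = c(2.5, 3.5)), seed = 9)
  v1 <- pocket_volume(tc$protein, tc$center, 6, grid = 0.5)
  v2 <- pocket_volume(tc$protein, tc$center, 6, grid = 0.25)
  expect_lt(abs(v1 - v2) / v2, 0.05)
})

test_that("the descriptor vector has 14 entries scaled by 1/maxD, PVol unscaled", {
  tc <- make_toy_complex("aspirin", data.frame(resid = "GLY", com_dist = 2),
                         seed = 3)
  md <- max_distance(tc$ligand)
  pd <- pocket_descriptors(tc$protein, tc$center, md)
  expect_length(pd, 14)
  expect_named(pd, c("PMR.Arom", "PMR.NonArom", "PlogP.Arom",
                     "PlogP.NonArom", "PD.AmideNH", "PD.KRHIP", "PD.KNQ",
                     "PD.WH", "PD.TSYDE", "PA.AmideO", "PA.DE",
                     "PA.NQTSDHEH", "PA.YH", "PVol"))
  raw <- residue_group_descriptors(
    select_pocket(tc$protein, tc$center, md))
  expect_equal(pd[["PD.AmideNH"]], raw[["PD.AmideNH"]] / md)
  expect_equal(pd[["PMR.NonArom"]], raw[["PMR.NonArom"]] / md)
})

test_that("doubling maxD in an empty environment scales PVol by 8", {
  empty <- protstruct_from_atoms(atom_row("N", "N", c(100, 0, 0), "GLY", 1))
  pd1 <- suppressWarnings(pocket_descriptors(empty, c(0, 0, 0), 4,
                                             grid = 0.25))
  pd2 <- suppressWarnings(pocket_descriptors(empty, c(0, 0, 0), 8,
                                             grid = 0.25))
  counts <- setdiff(names(pd1), "PVol")
  expect_true(all(pd1[counts] == 0) && all(pd2[counts] == 0))
  expect_equal(pd2[["PVol"]] / pd1[["PVol"]], 8, tolerance = 0.03)
})

test_that("pocket descriptors are pose invariant given equal maxD", {
  tc <- make_toy_complex("butane",
                         data.frame(resid = c("GLY", "ASP"),
                                    com_dist = c(2, 3)), seed = 13)
  lig1 <- tc$ligand
  # a rigidly rotated "conformer": same graph, same maxD, different pose
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  lig2 <- lig1
  lig2$coords <- lig1$coords %*% R + 0.5
  expect_equal(max_distance(lig1), max_distance(lig2), tolerance = 1e-9)
  f1 <- complex_features(tc$protein, lig1, center = tc$center)
  f2 <- complex_features(tc$protein, lig2, center = tc$center)
  pocket_cols <- c("PMR.Arom", "PMR.NonArom", "PlogP.Arom", "PlogP.NonArom",
                   "PD.AmideNH", "PD.KRHIP", "PD.KNQ", "PD.WH", "PD.TSYDE",
                   "PA.AmideO", "PA.DE", "PA.NQTSDHEH", "PA.YH", "PVol")
  expect_equal(f1[pocket_cols], f2[pocket_cols], tolerance = 1e-9)
})

test_that("joint translation of protein and centre leaves descriptors unchanged", {
  tc <- make_toy_complex("aspirin", data.frame(resid = "ASN", com_dist = 2),
                         seed = 21)
  md <- max_distance(tc$ligand)
  pd <- pocket_descriptors(tc$protein, tc$center, md)
  shift <- c(11, -7, 3)
  p2 <- tc$protein
  p2$atoms$x <- p2$atoms$x + shift[1]
  p2$atoms$y <- p2$atoms$y + shift[2]
  p2$atoms$z <- p2$atoms$z + shift[3]
  pd2 <- pocket_descriptors(p2, tc$center + shift, md)
  expect_equal(pd2, pd, tolerance = 1e-9)
})
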