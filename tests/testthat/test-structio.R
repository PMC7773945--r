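test_that("PDB reading keeps all atoms and round-trips through write", {
  f <- write_pdb_fixture()
  p <- read_protein(f)
  expect_s3_class(p, "protstruct")
  expect_equal(nrow(p$atoms), 4)
  expect_equal(nrow(protein_residues(p)), 1)
  expect_equal(p$atoms$element, c("N", "C", "C", "O"))

  out <- tempfile(fileext = ".pdb")
  write_protein(p, out)
  p2 <- read_protein(out)
  expect_equal(nrow(p2$atoms), nrow(p$atoms))
  expect_equal(sort(p2$atoms$element), sort(p$atoms$element))
  expect_equal(as.matrix(p2$atoms[, c("x", "y", "z")]),
               as.matrix(p$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.60 10.00           N",
    "ATOM      2  N  BGLY A   1       9.000   0.000   0.000  0.40 10.00           N",
    "ATOM      3  CA  GLY A   1       1.458   0.000   0.000  1.00 10.00           C",
    "END")
  p <- read_protein(write_pdb_fixture(lines))
  expect_equal(nrow(p$atoms), 2)
  n_atom <- p$atoms[p$atoms$atom_name == "N", ]
  expect_equal(n_atom$x, 0.0)   # conformer A (occupancy 0.6) retained

  # when B carries the higher occupancy, B wins
  lines2 <- sub("0.60", "0.30", lines, fixed = TRUE)
  p2 <- read_protein(write_pdb_fixture(lines2))
  expect_equal(p2$atoms$x[p2$atoms$atom_name == "N"], 9.0)

  # equal occupancies: alphabetical altLoc tie-break keeps A
  lines3 <- sub("0.60", "0.40", lines, fixed = TRUE)
  p3 <- read_protein(write_pdb_fixture(lines3))
  expect_equal(p3$atoms$x[p3$atoms$atom_name == "N"], 0.0)
})

test_that("a PDB without atom records is rejected", {
  f <- write_pdb_fixture(c("REMARK nothing here", "END"))
  expect_error(read_protein(f))
  expect_error(read_protein(tempfile()), "not found")
})

test_that("affinity conversion follows -RT ln of the association constant", {
  expect_identical(affinity_to_dG(1), 0)
  # hand value: 1.9872e-3 * 298.15 * ln(1e-9)
  expect_equal(affinity_to_dG(1e-9), -12.2782, tolerance = 1e-3)
  # strictly increasing in K
  K <- sort(10^stats::runif(50, -12, 0))
  expect_true(all(diff(affinity_to_dG(K)) > 0))
  # linear in T for fixed K
  expect_equal(affinity_to_dG(1e-6, temperature = 310) / 310,
               affinity_to_dG(1e-6, temperature = 298.15) / 298.15)
  expect_error(affinity_to_dG(0))
  expect_error(affinity_to_dG(-1))
})

test_that("affinity tables convert units and apply Kd > Ki > IC50 precedence", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,value,unit,type",
               "lig1,1,nM,Ki",
               "lig1,500,uM,Kd",
               "lig2,1,M,IC50",
               "lig3,2,mM,Kd"), f)
  a <- read_affinities(f)
  expect_equal(nrow(a), 3)
  # lig1 keeps the Kd row despite the stronger Ki
  expect_equal(a$type[a$id == "lig1"], "Kd")
  expect_equal(a$K[a$id == "lig1"], 5e-4)
  expect_equal(a$dG[a$id == "lig2"], 0)
  expect_equal(a$K[a$id == "lig3"], 2e-3)
})

test_that("metal filter discards only sub-cutoff contacts and is rigid-motion invariant", {
  lig <- molgraph(c("C", "C"), coords = rbind(c(0, 0, 0), c(1.5, 0, 0)),
                  bonds = cbind(1, 2, 1), name = "lig")
  prot_at <- function(d) protstruct_from_atoms(data.frame(
    record = "HETATM", atom_name = "ZN", element = "Zn",
    x = d, y = 0, z = 0, resid = "ZN", resno = 99, hetero = TRUE))
  expect_false(filter_metal_contacts(prot_at(-2.0), lig))  # 2.0 A contact
  expect_true(filter_metal_contacts(prot_at(-2.2), lig))   # above cutoff
  expect_true(filter_metal_contacts(prot_at(-2.1), lig))   # boundary keeps

  empty <- protstruct_from_atoms(data.frame(
    record = "ATOM", atom_name = "CA", element = "C", x = 5, y = 5, z = 5,
    resid = "GLY", resno = 1, hetero = FALSE))
  expect_true(filter_metal_contacts(empty, lig))

  # joint translation leaves the verdict unchanged
  shift <- c(13.2, -4.5, 8.8)
  p <- prot_at(-2.0)
  p$atoms$x <- p$atoms$x + shift[1]
  p$atoms$y <- p$atoms$y + shift[2]
  p$atoms$z <- p$atoms$z + shift[3]
  lig2 <- lig
  lig2$coords <- sweep(lig$coords, 2, -shift)
  expect_false(filter_metal_contacts(p, lig2))
})

test_that("ligand SDF writing round-trips the molecular graph", {
  figs <- fixture_ligands()
  for (nm in c("ethanol", "benzene", "acetamide", "aspirin")) {
    f <- tempfile(fileext = ".sdf")
    write_ligands(figs[[nm]], f)
    back <- read_ligands(f)[[1]]
    expect_equal(back$elements, figs[[nm]]$elements, label = nm)
    expect_equal(back$coords, figs[[nm]]$coords, tolerance = 1e-3)
    expect_equal(back$bonds[order(back$bonds[, 1], back$bonds[, 2]), ],
                 figs[[nm]]$bonds[order(figs[[nm]]$bonds[, 1],
                                        figs[[nm]]$bonds[, 2]), ])
  }
})

test_that("SMILES input yields the canonical benzene graph", {
  m <- smiles_to_molgraph("c1ccccc1 benzene")
  heavy <- m$elements != "H"
  expect_equal(sum(heavy), 6)
  expect_true(all(m$elements[heavy] == "C"))
  expect_true(all(m$aromatic[heavy]))
  b <- m$bonds
  ring_bonds <- b[m$elements[b[, 1]] != "H" & m$elements[b[, 2]] != "H", ]
  expect_equal(nrow(ring_bonds), 6)
})

test_that("SDF and MOL2 encodings give identical heavy-atom graphs", {
  figs <- fixture_ligands()
  for (nm in c("ethanol", "benzene", "acetamide", "butane", "aspirin")) {
    sdf <- tempfile(fileext = ".sdf")
    write_ligands(figs[[nm]], sdf)
    mol2 <- tempfile(fileext = ".mol2")
    writeLines(ChemmineOB::convertFormat(
      "SDF", "MOL2", paste(readLines(sdf), collapse = "\n")), mol2)
    a <- read_ligands(sdf)[[1]]
    b <- read_ligands(mol2)[[1]]
    ha <- which(a$elements != "H"); hb <- which(b$elements != "H")
    expect_equal(sort(a$elements[ha]), sort(b$elements[hb]), label = nm)
    expect_equal(wiener_index(a), wiener_index(b), label = nm)
  }
})

test_that("complex assembly attaches dG and applies the metal filter", {
  figs <- fixture_ligands()
  aff <- data.frame(id = "ethanol", K = 1e-6, type = "Kd",
                    dG = affinity_to_dG(1e-6))
  zn <- protstruct_from_atoms(data.frame(
    record = "HETATM", atom_name = "ZN", element = "Zn",
    x = 0, y = 0, z = 1.0, resid = "ZN", resno = 9, hetero = TRUE))
  cx <- assemble_complexes(zn, figs["ethanol"], aff)
  expect_false(cx[[1]]$kept)
  expect_equal(cx[[1]]$dG, affinity_to_dG(1e-6))
  cx2 <- assemble_complexes(zn, figs["ethanol"], aff, metal_cutoff = 0)
  expect_true(cx2[[1]]$kept)
})
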