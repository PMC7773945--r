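figs <- fixture_ligands()

test_that("molecular weight matches standard atomic weight sums", {
  expect_equal(molecular_weight(figs$methane), 16.04, tolerance = 0.01)
  expect_equal(molecular_weight(molgraph("He")), 4.0026)
  # additivity over a disconnected union (two ethanols in one graph)
  two <- molgraph(rep(c("C", "C", "O"), 2),
                  bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(4, 5, 1),
                                c(5, 6, 1)))
  expect_warning(w2 <- wiener_index(two), "disconnected")
  expect_equal(molecular_weight(two), 2 * molecular_weight(figs$ethanol))
  expect_error(molecular_weight(molgraph("Xx")))
})

test_that("donor/acceptor counting follows the documented N/O rule set", {
  expect_equal(hbond_counts(figs$benzene), c(D = 0L, A = 0L))
  expect_equal(hbond_counts(figs$ethanol), c(D = 1L, A = 1L))
  # acetamide: amide N donates; carbonyl O and amide N accept
  expect_equal(hbond_counts(figs$acetamide), c(D = 1L, A = 2L))
  # nitromethane: nitro N and O excluded entirely
  nitro <- molgraph(c("C", "N", "O", "O"),
                    bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
                    charges = c(0L, 1L, 0L, -1L))
  expect_equal(hbond_counts(nitro), c(D = 0L, A = 0L))
  # pyrrole (kekule form): aromatic NH is a donor but not an acceptor
  pyrrole <- molgraph(c("N", "C", "C", "C", "C"),
                      bonds = cbind(1:5, c(2:5, 1), c(1L, 2L, 1L, 2L, 1L)))
  expect_true(all(pyrrole$aromatic))
  expect_equal(hbond_counts(pyrrole), c(D = 1L, A = 0L))
  # pyridine (kekule form): aromatic N without H accepts
  pyridine <- molgraph(c("N", rep("C", 5)),
                       bonds = cbind(1:6, c(2:6, 1), c(2L, 1L, 2L, 1L, 2L, 1L)))
  expect_true(all(pyridine$aromatic))
  expect_equal(hbond_counts(pyridine), c(D = 0L, A = 1L))
})

test_that("Wildman-Crippen contributions match the reference implementation values", {
  # expected values frozen from an independent reference implementation of
  # the published contribution table (tolerance 1e-3)
  expected <- list(methane = c(0.6361, 6.7310),
                   ethanol = c(-0.0014, 12.7598),
                   benzene = c(1.6866, 26.4420),
                   butane = c(1.8064, 20.5820),
                   cyclohexane = c(2.3406, 27.7020),
                   acetamide = c(-0.5084, 14.8684),
                   aspirin = c(1.3101, 44.7103))
  for (nm in names(expected)) {
    cc <- crippen_contributions(figs[[nm]])
    expect_equal(cc$logP, expected[[nm]][1], tolerance = 1e-3, label = nm)
    expect_equal(cc$MR, expected[[nm]][2], tolerance = 1e-3, label = nm)
  }
})

test_that("Crippen contributions are additive over disconnected components", {
  two <- molgraph(rep(c("C", "C", "O"), 2),
                  bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(4, 5, 1),
                                c(5, 6, 1)))
  cc <- crippen_contributions(two)
  one <- crippen_contributions(figs$ethanol)
  expect_equal(cc$logP, 2 * one$logP)
  expect_equal(cc$MR, 2 * one$MR)
})

test_that("Wiener index matches the path-graph closed form", {
  for (n in 2:10) {
    path <- molgraph(rep("C", n), bonds = cbind(seq_len(n - 1), 2:n, 1L))
    expect_equal(wiener_index(path), n * (n^2 - 1) / 6)
  }
  expect_equal(wiener_index(molgraph("C")), 0)
  expect_equal(wiener_index(figs$butane), 10)
  expect_equal(wiener_index(figs$cyclohexane), 27)
})

test_that("Wiener index agrees with brute-force BFS on random connected graphs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:15, 1)
    edges <- random_connected_graph(n)
    m <- molgraph(rep("C", n), bonds = cbind(edges, 1L))
    expect_equal(wiener_index(m), oracle_wiener(n, edges))
  }
})

test_that("hydrogens are excluded from the Wiener index", {
  # ethane with explicit hydrogens still has W = 1
  eth <- molgraph(c("C", "C", rep("H", 6)),
                  bonds = rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                                c(1, 5, 1), c(2, 6, 1), c(2, 7, 1),
                                c(2, 8, 1)))
  expect_equal(wiener_index(eth), 1)
})

test_that("maxD is the largest distance to the mass-weighted centre of mass", {
  expect_equal(max_distance(figs$methane), 0)
  two <- molgraph(c("C", "C"), coords = rbind(c(0, 0, 0), c(2, 0, 0)),
                  bonds = cbind(1, 2, 1))
  expect_equal(max_distance(two), 1)
  three <- molgraph(rep("C", 3),
                    coords = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                    bonds = rbind(c(1, 2, 1), c(2, 3, 1)))
  expect_equal(max_distance(three), 1)
  expect_error(max_distance(molgraph("C")), "coordinates")
})

test_that("descriptors are invariant to rotation, translation and atom order", {
  m <- figs$aspirin
  d0 <- ligand_descriptors(m)
  # rigid rotation + translation
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- m; m2$coords <- sweep(m$coords %*% R, 2, c(3, -2, 7), "+")
  expect_equal(ligand_descriptors(m2), d0, tolerance = 1e-10)
  # atom permutation
  set.seed(1)
  perm <- sample(n_atoms(m))
  inv <- order(perm)
  b <- m$bonds
  m3 <- molgraph(m$elements[perm], coords = m$coords[perm, , drop = FALSE],
                 bonds = cbind(inv[b[, 1]], inv[b[, 2]], b[, 3]),
                 charges = m$charges[perm], name = m$name)
  expect_equal(ligand_descriptors(m3), d0, tolerance = 1e-10)
})

test_that("the descriptor vector has exactly the six features plus maxD", {
  d <- ligand_descriptors(figs$ethanol)
  expect_named(d, c("MASS", "D", "A", "logP", "MR", "W", "maxD"))
  expect_true(all(d[c("MASS", "D", "A", "W", "maxD")] >= 0))
  expect_equal(d[["W"]], round(d[["W"]]))
})

test_that("salts are reduced to the largest component before description", {
  # ethanol + sodium ion in one record
  salt <- molgraph(c("C", "C", "O", "Na"),
                   coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
                                  c(8, 8, 8)),
                   bonds = rbind(c(1, 2, 1), c(2, 3, 1)),
                   charges = c(0L, 0L, 0L, 1L), name = "salt")
  d <- ligand_descriptors(salt)
  ref <- ligand_descriptors(figs$ethanol)
  expect_equal(d[c("MASS", "D", "A", "W")], ref[c("MASS", "D", "A", "W")])
})
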