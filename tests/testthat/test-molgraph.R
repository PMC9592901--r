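test_that("SDF reading populates atoms, bonds, coordinates and charge", {
  skip_if_not_installed("ChemmineR")
  fx <- test_fixtures()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(fx$cyclopentanone, path)
  mol <- read_structure(path, "sdf")
  expect_s3_class(mol, "Molecule")
  expect_equal(nrow(mol$atoms), 14)
  expect_equal(sum(mol$atoms$element == "C"), 5)
  expect_equal(sum(mol$atoms$element == "O"), 1)
  expect_equal(sum(mol$atoms$element == "H"), 8)
  expect_equal(mol$formal_charge, 0L)
  expect_equal(unname(mol$coords), unname(fx$cyclopentanone$coords),
               tolerance = 1e-3)

  write_sdf(fx$aniline, path)
  expect_equal(nrow(read_structure(path, "sdf")$atoms), 14)

  write_sdf(fx$methane, path)
  mm <- read_structure(path, "sdf")
  expect_equal(nrow(mm$atoms), 5)
  expect_equal(nrow(mm$bonds), 4)

  # formal charge survives the round trip via M CHG
  write_sdf(fx$methylammonium, path)
  expect_equal(read_structure(path, "sdf")$formal_charge, 1L)
})

test_that("MOL2 reading gives the same molecule as SDF", {
  skip_if_not_installed("bio3d")
  fx <- test_fixtures()
  mol <- fx$ethanol
  path <- withr::local_tempfile(fileext = ".mol2")
  lines <- c("@<TRIPOS>MOLECULE", "ethanol",
             sprintf(" %d %d 1 0 0", nrow(mol$atoms), nrow(mol$bonds)),
             "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM",
             sprintf("%d %s%d %.4f %.4f %.4f %s 1 MOL 0.0",
                     seq_len(nrow(mol$atoms)), mol$atoms$element,
                     seq_len(nrow(mol$atoms)), mol$coords[, 1],
                     mol$coords[, 2], mol$coords[, 3],
                     mol$atoms$element),
             "@<TRIPOS>BOND",
             sprintf("%d %d %d %s", seq_len(nrow(mol$bonds)),
                     mol$bonds$i, mol$bonds$j, mol$bonds$order))
  writeLines(lines, path)
  m2 <- read_structure(path, "mol2")
  expect_equal(m2$atoms$element, mol$atoms$element)
  expect_equal(nrow(m2$bonds), nrow(mol$bonds))
})

test_that("malformed inputs are rejected with the documented errors", {
  expect_error(new_molecule(c("C", "B"), data.frame(i = 1, j = 2,
                                                    order = "1"),
                            matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3,
                                   byrow = TRUE)),
               "element out of vocabulary")
  # two fragments
  expect_error(new_molecule(c("C", "C", "C"),
                            data.frame(i = 1, j = 2, order = "1"),
                            matrix(c(0, 0, 0, 1.5, 0, 0, 9, 9, 9), 3, 3,
                                   byrow = TRUE)),
               "multi-fragment input")
  # coincident bonded atoms (no real 3D information)
  expect_error(new_molecule(c("C", "C"),
                            data.frame(i = 1, j = 2, order = "1"),
                            matrix(0, 2, 3)),
               "no 3D coordinates")
})

test_that("perception flags match canonical cases", {
  fx <- test_fixtures()
  bz <- fx$benzene
  carbons <- bz$atoms$element == "C"
  expect_true(all(bz$atoms$aromatic[carbons]))
  expect_true(all(bz$atoms$hybridization[carbons] == "sp2"))
  expect_true(all(bz$atoms$in_ring[carbons]))

  cp <- fx$cyclopentanone
  carbonyl <- which(cp$atoms$element == "C" &
                      cp$atoms$hybridization == "sp2")
  expect_length(carbonyl, 1)
  expect_equal(sum(cp$atoms$element == "C" &
                     cp$atoms$hybridization == "sp3"), 4)
  expect_false(any(cp$atoms$aromatic))

  et <- fx$ethane
  expect_true(all(et$atoms$hybridization[et$atoms$element == "C"] ==
                    "sp3"))
  expect_false(any(et$atoms$in_ring))

  # donor/acceptor stand-in rule: aniline N donates and accepts,
  # phenol O donates, benzene has neither
  an <- fx$aniline
  n_at <- which(an$atoms$element == "N")
  expect_true(an$atoms$h_donor[n_at])
  expect_true(an$atoms$h_acceptor[n_at])
  expect_false(any(fx$benzene$atoms$h_donor))

  # impossible valence
  expect_error(perceive_environment(
    new_molecule(c("H", "H", "O", "H"),
                 data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                            order = "1"),
                 matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3,
                        byrow = TRUE))),
    "perception failure")
})

test_that("shells match an independent BFS oracle and are disjoint", {
  fx <- test_fixtures()
  for (mol in list(fx$cyclopentanone, fx$aniline, fx$octanol)) {
    for (a in seq_len(nrow(mol$atoms))) {
      d <- bfs_distances(nrow(mol$atoms), mol$bonds$i, mol$bonds$j, a)
      s1 <- shell_atoms(mol, a, 1)
      s2 <- shell_atoms(mol, a, 2)
      s3 <- shell_atoms(mol, a, 3)
      expect_equal(sort(s1), which(d == 1))
      expect_equal(sort(s2), which(d == 2))
      expect_equal(sort(s3), which(d == 3))
      expect_length(intersect(s1, s2), 0)
      expect_length(intersect(s2, s3), 0)
      expect_false(a %in% c(s1, s2, s3))
    }
  }
  # aniline N: third shell is the two meta carbons plus the two ortho
  # ring hydrogens
  an <- fx$aniline
  n_at <- which(an$atoms$element == "N")
  s3 <- shell_atoms(an, n_at, 3)
  expect_length(s3, 4)
  expect_equal(sort(an$atoms$element[s3]), c("C", "C", "H", "H"))
  # methane C has nothing beyond shell 1
  expect_length(shell_atoms(fx$methane, 1, 2), 0)
  expect_error(shell_atoms(fx$methane, 1, 4), "shell depth unsupported")
})

test_that("internal coordinates are exhaustive and duplicate-free", {
  fx <- test_fixtures()
  for (mol in list(fx$ethane, fx$benzene, fx$cyclopentanone, fx$butane)) {
    ic <- internal_coordinates(mol)
    oracle <- brute_internal_counts(nrow(mol$atoms), mol$bonds$i,
                                    mol$bonds$j)
    expect_equal(nrow(ic$bonds), oracle$bonds)
    expect_equal(nrow(ic$angles), oracle$angles)
    # the brute count enumerates each torsion once per bond direction
    # already handled; halving is not needed because each (a,b,c,d) is
    # generated once per central bond orientation
    expect_equal(nrow(ic$torsions), oracle$torsions)
    # no duplicated angle/torsion under reversal
    akey <- apply(ic$angles[, 1:3], 1, function(r)
      paste(min(r[1], r[3]), r[2], max(r[1], r[3])))
    expect_false(any(duplicated(akey)))
    tkey <- apply(ic$torsions[, 1:4], 1, function(r)
      paste(pmin(paste(r, collapse = "-"),
                 paste(rev(r), collapse = "-"))))
    expect_false(any(duplicated(tkey)))
  }
  ic <- internal_coordinates(fx$ethane)
  expect_equal(c(nrow(ic$bonds), nrow(ic$angles), nrow(ic$torsions)),
               c(7, 12, 9))
  icb <- internal_coordinates(fx$benzene)
  expect_equal(c(nrow(icb$bonds), nrow(icb$angles)), c(12, 18))
})

test_that("stored bond lengths equal recomputed distances", {
  fx <- test_fixtures()
  for (mol in fx[c("octanol", "aniline", "naphthalene")]) {
    d <- sqrt(rowSums((mol$coords[mol$bonds$i, , drop = FALSE] -
                         mol$coords[mol$bonds$j, , drop = FALSE])^2))
    expect_lt(max(abs(mol$bonds$length - d)), 1e-6)
  }
})

test_that("enumeration is invariant to atom relabeling", {
  fx <- test_fixtures()
  mol <- fx$cyclopentanone
  n <- nrow(mol$atoms)
  set.seed(11)
  perm <- sample(n)             # perm[old] = new index
  inv <- order(perm)
  pm <- perceive_environment(new_molecule(
    mol$atoms$element[inv],
    data.frame(i = perm[mol$bonds$i], j = perm[mol$bonds$j],
               order = mol$bonds$order),
    mol$coords[inv, , drop = FALSE],
    formal_charge = mol$formal_charge))
  ic <- internal_coordinates(mol)
  icp <- internal_coordinates(pm)
  expect_equal(nrow(icp$bonds), nrow(ic$bonds))
  expect_equal(nrow(icp$angles), nrow(ic$angles))
  expect_equal(nrow(icp$torsions), nrow(ic$torsions))
  # perceived flags carry over under the relabeling
  expect_equal(pm$atoms$hybridization[perm], mol$atoms$hybridization)
  expect_equal(pm$atoms$aromatic[perm], mol$atoms$aromatic)
})
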