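test_that("EEM charges solve the constrained equalization system", {
  # heteronuclear diatomic without Coulomb coupling: the hand-solved 2x2
  # system gives q = (chi_B - chi_A) / (2 (eta_A + eta_B)) on atom A
  mol <- new_molecule(c("C", "O"), data.frame(i = 1, j = 2, order = "1"),
                      matrix(c(0, 0, 0, 1.43, 0, 0), 2, 3, byrow = TRUE))
  p <- eem_parameters(coupling = 0)
  q <- eem_charges(mol, p)
  q_hand <- (p$chi[["O"]] - p$chi[["C"]]) /
    (2 * (p$eta[["C"]] + p$eta[["O"]]))
  expect_equal(q[1], q_hand, tolerance = 1e-12)
  expect_equal(q[2], -q_hand, tolerance = 1e-12)

  # homonuclear diatomic: zero by symmetry
  mol2 <- new_molecule(c("C", "C"), data.frame(i = 1, j = 2, order = "1"),
                       matrix(c(0, 0, 0, 1.54, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(eem_charges(mol2, p), c(0, 0), tolerance = 1e-14)

  # charge constraint holds with coupling, on neutral and ionic species
  fx <- test_fixtures()
  for (mol in fx[c("aniline", "octanol", "methylammonium", "acetate")]) {
    q <- eem_charges(mol)
    expect_lt(abs(sum(q) - mol$formal_charge), 1e-10)
  }
  # electron density flows toward the more electronegative atom
  cpq <- eem_charges(fx$cyclopentanone)
  expect_lt(cpq[which(fx$cyclopentanone$atoms$element == "O")], 0)
})

test_that("EEM responds continuously to parameter perturbations", {
  fx <- test_fixtures()
  mol <- fx$ethanol
  p <- eem_parameters()
  q0 <- eem_charges(mol, p)
  for (delta in c(1e-4, 1e-3, 1e-2)) {
    p2 <- p
    p2$chi[["O"]] <- p2$chi[["O"]] + delta
    dq <- max(abs(eem_charges(mol, p2) - q0))
    expect_lt(dq, 10 * delta)
    expect_gt(dq, 0)
  }
})

test_that("fixture generation is deterministic and well-formed", {
  a <- fixture_molecules(seed = 7, n_generated = 10)
  b <- fixture_molecules(seed = 7, n_generated = 10)
  expect_identical(names(a), names(b))
  for (nm in names(a)) {
    expect_identical(a[[nm]]$coords, b[[nm]]$coords)
    expect_identical(a[[nm]]$atoms$element, b[[nm]]$atoms$element)
  }
  # a different seed changes the generated subset
  d <- fixture_molecules(seed = 8, n_generated = 10)
  gen <- grep("^gen", names(a), value = TRUE)
  expect_false(identical(lapply(a[gen], function(m) m$atoms$element),
                         lapply(d[grep("^gen", names(d), value = TRUE)],
                                function(m) m$atoms$element)))
  # every fixture is perceived, connected and within the vocabulary
  for (nm in names(a)) {
    m <- a[[nm]]
    expect_true(m$perceived, label = nm)
    expect_true(all(m$atoms$element %in% c("C", "H", "O", "N", "S", "P",
                                           "F", "Cl", "Br")), label = nm)
  }
  # coverage report names the functional groups the fixtures span
  cov <- attr(a, "coverage")
  expect_true(all(c("ketone", "aromatic_ring", "amine", "halogen",
                    "fused_ring") %in% cov$group))
  expect_true(all(cov$n_molecules > 0))
})

test_that("fixtures round-trip through the SDF writer and reader", {
  skip_if_not_installed("ChemmineR")
  fx <- test_fixtures()
  path <- withr::local_tempfile(fileext = ".sdf")
  for (mol in fx[c("methane", "cyclopentanone", "aniline", "octanol",
                   "acetate")]) {
    write_sdf(mol, path)
    rt <- read_structure(path, "sdf")
    expect_equal(rt$atoms$element, mol$atoms$element)
    expect_equal(nrow(rt$bonds), nrow(mol$bonds))
    expect_equal(rt$formal_charge, mol$formal_charge)
    expect_equal(unname(rt$coords), unname(mol$coords), tolerance = 1e-3)
  }
})

test_that("torsion and force-constant convention oracles behave", {
  fx <- test_fixtures()
  et <- fx$ethane
  cc_bond <- which(et$atoms$element[internal_coordinates(et)$torsions$j]
                   == "C")[1]
  tors <- internal_coordinates(et)$torsions
  conv <- torsion_convention(et, tors$j[1], tors$k[1])
  expect_equal(conv$phase, 0)
  expect_equal(conv$periodicity, 3L)
  bz <- fx$benzene
  tb <- internal_coordinates(bz)$torsions
  ring <- which(bz$atoms$element == "C")
  r <- which(tb$j %in% ring & tb$k %in% ring)[1]
  convb <- torsion_convention(bz, tb$j[r], tb$k[r])
  expect_equal(convb$phase, 180)
  expect_equal(convb$periodicity, 2L)
  # stiffer label for double than single CC bonds, positive angle labels
  expect_gt(bond_k_label("C", "O", "2"), bond_k_label("C", "C", "1"))
  expect_gt(angle_k_label("C", "sp3", c("C", "C")), 0)
})

test_that("training-set bundle is label-complete and shuffle-stable", {
  fx <- test_fixtures()
  sub <- fx[c("methane", "ethanol", "benzene", "cyclopentanone",
              "aniline", "acetone")]
  ds <- make_training_set(sub)
  n_atoms <- sum(vapply(sub, function(m) nrow(m$atoms), integer(1)))
  expect_equal(nrow(ds$charges$features), n_atoms)
  expect_equal(length(ds$atomtype$labels), n_atoms)
  expect_false(anyNA(ds$charges$labels))
  expect_false(anyNA(ds$atomtype$labels))
  expect_equal(nrow(ds$phase$features), length(ds$periodicity$labels))
  # shuffling molecule order permutes rows but changes no labels
  ds2 <- make_training_set(rev(sub))
  for (k in c("charges", "atomtype")) {
    o1 <- order(ds[[k]]$provenance$molecule, ds[[k]]$provenance$row_id)
    o2 <- order(ds2[[k]]$provenance$molecule, ds2[[k]]$provenance$row_id)
    expect_equal(ds[[k]]$labels[o1], ds2[[k]]$labels[o2])
  }
})
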