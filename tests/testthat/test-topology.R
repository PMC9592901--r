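test_that("charge normalization distributes the residual evenly", {
  raw <- rep(0.001, 14)
  q <- normalize_charges(raw, 0L)
  expect_equal(q, raw - 0.001)
  expect_equal(sum(q), 0)
  # already normalized input is unchanged
  expect_equal(normalize_charges(q, 0L), q)
  q2 <- normalize_charges(rep(0.03, 10), 1L)
  expect_equal(q2, rep(0.03 + 0.07, 10))
  expect_equal(sum(q2), 1)
})

test_that("bond charge corrections are antisymmetric and unambiguous", {
  fx <- test_fixtures()
  mol <- fx$ethanol
  q0 <- normalize_charges(eem_charges(mol), 0L)
  # empty table is the identity
  expect_identical(apply_bond_charge_corrections(mol, q0, bcc_table()),
                   q0)
  types <- assign_atom_types(mol)
  tbl <- bcc_table("c3", "oh", "1", 0.03)
  q1 <- apply_bond_charge_corrections(mol, q0, tbl, types)
  c_at <- which(types == "c3" &
                  vapply(seq_along(types), function(a)
                    "oh" %in% types[c(mol$bonds$j[mol$bonds$i == a],
                                      mol$bonds$i[mol$bonds$j == a])],
                    logical(1)))
  o_at <- which(types == "oh")
  expect_equal(q1[c_at] - q0[c_at], 0.03)
  expect_equal(q1[o_at] - q0[o_at], -0.03)
  expect_lt(abs(sum(q1) - sum(q0)), 1e-12)
  # duplicate patterns matching one bond are refused
  dup <- bcc_table(c("c3", "oh"), c("oh", "c3"), c("1", "*"),
                   c(0.03, 0.01))
  expect_error(apply_bond_charge_corrections(mol, q0, dup, types),
               "ambiguous BCC rule")
})

test_that("1-4 pairs respect exact graph distance three", {
  fx <- test_fixtures()
  bu <- fx$butane
  p <- enumerate_pairs14(internal_coordinates(bu), bu)
  heavy <- which(bu$atoms$element == "C")
  expect_equal(sum(p$i %in% heavy & p$l %in% heavy), 1)
  # every listed pair is at BFS distance exactly 3
  for (r in seq_len(nrow(p))) {
    d <- bfs_distances(nrow(bu$atoms), bu$bonds$i, bu$bonds$j, p$i[r])
    expect_equal(unname(d[p$l[r]]), 3)
  }
  # 5-ring: the formal 1-4 ring pairs are 1-2/1-3 by the short way around
  cyc <- fx$cyclopentane
  pc <- enumerate_pairs14(internal_coordinates(cyc), cyc)
  ring <- which(cyc$atoms$element == "C")
  expect_equal(sum(pc$i %in% ring & pc$l %in% ring), 0)
  # benzene: exactly the three para pairs among ring atoms
  bz <- fx$benzene
  pb <- enumerate_pairs14(internal_coordinates(bz), bz)
  rb <- which(bz$atoms$element == "C")
  expect_equal(sum(pb$i %in% rb & pb$l %in% rb), 3)
  expect_false(any(duplicated(paste(pb$i, pb$l))))
})

test_that("improper enumeration targets three-coordinate sp2 carbons", {
  fx <- test_fixtures()
  # independent oracle: count atoms that are carbon, have exactly three
  # neighbors, and carry a double/aromatic bond
  oracle_count <- function(mol) {
    cnt <- 0L
    for (a in seq_len(nrow(mol$atoms))) {
      if (mol$atoms$element[a] != "C") next
      nb <- sum(mol$bonds$i == a | mol$bonds$j == a)
      has_pi <- any((mol$bonds$i == a | mol$bonds$j == a) &
                      (mol$bonds$order %in% c("2", "ar")))
      if (nb == 3L && has_pi) cnt <- cnt + 1L
    }
    cnt
  }
  for (nm in c("benzene", "cyclopentanone", "ethane", "toluene",
               "butadiene", "acetone", "naphthalene")) {
    imp <- enumerate_impropers(fx[[nm]])
    expect_equal(nrow(imp), oracle_count(fx[[nm]]), label = nm)
  }
  expect_equal(nrow(enumerate_impropers(fx$benzene)), 6)
  expect_equal(nrow(enumerate_impropers(fx$cyclopentanone)), 1)
  expect_equal(nrow(enumerate_impropers(fx$ethane)), 0)
  # central atom sits third
  imp <- enumerate_impropers(fx$cyclopentanone)
  expect_equal(fx$cyclopentanone$atoms$hybridization[imp$k], "sp2")
})

test_that("assembled topologies are complete and charge-conserving", {
  fx <- test_fixtures()
  params <- read_parameter_table()
  top <- assemble_topology(fx$cyclopentanone, bundle = NULL,
                           params = params)
  expect_equal(nrow(top$atoms), 14)
  expect_equal(nrow(top$bonds), 14)
  expect_lt(abs(sum(top$atoms$charge)), 1e-9)
  expect_equal(nrow(top$impropers), 1)
  expect_true(all(top$bonds$kb > 0))
  expect_true(all(top$angles$ktheta > 0))
  # aniline types flow through to the topology
  ta <- assemble_topology(fx$aniline, bundle = NULL, params = params)
  expect_equal(sort(unique(ta$atoms$type)), c("ca", "ha", "hn", "nh"))
  # charged species conserve their formal charge
  tm <- assemble_topology(fx$methylammonium, bundle = NULL,
                          params = params)
  expect_lt(abs(sum(tm$atoms$charge) - 1), 1e-9)
  # missing LJ entry fails loudly
  p2 <- params
  p2$lj <- p2$lj[p2$lj$type != "o", ]
  expect_error(assemble_topology(fx$cyclopentanone, bundle = NULL,
                                 params = p2),
               "parameter table incomplete")
})

test_that("GROMACS files round-trip and re-write bit-identically", {
  fx <- test_fixtures()
  params <- read_parameter_table()
  for (nm in c("cyclopentanone", "benzene", "methane", "octanol",
               "nitrobenzene")) {
    top <- assemble_topology(fx[[nm]], bundle = NULL, params = params)
    f1 <- withr::local_tempfile(fileext = ".itp")
    f2 <- withr::local_tempfile(fileext = ".itp")
    write_gromacs(top, f1)
    rt <- read_gromacs(f1)
    write_gromacs(rt, f2)
    expect_identical(readLines(f1), readLines(f2), label = nm)
    expect_equal(rt$atoms$charge, top$atoms$charge, tolerance = 1e-6)
    expect_equal(rt$bonds$kb, top$bonds$kb, tolerance = 1e-6)
    expect_equal(rt$angles$theta0, top$angles$theta0, tolerance = 1e-6)
    expect_equal(nrow(rt$dihedrals), nrow(top$dihedrals))
    expect_equal(nrow(rt$impropers), nrow(top$impropers))
    expect_equal(nrow(rt$pairs14), nrow(top$pairs14))
  }
  # benzene improper block: six func-4 lines
  top <- assemble_topology(fx$benzene, bundle = NULL, params = params)
  f <- withr::local_tempfile(fileext = ".itp")
  write_gromacs(top, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^\\s*\\d+\\s+\\d+\\s+\\d+\\s+\\d+\\s+4\\s",
                         lines)), 6)
  # methane: no pairs or dihedral sections at all
  tm <- assemble_topology(fx$methane, bundle = NULL, params = params)
  write_gromacs(tm, f)
  lines <- readLines(f)
  expect_false(any(grepl("\\[ pairs \\]", lines)))
  expect_false(any(grepl("\\[ dihedrals \\]", lines)))
})

test_that("bonded energy matches closed forms and the per-term oracle", {
  fx <- test_fixtures()
  params <- read_parameter_table()
  # equilibrium geometry: zero bond and angle energy by construction
  top <- assemble_topology(fx$cyclopentanone, bundle = NULL,
                           params = params)
  e <- evaluate_bonded_energy(top, fx$cyclopentanone$coords)
  expect_equal(e$bond, 0, tolerance = 1e-10)
  expect_equal(e$angle, 0, tolerance = 1e-10)

  # single-dihedral closed form: K=1, n=2, gamma=180, phi=0 -> 0
  single <- random_topology(4, seed = 1)
  single$bonds <- single$bonds[0, ]
  single$angles <- single$angles[0, ]
  single$dihedrals <- data.frame(i = 1, j = 2, k = 3, l = 4, phase = 180,
                                 periodicity = 2L, kphi = 1)
  coords_planar <- matrix(c(0, 1, 0,
                            0, 0, 0,
                            1, 0, 0,
                            1, 1, 0), 4, 3, byrow = TRUE)  # phi = 0
  e1 <- evaluate_bonded_energy(single, coords_planar)
  expect_equal(e1$dihedral, 0, tolerance = 1e-10)
  # and phi = 0 with gamma = 0 gives the full barrier 2K
  single$dihedrals$phase <- 0
  expect_equal(evaluate_bonded_energy(single, coords_planar)$dihedral, 2,
               tolerance = 1e-10)

  # bond stretched by 0.1 A at K = 300 costs 3.0 kcal/mol
  stretch <- single
  stretch$dihedrals <- stretch$dihedrals[0, ]
  stretch$bonds <- data.frame(i = 1, j = 2, r0 = 1.0, kb = 300)
  coords_s <- matrix(c(0, 0, 0, 1.1, 0, 0, 5, 5, 5, 6, 6, 6), 4, 3,
                     byrow = TRUE)
  expect_equal(evaluate_bonded_energy(stretch, coords_s)$bond, 3.0,
               tolerance = 1e-10)

  # random topologies against the scalar loop oracle
  for (s in 1:25) {
    top_r <- random_topology(sample(4:8, 1), seed = s)
    set.seed(s + 1000)
    coords <- matrix(rnorm(nrow(top_r$atoms) * 3, sd = 2),
                     nrow(top_r$atoms), 3)
    expect_equal(evaluate_bonded_energy(top_r, coords)$total,
                 brute_bonded_energy(top_r, coords), tolerance = 1e-10)
  }
  expect_error(evaluate_bonded_energy(top, top$atoms[1:3, ]),
               "mismatch")
})
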