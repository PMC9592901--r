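# Topology assembly: combine model predictions (or the rule/oracle
# fallbacks) with the GAFF parameter table into a complete bonded +
# nonbonded parameter set for one molecule.
#
# Unit conventions inside a Topology object: lengths in Angstrom, angles and
# phases in degrees, K_b in kcal/mol/A^2, K_theta in kcal/mol/rad^2, K_phi
# in kcal/mol, charges in e, LJ sigma in nm and epsilon in kJ/mol (the only
# fields stored directly in GROMACS units because they are never used in
# the energy expression here). The GROMACS writer converts the harmonic
# constants to the 1/2 k convention (factor 2) and kcal->kJ, A->nm.

#' Spread the residual charge evenly over all atoms
#'
#' The predicted charges rarely sum exactly to the molecular formal charge;
#' the difference is distributed equally among all atoms so the total charge
#' matches exactly.
#'
#' @param raw numeric per-atom charges (e).
#' @param formal_charge integer molecular charge (e).
#' @return adjusted charges summing to `formal_charge` exactly.
#' @export
normalize_charges <- function(raw, formal_charge) {
  if (length(raw) == 0L) stop("no atoms")
  raw + (formal_charge - sum(raw)) / length(raw)
}

#' Apply localized bond charge corrections
#'
#' For every bond matching a (directed) type pattern in the table, `delta`
#' is moved across the bond: +delta on the atom matching `type_i`, -delta on
#' the atom matching `type_j`. Increments are antisymmetric, so the total
#' charge is invariant. Two rules matching one bond is an error.
#'
#' @param mol perceived `Molecule`.
#' @param charges per-atom charges (e), already normalized.
#' @param table a `BCCTable` (possibly empty).
#' @param types atom-type codes; defaults to the rule-based assignment.
#' @return corrected charges.
#' @export
apply_bond_charge_corrections <- function(mol, charges, table,
                                          types = NULL) {
  if (is.null(table) || nrow(table) == 0L) return(charges)
  if (is.null(types)) types <- assign_atom_types(mol)
  b <- mol$bonds
  for (e in seq_len(nrow(b))) {
    i <- b$i[e]; j <- b$j[e]
    ord <- if (b$aromatic[e]) "ar" else b$order[e]
    hits <- which((table$order == "*" | table$order == ord) &
                    ((table$type_i == types[i] & table$type_j == types[j]) |
                     (table$type_i == types[j] & table$type_j == types[i])))
    if (length(hits) > 1L)
      stop(sprintf("ambiguous BCC rule: bond %d-%d (%s-%s) matches %d rules",
                   i, j, types[i], types[j], length(hits)))
    if (length(hits) == 1L) {
      r <- table[hits, ]
      if (r$type_i == types[i]) {
        charges[i] <- charges[i] + r$delta
        charges[j] <- charges[j] - r$delta
      } else {
        charges[j] <- charges[j] + r$delta
        charges[i] <- charges[i] - r$delta
      }
    }
  }
  charges
}

#' Enumerate 1-4 nonbonded pairs
#'
#' Takes the first and fourth atoms of every proper torsion and keeps the
#' unique unordered pairs whose shortest graph distance is exactly three
#' bonds. In small rings a formal 1-4 pair can also be a 1-2 or 1-3 pair by
#' the shorter path around the ring; those are excluded.
#'
#' @param internal an `InternalCoordinates` object.
#' @param mol the `Molecule`.
#' @return data.frame with columns `i`, `l`.
#' @export
enumerate_pairs14 <- function(internal, mol) {
  tors <- internal$torsions
  if (nrow(tors) == 0L) return(data.frame(i = integer(), l = integer()))
  d <- igraph::distances(mol_graph(mol))
  lo <- pmin(tors$i, tors$l); hi <- pmax(tors$i, tors$l)
  keep <- d[cbind(lo, hi)] == 3
  u <- unique(data.frame(i = lo[keep], l = hi[keep]))
  u <- u[order(u$i, u$l), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Enumerate improper dihedrals
#'
#' One improper torsion per three-coordinate sp2 (or aromatic) carbon,
#' keeping aromatic and conjugated centers planar. The central atom is
#' placed third (AMBER/GROMACS convention); phase 180 degrees, periodicity
#' 2.
#'
#' @param mol perceived `Molecule`.
#' @return data.frame with columns i, j, k, l (k is the sp2 center).
#' @export
enumerate_impropers <- function(mol) {
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  centers <- which(mol$atoms$element == "C" &
                     mol$atoms$hybridization == "sp2" &
                     mol$atoms$valence == 3L)
  if (length(centers) == 0L)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer()))
  rows <- lapply(centers, function(cen) {
    nb <- sort(mol_neighbors(mol, cen))
    data.frame(i = nb[1], j = nb[2], k = cen, l = nb[3])
  })
  do.call(rbind, rows)
}

# improper barrier: GAFF uses 10.5 kcal/mol at carbonyl-type centers and
# 1.1 kcal/mol elsewhere
improper_barrier <- function(mol, center) {
  nb <- mol_neighbors(mol, center)
  eids <- vapply(nb, function(x) bond_between(mol, center, x), integer(1))
  dbl_o <- any(mol$atoms$element[nb] %in% c("O", "S") &
                 mol$bonds$order[eids] == "2")
  if (dbl_o) 10.5 else 1.1
}

#' Assemble a complete topology
#'
#' Runs the full parameterization workflow for one molecule: atom types
#' (classifier head with rule fallback for codes missing from the table, or
#' rules directly), Lennard-Jones assignment by type, predicted charges
#' normalized to the formal charge and optionally bond-charge corrected,
#' bond/angle terms with structure equilibrium values and predicted force
#' constants, torsion terms with predicted phase/periodicity and
#' table-derived barriers, improper terms on sp2 carbons, and 1-4 pairs.
#'
#' @param mol perceived `Molecule`.
#' @param bundle a `ModelBundle`, or `NULL` to parameterize entirely from
#'   the deterministic oracles (rule types, EEM charges, convention tables).
#' @param params a `ParameterTable`.
#' @param bcc optional `BCCTable`.
#' @return object of class `Topology`.
#' @export
assemble_topology <- function(mol, bundle = NULL,
                              params = read_parameter_table(),
                              bcc = NULL) {
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  ic <- internal_coordinates(mol)
  rule_types <- assign_atom_types(mol)

  if (!is.null(bundle)) {
    types <- predict_atom_types(bundle$atomtype, mol)
    unknown <- !(types %in% params$lj$type)
    types[unknown] <- rule_types[unknown]
    raw <- predict_charges(bundle$charge, mol)
    fc <- predict_force_constants(bundle$fc, mol)
    tor_par <- predict_torsion_params(
      list(phase = bundle$phase, periodicity = bundle$periodicity), mol)
  } else {
    types <- rule_types
    raw <- eem_charges(mol)
    b <- mol$bonds
    fc <- list(
      bonds = data.frame(i = b$i, j = b$j, r0 = b$length,
                         kb = vapply(seq_len(nrow(b)), function(e)
                           bond_k_label(mol$atoms$element[b$i[e]],
                                        mol$atoms$element[b$j[e]],
                                        if (b$aromatic[e]) "ar" else
                                          b$order[e]), numeric(1))),
      angles = data.frame(ic$angles[, c("i", "j", "k")],
                          theta0 = ic$angles$theta,
                          ktheta = vapply(seq_len(nrow(ic$angles)),
                                          function(r) angle_k_label(
                            mol$atoms$element[ic$angles$j[r]],
                            mol$atoms$hybridization[ic$angles$j[r]],
                            mol$atoms$element[c(ic$angles$i[r],
                                                ic$angles$k[r])]),
                            numeric(1))))
    tor_par <- if (nrow(ic$torsions) > 0L) {
      conv <- lapply(seq_len(nrow(ic$torsions)), function(r)
        torsion_convention(mol, ic$torsions$j[r], ic$torsions$k[r]))
      data.frame(ic$torsions[, c("i", "j", "k", "l")],
                 phase = vapply(conv, `[[`, numeric(1), "phase"),
                 periodicity = vapply(conv, `[[`, integer(1),
                                      "periodicity"))
    } else data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer(), phase = numeric(),
                      periodicity = integer())
  }

  lj <- lj_parameters(params, types)
  charges <- normalize_charges(raw, mol$formal_charge)
  charges <- apply_bond_charge_corrections(mol, charges, bcc, types)

  dihedrals <- if (nrow(tor_par) > 0L) {
    data.frame(tor_par,
               kphi = vapply(seq_len(nrow(tor_par)), function(r)
                 dihedral_barrier(params, types[tor_par$j[r]],
                                  types[tor_par$k[r]]), numeric(1)))
  } else cbind(tor_par, data.frame(kphi = numeric()))

  imp <- enumerate_impropers(mol)
  impropers <- if (nrow(imp) > 0L) {
    data.frame(imp, phase = 180, periodicity = 2L,
               kphi = vapply(imp$k, function(cen)
                 improper_barrier(mol, cen), numeric(1)))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), phase = numeric(),
                    periodicity = integer(), kphi = numeric())

  structure(list(
    name = mol$name,
    atoms = data.frame(index = seq_len(nrow(mol$atoms)),
                       element = mol$atoms$element, type = types,
                       charge = charges, mass = lj$mass,
                       sigma = lj$sigma, epsilon = lj$epsilon),
    bonds = fc$bonds,
    angles = fc$angles,
    dihedrals = dihedrals,
    impropers = impropers,
    pairs14 = enumerate_pairs14(ic, mol),
    formal_charge = mol$formal_charge),
    class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf(
    "<Topology> %s: %d atoms (sum q = %+.6f e), %d bonds, %d angles, %d dihedrals, %d impropers, %d 1-4 pairs\n",
    x$name, nrow(x$atoms), sum(x$atoms$charge), nrow(x$bonds),
    nrow(x$angles), nrow(x$dihedrals), nrow(x$impropers),
    nrow(x$pairs14)))
  invisible(x)
}

#' Evaluate the bonded potential energy
#'
#' Computes V = sum K_b (r - r_0)^2 + sum K_theta (theta - theta_0)^2 +
#' sum K_phi [1 + cos(n phi - gamma)] over the topology's bond, angle and
#' (proper + improper) dihedral terms at the supplied coordinates. Note the
#' harmonic terms carry no 1/2: the GROMACS writer compensates by emitting
#' doubled constants.
#'
#' @param top a `Topology`.
#' @param coords coordinate matrix (Angstrom), one row per atom.
#' @return list with components `bond`, `angle`, `dihedral` (proper +
#'   improper) and `total`, kcal/mol.
#' @export
evaluate_bonded_energy <- function(top, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(top$atoms))
    stop("coordinate/atom count mismatch")
  deg2rad <- pi / 180
  e_bond <- 0
  if (nrow(top$bonds) > 0L) {
    r <- sqrt(rowSums((coords[top$bonds$i, , drop = FALSE] -
                         coords[top$bonds$j, , drop = FALSE])^2))
    e_bond <- sum(top$bonds$kb * (r - top$bonds$r0)^2)
  }
  e_angle <- 0
  if (nrow(top$angles) > 0L) {
    th <- vapply(seq_len(nrow(top$angles)), function(r)
      vec_angle(coords[top$angles$i[r], ], coords[top$angles$j[r], ],
                coords[top$angles$k[r], ]), numeric(1))
    e_angle <- sum(top$angles$ktheta *
                     ((th - top$angles$theta0) * deg2rad)^2)
  }
  e_dih <- 0
  for (dd in list(top$dihedrals, top$impropers)) {
    if (nrow(dd) == 0L) next
    phi <- vapply(seq_len(nrow(dd)), function(r)
      vec_dihedral(coords[dd$i[r], ], coords[dd$j[r], ],
                   coords[dd$k[r], ], coords[dd$l[r], ]), numeric(1))
    e_dih <- e_dih + sum(dd$kphi *
                           (1 + cos((dd$periodicity * phi - dd$phase) *
                                      deg2rad)))
  }
  list(bond = e_bond, angle = e_angle, dihedral = e_dih,
       total = e_bond + e_angle + e_dih)
}
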