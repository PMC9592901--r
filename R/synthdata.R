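# Synthetic fixture molecules and label oracles.
# Molecules are defined as heavy-atom skeletons (a small spec DSL), hydrogens
# are added to satisfy standard valences, and idealized 3D coordinates are
# built from connectivity. Labels come from the EEM charge oracle, the
# rule-based GAFF typer, and deterministic torsion / force-constant
# convention tables.

spec_new <- function(name, formal_charge = 0L) {
  list(name = name, elements = character(), bonds = data.frame(
    i = integer(), j = integer(), order = character()),
    noh = logical(), formal_charge = as.integer(formal_charge))
}

spec_add_atom <- function(spec, element, noh = FALSE) {
  spec$elements <- c(spec$elements, element)
  spec$noh <- c(spec$noh, noh)
  spec
}

spec_add_bond <- function(spec, i, j, order = "1") {
  spec$bonds <- rbind(spec$bonds,
                      data.frame(i = as.integer(i), j = as.integer(j),
                                 order = as.character(order)))
  spec
}

# append `element` bonded to atom `at`; returns spec with attr "last" index
spec_graft_atom <- function(spec, at, element, order = "1", noh = FALSE) {
  spec <- spec_add_atom(spec, element, noh = noh)
  idx <- length(spec$elements)
  spec <- spec_add_bond(spec, at, idx, order)
  attr(spec, "last") <- idx
  spec
}

SPEC_TARGET_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                         F = 1, Cl = 1, Br = 1, H = 1)

# fill remaining valence with hydrogens (aromatic bonds count 1.5)
spec_add_hydrogens <- function(spec) {
  n <- length(spec$elements)
  ords <- bond_order_numeric(spec$bonds$order)
  occ <- numeric(n)
  for (e in seq_len(nrow(spec$bonds))) {
    occ[spec$bonds$i[e]] <- occ[spec$bonds$i[e]] + ords[e]
    occ[spec$bonds$j[e]] <- occ[spec$bonds$j[e]] + ords[e]
  }
  for (a in seq_len(n)) {
    if (spec$noh[a]) next
    need <- round(SPEC_TARGET_VALENCE[[spec$elements[a]]] - occ[a])
    if (need > 0L && spec$elements[a] != "H") {
      for (h in seq_len(need)) spec <- spec_graft_atom(spec, a, "H")
    }
  }
  spec
}

spec_to_molecule <- function(spec, coords = NULL, hydrogens = TRUE) {
  if (hydrogens) spec <- spec_add_hydrogens(spec)
  if (is.null(coords)) coords <- build_geometry(spec$elements, spec$bonds)
  mol <- new_molecule(spec$elements, spec$bonds, coords,
                      formal_charge = spec$formal_charge, name = spec$name)
  perceive_environment(mol)
}

# ---- skeleton helpers ------------------------------------------------------

chain_spec <- function(name, k) {
  spec <- spec_new(name)
  for (a in seq_len(k)) spec <- spec_add_atom(spec, "C")
  if (k > 1L) for (a in seq_len(k - 1L)) spec <- spec_add_bond(spec, a, a + 1L)
  spec
}

ring_spec <- function(name, size, order = "1", elements = rep("C", size)) {
  spec <- spec_new(name)
  for (el in elements) spec <- spec_add_atom(spec, el)
  for (a in seq_len(size))
    spec <- spec_add_bond(spec, a, if (a == size) 1L else a + 1L,
                          if (length(order) == 1L) order else order[a])
  spec
}

kekule5 <- c("1", "2", "1", "2", "1")   # heteroatom first: X-C=C-C=C

# substituent grafts; `at` is the attachment atom index
graft_group <- function(spec, at, group) {
  g <- function(...) spec_graft_atom(spec, at, ...)
  switch(group,
    OH = g("O"), NH2 = g("N"), SH = g("S"),
    F = g("F"), Cl = g("Cl"), Br = g("Br"),
    CH3 = g("C"),
    C2H5 = { spec <- g("C"); spec_graft_atom(spec, attr(spec, "last"), "C") },
    OCH3 = { spec <- g("O"); spec_graft_atom(spec, attr(spec, "last"), "C") },
    CN = { spec <- g("C")
           spec_graft_atom(spec, attr(spec, "last"), "N", order = "3") },
    NO2 = { spec <- g("N")
            at2 <- attr(spec, "last")
            spec <- spec_graft_atom(spec, at2, "O", order = "2")
            spec_graft_atom(spec, at2, "O", order = "2") },
    CHO = { spec <- g("C")
            spec_graft_atom(spec, attr(spec, "last"), "O", order = "2") },
    COOH = { spec <- g("C")
             at2 <- attr(spec, "last")
             spec <- spec_graft_atom(spec, at2, "O", order = "2")
             spec_graft_atom(spec, at2, "O") },
    stop("unknown substituent group: ", group)
  )
}

# ---- named fixtures --------------------------------------------------------

naphthalene_molecule <- function() {
  L <- 1.39
  ang <- (c(30, 90, 150, 210, 270, 330)) * pi / 180
  A <- cbind(L * cos(ang), L * sin(ang))
  B <- cbind(L * sqrt(3) + L * cos(ang), L * sin(ang))
  pts <- rbind(A, B)
  keep <- !duplicated(round(pts, 6))
  pts <- pts[keep, , drop = FALSE]        # 10 unique carbons
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n))
    if (abs(d[i, j] - L) < 1e-6)
      bonds <- rbind(bonds, data.frame(i = i, j = j, order = "ar"))
  elements <- rep("C", n)
  coords <- cbind(pts, 0)
  # hydrogens outward from the centroid of the two ring centers
  ctr <- c(L * sqrt(3) / 2, 0)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  for (a in which(deg == 2L)) {
    dir <- pts[a, ] - ctr
    dir <- dir / sqrt(sum(dir^2))
    elements <- c(elements, "H")
    coords <- rbind(coords, c(pts[a, ] + 1.09 * dir, 0))
    bonds <- rbind(bonds, data.frame(i = a, j = length(elements),
                                     order = "1"))
  }
  perceive_environment(new_molecule(elements, bonds, coords,
                                    name = "naphthalene"))
}

named_fixture_specs <- function() {
  sp <- list()
  sp$methane <- chain_spec("methane", 1)
  sp$ethane <- chain_spec("ethane", 2)
  sp$propane <- chain_spec("propane", 3)
  sp$butane <- chain_spec("butane", 4)
  sp$hexane <- chain_spec("hexane", 6)
  sp$octane <- chain_spec("octane", 8)
  sp$isobutane <- {
    s <- chain_spec("isobutane", 3); s <- graft_group(s, 2, "CH3"); s
  }
  sp$cyclopropane <- ring_spec("cyclopropane", 3)
  sp$cyclobutane <- ring_spec("cyclobutane", 4)
  sp$cyclopentane <- ring_spec("cyclopentane", 5)
  sp$cyclohexane <- ring_spec("cyclohexane", 6)
  sp$benzene <- ring_spec("benzene", 6, order = "ar")
  sp$toluene <- graft_group(ring_spec("toluene", 6, order = "ar"), 1, "CH3")
  sp$phenol <- graft_group(ring_spec("phenol", 6, order = "ar"), 1, "OH")
  sp$aniline <- graft_group(ring_spec("aniline", 6, order = "ar"), 1, "NH2")
  sp$fluorobenzene <-
    graft_group(ring_spec("fluorobenzene", 6, order = "ar"), 1, "F")
  sp$chlorobenzene <-
    graft_group(ring_spec("chlorobenzene", 6, order = "ar"), 1, "Cl")
  sp$bromobenzene <-
    graft_group(ring_spec("bromobenzene", 6, order = "ar"), 1, "Br")
  sp$nitrobenzene <-
    graft_group(ring_spec("nitrobenzene", 6, order = "ar"), 1, "NO2")
  sp$benzaldehyde <-
    graft_group(ring_spec("benzaldehyde", 6, order = "ar"), 1, "CHO")
  sp$benzonitrile <-
    graft_group(ring_spec("benzonitrile", 6, order = "ar"), 1, "CN")
  sp$styrene <- {
    s <- ring_spec("styrene", 6, order = "ar")
    s <- spec_graft_atom(s, 1, "C")
    spec_graft_atom(s, attr(s, "last"), "C", order = "2")
  }
  sp$pyridine <- ring_spec("pyridine", 6, order = "ar",
                           elements = c("N", rep("C", 5)))
  sp$pyrrole <- ring_spec("pyrrole", 5, order = kekule5,
                          elements = c("N", rep("C", 4)))
  sp$furan <- ring_spec("furan", 5, order = kekule5,
                        elements = c("O", rep("C", 4)))
  sp$thiophene <- ring_spec("thiophene", 5, order = kekule5,
                            elements = c("S", rep("C", 4)))
  sp$cyclopentanone <- {
    s <- ring_spec("cyclopentanone", 5)
    spec_graft_atom(s, 1, "O", order = "2")
  }
  sp$cyclohexanone <- {
    s <- ring_spec("cyclohexanone", 6)
    spec_graft_atom(s, 1, "O", order = "2")
  }
  sp$methanol <- graft_group(chain_spec("methanol", 1), 1, "OH")
  sp$ethanol <- graft_group(chain_spec("ethanol", 2), 2, "OH")
  sp$octanol <- graft_group(chain_spec("1-octanol", 8), 1, "OH")
  sp$acetone <- {
    s <- chain_spec("acetone", 3); spec_graft_atom(s, 2, "O", order = "2")
  }
  sp$acetaldehyde <- {
    s <- chain_spec("acetaldehyde", 2)
    spec_graft_atom(s, 2, "O", order = "2")
  }
  sp$acetic_acid <- {
    s <- chain_spec("acetic acid", 1); graft_group(s, 1, "COOH")
  }
  sp$acetamide <- {
    s <- chain_spec("acetamide", 2)
    s <- spec_graft_atom(s, 2, "O", order = "2")
    graft_group(s, 2, "NH2")
  }
  sp$methylamine <- graft_group(chain_spec("methylamine", 1), 1, "NH2")
  sp$dimethylamine <- {
    s <- chain_spec("dimethylamine", 1)
    s <- spec_graft_atom(s, 1, "N")
    spec_graft_atom(s, attr(s, "last"), "C")
  }
  sp$trimethylamine <- {
    s <- chain_spec("trimethylamine", 1)
    s <- spec_graft_atom(s, 1, "N")
    n_at <- attr(s, "last")
    s <- spec_graft_atom(s, n_at, "C")
    spec_graft_atom(s, n_at, "C")
  }
  sp$dimethyl_ether <- graft_group(chain_spec("dimethyl ether", 1), 1, "OCH3")
  sp$acetonitrile <- graft_group(chain_spec("acetonitrile", 1), 1, "CN")
  sp$propyne <- {
    s <- chain_spec("propyne", 2)
    spec_graft_atom(s, 2, "C", order = "3")
  }
  sp$butadiene <- {
    s <- spec_new("1,3-butadiene")
    for (k in 1:4) s <- spec_add_atom(s, "C")
    s <- spec_add_bond(s, 1, 2, "2")
    s <- spec_add_bond(s, 2, 3, "1")
    spec_add_bond(s, 3, 4, "2")
  }
  sp$nitromethane <- graft_group(chain_spec("nitromethane", 1), 1, "NO2")
  sp$methanethiol <- graft_group(chain_spec("methanethiol", 1), 1, "SH")
  sp$dimethyl_sulfide <- {
    s <- chain_spec("dimethyl sulfide", 1)
    s <- spec_graft_atom(s, 1, "S")
    spec_graft_atom(s, attr(s, "last"), "C")
  }
  sp$dimethyl_disulfide <- {
    s <- chain_spec("dimethyl disulfide", 1)
    s <- spec_graft_atom(s, 1, "S")
    s <- spec_graft_atom(s, attr(s, "last"), "S")
    spec_graft_atom(s, attr(s, "last"), "C")
  }
  sp$dmso <- {
    s <- chain_spec("dimethyl sulfoxide", 1)
    s <- spec_graft_atom(s, 1, "S")
    s_at <- attr(s, "last")
    s <- spec_graft_atom(s, s_at, "C")
    spec_graft_atom(s, s_at, "O", order = "2")
  }
  sp$dimethyl_sulfone <- {
    s <- chain_spec("dimethyl sulfone", 1)
    s <- spec_graft_atom(s, 1, "S")
    s_at <- attr(s, "last")
    s <- spec_graft_atom(s, s_at, "C")
    s <- spec_graft_atom(s, s_at, "O", order = "2")
    spec_graft_atom(s, s_at, "O", order = "2")
  }
  sp$tmpo <- {
    s <- spec_new("trimethylphosphine oxide")
    s <- spec_add_atom(s, "P")
    s <- spec_graft_atom(s, 1, "O", order = "2")
    s <- spec_graft_atom(s, 1, "C")
    s <- spec_graft_atom(s, 1, "C")
    spec_graft_atom(s, 1, "C")
  }
  sp$chloromethane <- graft_group(chain_spec("chloromethane", 1), 1, "Cl")
  sp$bromoethane <- graft_group(chain_spec("bromoethane", 2), 1, "Br")
  sp$fluoromethane <- graft_group(chain_spec("fluoromethane", 1), 1, "F")
  sp$methylammonium <- {
    s <- spec_new("methylammonium", formal_charge = 1L)
    s <- spec_add_atom(s, "C")
    s <- spec_graft_atom(s, 1, "N")
    n_at <- attr(s, "last")
    for (k in 1:3) s <- spec_graft_atom(s, n_at, "H")
    s
  }
  sp$acetate <- {
    s <- spec_new("acetate", formal_charge = -1L)
    s <- spec_add_atom(s, "C")
    s <- spec_graft_atom(s, 1, "C")
    c_at <- attr(s, "last")
    s <- spec_graft_atom(s, c_at, "O", order = "2")
    spec_graft_atom(s, c_at, "O", noh = TRUE)
  }
  sp
}

# ---- random generated fixtures --------------------------------------------

random_spec <- function(id) {
  skeleton <- sample(c("chain", "ring5", "ring6", "benzene"), 1,
                     prob = c(0.45, 0.15, 0.15, 0.25))
  name <- sprintf("gen%03d_%s", id, skeleton)
  spec <- switch(skeleton,
    chain = chain_spec(name, sample(2:6, 1)),
    ring5 = ring_spec(name, 5),
    ring6 = ring_spec(name, 6),
    benzene = ring_spec(name, 6, order = "ar"))
  n_heavy <- length(spec$elements)
  groups <- c("OH", "NH2", "SH", "F", "Cl", "Br", "CH3", "C2H5",
              "OCH3", "CN", "NO2", "CHO", "COOH")
  nsub <- sample(1:3, 1)
  sites <- sample(seq_len(n_heavy), min(nsub, n_heavy))
  for (at in sites) spec <- graft_group(spec, at, sample(groups, 1))
  # occasionally turn an unsubstituted interior chain carbon into a ketone
  if (skeleton == "chain" && n_heavy >= 3 && stats::runif(1) < 0.3) {
    free <- setdiff(2:(n_heavy - 1L), sites)
    if (length(free) > 0L)
      spec <- spec_graft_atom(spec, free[sample.int(length(free), 1)], "O",
                              order = "2")
  }
  spec
}

#' Generate the synthetic fixture set
#'
#' A deterministic library of small molecules: named fixtures spanning
#' alkanes, rings, aromatics, alcohols, amines, thiols, carbonyls, nitriles,
#' nitro compounds, sulfoxides/sulfones, a phosphine oxide, halides and two
#' charged species, plus `n_generated` randomly decorated chain/ring
#' skeletons. All molecules are built with idealized geometries, perceived,
#' and carry every descriptor input.
#'
#' @param seed RNG seed controlling the generated subset.
#' @param n_generated number of additional random molecules.
#' @return named list of perceived `Molecule` objects, with a functional-group
#'   `coverage` attribute.
#' @export
fixture_molecules <- function(seed = 7L, n_generated = 50L) {
  specs <- named_fixture_specs()
  mols <- lapply(specs, spec_to_molecule)
  mols$naphthalene <- naphthalene_molecule()
  if (n_generated > 0L) {
    set.seed(seed)
    for (id in seq_len(n_generated)) {
      spec <- random_spec(id)
      mols[[spec$name]] <- spec_to_molecule(spec)
    }
  }
  attr(mols, "coverage") <- fixture_coverage(mols)
  mols
}

# functional-group coverage report (presence across the fixture set)
fixture_coverage <- function(mols) {
  has <- function(f) vapply(mols, f, logical(1))
  probe <- list(
    ketone = function(m) any(m$atoms$element == "O" & m$atoms$valence == 1 &
      vapply(seq_len(nrow(m$atoms)), function(a) {
        nb <- mol_neighbors(m, a)
        m$atoms$element[a] == "O" && length(nb) == 1 &&
          m$atoms$element[nb] == "C"
      }, logical(1))),
    aromatic_ring = function(m) any(m$atoms$aromatic),
    alcohol_or_thiol = function(m) any(m$atoms$element %in% c("O", "S") &
                                         m$atoms$h_donor),
    amine = function(m) any(m$atoms$element == "N" & m$atoms$h_donor),
    nitrile = function(m) any(m$atoms$element == "N" &
                                m$atoms$hybridization == "sp"),
    halogen = function(m) any(m$atoms$element %in% c("F", "Cl", "Br")),
    ring = function(m) any(m$atoms$in_ring),
    fused_ring = function(m) any(m$atoms$in_fused_ring),
    charged = function(m) m$formal_charge != 0L
  )
  counts <- vapply(probe, function(f) sum(has(f)), integer(1))
  data.frame(group = names(counts), n_molecules = unname(counts))
}

# ---- convention label oracles ---------------------------------------------

#' GAFF-style torsion phase/periodicity convention
#'
#' Deterministic surrogate labels for the torsion classifier heads, keyed on
#' the hybridization of the central bond: aromatic/sp2-sp2 bonds get the
#' planarity-preserving (180 deg, n=2), sp3-sp3 the staggered (0 deg, n=3),
#' mixed sp2-sp3 (0 deg, n=2) and bonds involving an sp center (0 deg, n=1).
#'
#' @param mol perceived `Molecule`.
#' @param j,k central-bond atom indices of the torsion.
#' @return list with `phase` (degrees, 0 or 180) and `periodicity`.
#' @export
torsion_convention <- function(mol, j, k) {
  hj <- mol$atoms$hybridization[j]
  hk <- mol$atoms$hybridization[k]
  if (hj == "sp" || hk == "sp") return(list(phase = 0, periodicity = 1L))
  if (hj == "sp2" && hk == "sp2") return(list(phase = 180, periodicity = 2L))
  if (hj == "sp3" && hk == "sp3") return(list(phase = 0, periodicity = 3L))
  list(phase = 0, periodicity = 2L)
}

# surrogate bond stretch force constants, kcal/mol/A^2, keyed by element
# pair + order class (GAFF-like magnitudes)
BOND_K_TABLE <- c(
  "C-C:1" = 303, "C-H:1" = 337, "C-N:1" = 328, "C-O:1" = 314,
  "C-S:1" = 227, "C-F:1" = 363, "C-Cl:1" = 343, "C-Br:1" = 288,
  "C-P:1" = 250, "H-N:1" = 410, "H-O:1" = 369, "H-S:1" = 274,
  "N-O:1" = 300, "O-P:1" = 310, "O-S:1" = 310, "S-S:1" = 166,
  "C-C:2" = 589, "C-O:2" = 648, "C-N:2" = 540, "N-O:2" = 550,
  "O-S:2" = 493, "O-P:2" = 540,
  "C-C:3" = 923, "C-N:3" = 1010,
  "C-C:ar" = 478, "C-N:ar" = 483
)

bond_k_label <- function(el_i, el_j, order) {
  pair <- sort(c(el_i, el_j))
  key <- paste0(pair[1], "-", pair[2], ":", order)
  if (key %in% names(BOND_K_TABLE)) return(unname(BOND_K_TABLE[[key]]))
  switch(order, "2" = 600, "3" = 900, "ar" = 460, 300)
}

# surrogate angle bend force constants, kcal/mol/rad^2
angle_k_label <- function(center_el, center_hyb, flank_els) {
  base <- c(C = 63, N = 70, O = 75, S = 62, P = 45)[center_el]
  if (is.na(base)) base <- 50
  if (center_hyb == "sp2") base <- base + 5
  k <- base - 12 * sum(flank_els == "H")
  max(k, 30)
}
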