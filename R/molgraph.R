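#' @importFrom igraph graph_from_edgelist distances components shortest_paths
#'   delete_edges V ecount
NULL

#' Construct a Molecule object
#'
#' A `Molecule` is a typed molecular graph: explicit-hydrogen atoms with 3D
#' coordinates, bonds with orders, and (after [perceive_environment()])
#' perceived hybridization, aromaticity, ring membership and donor/acceptor
#' flags. Atom indices are 1-based throughout.
#'
#' @param elements character vector of element symbols (C, H, O, N, S, P, F,
#'   Cl, Br).
#' @param bonds data.frame with integer columns `i`, `j` and a character
#'   column `order` in `c("1", "2", "3", "ar")`.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param formal_charge integer net molecular charge in elementary charge
#'   units.
#' @param name molecule name.
#' @return object of class `Molecule`.
#' @export
new_molecule <- function(elements, bonds, coords, formal_charge = 0L,
                         name = "molecule") {
  n <- length(elements)
  bad <- setdiff(unique(elements), FF_ELEMENTS)
  if (length(bad) > 0L)
    stop("element out of vocabulary: ", paste(bad, collapse = ", "))
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop("no 3D coordinates: need one x/y/z row per atom")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop("no 3D coordinates: non-finite values")
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.character(bonds$order)
    if (any(bonds$i == bonds$j)) stop("bond references a single atom twice")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond references a missing atom")
    if (!all(bonds$order %in% c("1", "2", "3", "ar")))
      stop("unsupported bond order")
    bonds$length <- sqrt(rowSums((coords[bonds$i, , drop = FALSE] -
                                  coords[bonds$j, , drop = FALSE])^2))
    if (any(bonds$length < 1e-3))
      stop("no 3D coordinates: bonded atoms coincide")
    if (!"aromatic" %in% names(bonds)) bonds$aromatic <- bonds$order == "ar"
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = character(),
                        length = numeric(), aromatic = logical())
  }
  atoms <- data.frame(
    index = seq_len(n),
    element = elements,
    electronegativity = element_property(elements, "pauling_en"),
    covalent_radius = element_property(elements, "covalent_radius"),
    valence = 0L,
    hybridization = "other",
    aromatic = FALSE, in_ring = FALSE, in_fused_ring = FALSE,
    h_donor = FALSE, h_acceptor = FALSE, chiral = FALSE, axial = FALSE,
    stringsAsFactors = FALSE
  )
  mol <- structure(
    list(name = name, atoms = atoms, bonds = bonds, coords = coords,
         formal_charge = as.integer(formal_charge), perceived = FALSE),
    class = "Molecule"
  )
  if (n > 1L) {
    memb <- igraph::components(mol_graph(mol))$membership
    if (max(memb) > 1L) stop("multi-fragment input")
  }
  mol
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule> %s: %d atoms, %d bonds, formal charge %+d%s\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$formal_charge,
              if (x$perceived) ", perceived" else ""))
  invisible(x)
}

# igraph view of the bond graph (vertices = atoms, unweighted)
mol_graph <- function(mol) {
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0L)
    return(igraph::make_empty_graph(n = n, directed = FALSE))
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                   directed = FALSE)
  igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
}

# neighbor indices of atom a
mol_neighbors <- function(mol, a) {
  b <- mol$bonds
  c(b$j[b$i == a], b$i[b$j == a])
}

# numeric bond order (aromatic = 1.5) for feature use
bond_order_numeric <- function(order, aromatic = FALSE) {
  o <- ifelse(order == "ar", 1.5, suppressWarnings(as.numeric(order)))
  if (length(aromatic) == 1L) aromatic <- rep(aromatic, length(o))
  ifelse(aromatic, 1.5, o)
}

# order of the bond between atoms a and b ("1","2","3","ar"), NA if none
bond_between <- function(mol, a, b) {
  hit <- which((mol$bonds$i == a & mol$bonds$j == b) |
               (mol$bonds$i == b & mol$bonds$j == a))
  if (length(hit) == 0L) return(NA_integer_)
  hit[1]
}

#' Read a small-molecule structure file
#'
#' Reads an SDF (V2000, via ChemmineR) or MOL2 (TRIPOS, via bio3d) file into
#' a [new_molecule()] `Molecule`. The file must carry explicit hydrogens and
#' 3D coordinates; multi-fragment inputs are rejected. Formal charges are
#' taken from `M  CHG` lines (SDF) or inferred as zero.
#'
#' @param path file path.
#' @param format `"sdf"` or `"mol2"`; default guessed from the extension.
#' @return a `Molecule` (not yet perceived; see [perceive_environment()]).
#' @export
read_structure <- function(path, format = c("sdf", "mol2")) {
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mol2", "ml2")) "mol2" else "sdf"
  }
  format <- match.arg(format)
  if (format == "sdf") read_sdf_file(path) else read_mol2_file(path)
}

read_sdf_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("package ChemmineR is required to read SDF files")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_\\d+$", "", rownames(ab))
  elements <- sub("^CL$", "Cl", sub("^BR$", "Br", elements))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  if (!is.null(bb) && nrow(bb) > 0L) {
    ord <- as.integer(bb[, 3])
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = ifelse(ord == 4L, "ar", as.character(ord)))
  }
  # ChemmineR drops M CHG property lines; recover the formal charge directly
  lines <- readLines(path, warn = FALSE)
  q <- 0L
  chg <- grep("^M  CHG", lines, value = TRUE)
  end <- grep("^M  END", lines)[1]
  if (length(chg) > 0L) {
    chg <- chg[seq_along(chg) <= sum(grepl("^M  CHG", lines[seq_len(end)]))]
    for (ln in chg) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      q <- q + sum(f[seq(3, length(f), by = 2)])
    }
  }
  name <- trimws(lines[1])
  if (nzchar(name) == FALSE) name <- basename(path)
  if (nrow(coords) > 1L && all(abs(coords) < 1e-8))
    stop("no 3D coordinates")
  new_molecule(elements, bonds, coords, formal_charge = q, name = name)
}

read_mol2_file <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("package bio3d is required to read MOL2 files")
  m <- bio3d::read.mol2(path)
  elements <- sub("\\..*$", "", m$atom$elety)
  elements <- sub("^CL$", "Cl", sub("^BR$", "Br", elements))
  coords <- cbind(m$atom$x, m$atom$y, m$atom$z)
  ord <- tolower(as.character(m$bond$type))
  ord[ord %in% c("am")] <- "1"   # amide bonds stored as single
  bonds <- data.frame(i = as.integer(m$bond$origin),
                      j = as.integer(m$bond$target),
                      order = ifelse(ord == "ar", "ar", ord))
  q <- as.integer(round(sum(m$atom$charge)))
  new_molecule(elements, bonds, coords, formal_charge = q,
               name = if (is.null(m$name)) basename(path) else m$name)
}

#' Write a Molecule as an SDF V2000 file
#'
#' Minimal V2000 writer used for fixture round-tripping; aromatic bonds are
#' written with bond type 4 and the net formal charge as a single `M  CHG`
#' entry on atom 1 (per-atom charge localization is not tracked).
#'
#' @param mol a `Molecule`.
#' @param path output file path.
#' @export
write_sdf <- function(mol, path) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  lines <- c(mol$name, "  ffforge", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              mol$coords[a, 1], mol$coords[a, 2],
                              mol$coords[a, 3], mol$atoms$element[a]))
  }
  ordnum <- vapply(mol$bonds$order, function(o)
    if (o == "ar") 4L else as.integer(o), integer(1))
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$i[b], mol$bonds$j[b],
                              ordnum[b]))
  }
  if (mol$formal_charge != 0L)
    lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, 1L, mol$formal_charge))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

# ---- ring perception -------------------------------------------------------

# smallest rings: for every edge, the shortest cycle through it (edge removed,
# shortest remaining path between endpoints). Deduplicated; size capped at 8.
find_rings <- function(mol, max_size = 8L) {
  rings_from_graph(mol_graph(mol), max_size)
}

rings_from_graph <- function(g, max_size = 8L) {
  rings <- list()
  seen <- character()
  el <- igraph::as_edgelist(g)
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]])
    if (length(sp) == 0L || length(sp) > max_size) next
    ring <- as.integer(sp)
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# ---- perception ------------------------------------------------------------

#' Perceive chemical environment
#'
#' Fills in hybridization, aromaticity, ring flags, hydrogen-bond donor and
#' acceptor flags, valence and a simple chirality flag for every atom, and
#' marks aromatic bonds. Aromaticity uses a Hueckel-style rule on 5- and
#' 6-membered rings: every ring atom must be able to contribute to the pi
#' system (sp2 carbon contributes 1 electron, ring N/O/S without a double
#' bond contributes a lone pair), and the pi-electron count must be 4n+2.
#'
#' @param mol a `Molecule`.
#' @return the `Molecule` with perception fields populated
#'   (`mol$perceived == TRUE`).
#' @export
perceive_environment <- function(mol) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  ords <- bond_order_numeric(b$order)
  deg <- tabulate(c(b$i, b$j), nbins = n)
  # per-atom double/triple/aromatic-input bond counts
  ndouble <- tabulate(c(b$i[b$order == "2"], b$j[b$order == "2"]), nbins = n)
  ntriple <- tabulate(c(b$i[b$order == "3"], b$j[b$order == "3"]), nbins = n)
  naromin <- tabulate(c(b$i[b$order == "ar"], b$j[b$order == "ar"]), nbins = n)

  el <- mol$atoms$element
  # valence sanity (max connections per element)
  maxdeg <- c(C = 4, H = 1, O = 2, N = 4, S = 6, P = 6,
              F = 1, Cl = 1, Br = 1)[el]
  if (any(deg > maxdeg)) {
    bad <- which(deg > maxdeg)[1]
    stop(sprintf("perception failure: atom %d (%s) has %d connections",
                 bad, el[bad], deg[bad]))
  }

  hyb <- rep("other", n)
  heavy <- el != "H"
  hyb[heavy] <- "sp3"
  hyb[heavy & (ndouble == 1L | naromin > 0L)] <- "sp2"
  hyb[heavy & (ntriple > 0L | ndouble >= 2L)] <- "sp"

  rings <- find_rings(mol)
  in_ring <- rep(FALSE, n)
  ring_count <- integer(n)
  for (r in rings) {
    in_ring[r] <- TRUE
    ring_count[r] <- ring_count[r] + 1L
  }

  # Hueckel-style aromatic rings
  aromatic <- rep(FALSE, n)
  arom_bond <- rep(FALSE, nrow(b))
  for (r in rings) {
    if (!length(r) %in% c(5L, 6L)) next
    pi_e <- 0L; ok <- TRUE
    for (a in r) {
      if (el[a] == "C") {
        if (hyb[a] == "sp2") pi_e <- pi_e + 1L else { ok <- FALSE; break }
      } else if (el[a] %in% c("N", "O", "S")) {
        if (hyb[a] == "sp2") pi_e <- pi_e + 1L
        else if (deg[a] <= ifelse(el[a] == "N", 3L, 2L)) pi_e <- pi_e + 2L
        else { ok <- FALSE; break }
      } else { ok <- FALSE; break }
    }
    if (ok && pi_e %% 4L == 2L) {
      aromatic[r] <- TRUE
      for (k in seq_along(r)) {
        a <- r[k]; a2 <- r[if (k == length(r)) 1L else k + 1L]
        e <- bond_between(mol, a, a2)
        if (!is.na(e)) arom_bond[e] <- TRUE
      }
    }
  }
  hyb[aromatic] <- "sp2"

  # donor/acceptor: donor = N/O/S carrying >=1 H; acceptor = N or O that is
  # not a quaternary/aromatic-NH nitrogen (lone-pair heuristic)
  has_h <- vapply(seq_len(n), function(a)
    any(el[mol_neighbors(mol, a)] == "H"), logical(1))
  h_donor <- el %in% c("N", "O", "S") & has_h
  h_acceptor <- (el == "O") | (el == "N" & deg < 4L & !(aromatic & deg == 3L))

  # chirality heuristic: sp3 carbon whose four substituents start distinct
  # element-wise (full CIP ranking is out of scope)
  chiral <- vapply(seq_len(n), function(a) {
    if (el[a] != "C" || deg[a] != 4L) return(FALSE)
    length(unique(el[mol_neighbors(mol, a)])) == 4L
  }, logical(1))

  mol$atoms$valence <- deg
  mol$atoms$hybridization <- hyb
  mol$atoms$aromatic <- aromatic
  mol$atoms$in_ring <- in_ring
  mol$atoms$in_fused_ring <- ring_count >= 2L
  mol$atoms$h_donor <- h_donor
  mol$atoms$h_acceptor <- h_acceptor
  mol$atoms$chiral <- chiral
  mol$atoms$axial <- FALSE   # undecidable without conformer analysis
  mol$bonds$aromatic <- arom_bond | b$order == "ar"
  mol$rings <- rings
  mol$perceived <- TRUE
  mol
}

#' Atoms at an exact graph distance from a reference atom
#'
#' Returns the indices of atoms in the k-th bonded shell around a reference
#' atom: graph distance exactly `k`, reference excluded. Shells 1-3 are the
#' neighborhoods the atomic descriptors encode.
#'
#' @param mol a `Molecule`.
#' @param atom_index 1-based reference atom index.
#' @param k shell depth, 1, 2 or 3.
#' @return integer vector of atom indices (possibly empty).
#' @export
shell_atoms <- function(mol, atom_index, k) {
  if (!(k %in% 1:3)) stop("shell depth unsupported")
  n <- nrow(mol$atoms)
  if (atom_index < 1L || atom_index > n) stop("atom index out of range")
  d <- igraph::distances(mol_graph(mol), v = atom_index)
  which(d[1, ] == k)
}

# ---- geometry --------------------------------------------------------------

vec_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Enumerate internal coordinates
#'
#' Exhaustive, duplicate-free enumeration of bonds, bond angles and proper
#' torsions with their geometric values (Angstrom / degrees) computed from
#' the coordinates. A torsion (a,b,c,d) and its reversal are the same term
#' and are listed once, with `b < c`.
#'
#' @param mol a perceived `Molecule`.
#' @return list of class `InternalCoordinates` with data.frames `bonds`
#'   (i, j, r), `angles` (i, j, k, theta) and `torsions` (i, j, k, l, phi).
#' @export
internal_coordinates <- function(mol) {
  co <- mol$coords
  bonds <- data.frame(i = mol$bonds$i, j = mol$bonds$j, r = mol$bonds$length)
  n <- nrow(mol$atoms)
  adj <- lapply(seq_len(n), function(a) sort(mol_neighbors(mol, a)))

  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    for (x in seq_len(length(nb) - 1L)) for (y in seq((x + 1L), length(nb))) {
      i <- nb[x]; k <- nb[y]
      ang[[length(ang) + 1L]] <- c(i, j, k,
                                   vec_angle(co[i, ], co[j, ], co[k, ]))
    }
  }
  angles <- if (length(ang)) {
    m <- do.call(rbind, ang)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
               k = as.integer(m[, 3]), theta = m[, 4])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    theta = numeric())

  tor <- list()
  for (e in seq_len(nrow(mol$bonds))) {
    bb <- mol$bonds$i[e]; cc <- mol$bonds$j[e]
    if (bb > cc) { tmp <- bb; bb <- cc; cc <- tmp }
    for (a in adj[[bb]]) {
      if (a == cc) next
      for (d in adj[[cc]]) {
        if (d == bb || d == a) next
        tor[[length(tor) + 1L]] <-
          c(a, bb, cc, d, vec_dihedral(co[a, ], co[bb, ], co[cc, ], co[d, ]))
      }
    }
  }
  torsions <- if (length(tor)) {
    m <- do.call(rbind, tor)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
               k = as.integer(m[, 3]), l = as.integer(m[, 4]), phi = m[, 5])
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), phi = numeric())

  structure(list(bonds = bonds, angles = angles, torsions = torsions),
            class = "InternalCoordinates")
}
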