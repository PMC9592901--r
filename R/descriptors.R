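# Fixed-width atomic descriptors of the three bonded shells around a
# reference atom. The manifest is the single source of truth for the layout;
# the default layout totals exactly 241 features per atom:
#   reference block ... 22  (element one-hot x9, EN, radius, valence,
#                            hybridization indicators sp/sp2/sp3, aromatic,
#                            ring, fused ring, chiral, axial, donor, acceptor)
#   shell slots ....... 216 (4 + 8 + 12 slots x 9 features each: presence,
#                            atomic number, EN, bond order to parent, bond
#                            length to parent, aromatic, ring, sp2, sp3)
#   overflow flags .... 3   (one per shell)
# Absent neighbors stay at the padding value with presence = 0, so the
# vector width never varies.

SLOT_FEATURES <- c("presence", "atomic_number", "electronegativity",
                   "bond_order_parent", "bond_length_parent", "aromatic",
                   "in_ring", "sp2", "sp3")

#' Default descriptor manifest
#'
#' Describes the fixed 241-wide per-atom feature layout: the reference-atom
#' block, per-shell slot counts (4, 8, 12) and per-slot features, the
#' padding value for absent neighbors, and a version string frozen alongside
#' trained models.
#'
#' @param slots_per_shell integer vector of slot counts for shells 1-3.
#' @param padding padding value for absent-neighbor slots.
#' @return object of class `DescriptorManifest`.
#' @export
default_manifest <- function(slots_per_shell = c(4L, 8L, 12L), padding = 0) {
  ref <- c(paste0("ref_is_", FF_ELEMENTS), "ref_electronegativity",
           "ref_covalent_radius", "ref_valence",
           paste0("ref_hyb_", c("sp", "sp2", "sp3")),
           "ref_aromatic", "ref_in_ring", "ref_in_fused_ring", "ref_chiral",
           "ref_axial", "ref_h_donor", "ref_h_acceptor")
  slot_names <- unlist(lapply(1:3, function(s)
    unlist(lapply(seq_len(slots_per_shell[s]), function(k)
      paste0("s", s, "_", k, "_", SLOT_FEATURES)))))
  feature_names <- c(ref, slot_names, paste0("overflow_shell", 1:3))
  structure(list(version = "ffforge-241-v1",
                 ref_features = ref,
                 slots_per_shell = as.integer(slots_per_shell),
                 slot_features = SLOT_FEATURES,
                 padding = padding,
                 feature_names = feature_names,
                 width = length(feature_names)),
            class = "DescriptorManifest")
}

#' @export
print.DescriptorManifest <- function(x, ...) {
  cat(sprintf("<DescriptorManifest> %s: width %d (%d ref + %s slots x %d + 3 overflow)\n",
              x$version, x$width, length(x$ref_features),
              paste(x$slots_per_shell, collapse = "/"),
              length(x$slot_features)))
  invisible(x)
}

#' Serialize / restore a descriptor manifest
#'
#' @param manifest a `DescriptorManifest`.
#' @param path JSON file path.
#' @rdname manifest_io
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$slots_per_shell <- as.integer(m$slots_per_shell)
  structure(m, class = "DescriptorManifest")
}

# reference block of one atom (length 22)
atom_ref_block <- function(mol, a) {
  at <- mol$atoms[a, ]
  c(as.numeric(FF_ELEMENTS == at$element),
    at$electronegativity, at$covalent_radius, at$valence,
    as.numeric(c("sp", "sp2", "sp3") == at$hybridization),
    as.numeric(c(at$aromatic, at$in_ring, at$in_fused_ring, at$chiral,
                 at$axial, at$h_donor, at$h_acceptor)))
}

# precomputed per-molecule featurization context: graph distances, O(1)
# bond lookups, and the static parts of the reference and slot blocks.
# Building it once per molecule keeps featurization linear-ish in atoms.
mol_context <- function(mol) {
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  n <- nrow(mol$atoms)
  b <- mol$bonds
  eid <- matrix(0L, n, n)
  if (nrow(b) > 0L) {
    eid[cbind(b$i, b$j)] <- seq_len(nrow(b))
    eid[cbind(b$j, b$i)] <- seq_len(nrow(b))
  }
  at <- mol$atoms
  slot_static <- cbind(
    1,
    element_property(at$element, "atomic_number"),
    at$electronegativity, 0, 0,
    as.numeric(at$aromatic), as.numeric(at$in_ring),
    as.numeric(at$hybridization == "sp2"),
    as.numeric(at$hybridization == "sp3"))
  ref_blocks <- t(vapply(seq_len(n), function(a) atom_ref_block(mol, a),
                         numeric(22L)))
  list(mol = mol,
       dist = igraph::distances(mol_graph(mol)),
       eid = eid,
       ordnum = bond_order_numeric(b$order, b$aromatic),
       blen = b$length,
       slot_static = slot_static,
       ref_blocks = ref_blocks)
}

# slot features of shell member m (parent = closest previous-shell neighbor;
# with several tree parents, max bond order and min bond length are used so
# the encoding is independent of input atom order)
slot_block <- function(ctx, m, prev_shell) {
  eids <- ctx$eid[m, prev_shell]
  eids <- eids[eids > 0L]
  row <- ctx$slot_static[m, ]
  if (length(eids) > 0L) {
    row[4] <- max(ctx$ordnum[eids])
    row[5] <- min(ctx$blen[eids])
  }
  row
}

#' Featurize one atom
#'
#' Builds the fixed 241-entry descriptor of an atom's chemical environment.
#' Within each shell, members are ordered canonically by their full slot
#' feature vector (lexicographically), so the result is invariant to input
#' atom ordering; shells with more members than slots keep the
#' canonically-first ones and set the shell's overflow flag.
#'
#' @param mol perceived `Molecule`.
#' @param atom_index 1-based atom index.
#' @param manifest a `DescriptorManifest` of width 241.
#' @param ctx optional precomputed [mol_context()] (internal fast path).
#' @return numeric vector of length `manifest$width`.
#' @export
featurize_atom <- function(mol, atom_index, manifest = default_manifest(),
                           ctx = NULL) {
  if (manifest$width != 241L) stop("manifest mismatch: width must be 241")
  if (is.null(ctx)) ctx <- mol_context(mol)
  vec <- ctx$ref_blocks[atom_index, ]
  overflow <- numeric(3)
  slot_w <- length(manifest$slot_features)
  d <- ctx$dist[atom_index, ]
  for (s in 1:3) {
    members <- which(d == s)
    prev <- which(d == s - 1L)
    blocks <- lapply(members, function(m) slot_block(ctx, m, prev))
    if (length(blocks) > 1L) {
      keymat <- do.call(rbind, blocks)
      ord <- do.call(order, as.data.frame(keymat))
      blocks <- blocks[ord]
    }
    nslot <- manifest$slots_per_shell[s]
    if (length(blocks) > nslot) {
      overflow[s] <- 1
      blocks <- blocks[seq_len(nslot)]
    }
    shell_vec <- rep(manifest$padding, nslot * slot_w)
    if (length(blocks) > 0L) {
      filled <- unlist(blocks)
      shell_vec[seq_along(filled)] <- filled
    }
    vec <- c(vec, shell_vec)
  }
  out <- c(vec, overflow)
  names(out) <- manifest$feature_names
  out
}

#' Featurize one proper torsion
#'
#' Concatenates the four atoms' full descriptors with the signed dihedral
#' value appended. The quadruple is canonicalized so a torsion and its
#' reversal give identical vectors (the signed dihedral is itself invariant
#' under reversal).
#'
#' @param mol perceived `Molecule`.
#' @param torsion integer vector (a, b, c, d) of atom indices.
#' @param manifest a `DescriptorManifest`.
#' @param ctx optional precomputed [mol_context()] (internal fast path).
#' @return numeric vector of length `4 * manifest$width + 1`; the last entry
#'   (`dihedral_deg`) is the dihedral in degrees in (-180, 180].
#' @export
featurize_torsion <- function(mol, torsion, manifest = default_manifest(),
                              ctx = NULL) {
  if (is.null(ctx)) ctx <- mol_context(mol)
  mol <- ctx$mol
  t <- as.integer(torsion)
  if (length(t) != 4L) stop("not a torsion")
  ok <- ctx$eid[t[1], t[2]] > 0L && ctx$eid[t[2], t[3]] > 0L &&
    ctx$eid[t[3], t[4]] > 0L &&
    t[1] != t[4] && length(unique(t[1:3])) == 3L &&
    length(unique(t[2:4])) == 3L
  if (!ok) stop("not a torsion")
  af <- atom_feature_matrix(mol, manifest, ctx)
  co <- mol$coords
  phi <- vec_dihedral(co[t[1], ], co[t[2], ], co[t[3], ], co[t[4], ])
  torsion_row(af, t, phi)
}

torsion_row <- function(af, t, phi) {
  fwd <- as.vector(t(af[t, , drop = FALSE]))
  bwd <- as.vector(t(af[rev(t), , drop = FALSE]))
  diff <- which(fwd != bwd)
  pick <- if (length(diff) == 0L || fwd[diff[1]] <= bwd[diff[1]]) fwd else bwd
  c(pick, dihedral_deg = phi)
}

#' Featurize every atom of a molecule
#'
#' Convenience wrapper returning the full atom-descriptor matrix (one
#' 241-wide row per atom), sharing one precomputed context across atoms.
#'
#' @param mol perceived `Molecule`.
#' @param manifest a `DescriptorManifest`.
#' @param ctx optional precomputed context (internal fast path).
#' @return numeric matrix, `nrow(mol$atoms)` x `manifest$width`.
#' @export
atom_feature_matrix <- function(mol, manifest = default_manifest(),
                                ctx = NULL) {
  if (is.null(ctx)) ctx <- mol_context(mol)
  if (!is.null(ctx$af_cache)) return(ctx$af_cache)
  t(vapply(seq_len(nrow(ctx$mol$atoms)), function(a)
    featurize_atom(ctx$mol, a, manifest, ctx), numeric(manifest$width)))
}

# per-molecule matrix of reference blocks (rows = atoms)
ref_block_matrix <- function(mol) {
  t(vapply(seq_len(nrow(mol$atoms)), function(a) atom_ref_block(mol, a),
           numeric(22L)))
}

# bond descriptor: two reference blocks in canonical order + numeric bond
# order + bond length (width 46)
featurize_bond <- function(mol, i, j, rb = ref_block_matrix(mol)) {
  e <- bond_between(mol, i, j)
  if (is.na(e)) stop("atoms are not bonded")
  bi <- rb[i, ]; bj <- rb[j, ]
  if (any(bi != bj)) {
    first <- which(bi != bj)[1]
    if (bi[first] > bj[first]) { tmp <- bi; bi <- bj; bj <- tmp }
  }
  c(bi, bj,
    bond_order_numeric(mol$bonds$order[e], mol$bonds$aromatic[e]),
    mol$bonds$length[e])
}

# angle descriptor: center block + two canonically ordered flank blocks +
# the angle value in degrees (width 67)
featurize_angle <- function(mol, i, j, k, rb = ref_block_matrix(mol)) {
  bi <- rb[i, ]; bk <- rb[k, ]
  if (any(bi != bk)) {
    first <- which(bi != bk)[1]
    if (bi[first] > bk[first]) { tmp <- bi; bi <- bk; bk <- tmp }
  }
  theta <- vec_angle(mol$coords[i, ], mol$coords[j, ], mol$coords[k, ])
  c(rb[j, ], bi, bk, theta)
}

#' Build an aligned feature/label dataset
#'
#' Assembles the feature matrix and label vector the model heads train on,
#' with row provenance (molecule, atom or torsion indices) retained.
#'
#' @param mols list of perceived `Molecule` objects.
#' @param label_fun function of a `Molecule` returning per-row labels: a
#'   numeric vector (one per atom) for `kind = "atom"`, or a vector aligned
#'   with `internal_coordinates(mol)$torsions` rows for `kind = "torsion"`.
#' @param kind `"atom"` or `"torsion"`.
#' @param manifest a `DescriptorManifest`.
#' @return object of class `TrainingDataset`: list with `features` (matrix),
#'   `labels`, `provenance` (data.frame).
#' @export
build_dataset <- function(mols, label_fun, kind = c("atom", "torsion"),
                          manifest = default_manifest()) {
  kind <- match.arg(kind)
  feats <- list(); labs <- list(); prov <- list()
  for (nm in seq_along(mols)) {
    mol <- mols[[nm]]
    if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
    ctx <- mol_context(mol)
    if (kind == "atom") {
      y <- label_fun(mol)
      if (length(y) != nrow(mol$atoms))
        stop("incomplete labels for molecule ", mol$name)
      f <- atom_feature_matrix(mol, manifest, ctx)
      p <- data.frame(molecule = mol$name,
                      row_id = seq_len(nrow(mol$atoms)))
    } else {
      tors <- internal_coordinates(mol)$torsions
      if (nrow(tors) == 0L) next
      y <- label_fun(mol)
      if (length(y) != nrow(tors))
        stop("incomplete labels for molecule ", mol$name)
      af <- atom_feature_matrix(mol, manifest, ctx)
      f <- t(vapply(seq_len(nrow(tors)), function(r)
        torsion_row(af, c(tors$i[r], tors$j[r], tors$k[r], tors$l[r]),
                    tors$phi[r]),
        numeric(4L * manifest$width + 1L)))
      p <- data.frame(molecule = mol$name, row_id = seq_len(nrow(tors)))
    }
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- y
    prov[[length(prov) + 1L]] <- p
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    matrix(numeric(), 0L, manifest$width)
  labels <- if (length(labs)) do.call(c, labs) else numeric()
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(molecule = character(), row_id = integer())
  structure(list(features = features, labels = labels,
                 provenance = provenance, manifest = manifest, kind = kind),
            class = "TrainingDataset")
}

#' @export
print.TrainingDataset <- function(x, ...) {
  cat(sprintf("<TrainingDataset> %s: %d rows x %d features from %d molecules\n",
              x$kind, nrow(x$features), ncol(x$features),
              length(unique(x$provenance$molecule))))
  invisible(x)
}
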