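# Deterministic GAFF-style atom typing. This is the label oracle the
# classifier head trains against and the reference for the worked
# cyclopentanone/aniline examples. Rules are an ordered first-match-wins
# list over the perceived atom environment; within the mutually confusable
# sp2-carbon pairs (cc/cd, ce/cf, cp/cq) a single representative of each
# pair is emitted, which shares its van der Waals parameters with the twin.

GAFF_TYPE_VOCABULARY <- c(
  "c", "c1", "c2", "c3", "ca", "cc", "cd", "ce", "cf", "cg", "ch", "cp",
  "cq", "cv", "cx", "cy",
  "h1", "h2", "h3", "h4", "h5", "ha", "hc", "hn", "ho", "hp", "hs", "hx",
  "n", "n1", "n2", "n3", "n4", "na", "nb", "nc", "nd", "ne", "nf", "nh",
  "nj", "nm", "no", "np", "nq",
  "o", "oh", "op", "os",
  "p3", "p5", "py",
  "s", "s4", "s6", "sh", "ss", "sx", "sy",
  "f", "cl", "br"
)

# electron-withdrawing neighbor elements used for hydrogen subtyping
EWD_ELEMENTS <- c("N", "O", "F", "Cl", "Br", "S")

# local environment summary consumed by the rules
atom_env <- function(mol, a) {
  nb <- mol_neighbors(mol, a)
  eids <- vapply(nb, function(x) bond_between(mol, a, x), integer(1))
  ords <- if (length(eids)) mol$bonds$order[eids] else character()
  arom <- if (length(eids)) mol$bonds$aromatic[eids] else logical()
  list(a = a,
       element = mol$atoms$element[a],
       hyb = mol$atoms$hybridization[a],
       aromatic = mol$atoms$aromatic[a],
       in_ring = mol$atoms$in_ring[a],
       degree = length(nb),
       neighbors = nb,
       nb_elements = mol$atoms$element[nb],
       nb_hyb = mol$atoms$hybridization[nb],
       nb_aromatic = mol$atoms$aromatic[nb],
       nb_degree = mol$atoms$valence[nb],
       bond_orders = ords,
       bond_aromatic = arom,
       ring_sizes = if (is.null(mol$rings)) integer() else
         lengths(mol$rings)[vapply(mol$rings, function(r) a %in% r,
                                   logical(1))])
}

type_hydrogen <- function(env, mol) {
  p <- env$neighbors[1]
  pel <- mol$atoms$element[p]
  if (pel == "O") return("ho")
  if (pel == "N") return("hn")
  if (pel == "S") return("hs")
  if (pel == "P") return("hp")
  if (pel != "C") return(NA_character_)
  penv <- atom_env(mol, p)
  # H on carbon adjacent to a four-coordinate (protonated) nitrogen
  if (any(penv$nb_degree[penv$nb_elements == "N"] == 4L)) return("hx")
  new <- sum(penv$nb_elements %in% EWD_ELEMENTS)
  if (penv$hyb %in% c("sp2", "sp")) {
    if (new == 0L) return("ha")
    if (new == 1L) return("h4")
    return("h5")
  }
  c("hc", "h1", "h2", "h3")[min(new, 3L) + 1L]
}

type_oxygen <- function(env, mol) {
  if (any(env$nb_elements == "H")) return("oh")
  if (env$degree == 1L) return("o")    # carbonyl, nitro, carboxylate, P=O
  if (any(env$nb_elements == "P")) return("op")
  "os"
}

type_nitrogen <- function(env, mol) {
  n_o_dbl <- sum(env$nb_elements == "O" & env$bond_orders == "2")
  if (n_o_dbl >= 2L) return("no")
  if (env$degree == 4L) return("n4")
  if (env$aromatic) return(if (env$degree == 2L) "nb" else "na")
  # amide: single-bonded to a carbonyl carbon
  for (k in seq_along(env$neighbors)) {
    x <- env$neighbors[k]
    if (env$nb_elements[k] == "C" && env$bond_orders[k] %in% c("1", "ar")) {
      xenv <- atom_env(mol, x)
      if (any(xenv$nb_elements %in% c("O", "S") & xenv$bond_orders == "2"))
        return("n")
    }
  }
  if (env$hyb == "sp") return("n1")
  if (any(env$bond_orders == "2")) return("n2")
  if (any(env$nb_aromatic)) return("nh")
  "n3"
}

type_carbon <- function(env, mol) {
  if (env$hyb == "sp") return("c1")
  if (env$aromatic) {
    # five-membered aromatic rings use the cc/cd family, not ca
    if (5L %in% env$ring_sizes && !6L %in% env$ring_sizes) return("cc")
    # biphenyl-style bridge: aromatic C single-bonded to another aromatic C
    # in a different ring (cp; its twin cq is not emitted)
    bridge <- env$nb_aromatic & env$bond_orders == "1" & !env$bond_aromatic
    if (any(bridge)) return("cp")
    return("ca")
  }
  if (env$hyb == "sp2") {
    if (any(env$nb_elements %in% c("O", "S") & env$bond_orders == "2"))
      return("c")
    conj <- env$bond_orders == "1" & env$nb_hyb %in% c("sp2", "sp")
    if (env$in_ring && any(conj)) return("cc")   # twin cd not emitted
    if (any(conj)) return("ce")                  # twin cf not emitted
    return("c2")
  }
  if (env$hyb == "sp3") {
    if (3L %in% env$ring_sizes) return("cx")
    if (4L %in% env$ring_sizes) return("cy")
    return("c3")
  }
  NA_character_
}

type_sulfur <- function(env, mol) {
  if (any(env$nb_elements == "H")) return("sh")
  if (env$degree <= 1L) return("s")
  if (env$degree == 2L && all(env$bond_orders %in% c("1", "ar"))) return("ss")
  if (env$degree == 2L) return("s")            # sp2 =S with one substituent
  if (env$degree == 3L) return("s4")
  "s6"
}

type_phosphorus <- function(env, mol) {
  if (env$degree >= 4L) return("p5")
  "p3"
}

#' Assign GAFF-style atom types
#'
#' Deterministic rule-based typing over the perceived environment; one code
#' per atom from the GAFF vocabulary. Within the mutually confusable
#' sp2-carbon pairs (cc/cd, ce/cf, cp/cq) the first member is always
#' emitted; both members share van der Waals parameters, so downstream
#' Lennard-Jones assignment is unaffected.
#'
#' @param mol perceived `Molecule`.
#' @return character vector of atom-type codes, one per atom.
#' @export
assign_atom_types <- function(mol) {
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  vapply(seq_len(nrow(mol$atoms)), function(a) {
    env <- atom_env(mol, a)
    code <- switch(env$element,
                   H = type_hydrogen(env, mol),
                   C = type_carbon(env, mol),
                   N = type_nitrogen(env, mol),
                   O = type_oxygen(env, mol),
                   S = type_sulfur(env, mol),
                   P = type_phosphorus(env, mol),
                   F = "f", Cl = "cl", Br = "br",
                   NA_character_)
    if (is.na(code))
      stop(sprintf(
        "untypeable atom %d: element %s, hybridization %s, degree %d",
        a, env$element, env$hyb, env$degree))
    code
  }, character(1))
}

# pairs the classifier is allowed to confuse without parameter consequences
CONFUSABLE_TYPE_PAIRS <- list(c("cc", "cd"), c("ce", "cf"), c("cp", "cq"),
                              c("nc", "nd"), c("ne", "nf"))

# TRUE where predicted and reference codes agree up to a confusable pair
types_equivalent <- function(pred, ref) {
  same <- pred == ref
  for (p in CONFUSABLE_TYPE_PAIRS)
    same <- same | (pred %in% p & ref %in% p)
  same
}
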