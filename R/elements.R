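# Element property tables for the supported vocabulary.
# Electronegativities: Pauling scale (descriptor use) and Mulliken-scale
# chi/eta in eV (electronegativity-equalization oracle).
# Covalent radii: Cordero et al. single-bond values, Angstrom.

FF_ELEMENTS <- c("C", "H", "O", "N", "S", "P", "F", "Cl", "Br")

FF_ELEMENT_TABLE <- data.frame(
  element        = FF_ELEMENTS,
  atomic_number  = c(6, 1, 8, 7, 16, 15, 9, 17, 35),
  pauling_en     = c(2.55, 2.20, 3.44, 3.04, 2.58, 2.19, 3.98, 3.16, 2.96),
  covalent_radius = c(0.76, 0.31, 0.66, 0.71, 1.05, 1.07, 0.57, 1.02, 1.20),
  mass           = c(12.011, 1.008, 15.999, 14.007, 32.06, 30.974,
                     18.998, 35.45, 79.904),
  # Mulliken electronegativity chi and chemical hardness eta (Pearson), eV
  eem_chi        = c(6.27, 7.18, 7.54, 7.30, 6.22, 5.62, 10.41, 8.29, 7.59),
  eem_eta        = c(5.00, 6.45, 6.08, 7.23, 4.14, 4.88, 7.01, 4.68, 4.22),
  stringsAsFactors = FALSE
)
rownames(FF_ELEMENT_TABLE) <- FF_ELEMENTS

element_property <- function(element, property) {
  bad <- setdiff(unique(element), FF_ELEMENTS)
  if (length(bad) > 0L)
    stop("element out of vocabulary: ", paste(bad, collapse = ", "))
  FF_ELEMENT_TABLE[element, property]
}

# Reference bond lengths (Angstrom) keyed by "A-B:order"; order "ar" for
# aromatic. Fallback is the sum of covalent radii. Used by the idealized
# geometry builder, never by perception (which trusts input coordinates).
FF_BOND_LENGTHS <- c(
  "C-C:1" = 1.54,  "C-C:2" = 1.34,  "C-C:3" = 1.20, "C-C:ar" = 1.39,
  "C-H:1" = 1.09,  "C-O:1" = 1.43,  "C-O:2" = 1.22,
  "C-N:1" = 1.47,  "C-N:2" = 1.28,  "C-N:3" = 1.16, "C-N:ar" = 1.34,
  "C-S:1" = 1.82,  "C-S:2" = 1.60,
  "C-F:1" = 1.35,  "C-Cl:1" = 1.77, "C-Br:1" = 1.94,
  "C-P:1" = 1.84,
  "O-H:1" = 0.96,  "N-H:1" = 1.01,  "S-H:1" = 1.34,  "P-H:1" = 1.42,
  "N-O:1" = 1.40,  "N-O:2" = 1.21,  "N-N:1" = 1.45,  "N-N:2" = 1.25,
  "O-P:1" = 1.63,  "O-P:2" = 1.48,  "O-S:1" = 1.57,  "O-S:2" = 1.45,
  "S-S:1" = 2.05
)

ideal_bond_length <- function(el_i, el_j, order) {
  pair <- sort(c(el_i, el_j))
  key <- paste0(pair[1], "-", pair[2], ":", order)
  if (key %in% names(FF_BOND_LENGTHS)) return(unname(FF_BOND_LENGTHS[[key]]))
  # aromatic fallback: shrink the single-bond value slightly
  if (identical(order, "ar")) {
    key1 <- paste0(pair[1], "-", pair[2], ":1")
    if (key1 %in% names(FF_BOND_LENGTHS))
      return(unname(FF_BOND_LENGTHS[[key1]]) * 0.93)
  }
  sum(element_property(c(el_i, el_j), "covalent_radius"))
}
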