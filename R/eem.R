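# Electronegativity-equalization (EEM) surrogate charges.
# Closed-form linear model used ONLY as a training-label oracle: it has the
# qualitative neighborhood dependence of ESP charges (electron density flows
# toward electronegative atoms, modulated by geometry) but does NOT reproduce
# DFT/ESP values.

#' Default EEM parameters
#'
#' Per-element Mulliken-scale electronegativity chi (eV) and chemical
#' hardness eta (eV/e), with a damped Coulomb coupling between atom pairs.
#' `coupling` is the Coulomb constant (14.4 eV*Angstrom for point charges in
#' vacuum); `damping` (Angstrom) softens short-range interactions via
#' 1/sqrt(r^2 + damping^2).
#'
#' @param coupling Coulomb prefactor, eV*Angstrom; 0 disables geometry
#'   coupling.
#' @param damping short-range damping length, Angstrom.
#' @return object of class `EEMParameters`.
#' @export
eem_parameters <- function(coupling = 14.4, damping = 2.0) {
  structure(list(chi = stats::setNames(FF_ELEMENT_TABLE$eem_chi, FF_ELEMENTS),
                 eta = stats::setNames(FF_ELEMENT_TABLE$eem_eta, FF_ELEMENTS),
                 coupling = coupling, damping = damping),
            class = "EEMParameters")
}

#' Electronegativity-equalization charges
#'
#' Solves the constrained linear system in which every atom's effective
#' electronegativity chi_i + 2 eta_i q_i + sum_j J_ij q_j is equalized and
#' the charges sum to the molecular formal charge. J_ij is a damped Coulomb
#' kernel over the 3D geometry.
#'
#' @param mol a `Molecule`.
#' @param params an `EEMParameters` object.
#' @return numeric vector of per-atom charges (e), summing to the formal
#'   charge to machine precision.
#' @export
eem_charges <- function(mol, params = eem_parameters()) {
  el <- mol$atoms$element
  missing_el <- setdiff(unique(el), names(params$chi))
  if (length(missing_el) > 0L)
    stop("EEM parameters missing for element: ",
         paste(missing_el, collapse = ", "))
  if (any(params$eta[el] <= 0)) stop("degenerate EEM parameters")
  n <- nrow(mol$atoms)
  A <- matrix(0, n + 1L, n + 1L)
  diag(A)[seq_len(n)] <- 2 * params$eta[el]
  if (params$coupling != 0 && n > 1L) {
    d2 <- as.matrix(stats::dist(mol$coords))^2
    J <- params$coupling / sqrt(d2 + params$damping^2)
    diag(J) <- 0
    A[seq_len(n), seq_len(n)] <- A[seq_len(n), seq_len(n)] + J
  }
  A[n + 1L, seq_len(n)] <- 1
  A[seq_len(n), n + 1L] <- 1
  rhs <- c(-params$chi[el], mol$formal_charge)
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("degenerate EEM parameters"))
  unname(sol[seq_len(n)])
}
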