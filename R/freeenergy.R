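# Alchemical decoupling schedule and Bennett Acceptance Ratio estimation.
# Only the estimator layer: energy-difference samples come from an MD
# engine (or, in tests, from constructed distributions); no sampling is
# done here.

#' Gas constant in kcal/mol/K
#' @keywords internal
R_KCAL <- 0.0019872041

#' Build a ligand-decoupling lambda schedule
#'
#' Coulomb interactions are switched off first on a uniform grid
#' (step 0.25 by default: 0, 0.25, 0.5, 0.75, 1), then van der Waals
#' interactions on a non-uniform grid concentrated near full decoupling.
#' The defaults give 5 + 15 = 20 windows.
#'
#' @param coulomb_step uniform Coulomb lambda step (fraction of 1).
#' @param vdw_values increasing vdW lambda values ending at 1.
#' @return object of class `LambdaSchedule` with `coulomb`, `vdw`,
#'   `n_windows` and the adjacent `window_pairs`.
#' @export
build_lambda_schedule <- function(coulomb_step = 0.25,
                                  vdw_values = c(0.05, 0.1, 0.2, 0.3, 0.4,
                                                 0.5, 0.6, 0.65, 0.7, 0.75,
                                                 0.8, 0.85, 0.9, 0.95,
                                                 1.0)) {
  if (coulomb_step <= 0 || coulomb_step > 1)
    stop("coulomb_step must be in (0, 1]")
  coulomb <- seq(0, 1, by = coulomb_step)
  if (coulomb[length(coulomb)] != 1) coulomb <- c(coulomb, 1)
  vdw <- as.numeric(vdw_values)
  if (any(diff(vdw) <= 0) || vdw[length(vdw)] != 1)
    stop("vdw_values must be strictly increasing and end at 1")
  states <- data.frame(
    leg = c(rep("coulomb", length(coulomb)), rep("vdw", length(vdw))),
    lambda = c(coulomb, vdw))
  pairs <- data.frame(from = seq_len(nrow(states) - 1L),
                      to = seq(2L, nrow(states)))
  structure(list(coulomb = coulomb, vdw = vdw, states = states,
                 window_pairs = pairs,
                 n_windows = length(coulomb) + length(vdw)),
            class = "LambdaSchedule")
}

#' @export
print.LambdaSchedule <- function(x, ...) {
  cat(sprintf("<LambdaSchedule> %d windows: %d coulomb (%s) + %d vdw\n",
              x$n_windows, length(x$coulomb),
              paste(x$coulomb, collapse = ", "), length(x$vdw)))
  invisible(x)
}

#' Package forward/reverse energy-difference samples
#'
#' @param forward Delta U_ij samples evaluated in state i (kcal/mol).
#' @param reverse Delta U_ji samples evaluated in state j (kcal/mol).
#' @param temperature K; beta = 1/(RT) is derived from it.
#' @return object of class `EnergyDifferenceSamples`.
#' @export
energy_difference_samples <- function(forward, reverse,
                                      temperature = 298) {
  forward <- as.numeric(forward); reverse <- as.numeric(reverse)
  if (length(forward) == 0L || length(reverse) == 0L)
    stop("both sample directions must be non-empty")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(forward = forward, reverse = reverse,
                 beta = 1 / (R_KCAL * temperature),
                 temperature = temperature),
            class = "EnergyDifferenceSamples")
}

fermi <- function(x) 1 / (1 + exp(x))

# balance function: mean_i f(beta(dU_f - dG)) - mean_j f(beta(dU_r + dG));
# strictly increasing in dG, so the root is unique when the work
# distributions overlap
bar_balance <- function(dG, s) {
  mean(fermi(s$beta * (s$forward - dG))) -
    mean(fermi(s$beta * (s$reverse + dG)))
}

#' Bennett Acceptance Ratio estimate for one window pair
#'
#' Solves the self-consistent BAR balance
#' \deqn{\langle f(\beta(\Delta U_{ij} - \Delta G))\rangle_i =
#'       \langle f(\beta(\Delta U_{ji} + \Delta G))\rangle_j}
#' (f the Fermi function) by monotone bracketing to 1e-8 kcal/mol, with the
#' asymptotic-variance standard error evaluated at the solution.
#'
#' @param samples an `EnergyDifferenceSamples` object.
#' @param tol root tolerance, kcal/mol.
#' @return object of class `FreeEnergyResult`: `dG`, `se` (kcal/mol), the
#'   sample sizes and temperature.
#' @export
bar_estimate <- function(samples, tol = 1e-8) {
  s <- samples
  # bracket around the exponential-averaging one-sided estimates
  lo <- min(-mean(s$reverse), mean(s$forward)) - 50 / s$beta
  hi <- max(-mean(s$reverse), mean(s$forward)) + 50 / s$beta
  flo <- bar_balance(lo, s); fhi <- bar_balance(hi, s)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("insufficient overlap between forward and reverse distributions")
  root <- stats::uniroot(bar_balance, c(lo, hi), s = s, tol = tol)
  dG <- root$root
  fF <- fermi(s$beta * (s$forward - dG))
  fR <- fermi(s$beta * (s$reverse + dG))
  # degenerate balance (all Fermi weights underflow) means the two work
  # distributions never cross: the root is meaningless
  if (mean(fF) <= 0 || mean(fR) <= 0)
    stop("insufficient overlap between forward and reverse distributions")
  var_dG <- (1 / s$beta^2) *
    ((mean(fF^2) / mean(fF)^2 - 1) / length(fF) +
       (mean(fR^2) / mean(fR)^2 - 1) / length(fR))
  if (!is.finite(var_dG))
    stop("insufficient overlap between forward and reverse distributions")
  structure(list(dG = dG, se = sqrt(max(var_dG, 0)),
                 n_forward = length(s$forward),
                 n_reverse = length(s$reverse),
                 temperature = s$temperature),
            class = "FreeEnergyResult")
}

#' @export
print.FreeEnergyResult <- function(x, ...) {
  cat(sprintf("<FreeEnergyResult> dG = %.4f +/- %.4f kcal/mol (n = %d/%d, %g K)\n",
              x$dG, x$se, x$n_forward, x$n_reverse, x$temperature))
  invisible(x)
}

#' Total solvation free energy from per-window results
#'
#' The windows decouple the ligand from solvent, so the solvation free
#' energy is minus the summed window free energies; window standard errors
#' combine in quadrature.
#'
#' @param window_results list of `FreeEnergyResult`s.
#' @return a `FreeEnergyResult` for the full decoupling.
#' @export
total_solvation_dG <- function(window_results) {
  if (length(window_results) == 0L) stop("need at least one window")
  dGs <- vapply(window_results, `[[`, numeric(1), "dG")
  ses <- vapply(window_results, `[[`, numeric(1), "se")
  structure(list(dG = -sum(dGs), se = sqrt(sum(ses^2)),
                 n_forward = NA_integer_, n_reverse = NA_integer_,
                 temperature = window_results[[1]]$temperature,
                 per_window = dGs),
            class = "FreeEnergyResult")
}

#' Read one window's energy-difference samples from a text file
#'
#' Plain two-column whitespace-separated text: direction (`F`/`R`) and
#' Delta U in kcal/mol.
#'
#' @param path file path.
#' @param temperature K.
#' @return an `EnergyDifferenceSamples`.
#' @export
read_window_samples <- function(path, temperature = 298) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("direction", "dU"),
                         stringsAsFactors = FALSE)
  energy_difference_samples(d$dU[toupper(d$direction) == "F"],
                            d$dU[toupper(d$direction) == "R"],
                            temperature = temperature)
}
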