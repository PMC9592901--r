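# GROMACS topology writer and validating reader. AMBER-dialect conventions:
# nbfunc 1 (Lennard-Jones), combination rule 2 (sigma/epsilon), fudgeLJ 0.5,
# fudgeQQ 0.8333, bond/angle function 1, proper dihedrals function 9,
# periodic impropers function 4. Unit conversions at the boundary:
# kcal -> kJ (x 4.184), Angstrom -> nm, and the Eq-style K(r-r0)^2 harmonic
# constants are doubled into the GROMACS (k/2)(r-r0)^2 convention.

KCAL2KJ <- 4.184

#' Write a topology as a GROMACS file
#'
#' Emits a self-contained `.top`/`.itp` with `[defaults]`, `[atomtypes]`,
#' `[moleculetype]`, `[atoms]`, `[bonds]`, `[pairs]`, `[angles]` and the
#' two `[dihedrals]` blocks (function 9 propers, function 4 periodic
#' impropers). Sections with no terms are omitted.
#'
#' @param top a `Topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gromacs <- function(top, path) {
  out <- c(
    "; ffforge GROMACS topology",
    sprintf("; molecule: %s", top$name),
    "",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    "1 2 yes 0.500000 0.833300",
    "",
    "[ atomtypes ]",
    "; name mass charge ptype sigma(nm) epsilon(kJ/mol)")
  ut <- !duplicated(top$atoms$type)
  out <- c(out, sprintf("%-4s %10.6f 0.000000 A %12.8f %12.8f",
                        top$atoms$type[ut], top$atoms$mass[ut],
                        top$atoms$sigma[ut], top$atoms$epsilon[ut]))
  out <- c(out, "", "[ moleculetype ]", "; name nrexcl",
           sprintf("%s 3", gsub("\\s+", "_", top$name)),
           "", "[ atoms ]",
           "; nr type resnr residue atom cgnr charge mass")
  out <- c(out, sprintf("%4d %-4s 1 MOL %-4s %4d %12.8f %10.6f",
                        top$atoms$index, top$atoms$type,
                        paste0(top$atoms$element, top$atoms$index),
                        top$atoms$index, top$atoms$charge,
                        top$atoms$mass))
  if (nrow(top$bonds) > 0L) {
    out <- c(out, "", "[ bonds ]", "; i j func b0(nm) kb(kJ/mol/nm2)",
             sprintf("%4d %4d 1 %12.8f %14.6f", top$bonds$i, top$bonds$j,
                     top$bonds$r0 / 10, 2 * top$bonds$kb * KCAL2KJ * 100))
  }
  if (nrow(top$pairs14) > 0L) {
    out <- c(out, "", "[ pairs ]", "; i j func",
             sprintf("%4d %4d 1", top$pairs14$i, top$pairs14$l))
  }
  if (nrow(top$angles) > 0L) {
    out <- c(out, "", "[ angles ]",
             "; i j k func th0(deg) cth(kJ/mol/rad2)",
             sprintf("%4d %4d %4d 1 %12.6f %14.6f", top$angles$i,
                     top$angles$j, top$angles$k, top$angles$theta0,
                     2 * top$angles$ktheta * KCAL2KJ))
  }
  if (nrow(top$dihedrals) > 0L) {
    out <- c(out, "", "[ dihedrals ]",
             "; i j k l func phase(deg) kphi(kJ/mol) pn",
             sprintf("%4d %4d %4d %4d 9 %10.4f %12.6f %d",
                     top$dihedrals$i, top$dihedrals$j, top$dihedrals$k,
                     top$dihedrals$l, top$dihedrals$phase,
                     top$dihedrals$kphi * KCAL2KJ,
                     top$dihedrals$periodicity))
  }
  if (nrow(top$impropers) > 0L) {
    out <- c(out, "", "[ dihedrals ]",
             "; improper dihedrals (periodic, func 4)",
             sprintf("%4d %4d %4d %4d 4 %10.4f %12.6f %d",
                     top$impropers$i, top$impropers$j, top$impropers$k,
                     top$impropers$l, top$impropers$phase,
                     top$impropers$kphi * KCAL2KJ,
                     top$impropers$periodicity))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a GROMACS topology written by [write_gromacs()]
#'
#' Validating reader for the dialect this package writes; converts back to
#' the internal units (Angstrom, kcal, K(r-r0)^2 convention) so that a
#' write/read round trip reproduces the `Topology` values.
#'
#' @param path file path.
#' @return a `Topology`.
#' @export
read_gromacs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- sub("^; molecule: ", "",
              grep("^; molecule: ", lines, value = TRUE)[1])
  lines <- trimws(sub(";.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- ""; dihedral_block <- 0L
  lj <- list(); atoms <- list(); bonds <- list(); pairs <- list()
  angles <- list(); dih <- list(); imp <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      if (section == "dihedrals") dihedral_block <- dihedral_block + 1L
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (section == "atomtypes") {
      lj[[f[1]]] <- c(mass = as.numeric(f[2]), sigma = as.numeric(f[5]),
                      epsilon = as.numeric(f[6]))
    } else if (section == "atoms") {
      atoms[[length(atoms) + 1L]] <- data.frame(
        index = as.integer(f[1]), type = f[2],
        element = sub("[0-9]+$", "", f[5]),
        charge = as.numeric(f[7]), mass = as.numeric(f[8]))
    } else if (section == "bonds") {
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]),
        r0 = as.numeric(f[4]) * 10,
        kb = as.numeric(f[5]) / (2 * KCAL2KJ * 100))
    } else if (section == "pairs") {
      pairs[[length(pairs) + 1L]] <- data.frame(i = as.integer(f[1]),
                                                l = as.integer(f[2]))
    } else if (section == "angles") {
      angles[[length(angles) + 1L]] <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        theta0 = as.numeric(f[5]), ktheta = as.numeric(f[6]) /
          (2 * KCAL2KJ))
    } else if (section == "dihedrals") {
      row <- data.frame(
        i = as.integer(f[1]), j = as.integer(f[2]), k = as.integer(f[3]),
        l = as.integer(f[4]), phase = as.numeric(f[6]),
        periodicity = as.integer(f[8]),
        kphi = as.numeric(f[7]) / KCAL2KJ)
      if (f[5] == "9") dih[[length(dih) + 1L]] <- row
      else imp[[length(imp) + 1L]] <- row
    }
  }
  atoms <- do.call(rbind, atoms)
  ljm <- do.call(rbind, lj[atoms$type])
  atoms$sigma <- ljm[, "sigma"]; atoms$epsilon <- ljm[, "epsilon"]
  empty_tor <- data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), phase = numeric(),
                          periodicity = integer(), kphi = numeric())
  reord <- function(d) d[, c("i", "j", "k", "l", "phase", "periodicity",
                             "kphi")]
  structure(list(
    name = name,
    atoms = atoms[, c("index", "element", "type", "charge", "mass",
                      "sigma", "epsilon")],
    bonds = if (length(bonds)) do.call(rbind, bonds) else
      data.frame(i = integer(), j = integer(), r0 = numeric(),
                 kb = numeric()),
    angles = if (length(angles)) do.call(rbind, angles) else
      data.frame(i = integer(), j = integer(), k = integer(),
                 theta0 = numeric(), ktheta = numeric()),
    dihedrals = if (length(dih)) reord(do.call(rbind, dih)) else empty_tor,
    impropers = if (length(imp)) reord(do.call(rbind, imp)) else empty_tor,
    pairs14 = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(i = integer(), l = integer()),
    formal_charge = as.integer(round(sum(atoms$charge)))),
    class = "Topology")
}
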