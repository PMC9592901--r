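# GAFF-format parameter table: Lennard-Jones well depths/radii and masses
# per atom type, plus torsion barrier heights keyed on the central-bond type
# pair. The packaged table (inst/extdata/gaff_params.dat) carries the GAFF
# values for every type the rule set can emit; users may supply their own
# file in the same format.

#' Read a GAFF-format parameter table
#'
#' The file has two sections. `[ atomtypes ]` rows are
#' `type mass rmin_half epsilon` with rmin_half in Angstrom and epsilon in
#' kcal/mol (the GAFF convention); `[ dihedraltypes ]` rows are
#' `type_j type_k kphi` giving the torsion barrier (kcal/mol) for a central
#' bond between the two types, `X` acting as a wildcard. `;` starts a
#' comment.
#'
#' @param path table file; default is the table shipped with the package.
#' @return object of class `ParameterTable`.
#' @export
read_parameter_table <- function(path = system.file("extdata",
                                                    "gaff_params.dat",
                                                    package = "ffforge")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub(";.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- ""
  lj <- list(); dih <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("[][ ]", "", ln)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (section == "atomtypes") {
      lj[[length(lj) + 1L]] <- data.frame(
        type = f[1], mass = as.numeric(f[2]),
        rmin_half = as.numeric(f[3]), epsilon = as.numeric(f[4]))
    } else if (section == "dihedraltypes") {
      dih[[length(dih) + 1L]] <- data.frame(
        tj = f[1], tk = f[2], kphi = as.numeric(f[3]))
    }
  }
  structure(list(lj = do.call(rbind, lj),
                 dihedral = if (length(dih)) do.call(rbind, dih) else
                   data.frame(tj = character(), tk = character(),
                              kphi = numeric())),
            class = "ParameterTable")
}

# LJ lookup; sigma returned in nm, epsilon in kJ/mol (GROMACS units)
lj_parameters <- function(params, type) {
  hit <- match(type, params$lj$type)
  if (any(is.na(hit)))
    stop("parameter table incomplete: ",
         paste(unique(type[is.na(hit)]), collapse = ", "))
  rmin_half <- params$lj$rmin_half[hit]
  data.frame(type = type,
             mass = params$lj$mass[hit],
             sigma = 2 * rmin_half / 2^(1 / 6) / 10,
             epsilon = params$lj$epsilon[hit] * 4.184)
}

# torsion barrier (kcal/mol) for a central bond between types tj and tk;
# exact pair first, then wildcard rows, then the global X-X default
dihedral_barrier <- function(params, tj, tk) {
  d <- params$dihedral
  pair_match <- (d$tj == tj & d$tk == tk) | (d$tj == tk & d$tk == tj)
  if (any(pair_match)) return(d$kphi[which(pair_match)[1]])
  wild <- (d$tj == "X" & d$tk %in% c(tj, tk)) |
    (d$tk == "X" & d$tj %in% c(tj, tk))
  if (any(wild)) return(d$kphi[which(wild)[1]])
  def <- d$tj == "X" & d$tk == "X"
  if (any(def)) return(d$kphi[which(def)[1]])
  stop("parameter table incomplete: no dihedral barrier for ",
       tj, "-", tk)
}

#' Read a bond-charge-correction table
#'
#' CSV with columns `type_i`, `type_j`, `order`, `delta`: for every bond
#' matching the (directed) type pattern, `delta` (e) is added to the atom
#' matching `type_i` and subtracted from the atom matching `type_j`.
#' `order` may be `1`, `2`, `3`, `ar` or `*`. The package ships no values:
#' corrections are system-specific and user-supplied.
#'
#' @param path CSV file path.
#' @return object of class `BCCTable` (a data.frame).
#' @export
read_bcc_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(type_i = "character",
                                      type_j = "character",
                                      order = "character",
                                      delta = "numeric"))
  structure(t, class = c("BCCTable", "data.frame"))
}

#' Construct a bond-charge-correction table in code
#'
#' @param type_i,type_j atom-type patterns (increment +delta on i, -delta
#'   on j).
#' @param order bond-order pattern (`"1"`, `"2"`, `"3"`, `"ar"` or `"*"`).
#' @param delta increments in e.
#' @return a `BCCTable`.
#' @export
bcc_table <- function(type_i = character(), type_j = character(),
                      order = character(), delta = numeric()) {
  structure(data.frame(type_i = as.character(type_i),
                       type_j = as.character(type_j),
                       order = as.character(order),
                       delta = as.numeric(delta)),
            class = c("BCCTable", "data.frame"))
}
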