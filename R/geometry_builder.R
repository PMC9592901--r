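# Idealized 3D geometry from connectivity alone: bonds get reference lengths,
# centers get canonical sp/sp2/sp3 angles, acyclic torsions are staggered
# (anti for the heavy-atom chain) and single rings are regular polygons.
# Deterministic by construction; used by the synthetic fixture generator.
# Fused ring systems need an explicit coordinate template (see naphthalene).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate direction in geometry builder")
  v / nv
}

any_perpendicular <- function(u) {
  trial <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(cross3(u, trial))
}

# steric geometry class per atom from bond orders: "sp" (180 deg),
# "sp2" (120), "sp3" (109.47)
steric_class <- function(elements, bonds) {
  n <- length(elements)
  ndouble <- tabulate(c(bonds$i[bonds$order == "2"],
                        bonds$j[bonds$order == "2"]), nbins = n)
  ntriple <- tabulate(c(bonds$i[bonds$order == "3"],
                        bonds$j[bonds$order == "3"]), nbins = n)
  narom <- tabulate(c(bonds$i[bonds$order == "ar"],
                      bonds$j[bonds$order == "ar"]), nbins = n)
  cls <- rep("sp3", n)
  cls[ndouble >= 1L | narom >= 1L] <- "sp2"
  cls[ntriple >= 1L | ndouble >= 2L] <- "sp"
  cls
}

steric_angle <- function(cls) {
  switch(cls, sp = pi, sp2 = 120 * pi / 180, 109.471 * pi / 180)
}

#' Build idealized 3D coordinates from connectivity
#'
#' Places atoms with reference bond lengths and canonical valence angles:
#' chains are staggered zigzags, a single ring is laid out as a regular
#' polygon with substituents in-plane (sp2) or alternating above/below
#' (sp3). Molecules with fused or multiple rings are not supported here and
#' must supply a coordinate template.
#'
#' @param elements element symbols.
#' @param bonds data.frame `i`, `j`, `order` (`"1"`, `"2"`, `"3"`, `"ar"`).
#' @return numeric coordinate matrix (Angstrom), one row per atom.
#' @export
build_geometry <- function(elements, bonds) {
  n <- length(elements)
  pos <- matrix(NA_real_, n, 3)
  if (n == 1L) return(matrix(0, 1, 3))
  bonds <- as.data.frame(bonds)
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  adj <- lapply(seq_len(n), function(a)
    c(bonds$j[bonds$i == a], bonds$i[bonds$j == a]))
  blen <- matrix(NA_real_, n, n)
  for (e in seq_len(nrow(bonds))) {
    i <- bonds$i[e]; j <- bonds$j[e]
    L <- ideal_bond_length(elements[i], elements[j], bonds$order[e])
    blen[i, j] <- L; blen[j, i] <- L
  }
  cls <- steric_class(elements, bonds)

  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  rings <- rings_from_graph(g)
  if (length(rings) > 1L)
    stop("geometry builder supports at most one ring; supply a template")

  placed <- logical(n)
  if (length(rings) == 1L) {
    ring <- rings[[1]]
    m <- length(ring)
    L <- mean(vapply(seq_len(m), function(k) {
      blen[ring[k], ring[if (k == m) 1L else k + 1L]]
    }, numeric(1)))
    R <- L / (2 * sin(pi / m))
    for (k in seq_len(m)) {
      th <- 2 * pi * (k - 1) / m
      pos[ring[k], ] <- c(R * cos(th), R * sin(th), 0)
      placed[ring[k]] <- TRUE
    }
  } else {
    # start from a terminal heavy atom for a clean backbone
    deg <- lengths(adj)
    heavy <- which(elements != "H")
    start <- if (length(heavy)) heavy[which.min(deg[heavy])] else 1L
    pos[start, ] <- c(0, 0, 0)
    placed[start] <- TRUE
  }

  order_unplaced <- function(p) {
    un <- adj[[p]][!placed[adj[[p]]]]
    un[order(elements[un] == "H", un)]   # heavy atoms first, then by index
  }

  repeat {
    frontier <- which(placed & vapply(seq_len(n), function(a)
      any(!placed[adj[[a]]]), logical(1)))
    if (length(frontier) == 0L) break
    nplaced <- vapply(frontier, function(a) sum(placed[adj[[a]]]),
                      integer(1))
    p <- frontier[order(-nplaced, frontier)][1]
    un <- order_unplaced(p)
    u_nb <- adj[[p]][placed[adj[[p]]]]
    k <- length(u_nb)
    theta <- steric_angle(cls[p])

    if (k == 0L) {
      x <- un[1]
      pos[x, ] <- pos[p, ] + c(blen[p, x], 0, 0)
      placed[x] <- TRUE
      next
    }
    uvec <- lapply(u_nb, function(q) unit(pos[q, ] - pos[p, ]))

    if (k == 1L) {
      q <- u_nb[1]; u1 <- uvec[[1]]
      gp <- adj[[q]][placed[adj[[q]]] & adj[[q]] != p]
      e1 <- if (length(gp) > 0L) {
        v <- pos[gp[1], ] - pos[q, ]
        perp <- v - sum(v * u1) * u1
        if (sqrt(sum(perp^2)) > 1e-8) unit(perp) else any_perpendicular(u1)
      } else any_perpendicular(u1)
      e2 <- cross3(u1, e1)
      if (cls[p] == "sp") {
        for (x in un) {
          pos[x, ] <- pos[p, ] - blen[p, x] * u1
          placed[x] <- TRUE
        }
      } else {
        phis <- if (cls[p] == "sp2") c(pi, 0) else
          c(pi, pi / 3, -pi / 3)
        for (s in seq_along(un)) {
          x <- un[s]; phi <- phis[((s - 1L) %% length(phis)) + 1L]
          d <- cos(theta) * u1 + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
          pos[x, ] <- pos[p, ] + blen[p, x] * d
          placed[x] <- TRUE
        }
      }
    } else if (k == 2L) {
      u1 <- uvec[[1]]; u2 <- uvec[[2]]
      s <- u1 + u2
      b <- if (sqrt(sum(s^2)) > 1e-8) unit(-s) else any_perpendicular(u1)
      nv <- cross3(u1, u2)
      nv <- if (sqrt(sum(nv^2)) > 1e-8) unit(nv) else any_perpendicular(b)
      if (cls[p] == "sp2" || length(un) == 0L) {
        for (x in un) { pos[x, ] <- pos[p, ] + blen[p, x] * b; placed[x] <- TRUE }
      } else {
        beta <- 54.735 * pi / 180
        signs <- c(1, -1)
        for (s2 in seq_along(un)) {
          x <- un[s2]
          d <- unit(cos(beta) * b + signs[((s2 - 1L) %% 2L) + 1L] *
                      sin(beta) * nv)
          pos[x, ] <- pos[p, ] + blen[p, x] * d
          placed[x] <- TRUE
        }
      }
    } else {
      d <- unit(-Reduce(`+`, uvec))
      for (x in un) { pos[x, ] <- pos[p, ] + blen[p, x] * d; placed[x] <- TRUE }
    }
  }
  pos
}
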