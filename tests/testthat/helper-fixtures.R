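# Shared fixtures and independent mini-oracles for the test suite.
# Everything here is deliberately simple and separate from the package
# implementation paths it checks.

.ff_cache <- new.env(parent = emptyenv())

# moderate fixture set shared across test files
test_fixtures <- function() {
  if (is.null(.ff_cache$fx))
    .ff_cache$fx <- fixture_molecules(seed = 7, n_generated = 20)
  .ff_cache$fx
}

# small trained bundle (reduced sizes for test runtime), shared across files
test_bundle <- function() {
  if (is.null(.ff_cache$bundle)) {
    fx <- test_fixtures()
    .ff_cache$bundle <- train_model_bundle(
      fx, seed = 7, charge_trees = 150L, cv_folds = 0L, epochs = 30L)
  }
  .ff_cache$bundle
}

# plain breadth-first graph distances, written independently of igraph
bfs_distances <- function(n, bond_i, bond_j, from) {
  adj <- vector("list", n)
  for (e in seq_along(bond_i)) {
    adj[[bond_i[e]]] <- c(adj[[bond_i[e]]], bond_j[e])
    adj[[bond_j[e]]] <- c(adj[[bond_j[e]]], bond_i[e])
  }
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- from
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (d[w] > d[v] + 1) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# brute-force enumeration of bonds/angles/torsions counts from a bond list
brute_internal_counts <- function(n, bond_i, bond_j) {
  adj <- vector("list", n)
  for (e in seq_along(bond_i)) {
    adj[[bond_i[e]]] <- c(adj[[bond_i[e]]], bond_j[e])
    adj[[bond_j[e]]] <- c(adj[[bond_j[e]]], bond_i[e])
  }
  n_ang <- 0L
  for (j in seq_len(n)) {
    k <- length(adj[[j]])
    if (k >= 2L) n_ang <- n_ang + choose(k, 2)
  }
  n_tor <- 0L
  for (e in seq_along(bond_i)) {
    b <- bond_i[e]; cc <- bond_j[e]
    for (a in adj[[b]]) if (a != cc)
      for (d in adj[[cc]]) if (d != b && d != a) n_tor <- n_tor + 1L
  }
  list(bonds = length(bond_i), angles = as.integer(n_ang),
       torsions = as.integer(n_tor / 1L))
}

# independent BAR solver: plain interval bisection on the acceptance-ratio
# identity, written from scratch (no shared code with the package's
# Brent-based root-find)
reference_bar <- function(forward, reverse, beta, iters = 200L) {
  fermi_ <- function(x) 1 / (1 + exp(x))
  bal <- function(dG) mean(fermi_(beta * (forward - dG))) -
    mean(fermi_(beta * (reverse + dG)))
  lo <- min(forward, -reverse) - 10
  hi <- max(forward, -reverse) + 10
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (bal(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# build a small random Topology object directly (for energy-oracle tests)
random_topology <- function(n_atoms, seed) {
  set.seed(seed)
  coords <- matrix(rnorm(n_atoms * 3, sd = 2), n_atoms, 3)
  nb <- sample(1:(n_atoms - 1), 1)
  bonds <- data.frame(i = sample(n_atoms, nb, replace = TRUE),
                      j = sample(n_atoms, nb, replace = TRUE))
  bonds <- bonds[bonds$i != bonds$j, , drop = FALSE]
  bonds$r0 <- runif(nrow(bonds), 1, 2)
  bonds$kb <- runif(nrow(bonds), 100, 700)
  na_ <- sample(0:3, 1)
  angles <- if (na_ > 0 && n_atoms >= 3) {
    a <- t(replicate(na_, sample(n_atoms, 3)))
    data.frame(i = a[, 1], j = a[, 2], k = a[, 3],
               theta0 = runif(na_, 90, 130),
               ktheta = runif(na_, 30, 90))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    theta0 = numeric(), ktheta = numeric())
  nd <- sample(0:3, 1)
  dihedrals <- if (nd > 0 && n_atoms >= 4) {
    d <- t(replicate(nd, sample(n_atoms, 4)))
    data.frame(i = d[, 1], j = d[, 2], k = d[, 3], l = d[, 4],
               phase = sample(c(0, 180), nd, replace = TRUE),
               periodicity = sample(1:4, nd, replace = TRUE),
               kphi = runif(nd, 0.1, 5))
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    l = integer(), phase = numeric(),
                    periodicity = integer(), kphi = numeric())
  structure(list(name = paste0("rand", seed),
                 atoms = data.frame(index = seq_len(n_atoms),
                                    element = rep("C", n_atoms),
                                    type = rep("c3", n_atoms),
                                    charge = rep(0, n_atoms),
                                    mass = rep(12.011, n_atoms),
                                    sigma = rep(0.34, n_atoms),
                                    epsilon = rep(0.45, n_atoms)),
                 bonds = bonds, angles = angles, dihedrals = dihedrals,
                 impropers = dihedrals[0, ],
                 pairs14 = data.frame(i = integer(), l = integer()),
                 formal_charge = 0L),
            class = "Topology")
}

# scalar per-term bonded-energy oracle (plain loops, no vectorization)
brute_bonded_energy <- function(top, coords) {
  ang3 <- function(p1, p2, p3) {
    u <- p1 - p2; v <- p3 - p2
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  dih4 <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    atan2(sum(cr(n1, b2) * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }
  e <- 0
  for (r in seq_len(nrow(top$bonds))) {
    d <- sqrt(sum((coords[top$bonds$i[r], ] - coords[top$bonds$j[r], ])^2))
    e <- e + top$bonds$kb[r] * (d - top$bonds$r0[r])^2
  }
  for (r in seq_len(nrow(top$angles))) {
    th <- ang3(coords[top$angles$i[r], ], coords[top$angles$j[r], ],
               coords[top$angles$k[r], ]) * 180 / pi
    e <- e + top$angles$ktheta[r] *
      ((th - top$angles$theta0[r]) * pi / 180)^2
  }
  for (dd in list(top$dihedrals, top$impropers)) {
    for (r in seq_len(nrow(dd))) {
      phi <- dih4(coords[dd$i[r], ], coords[dd$j[r], ],
                  coords[dd$k[r], ], coords[dd$l[r], ]) * 180 / pi
      e <- e + dd$kphi[r] *
        (1 + cos((dd$periodicity[r] * phi - dd$phase[r]) * pi / 180))
    }
  }
  e
}
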