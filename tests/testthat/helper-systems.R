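# Builders for tiny constructed systems and independent brute-force
# oracles used across the tests.

# Build a topology directly from an atom table (bypassing file I/O).
make_topology <- function(atoms, xyz1) {
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, chains = unique(atoms$chain_id),
                 n_models = 1L, xyz = as.numeric(xyz1),
                 source = "constructed"), class = "topology")
}

# Single-bead-per-residue two-chain system from coordinate matrices.
# pep / dom: n x 3 matrices (one bead per residue).
make_bead_system <- function(pep, dom, pep_names = NULL,
                             frame_interval_ps = 10, n_frames = 1,
                             xyz = NULL) {
  if (is.null(pep_names)) pep_names <- rep("GLY", nrow(pep))
  atoms <- data.frame(
    serial = 1, name = "CA", element = "C",
    residue_index = c(seq_len(nrow(dom)), seq_len(nrow(pep))),
    residue_name = c(rep("GLY", nrow(dom)), pep_names),
    chain_id = c(rep("A", nrow(dom)), rep("P", nrow(pep))),
    stringsAsFactors = FALSE)
  flat <- as.numeric(t(rbind(dom, pep)))
  topo <- make_topology(atoms, flat)
  if (is.null(xyz)) xyz <- matrix(rep(flat, n_frames), nrow = n_frames,
                                  byrow = TRUE)
  list(topology = topo,
       trajectory = trajectory(xyz, topo, frame_interval_ps))
}

cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

# NeRF-style internal-to-cartesian placement: position of atom D given
# A, B, C and bond length |CD|, angle B-C-D (deg), torsion A-B-C-D (deg).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-length * cos(ang), length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an all-backbone peptide chain (N, CA, C per residue plus carbonyl
# O and amide H) with the requested per-residue (phi, psi) in degrees.
# Returns a topology + 1-frame trajectory.
make_backbone_chain <- function(phi, psi, res_names = NULL,
                                chain_id = "P") {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(res_names)) res_names <- rep("ALA", n)
  bl <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010)
  ba <- c(n_ca_c = 111.0, ca_c_n = 116.6, c_n_ca = 121.7,
          ca_c_o = 120.5, c_n_h = 119.0)
  coords <- list(); atoms <- list()
  add <- function(p, nm, el, res) {
    coords[[length(coords) + 1]] <<- p
    atoms[[length(atoms) + 1]] <<- data.frame(
      serial = length(coords), name = nm, element = el,
      residue_index = res, residue_name = res_names[res],
      chain_id = chain_id, stringsAsFactors = FALSE)
  }
  # seed residue 1
  N1 <- c(0, 0, 0); CA1 <- c(bl["n_ca"], 0, 0)
  C1 <- place_atom(c(0, 1, 0), N1, CA1, bl["ca_c"], ba["n_ca_c"], phi[1])
  add(N1, "N", "N", 1); add(CA1, "CA", "C", 1); add(C1, "C", "C", 1)
  prevN <- N1; prevCA <- CA1; prevC <- C1
  for (i in seq_len(n)[-1]) {
    Ni <- place_atom(prevN, prevCA, prevC, bl["c_n"], ba["ca_c_n"], psi[i - 1])
    CAi <- place_atom(prevCA, prevC, Ni, bl["n_ca"], ba["c_n_ca"], 180)  # omega
    Ci <- place_atom(prevC, Ni, CAi, bl["ca_c"], ba["n_ca_c"], phi[i])
    Oi1 <- place_atom(Ni, prevCA, prevC, bl["c_o"], ba["ca_c_o"],
                      psi[i - 1] + 180)
    Hi <- place_atom(CAi, prevC, Ni, bl["n_h"], ba["c_n_h"], 0)
    add(Oi1, "O", "O", i - 1); add(Ni, "N", "N", i)
    add(Hi, "H", "H", i); add(CAi, "CA", "C", i); add(Ci, "C", "C", i)
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
  }
  at <- do.call(rbind, atoms)
  flat <- as.numeric(t(do.call(rbind, coords)))
  ord <- order(at$residue_index, match(at$name, c("N", "H", "CA", "C", "O")))
  at <- at[ord, ]
  flat <- as.numeric(t(do.call(rbind, coords)[ord, ]))
  topo <- make_topology(at, flat)
  list(topology = topo,
       trajectory = trajectory(matrix(flat, nrow = 1), topo, 10))
}

# ---- brute-force oracles -------------------------------------------------

# all-pairs residue geometric-center contact fractions
oracle_contact_fraction <- function(traj, pep_res, dom_res, cutoff) {
  topo <- traj$topology
  nf <- n_frames(traj)
  out <- matrix(0, length(pep_res), length(dom_res))
  for (f in seq_len(nf)) {
    crd <- frame_coords(traj, f)
    for (i in seq_along(pep_res)) for (j in seq_along(dom_res)) {
      ai <- which(topo$atoms$chain_id == "P" &
                    topo$atoms$residue_index == pep_res[i] &
                    topo$atoms$element != "H")
      bj <- which(topo$atoms$chain_id == "A" &
                    topo$atoms$residue_index == dom_res[j] &
                    topo$atoms$element != "H")
      ci <- colMeans(crd[ai, , drop = FALSE])
      cj <- colMeans(crd[bj, , drop = FALSE])
      if (sqrt(sum((ci - cj)^2)) <= cutoff)
        out[i, j] <- out[i, j] + 1 / nf
    }
  }
  out
}

# per-frame count of atom pairs within cutoff
oracle_pair_counts <- function(traj, atoms_a, atoms_b, cutoff) {
  vapply(seq_len(n_frames(traj)), function(f) {
    crd <- frame_coords(traj, f)
    s <- 0L
    for (a in atoms_a) for (b in atoms_b)
      if (sqrt(sum((crd[a, ] - crd[b, ])^2)) <= cutoff) s <- s + 1L
    s
  }, integer(1))
}

# Monte Carlo SASA reference (independent random sphere sampling)
oracle_sasa_mc <- function(crd, radii, probe, n_pts = 40000, seed = 99) {
  set.seed(seed)
  r <- radii + probe
  total <- 0
  for (i in seq_len(nrow(crd))) {
    z <- stats::rnorm(n_pts); x <- stats::rnorm(n_pts); y <- stats::rnorm(n_pts)
    nrm <- sqrt(x^2 + y^2 + z^2)
    p <- cbind(x / nrm, y / nrm, z / nrm) * r[i]
    p <- sweep(p, 2, crd[i, ], "+")
    acc <- rep(TRUE, n_pts)
    for (j in seq_len(nrow(crd))[-i]) {
      d2 <- (p[, 1] - crd[j, 1])^2 + (p[, 2] - crd[j, 2])^2 +
        (p[, 3] - crd[j, 3])^2
      acc <- acc & d2 >= r[j]^2
    }
    total <- total + mean(acc) * 4 * pi * r[i]^2
  }
  total / 100
}
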