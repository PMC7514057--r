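test_that("residue contacts respect the 8 A center-of-mass cutoff", {
  near <- make_bead_system(matrix(c(7.9, 0, 0), 1, 3), matrix(0, 1, 3),
                           n_frames = 3)
  cfg <- analysis_config(
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1),
    numbering = peptide_numbering(1, pivot = 1))
  cm <- contact_map(near$trajectory, cfg)
  expect_equal(unname(cm$fraction[1, 1]), 1)
  far <- make_bead_system(matrix(c(8.1, 0, 0), 1, 3), matrix(0, 1, 3))
  expect_equal(unname(contact_map(far$trajectory, cfg)$fraction[1, 1]), 0)
})

test_that("contact map equals the exhaustive all-pairs oracle on a random toy", {
  set.seed(31)
  nf <- 6
  xyz <- matrix(stats::runif(nf * 10 * 3, 0, 15), nrow = nf)
  sys <- make_bead_system(matrix(0, 5, 3), matrix(0, 5, 3),
                          n_frames = nf, xyz = xyz)
  cfg <- analysis_config(
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1),
    numbering = peptide_numbering(5:1, pivot = 3))
  cm <- contact_map(sys$trajectory, cfg, peptide_chain = "P",
                    domain_chain = "A")
  oracle <- oracle_contact_fraction(sys$trajectory, 1:5, 1:5, 8)
  expect_equal(unname(cm$fraction[as.character(5:1), ]),
               oracle[, ], ignore_attr = TRUE)
  # frame-order invariance
  cm2 <- contact_map(trajectory(xyz[nf:1, ], sys$topology, 10), cfg,
                     peptide_chain = "P", domain_chain = "A")
  expect_equal(cm$fraction, cm2$fraction)
  # mixture identity over a frame partition
  cma <- contact_map(sys$trajectory, cfg, peptide_chain = "P",
                     domain_chain = "A", frames = 1:2)
  cmb <- contact_map(sys$trajectory, cfg, peptide_chain = "P",
                     domain_chain = "A", frames = 3:6)
  expect_equal((2 * cma$fraction + 4 * cmb$fraction) / 6, cm$fraction,
               tolerance = 1e-12)
})

# small two-chain system with explicit charged atoms
make_charged_system <- function(nz_xyz, acid_xyz, nf = 1, xyz = NULL) {
  n_nz <- nrow(nz_xyz); n_ac <- nrow(acid_xyz)
  atoms <- data.frame(
    serial = 1,
    name = c(rep("CG", n_ac), rep("NZ", n_nz)),
    element = c(rep("C", n_ac), rep("N", n_nz)),
    residue_index = c(seq_len(n_ac), seq_len(n_nz)),
    residue_name = c(rep("ASP", n_ac), rep("LYS", n_nz)),
    chain_id = c(rep("A", n_ac), rep("P", n_nz)))
  flat <- as.numeric(t(rbind(acid_xyz, nz_xyz)))
  topo <- make_topology(atoms, flat)
  if (is.null(xyz)) xyz <- matrix(rep(flat, nf), nrow = nf, byrow = TRUE)
  trajectory(xyz, topo, 10)
}

test_that("electrostatic contacts respect the 10 A cutoff and occupancy filter", {
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  tr_in <- make_charged_system(matrix(c(9.9, 0, 0), 1, 3),
                               matrix(0, 1, 3), nf = 4)
  ec <- electrostatic_contacts(tr_in, cfg, peptide_chain = "P", domain_chain = "A")
  expect_equal(ec$occupancy$occupancy, 1)
  expect_equal(ec$mean_count, 1)
  tr_out <- make_charged_system(matrix(c(10.1, 0, 0), 1, 3),
                                matrix(0, 1, 3))
  expect_equal(electrostatic_contacts(tr_out, cfg, peptide_chain = "P",
                                      domain_chain = "A")$occupancy$occupancy, 0)
})

test_that("electrostatic counts match the brute-force oracle; low-occupancy pairs drop from the report only", {
  set.seed(77)
  nf <- 100
  # 3 Lys x 2 acidic toy with random frames
  n_atoms <- 5
  xyz <- matrix(stats::runif(nf * n_atoms * 3, 0, 18), nrow = nf)
  tr <- make_charged_system(matrix(0, 3, 3), matrix(0, 2, 3), xyz = xyz)
  cfg <- analysis_config(numbering = peptide_numbering(3:1, pivot = 2),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  ec <- electrostatic_contacts(tr, cfg, peptide_chain = "P", domain_chain = "A")
  oracle <- oracle_pair_counts(tr, 3:5, 1:2, 10)
  expect_equal(ec$per_frame_counts, oracle)
  expect_equal(ec$mean_count, mean(oracle))
  # pairs under 10% occupancy are excluded from the report, not the count
  low <- ec$occupancy$occupancy < 0.10
  expect_identical(ec$occupancy$reported, !low)
  expect_equal(sum(ec$occupancy$occupancy) * nf, sum(oracle))
})

test_that("hydrophobic group contacts use the minimum inter-group distance", {
  # two methyl-like groups: carbon + hydrogens
  mk <- function(cpos, hshift) rbind(C = cpos, H1 = cpos + hshift)
  g1 <- mk(c(0, 0, 0), c(0.9, 0, 0))
  g2 <- mk(c(5.9, 3, 0), c(-0.9, 0, 0))
  atoms <- data.frame(serial = 1, name = c("CB", "HB1", "CD", "HD1"),
                      element = c("C", "H", "C", "H"),
                      residue_index = c(1, 1, 1, 1),
                      residue_name = "LEU",
                      chain_id = c("P", "P", "A", "A"))
  flat <- as.numeric(t(rbind(g1, g2)))
  topo <- make_topology(atoms, flat)
  tr <- trajectory(matrix(flat, nrow = 1), topo, 10)
  pairs <- data.frame(peptide_position = 1, peptide_group = "CB",
                      domain_residue = 1, domain_group = "CD",
                      mean_dist = NA)
  pairs$peptide_atoms <- list(1:2); pairs$domain_atoms <- list(3:4)
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  # carbon-carbon distance sqrt(5.9^2+9) > 6 but H1-H2 gap is smaller
  hc <- hydrophobic_contacts(tr, pairs, cfg)
  dmin <- min(as.matrix(stats::dist(rbind(g1, g2)))[1:2, 3:4])
  expect_equal(hc$occupancy, as.numeric(dmin <= 6))
  # shift apart: no contact
  g2b <- mk(c(20, 0, 0), c(-0.9, 0, 0))
  tr2 <- trajectory(matrix(as.numeric(t(rbind(g1, g2b))), nrow = 1), topo, 10)
  expect_equal(hydrophobic_contacts(tr2, pairs, cfg)$occupancy, 0)
})

test_that("reference-ensemble hydrophobic pairs minimize the mean distance", {
  # peptide residue with one group; domain with two candidate groups whose
  # ranking differs between the two models; the mean decides
  atoms <- data.frame(serial = 1,
                      name = c("CB", "CG", "CD"),
                      element = "C",
                      residue_index = c(1, 1, 2),
                      residue_name = c("ALA", "LEU", "LEU"),
                      chain_id = c("P", "A", "A"))
  m1 <- rbind(c(0, 0, 0), c(4, 0, 0), c(6, 0, 0))
  m2 <- rbind(c(0, 0, 0), c(9, 0, 0), c(5, 0, 0))
  flat1 <- as.numeric(t(m1))
  topo <- make_topology(atoms, flat1)
  ref <- trajectory(rbind(flat1, as.numeric(t(m2))), topo, 10)
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  pr <- derive_reference_hydrophobic_pairs(ref, cfg, peptide_chain = "P",
                                           domain_chain = "A")
  # means: CG (4+9)/2 = 6.5, CD (6+5)/2 = 5.5 -> CD wins
  expect_equal(pr$domain_group, "CD")
  expect_equal(pr$mean_dist, 5.5)
  pr2 <- derive_reference_hydrophobic_pairs(ref, cfg, peptide_chain = "P",
                                            domain_chain = "A", k = 2)
  expect_equal(pr2$domain_group, c("CD", "CG"))  # sorted by mean distance
  expect_equal(pr2$mean_dist, c(5.5, 6.5))
})

# donor-hydrogen-acceptor toy across two chains
make_hbond_system <- function(o_pos) {
  atoms <- data.frame(serial = 1, name = c("N", "H", "O"),
                      element = c("N", "H", "O"),
                      residue_index = c(1, 1, 1),
                      residue_name = c("ALA", "ALA", "SER"),
                      chain_id = c("P", "P", "A"))
  flat <- as.numeric(t(rbind(c(0, 0, 0), c(1, 0, 0), o_pos)))
  topo <- make_topology(atoms, flat)
  trajectory(matrix(flat, nrow = 1), topo, 10)
}

test_that("hydrogen-bond criterion needs under 3 A and over 135 degrees", {
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  # collinear N(0,0,0)-H(1,0,0)...O(2.8,0,0): angle 180, distance 2.8
  hb <- short_range_interactions(make_hbond_system(c(2.8, 0, 0)), "hbond", cfg)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$occupancy, 1)
  # same geometry at 3.1 A: too far
  hb2 <- short_range_interactions(make_hbond_system(c(3.1, 0, 0)), "hbond", cfg)
  expect_equal(nrow(hb2), 0L)
  # acceptor placed for a 120-degree angle at the hydrogen, 2.8 A from N
  # (O at angle such that acceptor-H-donor = 120): rejected
  oh <- 2.1626  # |H-O| chosen so that |N-O| = 2.8 with 120 deg at H
  o <- c(1 + oh * cos(pi / 3), oh * sin(pi / 3), 0)
  expect_lt(abs(sqrt(sum(o^2)) - 2.8), 0.05)
  hb3 <- short_range_interactions(make_hbond_system(o), "hbond", cfg)
  expect_equal(nrow(hb3), 0L)
})

test_that("salt bridges test every hydrogen-oxygen combination of the charged groups", {
  atoms <- data.frame(serial = 1,
                      name = c("NZ", "HZ1", "HZ2", "OD1", "OD2"),
                      element = c("N", "H", "H", "O", "O"),
                      residue_index = c(1, 1, 1, 1, 1),
                      residue_name = c("LYS", "LYS", "LYS", "ASP", "ASP"),
                      chain_id = c("P", "P", "P", "A", "A"))
  # HZ2 points toward OD2 in perfect geometry; HZ1 away; OD1 far
  crd <- rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0),
               c(0, 40, 0), c(2.8, 0, 0))
  flat <- as.numeric(t(crd))
  topo <- make_topology(atoms, flat)
  tr <- trajectory(matrix(flat, nrow = 1), topo, 10)
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  sb <- short_range_interactions(tr, "saltbridge", cfg)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$acceptor_name, "OD2")
  expect_equal(sb$occupancy, 1)
})

test_that("SASA matches the analytic sphere and is additive when separated", {
  atoms <- data.frame(serial = 1, name = "SG", element = "S",
                      residue_index = 1, residue_name = "CYS", chain_id = "A")
  topo <- make_topology(atoms, c(0, 0, 0))
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1),
    vdw_radii = c(S = 1.6))
  a1 <- sasa(c(0, 0, 0), topology = topo, config = cfg)
  expect_equal(a1, 4 * pi * 3.0^2 / 100, tolerance = 0.01)
  # two identical atoms far apart: twice the single-atom area
  atoms2 <- rbind(atoms, atoms)
  atoms2$residue_index <- c(1, 2)
  topo2 <- make_topology(atoms2, c(0, 0, 0, 100, 0, 0))
  a2 <- sasa(c(0, 0, 0, 100, 0, 0), topology = topo2, config = cfg)
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
  # unknown element radius is reported by name
  topo3 <- topo
  topo3$atoms$element <- "XX"
  expect_error(sasa(c(0, 0, 0), topology = topo3, config = cfg), "XX")
})

test_that("overlapping-sphere SASA agrees with an independent Monte Carlo oracle", {
  atoms <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                      residue_index = 1:2, residue_name = "ALA",
                      chain_id = "A")
  crd <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  topo <- make_topology(atoms, as.numeric(t(crd)))
  cfg <- analysis_config(numbering = peptide_numbering(1, pivot = 1),
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1))
  mine <- sasa(as.numeric(t(crd)), topology = topo, config = cfg)
  ref <- oracle_sasa_mc(crd, radii = rep(1.70, 2), probe = 1.4)
  expect_equal(mine, ref, tolerance = 0.02)
  # translation / rotation invariance
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  crd2 <- sweep(crd %*% rot, 2, c(5, -3, 2), "+")
  mine2 <- sasa(as.numeric(t(crd2)), topology = topo, config = cfg)
  expect_equal(mine, mine2, tolerance = 0.01)  # to sphere-sampling resolution
  # monotone non-increasing as the atoms approach
  seps <- c(6, 4, 3, 2, 1)
  areas <- vapply(seps, function(s)
    sasa(c(0, 0, 0, s, 0, 0), topology = topo, config = cfg), numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})
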