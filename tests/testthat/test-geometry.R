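test_that("binding surface distance averages Calpha pair distances", {
  # one pair: 3-4-5 triangle
  sys <- make_bead_system(pep = matrix(c(3, 4, 0), 1, 3),
                          dom = matrix(c(0, 0, 0), 1, 3))
  cfg <- analysis_config(
    binding_surface_pairs = data.frame(position = 1, domain_residue = 1),
    numbering = peptide_numbering(1, pivot = 1))
  expect_equal(binding_surface_distance(sys$trajectory, cfg)$values, 5)
  # two pairs with distances 5 and 7
  sys2 <- make_bead_system(pep = rbind(c(0, 0, 5), c(10, 0, 7)),
                           dom = rbind(c(0, 0, 0), c(10, 0, 0)))
  cfg2 <- analysis_config(
    binding_surface_pairs = data.frame(position = c(1, 0),
                                       domain_residue = c(1, 2)),
    numbering = peptide_numbering(1:0, pivot = 1))
  expect_equal(binding_surface_distance(sys2$trajectory, cfg2)$values, 6)
})

test_that("binding surface distance equals a brute-force mean on random coordinates", {
  set.seed(42)
  for (rep in 1:5) {
    pep <- matrix(stats::runif(21, -20, 20), 7, 3)
    dom <- matrix(stats::runif(21, -20, 20), 7, 3)
    sys <- make_bead_system(pep, dom)
    cfg <- analysis_config(
      binding_surface_pairs = data.frame(position = 7:1, domain_residue = 1:7),
      numbering = peptide_numbering(7:-4, pivot = 4))
    # numbering has 12 positions but chain has 7 residues; use exact 7
    cfg <- analysis_config(
      binding_surface_pairs = data.frame(position = 7:1, domain_residue = 1:7),
      numbering = peptide_numbering(7:1, pivot = 4))
    expected <- mean(sqrt(rowSums((pep - dom)^2)))
    expect_equal(binding_surface_distance(sys$trajectory, cfg)$values,
                 expected, tolerance = 1e-9)
  }
})

test_that("dihedral RMSD wraps differences and obeys its identities", {
  ch <- make_backbone_chain(c(-75, -75, -75, -75), c(145, 145, 145, 145))
  ds <- dihedral_set(ch$topology, "P")
  expect_equal(dihedral_rmsd(ch$trajectory, ds)$values, 0)
  # two dihedrals differing by +10 and -20: sqrt((100+400)/2)
  ref <- c(10, 170)
  obs <- c(20, 150)
  fake <- data.frame(residue_index = 1:2, angle = "phi")
  dev <- idpbind:::.wrap180(obs - ref)
  expect_equal(sqrt(mean(dev^2)), sqrt(250), tolerance = 1e-12)
  # periodic wrap: 170 vs -170 differ by 20, not 340
  ch_a <- make_backbone_chain(c(-60, 170, -60), c(100, 100, 100))
  ch_b <- make_backbone_chain(c(-60, -170, -60), c(100, 100, 100))
  ds_a <- dihedral_set(ch_a$topology, "P")
  v <- dihedral_rmsd(ch_b$trajectory, ds_a)$values
  # only phi2, phi3, psi1, psi2 exist; the single 20-degree deviation
  expect_equal(v, sqrt(20^2 / 4), tolerance = 1e-6)
})

test_that("dihedral RMSD is symmetric and bounded by 180", {
  set.seed(7)
  for (rep in 1:4) {
    phi1 <- stats::runif(5, -180, 180); psi1 <- stats::runif(5, -180, 180)
    phi2 <- stats::runif(5, -180, 180); psi2 <- stats::runif(5, -180, 180)
    a <- make_backbone_chain(phi1, psi1)
    b <- make_backbone_chain(phi2, psi2)
    ds_a <- dihedral_set(a$topology, "P")
    ds_b <- dihedral_set(b$topology, "P")
    vab <- dihedral_rmsd(b$trajectory, ds_a)$values
    vba <- dihedral_rmsd(a$trajectory, ds_b)$values
    expect_equal(vab, vba, tolerance = 1e-9)
    expect_lte(vab, 180)
    expect_gte(vab, 0)
  }
})

test_that("end-to-end distance uses terminal Calphas", {
  pep <- matrix(0, 12, 3); pep[, 1] <- (0:11) * 3.8
  sys <- make_bead_system(pep, matrix(100, 2, 3))
  expect_equal(end_to_end_distance(sys$trajectory, chain = "P")$values,
               11 * 3.8)
  z <- make_bead_system(rbind(c(0, 0, 0), c(0, 0, 10)), matrix(100, 3, 3))
  expect_equal(end_to_end_distance(z$trajectory, chain = "P")$values, 10)
})

test_that("PPII fractions follow the phi/psi window", {
  cfg <- analysis_config(
    binding_surface_pairs = data.frame(position = 3, domain_residue = 1),
    numbering = peptide_numbering(3:-2, pivot = 0))
  ppii <- make_backbone_chain(rep(-75, 6), rep(145, 6))
  f1 <- secondary_structure_fractions(ppii$trajectory, cfg, chain = "P")
  expect_equal(f1$ppii[2:5], rep(1, 4))  # interior residues
  alpha <- make_backbone_chain(rep(-60, 6), rep(-45, 6))
  f0 <- secondary_structure_fractions(alpha$trajectory, cfg, chain = "P")
  expect_equal(f0$ppii[2:5], rep(0, 4))
  # 50/50 alternating frames
  xyz <- rbind(ppii$trajectory$xyz, alpha$trajectory$xyz)
  tr <- trajectory(xyz, ppii$topology, 10)
  fh <- secondary_structure_fractions(tr, cfg, chain = "P")
  expect_equal(fh$ppii[2:5], rep(0.5, 4))
  # fractions in [0,1] and invariant to frame order
  tr_rev <- trajectory(xyz[2:1, ], ppii$topology, 10)
  fr <- secondary_structure_fractions(tr_rev, cfg, chain = "P")
  expect_equal(fh$ppii, fr$ppii)
  expect_true(all(fh$ppii >= 0 & fh$ppii <= 1, na.rm = TRUE))
  expect_true(all(fh$helix310 >= 0 & fh$helix310 <= 1))
})

test_that("3-10 helix assignment fires on an i to i+3 backbone hydrogen bond", {
  # hand-built 6-residue backbone; residue 2's O and residue 5's N-H are
  # placed in ideal collinear hydrogen-bond geometry, everything else far
  res <- lapply(1:6, function(i) {
    base <- c(10 * i, 0, 0)
    rbind(N = base, H = base + c(0, 1.0, 0), CA = base + c(1.4, 0, 0),
          C = base + c(2.4, 0.5, 0), O = base + c(2.4, 1.7, 0))
  })
  # overwrite: O(2) at origin-ish, N(5)/H(5) collinear 2.8 A away
  res[[2]]["O", ] <- c(0, 30, 0)
  res[[5]]["H", ] <- c(0, 31.0, 0)
  res[[5]]["N", ] <- c(0, 32.0, 0)
  atoms <- do.call(rbind, lapply(1:6, function(i)
    data.frame(serial = 1, name = rownames(res[[i]]),
               element = substr(rownames(res[[i]]), 1, 1),
               residue_index = i, residue_name = "ALA", chain_id = "P")))
  flat <- as.numeric(t(do.call(rbind, res)))
  topo <- make_topology(atoms, flat)
  tr <- trajectory(matrix(flat, nrow = 1), topo, 10)
  cfg <- analysis_config(
    binding_surface_pairs = data.frame(position = 3, domain_residue = 1),
    numbering = peptide_numbering(3:-2, pivot = 0))
  f <- secondary_structure_fractions(tr, cfg, chain = "P")
  expect_equal(f$helix310, c(0, 1, 1, 1, 1, 0))
})

test_that("running average and autocorrelation time behave as expected", {
  expect_equal(running_average(rep(4.2, 50)), rep(4.2, 50))
  expect_equal(running_average(c(1, 3, 5)), c(1, 2, 3))
  expect_warning(tc <- autocorrelation_time(rep(1, 100)), "constant")
  expect_true(is.na(tc))
  # AR(1) with coefficient 0.9: time constant -dt/log(0.9)
  set.seed(123)
  n <- 1e5; phi <- 0.9
  x <- stats::filter(stats::rnorm(n), phi, method = "recursive")
  tc <- autocorrelation_time(as.numeric(x), dt_ns = 1)
  expect_equal(tc, -1 / log(phi), tolerance = 0.15)
  # white noise: under two frame intervals
  set.seed(5)
  expect_lt(autocorrelation_time(stats::rnorm(5e4), dt_ns = 1), 2)
})

test_that("temperature ladder is geometric with exact endpoints", {
  expect_equal(temperature_ladder(290, 425, 2), c(290, 425))
  lad <- temperature_ladder(290, 425, 48)
  expect_equal(lad[1], 290)
  expect_equal(lad[48], 425)
  expect_equal(lad[2], 290 * (425 / 290)^(1 / 47), tolerance = 1e-12)
  expect_equal(round(lad[2], 2), 292.37)
  ratios <- lad[-1] / lad[-48]
  expect_lt(max(ratios) - min(ratios), 1e-10)
  expect_true(all(diff(lad) > 0))
  expect_error(temperature_ladder(425, 290, 10), "t_min")
})
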