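test_that("contact indicator is a smooth switch: midpoint 1/2, saturation, monotone decay", {
  cf <- contact_function()  # r_c = 1.75, eta = 3
  expect_equal(contact_indicator(cf$r_c, cf), 0.5)
  expect_gt(contact_indicator(0, cf), 0.99)
  r <- seq(0, 4, by = 0.01)
  f <- contact_indicator(r, cf)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) <= 0))
  expect_error(contact_indicator(-0.1, cf), "non-negative")
})

test_that("analytic contact derivative matches central differences at random radii", {
  cf <- contact_function()
  set.seed(4)
  r <- runif(50, 0.05, 3.5)
  h <- 1e-6
  num <- (contact_indicator(r + h, cf) - contact_indicator(r - h, cf)) / (2 * h)
  ana <- contact_indicator_deriv(r, cf)
  expect_equal(num, ana, tolerance = 1e-6)
})

test_that("chromatin pair energies follow the ideal/compartment/chromosome-pair rules", {
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 2, beads_per_chain = 10,
                                   n_nucleolus = 0, n_speckle = 0,
                                   n_lamina = 30))
  topo <- toy$topology
  params <- toy$params
  cf <- params$contact

  # all couplings zero: energy 0 for any pair and distance
  for (r in c(0.2, cf$r_c, 2)) {
    expect_identical(chromatin_pair_energy(topo, params, 1, 5, r), 0)
    expect_identical(chromatin_pair_energy(topo, params, 1, 15, r), 0)
  }

  # intra-chain at separation s with alpha_ideal(s) = -1, r = r_c:
  # -0.5 x shifted-midpoint normalization
  p <- params
  p$alpha_ideal[3] <- -1
  fmid <- contact_indicator(cf$r_c, cf, shifted = TRUE)
  expect_equal(chromatin_pair_energy(topo, p, 3, 6, cf$r_c), -1 * fmid)
  expect_equal(fmid, 0.5, tolerance = 2e-3)

  # beyond the tabulated ideal range the last value is used (clamp)
  p2 <- params
  p2$alpha_ideal[] <- 0
  p2$alpha_ideal[length(p2$alpha_ideal)] <- -2
  s_far <- length(p2$alpha_ideal)  # max separation on a 10-bead chain is 9
  expect_equal(chromatin_pair_energy(topo, p2, 1, 10, 0.5),
               -2 * contact_indicator(0.5, cf, shifted = TRUE))

  # inter-chain pair: compartment + chromosome-pair couplings
  p3 <- params
  p3$compartment["A", "A"] <- -0.3
  p3$chrom_pair[1, 2] <- p3$chrom_pair[2, 1] <- -0.2
  ann <- toy$annotation
  i <- 3                      # chain 1 (toy1 copy 1), label A
  j <- ann$chains$offset[3] + 3  # chain 3 = toy2 copy 1, label A
  expect_equal(p3$compartment["A", "A"] + p3$chrom_pair[1, 2],
               chromatin_pair_energy(topo, p3, i, j, cf$r_c) / fmid,
               tolerance = 1e-12)
  # homolog pair uses the diagonal chromosome coupling
  p4 <- params
  p4$chrom_pair[1, 1] <- -0.5
  jh <- ann$chains$offset[2] + 3  # copy 2 of chromosome 1
  expect_equal(chromatin_pair_energy(topo, p4, i, jh, cf$r_c), -0.5 * fmid)
  expect_error(chromatin_pair_energy(topo, params, 1, topo$n_particles, 1),
               "chromatin")
})

test_that("body pair energies: LJ minimum, P-state repulsive truncation, zero beyond cutoff", {
  toy <- small_toy()
  params <- toy$params
  params$lj$eps_nucleolus <- 1.7
  params$lj$eps_speckle <- 0.9
  sig <- params$lj$sigma
  rmin <- 2^(1 / 6) * sig
  cutoff <- params$lj$cutoff_factor * sig

  # analytic LJ minimum: -eps up to the cutoff shift
  sc6 <- (sig / cutoff)^6
  shift <- 4 * 1.7 * (sc6^2 - sc6)
  expect_equal(body_pair_energy(rmin, "nucleolus", "nucleolus", params = params),
               -1.7 - shift, tolerance = 1e-12)
  expect_equal(body_pair_energy(rmin, "speckle", "speckle", "dP", "dP", params),
               -0.9 - 4 * 0.9 * (sc6^2 - sc6), tolerance = 1e-12)
  # P-involved speckle pairs are purely repulsive: zero at/beyond the minimum
  expect_identical(body_pair_energy(rmin, "speckle", "speckle", "P", "dP", params), 0)
  expect_identical(body_pair_energy(rmin, "speckle", "speckle", "P", "P", params), 0)
  expect_gt(body_pair_energy(0.9 * rmin, "speckle", "speckle", "P", "P", params), 0)
  # exactly zero at and beyond the cutoff
  expect_identical(body_pair_energy(cutoff, "nucleolus", "nucleolus", params = params), 0)
  expect_identical(body_pair_energy(cutoff + 1, "nucleolus", "nucleolus", params = params), 0)
  # cross-category pairs are repulsive-only
  expect_identical(body_pair_energy(rmin, "nucleolus", "speckle", "dP", "dP", params), 0)
})

test_that("landmark couplings scale the contact weight and respect the dP convention", {
  toy <- small_toy()
  topo <- toy$topology
  params <- toy$params
  cf <- params$contact
  bead <- 1
  lam <- particle_indices(topo, "lamina")[1]
  spk <- particle_indices(topo, "speckle")[1]

  # zero coupling: zero at any distance
  for (r in c(0.1, cf$r_c, 2)) {
    expect_identical(landmark_coupling_energy(topo, params, bead, lam, r), 0)
  }
  hb <- topo$particles$hap_bin[bead]
  p <- params
  p$chi_lamina[hb] <- -2
  expect_equal(landmark_coupling_energy(topo, p, bead, lam, cf$r_c), -1,
               tolerance = 5e-3)
  p$chi_speckle[hb] <- -2
  expect_equal(landmark_coupling_energy(topo, p, bead, spk, cf$r_c,
                                        state = "dP"), -1, tolerance = 5e-3)
  expect_identical(landmark_coupling_energy(topo, p, bead, spk, cf$r_c,
                                            state = "P"), 0)
})

test_that("engine total energy equals the plain-R per-pair decomposition", {
  toy <- small_toy(seed = 3)
  topo <- toy$topology
  params <- plant_all_couplings(toy$params, toy$annotation)
  cfg <- toy$configuration
  cfg$speckle_state <- mixed_states(length(cfg$speckle_state))
  got <- total_energy_forces(cfg, topo, params)
  want <- reference_total_energy(cfg, topo, params)
  expect_equal(got$energy, want, tolerance = 1e-10)
  expect_equal(got$energy, sum(got$components), tolerance = 1e-12)
})

test_that("analytic forces match central-difference gradients", {
  toy <- small_toy(seed = 8)
  topo <- toy$topology
  params <- plant_all_couplings(toy$params, toy$annotation)
  cfg <- toy$configuration
  cfg$speckle_state <- mixed_states(length(cfg$speckle_state))
  ef <- total_energy_forces(cfg, topo, params)
  h <- 1e-5
  set.seed(21)
  comps <- sample(topo$n_particles * 3, 30)
  for (k in comps) {
    i <- (k - 1) %% topo$n_particles + 1
    d <- (k - 1) %/% topo$n_particles + 1
    cp <- cfg; cp$positions[i, d] <- cp$positions[i, d] + h
    cm <- cfg; cm$positions[i, d] <- cm$positions[i, d] - h
    num <- -(total_energy_forces(cp, topo, params)$energy -
               total_energy_forces(cm, topo, params)$energy) / (2 * h)
    denom <- max(1, abs(ef$forces[i, d]))
    expect_lt(abs(num - ef$forces[i, d]) / denom, 1e-4)
  }
})

test_that("energy is translation invariant with zero net force", {
  toy <- small_toy(seed = 12)
  topo <- toy$topology
  params <- plant_all_couplings(toy$params, toy$annotation)
  params$confinement$k <- 0  # confinement is defined relative to the centre
  cfg <- toy$configuration
  e1 <- total_energy_forces(cfg, topo, params)
  cfg2 <- cfg
  cfg2$positions <- sweep(cfg2$positions, 2, c(0.37, -1.2, 0.05), "+")
  e2 <- total_energy_forces(cfg2, topo, params)
  expect_equal(e1$energy, e2$energy, tolerance = 1e-10)
  expect_lt(max(abs(colSums(e1$forces))), 1e-8)
})

test_that("two bonded beads at rest length have zero bond energy and net force", {
  tab <- data.frame(chrom = "c1", length = 2e5, copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = c("A", "A")))
  topo <- build_topology(ann, 0, 0, NULL, radius = 50)
  params <- default_forcefield_parameters(ann, confinement_radius = 50)
  cfg <- nucleus_configuration(rbind(c(0, 0, 0), c(1, 0, 0)), topo)
  ef <- total_energy_forces(cfg, topo, params)
  expect_equal(unname(ef$components["bond"]), 0)
  expect_equal(ef$energy, 0)
  expect_equal(max(abs(ef$forces)), 0)
})

test_that("overlapping particles get capped soft-core energy and finite forces", {
  toy <- small_toy()
  topo <- toy$topology
  params <- toy$params
  cfg <- toy$configuration
  # put a nucleolus exactly on top of another
  idx <- particle_indices(topo, "nucleolus")[1:2]
  cfg$positions[idx[2], ] <- cfg$positions[idx[1], ]
  ef <- total_energy_forces(cfg, topo, params)
  expect_true(is.finite(ef$energy))
  expect_true(all(is.finite(ef$forces)))
  # and a chromatin bead on a lamina vertex
  lam <- particle_indices(topo, "lamina")[1]
  cfg$positions[1, ] <- cfg$positions[lam, ]
  ef2 <- total_energy_forces(cfg, topo, params)
  expect_true(is.finite(ef2$energy))
  expect_true(all(is.finite(ef2$forces)))
})

test_that("with only backbone bonds a free chain shows random-walk internal distances", {
  # ideal-chain limit: all couplings off, no confinement, free space
  tab <- data.frame(chrom = "c1", length = 4e6, copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = rep("A", 40)))
  topo <- build_topology(ann, 0, 0, NULL, radius = 1e4)
  params <- default_forcefield_parameters(ann, confinement_radius = 1e4)
  params$confinement$k <- 0
  params$excluded_volume$strength <- 0
  pos <- matrix(0, 40, 3)
  pos[, 1] <- seq_len(40)
  cfg <- nucleus_configuration(pos, topo)
  traj <- run_simulation(topo, params, n_steps = 60000, record_interval = 500,
                         reactions = NULL, seed = 2, initial = cfg)
  keep <- trajectory_frames(traj, 10000)
  seps <- c(2, 4, 8, 16)
  msd_int <- vapply(seps, function(s) {
    v <- 0; n <- 0
    for (k in keep) {
      X <- traj$frames[, , k]
      d <- X[seq_len(40 - s), ] - X[(s + 1):40, ]
      v <- v + sum(d^2); n <- n + nrow(d)
    }
    v / n
  }, numeric(1))
  # <R^2(s)> ~ b^2 s for a random walk: fit slope on log-log axes
  slope <- coef(lm(log(msd_int) ~ log(seps)))[2]
  expect_gt(slope, 0.75)
  expect_lt(slope, 1.25)
})

test_that("force-field parameters serialize to JSON and back losslessly", {
  toy <- small_toy()
  params <- plant_all_couplings(toy$params, toy$annotation)
  params$alpha_ideal[7] <- pi / 3  # full double precision must survive
  path <- withr::local_tempfile(fileext = ".json")
  write_forcefield_parameters(params, path)
  back <- read_forcefield_parameters(path)
  expect_equal(back$alpha_ideal, params$alpha_ideal, tolerance = 0)
  expect_equal(back$compartment, params$compartment, tolerance = 0)
  expect_equal(back$chrom_pair, params$chrom_pair, tolerance = 0)
  expect_equal(back$chi_lamina, params$chi_lamina, tolerance = 0)
  expect_equal(back$contact$r_c, params$contact$r_c)
  expect_equal(back$lj$eps_nucleolus, params$lj$eps_nucleolus)
  # and the engine accepts the round-tripped object unchanged
  e1 <- total_energy_forces(toy$configuration, toy$topology, params)$energy
  e2 <- total_energy_forces(toy$configuration, toy$topology, back)$energy
  expect_identical(e1, e2)
})
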