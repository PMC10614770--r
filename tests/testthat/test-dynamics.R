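test_that("integrator and reaction specs validate their inputs", {
  expect_equal(integrator_spec("langevin")$gamma_inv, 10)
  expect_equal(integrator_spec("brownian")$gamma_inv, 0.01)
  expect_equal(integrator_spec("langevin")$dt, 0.005)
  expect_error(integrator_spec(dt = -1))
  rx <- speckle_reaction_spec()
  expect_equal(rx$interval, 4000L)
  expect_equal(rx$prob, 0.2)
  expect_error(speckle_reaction_spec(prob = 1.5))
  expect_error(deformation_spec(-1), "non-negative")
})

test_that("zero forces at zero temperature leave positions unchanged", {
  sys <- free_particle_system()
  intg <- integrator_spec("brownian", temperature = 0)
  cfg <- integrate_step(sys$cfg, sys$topo, sys$params, intg, seed = 1,
                        n_steps = 100)
  expect_equal(cfg$positions, sys$cfg$positions, tolerance = 1e-14)
  intg2 <- integrator_spec("langevin", temperature = 0)
  cfg2 <- integrate_step(sys$cfg, sys$topo, sys$params, intg2, seed = 1,
                         n_steps = 100)
  expect_equal(cfg2$positions, sys$cfg$positions, tolerance = 1e-14)
})

test_that("identical seeds give bit-identical trajectories; different seeds differ", {
  toy <- small_toy(seed = 2)
  t1 <- run_simulation(toy$topology, toy$params, n_steps = 2000,
                       record_interval = 500, seed = 5,
                       initial = toy$configuration)
  t2 <- run_simulation(toy$topology, toy$params, n_steps = 2000,
                       record_interval = 500, seed = 5,
                       initial = toy$configuration)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$speckle_states, t2$speckle_states)
  t3 <- run_simulation(toy$topology, toy$params, n_steps = 2000,
                       record_interval = 500, seed = 6,
                       initial = toy$configuration)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("short runs record the initial frame only", {
  toy <- small_toy()
  tr <- run_simulation(toy$topology, toy$params, n_steps = 10,
                       record_interval = 2000, seed = 1,
                       initial = toy$configuration)
  expect_equal(n_frames(tr), 1L)
  expect_equal(tr$frames[, , 1], toy$configuration$positions)
})

test_that("frozen lamina coordinates are bit-identical across the trajectory", {
  toy <- small_toy(seed = 4)
  tr <- run_simulation(toy$topology, toy$params, n_steps = 4000,
                       record_interval = 500, seed = 9,
                       initial = toy$configuration)
  lam <- particle_indices(toy$topology, "lamina")
  for (k in 2:n_frames(tr)) {
    expect_identical(tr$frames[lam, , k], tr$frames[lam, , 1])
  }
  # non-lamina particles did move
  expect_false(identical(tr$frames[1, , 1], tr$frames[1, , n_frames(tr)]))
})

test_that("checkpoint/restart reproduces the uninterrupted run bit-exactly", {
  toy <- small_toy(seed = 6)
  full <- run_simulation(toy$topology, toy$params, n_steps = 3000,
                         record_interval = 500, seed = 11,
                         initial = toy$configuration)
  part1 <- run_simulation(toy$topology, toy$params, n_steps = 2000,
                          record_interval = 500, seed = 11,
                          initial = toy$configuration)
  part2 <- run_simulation(toy$topology, toy$params, n_steps = 1000,
                          record_interval = 500, seed = 11,
                          resume = part1$checkpoint)
  expect_identical(full$frames[, , 7], part2$frames[, , 3])
  expect_identical(full$frames[, , 6], part2$frames[, , 2])
  expect_identical(full$speckle_states[7, ], part2$speckle_states[3, ])
  expect_equal(part2$steps[3], 3000)
})

test_that("free Brownian particle recovers its diffusion coefficient and linear MSD", {
  sys <- free_particle_system()
  u <- unit_system()
  curves <- lapply(1:100, function(s) {
    tr <- run_simulation(sys$topo, sys$params, n_steps = 10000,
                         record_interval = 10,
                         integrator = integrator_spec("brownian"),
                         reactions = NULL, seed = s, initial = sys$cfg)
    compute_msd(tr, 1, units = u, fit_window = c(0, Inf),
                max_lag_frames = 100)
  })
  msd <- rowMeans(vapply(curves, function(r) r$msd_um2,
                         numeric(length(curves[[1]]$msd_um2))))
  lag_s <- curves[[1]]$lag_s
  fit <- lm(log(msd) ~ log(lag_s))
  alpha <- unname(coef(fit)[2])
  # MSD = 6 D t; convert the fitted coefficient back to reduced units
  D_red <- unname(exp(coef(fit)[1])) / 6 / (u$sigma_nm / 1000)^2 * u$tau_s
  expect_equal(alpha, 1.0, tolerance = 0.03)
  expect_equal(D_red, 0.01, tolerance = 0.05)  # input D = T / gamma = 0.01
})

test_that("harmonically tethered Langevin particle satisfies equipartition", {
  # confinement with radius 0 is an isotropic spring U = k r^2, i.e.
  # per-coordinate stiffness 2k: stationary variance T / (2k)
  sys <- free_particle_system(confinement = 5)
  sys$params$confinement$radius <- 0
  tr <- run_simulation(sys$topo, sys$params, n_steps = 1e6,
                       record_interval = 50,
                       integrator = integrator_spec("langevin", gamma_inv = 1),
                       reactions = NULL, seed = 7, initial = sys$cfg)
  burn <- 1000
  v <- c(tr$frames[1, 1, -(1:burn)], tr$frames[1, 2, -(1:burn)],
         tr$frames[1, 3, -(1:burn)])
  expect_equal(var(v), 1 / (2 * 5), tolerance = 0.03)
})

test_that("Langevin kinetic temperature sits at T = 1 after burn-in", {
  # chains-only toy (no stiff Lennard-Jones cores)
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 2, beads_per_chain = 50,
                                   n_nucleolus = 0, n_speckle = 0,
                                   n_lamina = 60, seed = 3))
  tr <- run_simulation(toy$topology, toy$params, n_steps = 30000,
                       record_interval = 100, reactions = NULL, seed = 13,
                       initial = toy$configuration)
  kt <- mean(tr$kinetic_temperature[-(1:100)])
  expect_equal(kt, 1.0, tolerance = 0.02)
})

test_that("speckle reactions flip states binomially at zero couplings", {
  toy <- small_toy(seed = 9)
  n_spk <- unname(toy$topology$counts["speckle"])
  p0 <- toy$params
  p0$lj$eps_speckle <- 0; p0$lj$eps_nucleolus <- 0; p0$lj$eps_repulsive <- 0
  cfg <- toy$configuration
  n_sweeps <- 500
  flips <- integer(n_sweeps)
  for (i in seq_len(n_sweeps)) {
    res <- speckle_reaction_sweep(cfg, toy$topology, p0, seed = i)
    flips[i] <- res$n_flips
    # particle count and positions unchanged
    expect_identical(res$configuration$positions, cfg$positions)
    expect_length(res$configuration$speckle_state, n_spk)
    cfg <- res$configuration
  }
  # with dE = 0 every proposal is accepted: flips ~ Binomial(N_Sp, 0.2)
  se <- sqrt(0.2 * 0.8 / (n_spk * n_sweeps))
  expect_lt(abs(mean(flips) / n_spk - 0.2), 3 * se)
  # symmetric Markov chain: stationary dP fraction 1/2
  frac <- mean(vapply(1:800, function(i) {
    res <- speckle_reaction_sweep(cfg, toy$topology, p0, seed = 1000 + i)
    cfg <<- res$configuration
    mean(cfg$speckle_state)
  }, numeric(1)))
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("Metropolis acceptance suppresses dP->P flips inside droplets", {
  # strongly bound dP droplet vs isolated dP particles far away
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 1, beads_per_chain = 2,
                                   n_nucleolus = 0, n_speckle = 20,
                                   n_lamina = 0, seed = 1))
  topo <- toy$topology
  params <- toy$params
  params$lj$eps_speckle <- 4
  params$confinement$k <- 0
  pos <- toy$configuration$positions
  spk <- particle_indices(topo, "speckle")
  # 10 droplet particles on a tight cluster, 10 isolated far apart
  rmin <- 2^(1 / 6) * params$lj$sigma
  grid <- as.matrix(expand.grid(0:1, 0:1, 0:2))[1:10, ] * rmin
  pos[spk[1:10], ] <- grid
  pos[spk[11:20], ] <- 100 + matrix(seq_len(30), 10, 3) * 10
  cfg <- nucleus_configuration(pos, topo,
                               speckle_state = rep(1L, 20))
  in_flips <- 0; out_flips <- 0
  for (i in 1:300) {
    res <- speckle_reaction_sweep(cfg, topo, params, seed = i)
    st <- res$configuration$speckle_state
    in_flips <- in_flips + sum(st[1:10] == 0L)
    out_flips <- out_flips + sum(st[11:20] == 0L)
    # reset states so each sweep starts from all-dP
    cfg$speckle_state <- rep(1L, 20)
  }
  expect_lt(in_flips, out_flips)
  expect_lt(in_flips / max(out_flips, 1), 0.5)
})

test_that("nucleolus particles coarsen into few droplets under the tuned coupling", {
  toy <- make_toy_nucleus(toy_spec(seed = 11))
  tr <- run_simulation(toy$topology, toy$params, n_steps = 2e5,
                       record_interval = 1e4, seed = 5,
                       initial = toy$configuration)
  first <- cluster_droplets(frame_configuration(tr, toy$topology, 1),
                            toy$topology, "nucleolus", min_size = 1)
  last <- cluster_droplets(frame_configuration(tr, toy$topology),
                           toy$topology, "nucleolus")
  expect_gt(first$n_clusters, 3)
  expect_lte(last$n_clusters, 3)
  expect_gte(max(last$sizes), 15)  # most particles condensed
})

test_that("deformation requires a dynamic lamina and compresses monotonically with force", {
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 2, beads_per_chain = 40,
                                   n_nucleolus = 6, n_speckle = 12,
                                   n_lamina = 300, seed = 8))
  topo <- toy$topology
  run_shape <- function(force_k, n_steps = 30000) {
    params <- apply_deformation(toy$params, deformation_spec(force_k),
                                frozen_lamina = FALSE)
    tr <- run_simulation(topo, params, n_steps = n_steps,
                         record_interval = n_steps / 10, seed = 3,
                         initial = toy$configuration, frozen_lamina = FALSE)
    lamina_shape(tr, topo, frames = 6:11)
  }
  expect_error(apply_deformation(toy$params, deformation_spec(1),
                                 frozen_lamina = TRUE), "unfrozen|dynamic")
  expect_error(run_simulation(topo,
                              apply_deformation(toy$params, deformation_spec(1)),
                              n_steps = 10, seed = 1,
                              initial = toy$configuration,
                              frozen_lamina = TRUE), "frozen_lamina")
  a0 <- run_shape(0)
  a1 <- run_shape(2)
  a2 <- run_shape(6)
  # no drive: the envelope stays spherical within 5%
  expect_lt(a0$sphericity, 1.05)
  # stronger z-compression -> more oblate
  expect_lt(a1$axial_ratio, a0$axial_ratio)
  expect_lt(a2$axial_ratio, a1$axial_ratio)
  # mesh integrity: no edge stretches beyond 3x its rest length
  expect_lt(a0$max_edge_stretch, 3)
  expect_lt(a2$max_edge_stretch, 3)
})

test_that("non-finite forces abort with a diagnostic naming the particle", {
  sys <- free_particle_system()
  sys$cfg$positions[1, ] <- c(NaN, 0, 0)
  expect_error(
    run_simulation(sys$topo, sys$params, n_steps = 2000,
                   record_interval = 100, seed = 1, initial = sys$cfg),
    "non-finite")
})
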