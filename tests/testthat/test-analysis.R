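test_that("contact maps equal the brute-force per-pair average and are symmetric", {
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 2, beads_per_chain = 8,
                                   n_nucleolus = 3, n_speckle = 4,
                                   n_lamina = 30, seed = 2))
  cf <- toy$params$contact
  traj <- run_simulation(toy$topology, toy$params, n_steps = 900,
                         record_interval = 300, seed = 7,
                         initial = toy$configuration)
  cm <- compute_contact_map(traj, toy$topology, cf)
  ref <- reference_contact_map(traj, toy$topology, cf)
  expect_equal(cm$matrix, ref, tolerance = 1e-12)
  expect_equal(max(abs(cm$matrix - t(cm$matrix))), 0)
  expect_true(all(cm$matrix >= 0 & cm$matrix <= 1))
  # diploid (raw) variant matches too
  cm2 <- compute_contact_map(traj, toy$topology, cf, homolog_average = FALSE)
  ref2 <- reference_contact_map(traj, toy$topology, cf, homolog = FALSE)
  expect_equal(cm2$matrix, ref2, tolerance = 1e-12)
  # diagonal sits at the contact saturation value
  expect_equal(unname(diag(cm$matrix)), rep(contact_indicator(0, cf),
                                            nrow(cm$matrix)))
})

test_that("homolog averaging is idempotent and commutes with frame averaging", {
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 2, beads_per_chain = 6,
                                   n_nucleolus = 0, n_speckle = 0,
                                   n_lamina = 20, seed = 5))
  cf <- toy$params$contact
  traj <- run_simulation(toy$topology, toy$params, n_steps = 1200,
                         record_interval = 300, seed = 1,
                         initial = toy$configuration)
  whole <- compute_contact_map(traj, toy$topology, cf)$matrix
  # per-frame maps collapsed then averaged
  per <- lapply(seq_len(n_frames(traj)), function(k) {
    sub <- traj
    sub$frames <- traj$frames[, , k, drop = FALSE]
    sub$speckle_states <- traj$speckle_states[k, , drop = FALSE]
    sub$steps <- traj$steps[k]
    compute_contact_map(sub, toy$topology, cf)$matrix
  })
  expect_equal(Reduce(`+`, per) / length(per), whole, tolerance = 1e-12)
})

test_that("straight unit-bond chain decays monotonically along off-diagonals", {
  tab <- data.frame(chrom = "c1", length = 1e6, copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = rep("A", 10)))
  topo <- build_topology(ann, 0, 0, NULL, radius = 100)
  cf <- contact_function()
  pos <- cbind(seq_len(10), 0, 0)
  traj <- structure(list(frames = array(pos, c(10, 3, 1)),
                         speckle_states = matrix(integer(0), 1, 0),
                         steps = 0, record_interval = 1,
                         integrator = integrator_spec()),
                    class = "nucleus_trajectory")
  cm <- compute_contact_map(traj, topo, cf)
  expect_equal(cm$matrix[1, 2], contact_indicator(1, cf))
  offdiag <- vapply(1:9, function(s) cm$matrix[1, 1 + s], numeric(1))
  expect_true(all(diff(offdiag) < 0))
  sc <- contact_scaling(cm)
  expect_equal(sc$p, offdiag, tolerance = 1e-12)  # straight chain: all equal
  # constant matrix gives a flat curve
  cm_const <- cm
  cm_const$matrix <- matrix(0.3, 10, 10)
  expect_equal(unique(contact_scaling(cm_const)$p), 0.3)
})

test_that("contact scaling of a free ideal chain shows random-walk decay", {
  # with only backbone bonds in free space, <R^2(s)> ~ s, so the contact
  # probability decays like s^(-3/2) at intermediate separations
  tab <- data.frame(chrom = "c1", length = 6e6, copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = rep("A", 60)))
  topo <- build_topology(ann, 0, 0, NULL, radius = 1e4)
  params <- default_forcefield_parameters(ann, confinement_radius = 1e4)
  params$confinement$k <- 0
  params$excluded_volume$strength <- 0
  pos <- cbind(seq_len(60), 0, 0)
  traj <- run_simulation(topo, params, n_steps = 120000,
                         record_interval = 1000, reactions = NULL, seed = 3,
                         initial = nucleus_configuration(pos, topo))
  cm <- compute_contact_map(traj, topo, contact_function(),
                            discard_steps = 20000)
  sc <- contact_scaling(cm)
  mid <- sc[sc$s >= 4 & sc$s <= 24, ]
  slope <- unname(coef(lm(log(mid$p) ~ log(mid$s)))[2])
  expect_lt(slope, -1.1)
  expect_gt(slope, -1.9)
})

test_that("in-silico profiles match the oracle, with the dP-only speckle convention", {
  toy <- small_toy(seed = 17)
  cf <- toy$params$contact
  traj <- run_simulation(toy$topology, toy$params, n_steps = 800,
                         record_interval = 400, seed = 4,
                         initial = toy$configuration)
  for (kind in c("damid", "tsaseq")) {
    pr <- insilico_profile(traj, toy$topology, kind, cf, standardize = TRUE)
    ref <- reference_profile(traj, toy$topology, kind, cf)
    expect_equal(pr$signal, ref, tolerance = 1e-12)
  }
  # all speckles permanently P: TSA-like profile identically zero
  trajP <- traj
  trajP$speckle_states[] <- 0L
  prP <- insilico_profile(trajP, toy$topology, "tsaseq", cf,
                          standardize = FALSE)
  expect_identical(prP$signal, rep(0, length(prP$signal)))
  # missing landmark category is rejected
  toy2 <- make_toy_nucleus(toy_spec(n_chromosomes = 1, beads_per_chain = 5,
                                    n_nucleolus = 0, n_speckle = 0,
                                    n_lamina = 0, seed = 1))
  traj2 <- run_simulation(toy2$topology, toy2$params, n_steps = 0,
                          record_interval = 1, seed = 1,
                          initial = toy2$configuration)
  expect_error(insilico_profile(traj2, toy2$topology, "damid"), "no lamina")
})

test_that("a bead pinned at the lamina saturates DamID while a central bead reads zero", {
  tab <- data.frame(chrom = "c1", length = 2e5, copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = c("A", "A")))
  mesh <- build_lamina_mesh(radius = 8, n_vertices = 100)
  topo <- build_topology(ann, 0, 0, mesh)
  cf <- contact_function()
  pos <- rbind(mesh$vertices[1, ] * (1 - 0.01), c(0, 0, 0), mesh$vertices)
  traj <- structure(list(frames = array(pos, c(nrow(pos), 3, 1)),
                         speckle_states = matrix(integer(0), 1, 0),
                         steps = 0, record_interval = 1,
                         integrator = integrator_spec()),
                    class = "nucleus_trajectory")
  pr <- insilico_profile(traj, topo, "damid", cf, standardize = FALSE)
  expect_gt(pr$signal[1], 0.99)
  expect_lt(pr$signal[2], 1e-6)
})

test_that("MSD estimator: immobile particle, translation invariance, pooled mean", {
  toy <- small_toy(seed = 19)
  traj <- run_simulation(toy$topology, toy$params, n_steps = 2000,
                         record_interval = 100, seed = 2,
                         initial = toy$configuration)
  lam <- particle_indices(toy$topology, "lamina")[1]  # frozen: immobile
  res <- compute_msd(traj, lam)
  expect_true(all(res$msd_um2 == 0))
  expect_true(is.na(res$alpha))  # fit refused on a degenerate curve
  ids <- 1:5
  res2 <- compute_msd(traj, ids, fit_window = c(0, Inf))
  # pooled MSD equals the mean of per-particle MSDs
  expect_equal(res2$msd_um2, rowMeans(res2$per_particle), tolerance = 1e-12)
  # invariant under global translation of every frame
  shifted <- traj
  shifted$frames <- traj$frames + 5
  res3 <- compute_msd(shifted, ids, fit_window = c(0, Inf))
  expect_equal(res2$msd_um2, res3$msd_um2, tolerance = 1e-12)
  # fewer than 5 lag points in the window: curve only
  res4 <- compute_msd(traj, ids, fit_window = c(1e9, 2e9))
  expect_true(is.na(res4$alpha))
  expect_true(all(is.finite(res4$msd_um2)))
})

test_that("chromosome geometry: analytic radii of gyration and radial positions", {
  tab <- data.frame(chrom = c("c1", "c2"), length = c(1e5, 2e5), copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = "A", c2 = c("A", "B")))
  topo <- build_topology(ann, 0, 0, NULL, radius = 2)
  pos <- rbind(c(0, 0, 0),          # single-bead chain at the centre
               c(2, 0, 0), c(2, 0, 0.8))  # two-bead chain, d = 0.8
  traj <- structure(list(frames = array(pos, c(3, 3, 1)),
                         speckle_states = matrix(integer(0), 1, 0),
                         steps = 0, record_interval = 1,
                         integrator = integrator_spec()),
                    class = "nucleus_trajectory")
  geo <- chromosome_geometry(traj, topo)
  u <- unit_system()
  expect_equal(geo$mean_rg_um[1], 0)
  expect_equal(geo$mean_rg_um[2], 0.4 * u$sigma_nm / 1000)  # d/2 in um
  expect_equal(geo$mean_radial_bead[1], 0)      # centre bead
  expect_equal(unname(geo$radial_chain[1, 1]), 0)
  expect_equal(geo$mean_radial_bead[2], 1)      # bead on the lamina radius
})

test_that("droplet clustering equals a union-find oracle and responds to cutoff monotonically", {
  toy <- make_toy_nucleus(toy_spec(n_chromosomes = 1, beads_per_chain = 2,
                                   n_nucleolus = 200, n_speckle = 0,
                                   n_lamina = 0, seed = 23))
  topo <- toy$topology
  cfg <- toy$configuration
  set.seed(31)
  idx <- particle_indices(topo, "nucleolus")
  cfg$positions[idx, ] <- matrix(runif(600, -3, 3), ncol = 3)
  # union-find oracle
  uf_clusters <- function(P, cutoff, min_size) {
    n <- nrow(P)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((P[i, ] - P[j, ])^2)) <= cutoff) {
        parent[find(i)] <<- find(j)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    sum(table(roots) >= min_size)
  }
  parent <- NULL
  for (cutoff in c(0.3, 0.6, 1.0)) {
    got <- cluster_droplets(cfg, topo, "nucleolus", cutoff = cutoff)
    P <- cfg$positions[idx, ]
    n <- nrow(P)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((P[i, ] - P[j, ])^2)) <= cutoff) {
        parent[find(i)] <- find(j)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    expect_equal(got$n_clusters, sum(table(roots) >= 2L))
  }
  # monotone: connected-component count non-increasing as the cutoff grows
  cuts <- seq(0.2, 2, by = 0.2)
  counts <- vapply(cuts, function(h)
    cluster_droplets(cfg, topo, "nucleolus", cutoff = h,
                     min_size = 1)$n_clusters, integer(1))
  expect_true(all(diff(counts) <= 0))
  # degenerate cases
  far <- cfg
  far$positions[idx, ] <- cbind(seq_along(idx) * 10, 0, 0)
  expect_equal(cluster_droplets(far, topo, "nucleolus", cutoff = 1)$n_clusters, 0L)
  expect_equal(cluster_droplets(far, topo, "nucleolus", cutoff = 11)$n_clusters, 1L)
})

test_that("ensemble correlations match direct Pearson computation", {
  set.seed(41)
  mats <- lapply(1:4, function(i) {
    m <- matrix(runif(64), 8, 8)
    (m + t(m)) / 2
  })
  res <- ensemble_correlations(mats)
  # direct textbook computation on flattened upper triangles
  v <- sapply(mats, function(m) m[upper.tri(m)])
  expect_equal(res$correlations, cor(v), tolerance = 1e-12)
  expect_equal(res$mean_offdiagonal, mean(cor(v)[upper.tri(cor(v))]),
               tolerance = 1e-12)
  # identical inputs correlate at exactly 1; a negation at -1
  same <- ensemble_correlations(list(mats[[1]], mats[[1]]))
  expect_equal(unname(same$correlations[1, 2]), 1)
  neg <- ensemble_correlations(list(mats[[1]], -mats[[1]]))
  expect_equal(unname(neg$correlations[1, 2]), -1)
  expect_error(ensemble_correlations(list(mats[[1]])), "two")
  expect_error(ensemble_correlations(list(mats[[1]], matrix(1, 2, 2))),
               "mismatched")
})
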