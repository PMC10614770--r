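# Shared builders for small deterministic test systems.

# single free particle in a huge sphere, all couplings off
free_particle_system <- function(radius = 100, confinement = 0) {
  tab <- data.frame(chrom = "c1", length = 1e5, copies = 1L)
  ann <- build_genome_annotation(tab, list(c1 = "A"))
  topo <- build_topology(ann, 0, 0, NULL, radius = radius)
  params <- default_forcefield_parameters(ann, confinement_radius = radius)
  params$confinement$k <- confinement
  cfg <- nucleus_configuration(matrix(0, 1, 3), topo)
  list(ann = ann, topo = topo, params = params, cfg = cfg)
}

# small dense toy used for force checks and oracle comparisons
small_toy <- function(seed = 3, n_chrom = 1L, beads = 20L) {
  make_toy_nucleus(toy_spec(
    n_chromosomes = n_chrom, beads_per_chain = beads,
    block_size = 5L, n_terminal_c = 1L,
    n_nucleolus = 5L, n_speckle = 8L, n_lamina = 30L, seed = seed
  ))
}

# plant every coupling class with non-zero values
plant_all_couplings <- function(params, ann) {
  params$alpha_ideal[seq_len(min(5, length(params$alpha_ideal)))] <-
    c(-0.5, -0.3, -0.2, -0.1, -0.05)[seq_len(min(5, length(params$alpha_ideal)))]
  params$compartment["A", "A"] <- -0.4
  params$compartment["A", "B"] <- params$compartment["B", "A"] <- 0.2
  params$compartment["C", "C"] <- -0.3
  params$chrom_pair[1, 1] <- -0.1
  if (nrow(params$chrom_pair) > 1) {
    params$chrom_pair[1, 2] <- params$chrom_pair[2, 1] <- -0.15
  }
  params$chi_lamina[] <- -0.3
  params$chi_speckle[] <- -0.2
  params$chi_nucleolus[] <- -0.25
  params
}

# mixed speckle states for state-dependent terms
mixed_states <- function(n) rep(c(1L, 0L), length.out = n)

# plain-R reference for the total energy of a configuration: loops over
# every pair and sums each term independently of the compiled engine
reference_total_energy <- function(cfg, topo, params) {
  pos <- cfg$positions
  n <- nrow(pos)
  pt <- topo$particles
  cf <- params$contact
  d_ev <- params$excluded_volume$diameters
  ev_e <- params$excluded_volume$strength
  bonded <- matrix(FALSE, n, n)
  if (nrow(topo$bonds) > 0) {
    bonded[topo$bonds] <- TRUE
    bonded[topo$bonds[, c(2, 1), drop = FALSE]] <- TRUE
  }
  state_of <- function(i) {
    if (pt$category[i] != "speckle") return(NA_character_)
    k <- match(i, particle_indices(topo, "speckle"))
    if (cfg$speckle_state[k] == 1L) "dP" else "P"
  }
  softcore <- function(r, d) if (r < d) ev_e * (1 - r / d)^2 else 0
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      ci <- pt$category[i]; cj <- pt$category[j]
      both_body <- ci %in% c("nucleolus", "speckle") &&
        cj %in% c("nucleolus", "speckle")
      if (both_body) {
        e <- e + body_pair_energy(r, ci, cj, state_of(i), state_of(j), params)
        next
      }
      if (!bonded[i, j]) {
        e <- e + softcore(r, (d_ev[[ci]] + d_ev[[cj]]) / 2)
      }
      if (ci == "chromatin" && cj == "chromatin") {
        e <- e + chromatin_pair_energy(topo, params, i, j, r)
      } else if (ci == "chromatin" || cj == "chromatin") {
        bead <- if (ci == "chromatin") i else j
        lm <- if (ci == "chromatin") j else i
        e <- e + landmark_coupling_energy(topo, params, bead, lm, r,
                                          state = state_of(lm))
      }
    }
  }
  for (b in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds[b, 1]; j <- topo$bonds[b, 2]
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    k <- if (topo$bond_type[b] == "backbone") params$bond$k else
      params$lamina_bond_k
    e <- e + 0.5 * k * (r - topo$bond_r0[b])^2
  }
  R <- params$confinement$radius
  kc <- params$confinement$k
  for (i in seq_len(n)) {
    if (kc > 0 && pt$category[i] != "lamina") {
      r <- sqrt(sum(pos[i, ]^2))
      if (r > R) e <- e + kc * (r - R)^2
    }
    if (params$deformation$k_z > 0 && pt$category[i] == "lamina") {
      e <- e + 0.5 * params$deformation$k_z * pos[i, 3]^2
    }
  }
  e
}

# plain-R oracle for the landmark union-contact profile
reference_profile <- function(traj, topo, kind, cf, discard = 0) {
  keep <- trajectory_frames(traj, discard)
  idx <- particle_indices(topo, "chromatin")
  ann <- topo$annotation
  acc <- numeric(length(idx))
  for (k in keep) {
    lm <- if (kind == "damid") particle_indices(topo, "lamina") else {
      spk <- particle_indices(topo, "speckle")
      spk[traj$speckle_states[k, ] == 1L]
    }
    for (b in seq_along(idx)) {
      prodterm <- 1
      for (l in lm) {
        r <- sqrt(sum((traj$frames[idx[b], , k] - traj$frames[l, , k])^2))
        prodterm <- prodterm * (1 - contact_indicator(r, cf))
      }
      acc[b] <- acc[b] + (1 - prodterm)
    }
  }
  per_bead <- acc / length(keep)
  out <- numeric(ann$n_haploid_bins)
  cnt <- numeric(ann$n_haploid_bins)
  for (b in seq_along(per_bead)) {
    h <- ann$haploid_index[b]
    out[h] <- out[h] + per_bead[b]; cnt[h] <- cnt[h] + 1
  }
  out / cnt
}


# brute-force contact map over diploid beads, then homolog-collapsed
reference_contact_map <- function(traj, topo, cf, homolog = TRUE) {
  idx <- particle_indices(topo, "chromatin")
  nb <- length(idx)
  M <- matrix(0, nb, nb)
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    X <- traj$frames[idx, , k]
    for (i in seq_len(nb)) {
      for (j in seq_len(nb)) {
        M[i, j] <- M[i, j] +
          contact_indicator(sqrt(sum((X[i, ] - X[j, ])^2)), cf)
      }
    }
  }
  M <- M / nf
  if (!homolog) return(M)
  ann <- topo$annotation
  H <- matrix(0, ann$n_haploid_bins, ann$n_haploid_bins)
  cnt <- matrix(0, ann$n_haploid_bins, ann$n_haploid_bins)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      u <- ann$haploid_index[i]; v <- ann$haploid_index[j]
      H[u, v] <- H[u, v] + M[i, j]
      cnt[u, v] <- cnt[u, v] + 1
    }
  }
  H <- H / cnt
  diag(H) <- contact_indicator(0, cf)
  H
}

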