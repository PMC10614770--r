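#' Smooth contact function
#'
#' The model scores a pair of particles at distance `r` as "in contact"
#' with the smooth, differentiable weight
#' `f(r) = (1 + tanh(eta * (r_c - r))) / 2`,
#' which is 1/2 at the contact radius `r_c`, saturates towards 1 at short range, and
#' decays to 0 beyond.  The same function defines coupling energies in the
#' force field and contact observables in the analysis, keeping the
#' parameterization self-consistent.  Interactions are truncated at
#' `cutoff` (default `r_c + 4/eta`, where `f < 2e-4`) and shifted so the
#' energy is continuous there.
#'
#' @param r_c contact radius in reduced units.
#' @param eta steepness (dimensionless).
#' @param cutoff truncation radius for energy terms.
#' @return A `contact_function` object.
#' @export
contact_function <- function(r_c = 1.75, eta = 3, cutoff = r_c + 4 / eta) {
  stopifnot(r_c > 0, eta > 0, cutoff > r_c)
  structure(list(r_c = r_c, eta = eta, cutoff = cutoff),
            class = "contact_function")
}

#' Contact weight at a distance
#'
#' @param distance non-negative distance(s) in reduced units.
#' @param cf a [contact_function()].
#' @param shifted if `TRUE`, subtract the value at the cutoff and clamp to
#'   zero beyond it (the form used inside energy terms); if `FALSE`
#'   (default) return the bare indicator used for observables.
#' @return weight(s) in (0, 1).
#' @export
contact_indicator <- function(distance, cf = contact_function(),
                              shifted = FALSE) {
  if (any(distance < 0)) stop("distance must be non-negative")
  f <- 0.5 * (1 + tanh(cf$eta * (cf$r_c - distance)))
  if (shifted) {
    fcut <- 0.5 * (1 + tanh(cf$eta * (cf$r_c - cf$cutoff)))
    f <- ifelse(distance < cf$cutoff, f - fcut, 0)
  }
  f
}

#' Analytic derivative of the contact weight with respect to distance
#' @inheritParams contact_indicator
#' @export
contact_indicator_deriv <- function(distance, cf = contact_function()) {
  t <- tanh(cf$eta * (cf$r_c - distance))
  -0.5 * cf$eta * (1 - t^2)
}

#' Default force-field parameters for a nucleus topology
#'
#' Creates a `forcefield_parameters` object with every tunable coupling
#' set to zero and the structural terms at their defaults: harmonic
#' backbone bonds (k = 30, rest length 1), bounded soft-core excluded
#' volume (height 10, particle diameter 0.5 for every category, which
#' permits rare chain crossing and speeds equilibration), 12-6
#' Lennard-Jones condensation for nucleolus-nucleolus and dP-dP speckle
#' pairs (sigma_LJ = 0.5, cutoff 2.5 sigma_LJ), and a harmonic spherical
#' confinement acting on non-lamina particles outside the nuclear radius
#' as a smooth backstop to the particulate lamina mesh.
#'
#' Tunable couplings (all dimensionless prefactors of the contact weight):
#' `alpha_ideal` by genomic separation (clamped at `s_max` beads),
#' `compartment` (symmetric 3x3 over A/B/C), `chrom_pair` (symmetric over
#' haploid chromosomes), and per-haploid-bin landmark couplings
#' `chi_lamina`, `chi_speckle` (dP particles only), `chi_nucleolus`.
#' Negative values are attractive.
#'
#' @param annotation a `genome_annotation` (fixes the coupling dimensions).
#' @param s_max largest tabulated genomic separation for the ideal term.
#' @param contact a [contact_function()].
#' @param eps_nucleolus,eps_speckle Lennard-Jones well depths for
#'   nucleolus-nucleolus and dP-dP speckle pairs; the defaults are tuned
#'   so nucleolar particles condense into a few droplets while the
#'   droplets remain liquid.
#' @param confinement_radius nuclear radius for the confinement backstop.
#' @return A `forcefield_parameters` object.
#' @export
default_forcefield_parameters <- function(annotation,
                                          s_max = NULL,
                                          contact = contact_function(),
                                          eps_nucleolus = 2.0,
                                          eps_speckle = 2.0,
                                          confinement_radius = NUCLEUS_RADIUS_REDUCED) {
  stopifnot(inherits(annotation, "genome_annotation"))
  max_len <- max(annotation$haploid$n_beads)
  if (is.null(s_max)) s_max <- min(1000L, max(1L, max_len - 1L))
  nhap <- nrow(annotation$haploid)
  nbin <- annotation$n_haploid_bins
  comp <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  chrom <- matrix(0, nhap, nhap,
                  dimnames = list(annotation$haploid$chrom,
                                  annotation$haploid$chrom))
  structure(
    list(
      schema_version = 1L,
      contact = contact,
      bond = list(style = "harmonic", k = 30, r0 = 1.0),
      excluded_volume = list(strength = 10,
                             diameters = c(chromatin = 0.5, nucleolus = 0.5,
                                           speckle = 0.5, lamina = 0.5)),
      alpha_ideal = numeric(s_max),
      compartment = comp,
      chrom_pair = chrom,
      chi_lamina = numeric(nbin),
      chi_speckle = numeric(nbin),
      chi_nucleolus = numeric(nbin),
      lj = list(sigma = 0.5, cutoff_factor = 2.5, rcap_factor = 0.8,
                eps_nucleolus = eps_nucleolus, eps_speckle = eps_speckle,
                eps_repulsive = 1.0),
      lamina_bond_k = 30,
      confinement = list(k = 10, radius = confinement_radius),
      deformation = list(k_z = 0)
    ),
    class = "forcefield_parameters"
  )
}

#' @export
print.forcefield_parameters <- function(x, ...) {
  nz <- function(v) sum(v != 0)
  cat(sprintf(
    paste0("forcefield_parameters: contact(r_c=%.3g, eta=%.3g), bond k=%g,",
           " ev=%g\n  nonzero couplings: ideal %d/%d, compartment %d/6,",
           " chrom-pair %d, chi(lam/spk/nuc) %d/%d/%d\n",
           "  LJ eps (nucleolus, speckle dP) = (%g, %g)\n"),
    x$contact$r_c, x$contact$eta, x$bond$k, x$excluded_volume$strength,
    nz(x$alpha_ideal), length(x$alpha_ideal),
    nz(x$compartment[upper.tri(x$compartment, diag = TRUE)]),
    nz(x$chrom_pair[upper.tri(x$chrom_pair, diag = TRUE)]),
    nz(x$chi_lamina), nz(x$chi_speckle), nz(x$chi_nucleolus),
    x$lj$eps_nucleolus, x$lj$eps_speckle
  ))
  invisible(x)
}

## flatten parameters to the list consumed by the compiled engine
.engine_params <- function(params, topology) {
  stopifnot(inherits(params, "forcefield_parameters"))
  if (!isSymmetric(unname(params$compartment)) ||
      !isSymmetric(unname(params$chrom_pair))) {
    stop("compartment and chromosome-pair coupling matrices must be symmetric")
  }
  cf <- params$contact
  list(
    r_c = cf$r_c, eta = cf$eta, cutoff = cf$cutoff,
    ev_strength = params$excluded_volume$strength,
    diameters = unname(params$excluded_volume$diameters[CATEGORY_LEVELS]),
    alpha_ideal = params$alpha_ideal,
    compartment = params$compartment,
    chrom_pair = params$chrom_pair,
    chi_lamina = params$chi_lamina,
    chi_speckle = params$chi_speckle,
    chi_nucleolus = params$chi_nucleolus,
    lj_sigma = params$lj$sigma,
    lj_cutoff = params$lj$cutoff_factor * params$lj$sigma,
    lj_rcap = params$lj$rcap_factor * params$lj$sigma,
    eps_nucleolus = params$lj$eps_nucleolus,
    eps_speckle = params$lj$eps_speckle,
    eps_repulsive = params$lj$eps_repulsive,
    confinement_k = params$confinement$k,
    confinement_radius = params$confinement$radius,
    deformation_k = params$deformation$k_z
  )
}

## integer encodings shared with the engine
.engine_arrays <- function(topology) {
  pt <- topology$particles
  cat_i <- match(pt$category, CATEGORY_LEVELS) - 1L
  chain_i <- ifelse(is.na(pt$chain), -1L, pt$chain - 1L)
  hapbin_i <- ifelse(is.na(pt$hap_bin), -1L, pt$hap_bin - 1L)
  label_i <- ifelse(is.na(pt$label), -1L, match(pt$label, c("A", "B", "C")) - 1L)
  ann <- topology$annotation
  hapchrom_by_chain <- ann$chains$hap_id - 1L
  hapchrom_i <- ifelse(is.na(pt$chain), -1L, hapchrom_by_chain[pt$chain])
  ## hapbin is 0-based over genome-wide haploid bins (indexes the chi
  ## vectors); on the same chain |hapbin_i - hapbin_j| is also the genomic
  ## separation in beads, so one array serves both purposes.
  list(
    cat = as.integer(cat_i), chain = as.integer(chain_i),
    hapbin = as.integer(hapbin_i), hapchrom = as.integer(hapchrom_i),
    label = as.integer(label_i)
  )
}

.engine_bonds <- function(topology, params) {
  bonds <- topology$bonds
  storage.mode(bonds) <- "integer"
  k <- ifelse(topology$bond_type == "backbone", params$bond$k,
              params$lamina_bond_k)
  r0 <- topology$bond_r0
  if (length(r0) == 0) r0 <- numeric(0)
  list(bonds = bonds, r0 = as.numeric(r0), k = as.numeric(k))
}

## speckle state as a per-particle vector (1 = dP, 0 = P, -1 = n/a)
.engine_state <- function(topology, configuration) {
  st <- rep(-1L, topology$n_particles)
  idx <- particle_indices(topology, "speckle")
  if (length(idx)) {
    ss <- configuration$speckle_state
    if (is.null(ss)) ss <- rep(1L, length(idx))
    st[idx] <- as.integer(ss)
  }
  st
}

#' Total potential energy and forces of a configuration
#'
#' Evaluates every energy term of the model (bonds, soft-core excluded
#' volume, chromatin pair couplings, chromatin-landmark couplings,
#' Lennard-Jones body condensation, confinement, z-compression) and the
#' analytic forces (negative gradient).  Forces on frozen lamina
#' particles are reported even though frozen particles are never moved by
#' the integrators.
#'
#' @param configuration a `nucleus_configuration`.
#' @param topology the matching `nucleus_topology`.
#' @param params a `forcefield_parameters`.
#' @param frozen_lamina logical; kept for signature symmetry with the
#'   integrators (forces are always reported for all particles).
#' @return list with `energy` (scalar), `components` (named vector) and
#'   `forces` (n x 3 matrix).
#' @export
total_energy_forces <- function(configuration, topology, params,
                                frozen_lamina = TRUE) {
  stopifnot(nrow(configuration$positions) == topology$n_particles)
  arr <- .engine_arrays(topology)
  bnd <- .engine_bonds(topology, params)
  frozen <- rep(FALSE, topology$n_particles)  # report forces everywhere
  cpp_energy_forces(
    configuration$positions, arr$cat, arr$chain, arr$hapbin, arr$hapchrom,
    arr$label, .engine_state(topology, configuration), frozen,
    bnd$bonds, bnd$r0, bnd$k, .engine_params(params, topology)
  )
}

#' Chromatin-chromatin coupling energy of a single bead pair
#'
#' Intra-chain pairs feel the ideal-by-separation coupling plus the
#' compartment coupling; inter-chain pairs feel the compartment coupling
#' plus the chromosome-pair coupling.  Separations beyond the tabulated
#' ideal range use the last tabulated value.  The coupling multiplies the
#' shifted contact weight, so the energy vanishes beyond the contact
#' cutoff.  Excluded volume and bonds are not included here.
#'
#' @param topology a `nucleus_topology`.
#' @param params a `forcefield_parameters`.
#' @param i,j chromatin particle indices (1-based).
#' @param r pair distance in reduced units.
#' @return scalar energy.
#' @export
chromatin_pair_energy <- function(topology, params, i, j, r) {
  pt <- topology$particles
  if (pt$category[i] != "chromatin" || pt$category[j] != "chromatin") {
    stop("both particles must be chromatin beads")
  }
  lab <- c(A = 1L, B = 2L, C = 3L)
  ci <- lab[[pt$label[i]]]; cj <- lab[[pt$label[j]]]
  if (!is.na(pt$chain[i]) && pt$chain[i] == pt$chain[j]) {
    s <- abs(pt$hap_bin[i] - pt$hap_bin[j])
    s <- min(max(s, 1L), length(params$alpha_ideal))
    a <- params$alpha_ideal[s] + params$compartment[ci, cj]
  } else {
    hap <- topology$annotation$chains$hap_id
    hi <- hap[pt$chain[i]]; hj <- hap[pt$chain[j]]
    a <- params$compartment[ci, cj] + params$chrom_pair[hi, hj]
  }
  a * contact_indicator(r, params$contact, shifted = TRUE)
}

#' Body-body pair energy (nuclear-body condensation)
#'
#' Nucleolus-nucleolus pairs and dP-dP speckle pairs interact through the
#' attractive 12-6 Lennard-Jones potential (truncated and shifted at the
#' cutoff); every other body pair -- pairs involving a phosphorylated (P)
#' speckle and nucleolus-speckle cross pairs -- is purely repulsive
#' (truncated-shifted at the LJ minimum).
#'
#' @param r distance in reduced units.
#' @param category_i,category_j `"nucleolus"` or `"speckle"`.
#' @param state_i,state_j speckle chemical states (`"dP"` or `"P"`;
#'   ignored for nucleoli).
#' @param params a `forcefield_parameters`.
#' @return scalar energy.
#' @export
body_pair_energy <- function(r, category_i, category_j,
                             state_i = "dP", state_j = "dP", params) {
  stopifnot(category_i %in% c("nucleolus", "speckle"),
            category_j %in% c("nucleolus", "speckle"))
  lj <- params$lj
  sig <- lj$sigma
  cutoff <- lj$cutoff_factor * sig
  rcap <- lj$rcap_factor * sig
  lj_u <- function(r, eps, rcut) {
    rr <- pmax(r, rcap)
    s6 <- (sig / rr)^6
    sc6 <- (sig / rcut)^6
    u <- 4 * eps * (s6^2 - s6) - 4 * eps * (sc6^2 - sc6)
    du <- -4 * eps * (12 * s6^2 - 6 * s6) / rr
    ifelse(r < rcap, u + du * (r - rcap), u)
  }
  attractive <- (category_i == "nucleolus" && category_j == "nucleolus") ||
    (category_i == "speckle" && category_j == "speckle" &&
       identical(state_i, "dP") && identical(state_j, "dP"))
  if (attractive) {
    eps <- if (category_i == "nucleolus") lj$eps_nucleolus else lj$eps_speckle
    if (r >= cutoff) return(0)
    lj_u(r, eps, cutoff)
  } else {
    rmin <- 2^(1 / 6) * sig
    if (r >= rmin) return(0)
    lj_u(r, lj$eps_repulsive, rmin)
  }
}

#' Chromatin-landmark coupling energy of a single pair
#'
#' The per-bead coupling strength (lamina, speckle or nucleolus channel,
#' indexed by the bead's haploid bin) multiplies the shifted contact
#' weight.  Speckle couplings act on dP particles only.
#'
#' @param topology a `nucleus_topology`.
#' @param params a `forcefield_parameters`.
#' @param bead chromatin particle index.
#' @param landmark landmark particle index.
#' @param r distance.
#' @param state speckle state of the landmark (`"dP"`/`"P"`), if a speckle.
#' @return scalar energy.
#' @export
landmark_coupling_energy <- function(topology, params, bead, landmark, r,
                                     state = "dP") {
  pt <- topology$particles
  stopifnot(pt$category[bead] == "chromatin")
  lcat <- pt$category[landmark]
  if (!lcat %in% c("lamina", "speckle", "nucleolus")) {
    stop("landmark particle must be lamina, speckle or nucleolus")
  }
  hb <- pt$hap_bin[bead]
  chi <- switch(lcat,
    lamina = params$chi_lamina[hb],
    nucleolus = params$chi_nucleolus[hb],
    speckle = if (identical(state, "dP")) params$chi_speckle[hb] else 0
  )
  chi * contact_indicator(r, params$contact, shifted = TRUE)
}

#' Serialize force-field parameters to JSON
#'
#' The document is a versioned, named mirror of the parameter object and
#' round-trips losslessly (full double precision).
#'
#' @param params a `forcefield_parameters`.
#' @param path output file.
#' @export
write_forcefield_parameters <- function(params, path) {
  stopifnot(inherits(params, "forcefield_parameters"))
  obj <- unclass(params)
  obj$compartment <- as.vector(params$compartment)
  obj$chrom_pair_dim <- nrow(params$chrom_pair)
  obj$chrom_pair <- as.vector(params$chrom_pair)
  obj$chrom_names <- rownames(params$chrom_pair)
  obj$contact <- unclass(params$contact)
  ## digits = I(17): full double precision, so the round trip is lossless
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_forcefield_parameters
#' @export
read_forcefield_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nhap <- obj$chrom_pair_dim
  cn <- obj$chrom_names
  out <- list(
    schema_version = as.integer(obj$schema_version),
    contact = structure(as.list(obj$contact), class = "contact_function"),
    bond = as.list(obj$bond),
    excluded_volume = list(
      strength = obj$excluded_volume$strength,
      diameters = setNames(as.numeric(obj$excluded_volume$diameters),
                           CATEGORY_LEVELS)
    ),
    alpha_ideal = as.numeric(obj$alpha_ideal),
    compartment = matrix(as.numeric(obj$compartment), 3, 3,
                         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
    chrom_pair = matrix(as.numeric(obj$chrom_pair), nhap, nhap,
                        dimnames = list(cn, cn)),
    chi_lamina = as.numeric(obj$chi_lamina),
    chi_speckle = as.numeric(obj$chi_speckle),
    chi_nucleolus = as.numeric(obj$chi_nucleolus),
    lj = as.list(obj$lj),
    lamina_bond_k = obj$lamina_bond_k,
    confinement = as.list(obj$confinement),
    deformation = as.list(obj$deformation)
  )
  structure(out, class = "forcefield_parameters")
}
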