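#' Chromatin volume fraction of the full-scale model
#'
#' Roughly 60,000 diploid 100-KB beads of diameter 0.5 reduced units
#' inside the 12.987-unit nuclear radius.
#' @export
FULL_SCALE_VOLUME_FRACTION <- 0.43

#' Toy-nucleus specification
#'
#' A desk-scale stand-in for the full nucleus: a few short chromosomes
#' (diploid: `n_chromosomes` haploid chromosomes, two copies each) with a
#' stylized compartment pattern -- alternating A/B blocks with terminal C
#' beads -- plus nuclear-body particles and a lamina mesh.  The nuclear
#' radius is chosen so the chromatin volume fraction matches the
#' full-scale model (phase behaviour such as droplet formation and
#' territory compaction depends on density, not on absolute particle
#' number).
#'
#' @param n_chromosomes haploid chromosome count (chains = 2x this).
#' @param beads_per_chain beads per chromosome copy.
#' @param block_size length of the alternating A/B blocks, in beads.
#' @param n_terminal_c number of C-labelled beads at each chain end.
#' @param n_nucleolus,n_speckle,n_lamina particle counts.
#' @param volume_fraction chromatin volume fraction to match.
#' @param contact_r_c,contact_eta contact-function parameters used for the
#'   toy's force field and observables.  The defaults (0.75, 8) scale the
#'   full-scale contact radius down with the nucleus: at full scale
#'   r_c = 1.75 is a small fraction of the 13-unit nuclear radius, but in
#'   a toy nucleus of radius ~2 it would cover most of the volume and
#'   saturate every contact observable.
#' @param seed seed for the initial configuration.
#' @return A `toy_spec`.
#' @export
toy_spec <- function(n_chromosomes = 2L, beads_per_chain = 100L,
                     block_size = 10L, n_terminal_c = 2L,
                     n_nucleolus = 30L, n_speckle = 80L, n_lamina = 500L,
                     volume_fraction = FULL_SCALE_VOLUME_FRACTION,
                     contact_r_c = 0.75, contact_eta = 8,
                     seed = 1L) {
  stopifnot(n_chromosomes >= 1, beads_per_chain >= 2,
            volume_fraction > 0, volume_fraction < 0.74)
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         beads_per_chain = as.integer(beads_per_chain),
         block_size = as.integer(block_size),
         n_terminal_c = as.integer(n_terminal_c),
         n_nucleolus = as.integer(n_nucleolus),
         n_speckle = as.integer(n_speckle),
         n_lamina = as.integer(n_lamina),
         volume_fraction = volume_fraction,
         contact_r_c = contact_r_c, contact_eta = contact_eta,
         seed = as.integer(seed)),
    class = "toy_spec"
  )
}

#' @export
print.toy_spec <- function(x, ...) {
  cat(sprintf(
    "toy_spec: %d chromosomes x 2 copies x %d beads + %d nucleolus + %d speckle + %d lamina (phi=%.2f, seed %d)\n",
    x$n_chromosomes, x$beads_per_chain, x$n_nucleolus, x$n_speckle,
    x$n_lamina, x$volume_fraction, x$seed))
  invisible(x)
}

## stylized compartment pattern: terminal C beads, alternating A/B blocks
.toy_labels <- function(n, block, n_c) {
  blocks <- ceiling(seq_len(n) / block)
  lab <- ifelse(blocks %% 2 == 1, "A", "B")
  if (n_c > 0) {
    lab[seq_len(min(n_c, n))] <- "C"
    lab[seq.int(max(1, n - n_c + 1), n)] <- "C"
  }
  lab
}

#' Nuclear radius that realizes a chromatin volume fraction
#' @param n_beads diploid chromatin bead count.
#' @param volume_fraction target fraction.
#' @param bead_diameter bead diameter in reduced units.
#' @export
radius_for_volume_fraction <- function(n_beads,
                                       volume_fraction = FULL_SCALE_VOLUME_FRACTION,
                                       bead_diameter = 0.5) {
  (bead_diameter / 2) * (n_beads / volume_fraction)^(1 / 3)
}

#' Chromatin volume fraction of a topology
#' @param topology a `nucleus_topology`.
#' @param bead_diameter bead diameter in reduced units.
#' @export
chromatin_volume_fraction <- function(topology, bead_diameter = 0.5) {
  n <- unname(topology$counts["chromatin"])
  n * (bead_diameter / 2)^3 / topology$radius^3
}

#' Build a ready-to-simulate toy nucleus
#'
#' Deterministic in the spec and its seed: the same spec yields the same
#' annotation, topology, initial configuration and default parameters.
#'
#' @param spec a [toy_spec()].
#' @param couplings optional function applied to the default
#'   `forcefield_parameters` before the initial relaxation (e.g. to plant
#'   non-zero couplings).
#' @return list with `annotation`, `topology`, `configuration`, `params`
#'   and the `spec`.
#' @export
make_toy_nucleus <- function(spec = toy_spec(), couplings = NULL) {
  stopifnot(inherits(spec, "toy_spec"))
  chrom_names <- paste0("toy", seq_len(spec$n_chromosomes))
  tab <- data.frame(chrom = chrom_names,
                    length = spec$beads_per_chain * 1e5,
                    copies = 2L)
  labels <- .toy_labels(spec$beads_per_chain, spec$block_size,
                        spec$n_terminal_c)
  track <- setNames(rep(list(labels), spec$n_chromosomes), chrom_names)
  ann <- build_genome_annotation(tab, track)

  n_beads <- ann$n_beads
  R <- radius_for_volume_fraction(n_beads, spec$volume_fraction)
  mesh <- if (spec$n_lamina >= 12) {
    build_lamina_mesh(radius = R, n_vertices = spec$n_lamina)
  } else NULL
  topo <- build_topology(ann, n_nucleolus = spec$n_nucleolus,
                         n_speckle = spec$n_speckle, lamina_mesh = mesh,
                         radius = R)
  params <- default_forcefield_parameters(
    ann, contact = contact_function(spec$contact_r_c, spec$contact_eta),
    confinement_radius = R)
  if (!is.null(couplings)) params <- couplings(params)
  config <- generate_initial_configuration(topo, spec$seed, params)
  list(annotation = ann, topology = topo, configuration = config,
       params = params, spec = spec)
}

#' Generate self-consistent synthetic optimization targets
#'
#' Runs the simulator with planted couplings and extracts the constraint
#' averages, producing targets with a known ground truth for closed-loop
#' recovery tests of the maximum-entropy machinery.
#'
#' @param planted_params `forcefield_parameters` holding the planted
#'   couplings.
#' @param topology the toy `nucleus_topology`.
#' @param budget list(`n_traj`, `n_steps`, `record_interval`,
#'   `discard_steps`).
#' @param seed integer seed (independent of the optimization's seeds).
#' @param integrator,reactions propagation specs.
#' @return A `constraint_set`.
#' @export
make_synthetic_targets <- function(planted_params, topology, budget,
                                   seed = 42L,
                                   integrator = integrator_spec("langevin"),
                                   reactions = speckle_reaction_spec()) {
  sets <- vector("list", budget$n_traj)
  for (t in seq_len(budget$n_traj)) {
    tseed <- (as.numeric(seed) * 131071 + t * 524287) %% 2147483647
    traj <- run_simulation(topology, planted_params,
                           n_steps = budget$n_steps,
                           record_interval = budget$record_interval,
                           integrator = integrator, reactions = reactions,
                           seed = tseed)
    sets[[t]] <- constraints_from_trajectory(
      traj, topology, planted_params$contact,
      discard_steps = budget$discard_steps,
      s_max = length(planted_params$alpha_ideal))
  }
  average_constraints(sets)
}

#' Synthetic DamID-like and TSA-Seq-like track fixtures
#'
#' Smooth correlated random tracks at 25-KB resolution emulating the
#' shapes of the experimental inputs: a lamina-association (DamID-like)
#' signal, an anti-correlated speckle-proximity (TSA-Seq-like) signal,
#' and two noisy replicates of each.
#'
#' @param seed integer seed.
#' @param n_bins native 25-KB bins per track.
#' @param chrom chromosome name stamped on the intervals.
#' @param resolution native resolution in bp.
#' @param replicate_noise standard deviation of per-replicate noise
#'   relative to the signal's.
#' @return list with `damid` and `tsaseq`, each a list of two replicate
#'   `experimental_track`s, plus the noise-free `truth` tracks.
#' @export
make_track_fixtures <- function(seed = 1L, n_bins = 400L, chrom = "toy1",
                                resolution = 25e3, replicate_noise = 0.4) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  smooth_noise <- function(n, span = 15) {
    x <- rnorm(n + 2 * span)
    as.numeric(stats::filter(x, rep(1 / span, span), sides = 2))[
      span + seq_len(n)]
  }
  base <- smooth_noise(n_bins)
  base <- (base - mean(base)) / sd(base)
  extra <- smooth_noise(n_bins)
  extra <- (extra - mean(extra)) / sd(extra)
  damid_truth <- base
  tsa_truth <- -0.85 * base + 0.55 * extra   # anti-correlated pair
  iv <- function(values) {
    data.frame(chrom = chrom,
               start = (seq_len(n_bins) - 1) * resolution,
               end = seq_len(n_bins) * resolution,
               value = values)
  }
  rep_of <- function(truth, name, k) {
    experimental_track(iv(truth + replicate_noise * rnorm(n_bins)),
                       resolution,
                       provenance = sprintf("synthetic %s replicate %d",
                                            name, k))
  }
  list(
    damid = list(rep_of(damid_truth, "damid", 1),
                 rep_of(damid_truth, "damid", 2)),
    tsaseq = list(rep_of(tsa_truth, "tsaseq", 1),
                  rep_of(tsa_truth, "tsaseq", 2)),
    truth = list(damid = experimental_track(iv(damid_truth), resolution,
                                            "synthetic damid truth"),
                 tsaseq = experimental_track(iv(tsa_truth), resolution,
                                             "synthetic tsaseq truth"))
  )
}
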