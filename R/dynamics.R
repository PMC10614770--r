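#' Integrator specification
#'
#' Two stochastic schemes propagate the system at constant reduced
#' temperature T = 1 with a time step dt = 0.005: a Langevin integrator
#' (BAOAB splitting, unit masses) with damping gamma^-1 = 10, used for
#' conformational sampling, and overdamped Brownian dynamics
#' (Euler-Maruyama) with gamma^-1 = 0.01, whose stronger damping mimics
#' the viscous nucleoplasm and maps one time unit to tau = 0.65 s for
#' dynamical observables.
#'
#' @param scheme `"langevin"` or `"brownian"`.
#' @param dt time step in reduced units.
#' @param gamma_inv inverse damping coefficient; defaults to 10
#'   (langevin) or 0.01 (brownian).
#' @param temperature reduced temperature.
#' @return An `integrator_spec`.
#' @export
integrator_spec <- function(scheme = c("langevin", "brownian"), dt = 0.005,
                            gamma_inv = NULL, temperature = 1.0) {
  scheme <- match.arg(scheme)
  if (is.null(gamma_inv)) gamma_inv <- if (scheme == "langevin") 10.0 else 0.01
  stopifnot(dt > 0, gamma_inv > 0, temperature >= 0)
  structure(list(scheme = scheme, dt = dt, gamma_inv = gamma_inv,
                 temperature = temperature),
            class = "integrator_spec")
}

#' Speckle chemical-reaction specification
#'
#' Speckle particles interconvert between phosphorylated (P) and
#' de-phosphorylated (dP) states by a semi-grand canonical Monte Carlo
#' scheme: every `interval` (4000) integration steps, `N_Sp` reaction
#' attempts are made (`N_Sp` = number of speckle particles); each attempt
#' picks a speckle uniformly at random and proposes flipping its state
#' with probability `prob` (0.2).  With `metropolis = TRUE` (default) the
#' proposed flip is accepted by the Metropolis criterion on the resulting
#' energy change, which preserves detailed balance and stabilizes dP
#' droplets; `metropolis = FALSE` flips unconditionally.
#'
#' @param interval steps between reaction sweeps.
#' @param prob per-attempt switch proposal probability.
#' @param metropolis apply Metropolis acceptance to proposed flips.
#' @return A `speckle_reaction_spec`.
#' @export
speckle_reaction_spec <- function(interval = 4000L, prob = 0.2,
                                  metropolis = TRUE) {
  stopifnot(interval >= 1, prob >= 0, prob <= 1)
  structure(list(interval = as.integer(interval), prob = prob,
                 metropolis = metropolis),
            class = "speckle_reaction_spec")
}

#' Nuclear-deformation specification
#'
#' A harmonic force along the z-axis (per lamina particle, strength
#' `force_k`) compresses the particle mesh; the lamina must be evolved
#' dynamically (unfrozen) during deformation, with the mesh bonds holding
#' the envelope together.
#'
#' @param force_k harmonic z-compression strength (>= 0).
#' @return A `deformation_spec`.
#' @export
deformation_spec <- function(force_k = 0) {
  if (force_k < 0) stop("deformation force strength must be non-negative")
  structure(list(force_k = force_k), class = "deformation_spec")
}

#' Install a deformation term into the force field
#'
#' Besides adding the z-compression term, the dynamic-envelope protocol
#' stiffens the lamina mesh bonds (the envelope must hold its shape
#' against the osmotic pressure of the nuclear contents once it is no
#' longer frozen) and removes the spherical confinement backstop, so the
#' particle mesh itself is the container that deforms.
#'
#' @param params a `forcefield_parameters`.
#' @param spec a [deformation_spec()].
#' @param frozen_lamina must be `FALSE`: deforming a frozen mesh is
#'   rejected.
#' @param lamina_bond_k mesh bond stiffness for the dynamic envelope.
#' @return modified `forcefield_parameters` with the z-compression term.
#' @export
apply_deformation <- function(params, spec, frozen_lamina = FALSE,
                              lamina_bond_k = 1000) {
  stopifnot(inherits(spec, "deformation_spec"))
  if (isTRUE(frozen_lamina)) {
    stop("deformation requires a dynamic (unfrozen) lamina")
  }
  params$deformation$k_z <- spec$force_k
  params$lamina_bond_k <- max(params$lamina_bond_k, lamina_bond_k)
  params$confinement$k <- 0
  params
}

.topology_hash <- function(topology, params) {
  key <- list(counts = topology$counts, n_bonds = nrow(topology$bonds),
              r_c = params$contact$r_c, eta = params$contact$eta)
  substr(digest_string(paste(deparse(key), collapse = "")), 1, 12)
}

## tiny stable string hash (djb2) for run metadata
digest_string <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- ((h * 33) + ch) %% 2^31
  sprintf("%08x%04x", h, nchar(s) %% 65536)
}

#' Advance a configuration by a fixed number of integration steps
#'
#' Thin single-call wrapper over the compiled propagator: advances
#' `n_steps` steps (default 1) of the chosen stochastic scheme and
#' returns the updated configuration.  Frozen lamina particles are not
#' moved.  Non-finite forces abort with a diagnostic naming the particle.
#'
#' @param configuration a `nucleus_configuration`.
#' @param topology,params system definition.
#' @param integrator an [integrator_spec()].
#' @param seed integer seed for the thermostat noise.
#' @param n_steps number of steps.
#' @param frozen_lamina freeze lamina particles (default `TRUE`).
#' @return the advanced `nucleus_configuration`.
#' @export
integrate_step <- function(configuration, topology, params,
                           integrator = integrator_spec(), seed = 1L,
                           n_steps = 1L, frozen_lamina = TRUE) {
  traj <- run_simulation(topology, params, n_steps = n_steps,
                         record_interval = n_steps,
                         integrator = integrator,
                         reactions = NULL, seed = seed,
                         initial = configuration,
                         frozen_lamina = frozen_lamina)
  last_configuration(traj)
}

#' Perform one semi-grand speckle reaction sweep
#'
#' Makes `N_Sp` attempts; each picks a speckle particle uniformly at
#' random, proposes flipping its P/dP state with the specified
#' probability, and (optionally) accepts by the Metropolis criterion on
#' the energy change.  Positions and particle counts are unchanged.
#'
#' @param configuration a `nucleus_configuration`.
#' @param topology,params system definition (the energy evaluator).
#' @param spec a [speckle_reaction_spec()].
#' @param seed integer seed.
#' @return list with the updated `configuration` and `n_flips`.
#' @export
speckle_reaction_sweep <- function(configuration, topology, params,
                                   spec = speckle_reaction_spec(),
                                   seed = 1L) {
  arr <- .engine_arrays(topology)
  bnd <- .engine_bonds(topology, params)
  n_spk <- unname(topology$counts["speckle"])
  if (n_spk == 0) return(list(configuration = configuration, n_flips = 0L))
  res <- cpp_speckle_sweep(
    configuration$positions, arr$cat, arr$chain, arr$hapbin, arr$hapchrom,
    arr$label, .engine_state(topology, configuration),
    rep(FALSE, topology$n_particles), bnd$bonds, bnd$r0, bnd$k,
    .engine_params(params, topology), as.integer(n_spk), spec$prob,
    isTRUE(spec$metropolis), 1.0, as.numeric(seed), ""
  )
  idx <- particle_indices(topology, "speckle")
  configuration$speckle_state <- as.integer(res$spk_state[idx])
  list(configuration = configuration, n_flips = res$n_flips)
}

#' Run a simulation and record a trajectory
#'
#' Propagates the full system with the chosen integrator, interleaving
#' semi-grand speckle reaction sweeps, and records configurations (and
#' speckle states) every `record_interval` steps, frame 0 included.  The
#' run is deterministic given the seed.  Equilibration discard is an
#' analysis-time choice ([trajectory_frames()]), not applied here.
#'
#' @param topology a `nucleus_topology`.
#' @param params a `forcefield_parameters`.
#' @param n_steps total integration steps.
#' @param record_interval steps between recorded frames (default 2000).
#' @param integrator an [integrator_spec()].
#' @param reactions a [speckle_reaction_spec()], or `NULL` to disable
#'   speckle chemistry.
#' @param seed integer seed driving all stochasticity of the run.
#' @param initial starting `nucleus_configuration`; defaults to
#'   [generate_initial_configuration()] with the same seed.
#' @param frozen_lamina freeze lamina particles (default `TRUE`).  Must
#'   be `FALSE` when the force field carries a deformation term.
#' @param resume optional checkpoint (`traj$checkpoint`) from a previous
#'   run segment; continuing from it reproduces an uninterrupted run
#'   bit-exactly.
#' @return A `nucleus_trajectory`: `frames` (n x 3 x n_frames array),
#'   `speckle_states`, `steps`, per-frame `energy` and kinetic
#'   temperature, flip statistics, a `checkpoint`, and run metadata.
#' @export
run_simulation <- function(topology, params, n_steps,
                           record_interval = 2000L,
                           integrator = integrator_spec(),
                           reactions = speckle_reaction_spec(),
                           seed = 1L, initial = NULL,
                           frozen_lamina = TRUE, resume = NULL) {
  stopifnot(inherits(topology, "nucleus_topology"),
            inherits(params, "forcefield_parameters"))
  n_steps <- as.integer(n_steps)
  record_interval <- as.integer(record_interval)
  stopifnot(n_steps >= 0, record_interval >= 1)
  if (params$deformation$k_z > 0 && frozen_lamina) {
    stop("deformation requires frozen_lamina = FALSE")
  }
  if (is.null(initial) && is.null(resume)) {
    initial <- generate_initial_configuration(topology, seed, params)
  }
  if (!is.null(resume)) {
    initial <- nucleus_configuration(resume$positions, topology,
                                     speckle_state = resume$speckle_state,
                                     seed = seed, frame = resume$step)
  }
  arr <- .engine_arrays(topology)
  bnd <- .engine_bonds(topology, params)
  frozen <- if (frozen_lamina) topology$particles$category == "lamina" else
    rep(FALSE, topology$n_particles)
  scheme <- match(integrator$scheme, c("langevin", "brownian")) - 1L
  do_rx <- !is.null(reactions) && topology$counts["speckle"] > 0
  rx_interval <- if (do_rx) reactions$interval else 0L
  rx_prob <- if (do_rx) reactions$prob else 0
  rx_metropolis <- if (do_rx) isTRUE(reactions$metropolis) else TRUE

  rng_state <- if (!is.null(resume)) resume$rng_state else ""
  vel0 <- if (!is.null(resume) && !is.null(resume$velocities)) {
    resume$velocities
  } else matrix(0, 1, 3)
  have_vel <- !is.null(resume) && !is.null(resume$velocities)

  res <- cpp_run_simulation(
    initial$positions, arr$cat, arr$chain, arr$hapbin, arr$hapchrom,
    arr$label, .engine_state(topology, initial), frozen,
    bnd$bonds, bnd$r0, bnd$k, .engine_params(params, topology),
    scheme, integrator$dt, integrator$gamma_inv, integrator$temperature,
    n_steps, record_interval, as.integer(rx_interval), rx_prob,
    do_rx, rx_metropolis, as.numeric(seed), rng_state, vel0, have_vel,
    as.integer(if (!is.null(resume)) resume$step else 0L), 200L
  )
  if (nzchar(res$abort)) {
    stop(sprintf("simulation aborted: %s (checkpoint retained up to last finite frame)",
                 res$abort))
  }
  nf <- res$n_recorded
  frames <- res$frames
  if (nf < dim(frames)[3]) frames <- frames[, , seq_len(nf), drop = FALSE]
  offset <- if (!is.null(resume)) resume$step else 0L
  n_spk <- unname(topology$counts["speckle"])
  state_frames <- if (n_spk > 0) {
    res$state_frames[seq_len(nf), , drop = FALSE]
  } else matrix(integer(0), nf, 0)

  structure(
    list(
      frames = frames,
      speckle_states = state_frames,
      steps = res$frame_steps[seq_len(nf)] + offset,
      energy = res$frame_energy[seq_len(nf)],
      kinetic_temperature = res$frame_ktemp[seq_len(nf)],
      record_interval = record_interval,
      integrator = integrator,
      reactions = if (do_rx) reactions else NULL,
      total_flips = res$total_flips,
      total_sweeps = res$total_sweeps,
      seed = seed,
      frozen_lamina = frozen_lamina,
      topology_hash = .topology_hash(topology, params),
      checkpoint = list(
        positions = res$final_positions,
        velocities = res$final_velocities,
        speckle_state = as.integer(res$final_state[
          seq_len(max(0L, unname(topology$counts["speckle"])))]),
        rng_state = res$rng_state,
        step = offset + n_steps
      )
    ),
    class = "nucleus_trajectory"
  )
}

#' @export
print.nucleus_trajectory <- function(x, ...) {
  cat(sprintf(
    "nucleus_trajectory: %d frames x %d particles (every %d steps, %s, dt=%g), seed %s\n",
    dim(x$frames)[3], dim(x$frames)[1], x$record_interval,
    x$integrator$scheme, x$integrator$dt, format(x$seed)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `nucleus_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$frames)[3]

#' Frame indices surviving the equilibration discard
#'
#' The production convention discards the first 500,000 steps of each
#' trajectory as equilibration; the discard is applied at analysis time
#' so raw trajectories stay complete.
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param discard_steps steps to discard from the start.
#' @return integer frame indices.
#' @export
trajectory_frames <- function(trajectory, discard_steps = 0) {
  which(trajectory$steps >= discard_steps)
}

#' Extract one frame as a configuration
#' @param trajectory a `nucleus_trajectory`.
#' @param i frame index (default: last frame).
#' @param topology the matching topology.
#' @export
frame_configuration <- function(trajectory, topology, i = n_frames(trajectory)) {
  nucleus_configuration(matrix(trajectory$frames[, , i], ncol = 3), topology,
                        speckle_state = trajectory$speckle_states[i, ],
                        seed = trajectory$seed,
                        frame = trajectory$steps[i])
}

#' @rdname frame_configuration
#' @export
last_configuration <- function(trajectory, topology = NULL) {
  i <- n_frames(trajectory)
  structure(
    list(positions = matrix(trajectory$frames[, , i], ncol = 3),
         speckle_state = as.integer(trajectory$speckle_states[i, ]),
         seed = trajectory$seed, frame = trajectory$steps[i]),
    class = "nucleus_configuration"
  )
}
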