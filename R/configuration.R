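#' Construct a configuration object
#'
#' @param positions n x 3 matrix of reduced-unit coordinates.
#' @param topology the matching `nucleus_topology`.
#' @param speckle_state integer vector (1 = dP, 0 = P) per speckle
#'   particle; defaults to all dP.
#' @param seed seed provenance (stored, not consumed).
#' @param frame frame timestamp (simulation step).
#' @return A `nucleus_configuration`.
#' @export
nucleus_configuration <- function(positions, topology, speckle_state = NULL,
                                  seed = NA_integer_, frame = 0) {
  stopifnot(nrow(positions) == topology$n_particles, ncol(positions) == 3)
  n_spk <- unname(topology$counts["speckle"])
  if (is.null(speckle_state)) speckle_state <- rep(1L, n_spk)
  stopifnot(length(speckle_state) == n_spk)
  structure(
    list(positions = unname(as.matrix(positions)),
         speckle_state = as.integer(speckle_state),
         seed = seed, frame = frame),
    class = "nucleus_configuration"
  )
}

#' @export
print.nucleus_configuration <- function(x, ...) {
  cat(sprintf("nucleus_configuration: %d particles, %d dP / %d speckles, seed %s, frame %s\n",
              nrow(x$positions), sum(x$speckle_state == 1L),
              length(x$speckle_state), format(x$seed), format(x$frame)))
  invisible(x)
}

## collapsed random walk of n beads with bond length `bond` confined to a
## ball of radius `rmax` around `center` (and inside the nucleus radius R)
.globule_walk <- function(n, center, rmax, R, bond = 1.0, max_try = 200) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- center
  for (b in seq_len(n)[-1]) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      u <- rnorm(3)
      step <- bond * u / sqrt(sum(u^2))
      cand <- pos[b - 1, ] + step
      if (sum((cand - center)^2) <= rmax^2 && sum(cand^2) <= R^2) {
        pos[b, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {  # fall back: step straight back towards the globule centre
      dir <- center - pos[b - 1, ]
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-9) dir <- c(1, 0, 0) else dir <- dir / nd
      pos[b, ] <- pos[b - 1, ] + bond * dir
    }
  }
  pos
}

## uniform point in a ball of radius r
.runif_ball <- function(n, r) {
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- runif(3, -r, r)
      if (sum(p^2) <= r^2) break
    }
    out[i, ] <- p
  }
  out
}

#' Generate a random initial configuration
#'
#' Each chromosome is laid down as a compact random-walk globule
#' (territory-like start) at a uniformly random interior location;
#' nucleolus and speckle particles are placed uniformly at random inside
#' the nucleus; lamina particles sit at their mesh positions.  A brief
#' capped steepest-descent relaxation removes the worst overlaps.  The
#' result is reproducible given the seed, and every non-lamina particle
#' lies inside the lamina radius.
#'
#' @param topology a `nucleus_topology`.
#' @param seed integer seed.
#' @param params optional `forcefield_parameters` used only for the
#'   relaxation; defaults to the topology's standard parameters.
#' @param minimize_steps number of relaxation steps (0 disables).
#' @param margin gap kept between chromatin/body particles and the lamina
#'   radius, in reduced units.
#' @return A `nucleus_configuration`.
#' @export
generate_initial_configuration <- function(topology, seed, params = NULL,
                                           minimize_steps = 50L,
                                           margin = 0.5) {
  stopifnot(inherits(topology, "nucleus_topology"))
  R <- topology$radius
  Rin <- R - margin
  if (Rin <= 0) stop("nucleus radius too small for the placement margin")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ann <- topology$annotation
  pos <- matrix(NA_real_, topology$n_particles, 3)
  phi_local <- 0.5  # local packing fraction of a territory globule
  d_chr <- 0.5
  for (i in seq_len(nrow(ann$chains))) {
    nb <- ann$chains$n_beads[i]
    r_glob <- max(1.0, (d_chr / 2) * (nb / phi_local)^(1 / 3))
    r_glob <- min(r_glob, Rin)
    center <- as.vector(.runif_ball(1, max(Rin - r_glob, 1e-6)))
    rows <- ann$chains$offset[i] + seq_len(nb)
    pos[rows, ] <- .globule_walk(nb, center, r_glob, Rin)
  }
  idx_nuc <- particle_indices(topology, "nucleolus")
  idx_spk <- particle_indices(topology, "speckle")
  if (length(idx_nuc)) pos[idx_nuc, ] <- .runif_ball(length(idx_nuc), Rin)
  if (length(idx_spk)) pos[idx_spk, ] <- .runif_ball(length(idx_spk), Rin)
  idx_lam <- particle_indices(topology, "lamina")
  if (length(idx_lam)) pos[idx_lam, ] <- topology$lamina_mesh$vertices

  cfg <- nucleus_configuration(pos, topology, seed = seed)
  if (minimize_steps > 0) {
    if (is.null(params)) params <- default_forcefield_parameters(ann)
    cfg <- relax_configuration(cfg, topology, params,
                               n_steps = minimize_steps)
    ## relaxation may push particles marginally past the enclosure; clamp
    ## non-lamina particles back inside the nuclear radius
    inner <- which(topology$particles$category != "lamina")
    r <- sqrt(rowSums(cfg$positions[inner, , drop = FALSE]^2))
    out <- r > R
    if (any(out)) {
      scale <- (R - 1e-6) / r[out]
      cfg$positions[inner[out], ] <- cfg$positions[inner[out], , drop = FALSE] * scale
    }
  }
  cfg
}

## save/restore the global RNG state so generators are pure in their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Briefly relax a configuration by capped steepest descent
#'
#' @param configuration a `nucleus_configuration`.
#' @param topology,params system definition.
#' @param n_steps descent steps.
#' @param max_disp per-step displacement cap in reduced units.
#' @return the relaxed `nucleus_configuration` (lamina particles fixed).
#' @export
relax_configuration <- function(configuration, topology, params,
                                n_steps = 50L, max_disp = 0.05) {
  arr <- .engine_arrays(topology)
  bnd <- .engine_bonds(topology, params)
  frozen <- topology$particles$category == "lamina"
  newpos <- cpp_minimize(
    configuration$positions, arr$cat, arr$chain, arr$hapbin, arr$hapchrom,
    arr$label, .engine_state(topology, configuration), frozen,
    bnd$bonds, bnd$r0, bnd$k, .engine_params(params, topology),
    as.integer(n_steps), max_disp
  )
  configuration$positions <- newpos
  configuration
}

#' Select starting configurations against experimental-style targets
#'
#' Given candidate configurations with precomputed per-bead lamina-contact
#' profiles and chromosome-pair contact matrices, chooses a subset of `k`
#' whose ensemble averages best match the targets, by stochastic
#' greedy-swap minimization of
#' `w_damid * ||mean(profile) - target_profile||^2 +
#'  w_pairs * ||mean(pairs) - target_pairs||^2`.
#' The search starts from the best of `n_init` random subsets and accepts
#' only improving swaps, so the reported objective is monotonically
#' non-increasing and never worse than the best initial random subset.
#'
#' @param profiles matrix (n_candidates x n_bins) of per-bead
#'   lamina-contact profiles, one row per candidate.
#' @param pair_maps 3-d array (n_hap x n_hap x n_candidates) of
#'   chromosome-pair contact matrices.
#' @param target_profile,target_pairs target ensemble averages.
#' @param k subset size.
#' @param weights length-2 weights for the profile and pair terms.
#' @param n_init number of random initial subsets.
#' @param n_sweeps swap sweeps over the chosen set.
#' @param seed integer seed.
#' @return list with `selected` (indices), `objective`, and the objective
#'   `trace` across accepted moves.
#' @export
select_starting_configurations <- function(profiles, pair_maps,
                                           target_profile, target_pairs,
                                           k, weights = c(1, 1),
                                           n_init = 20L, n_sweeps = 20L,
                                           seed = 1L) {
  n_cand <- nrow(profiles)
  stopifnot(dim(pair_maps)[3] == n_cand,
            length(target_profile) == ncol(profiles))
  if (k > n_cand) stop("k exceeds the number of candidate configurations")
  ## rows of pair_flat: candidate; columns: flattened pair matrix
  pair_flat <- t(apply(pair_maps, 3, as.vector))
  tgt_pair <- as.vector(target_pairs)

  objective <- function(sel) {
    dp <- colMeans(profiles[sel, , drop = FALSE]) - target_profile
    dm <- colMeans(pair_flat[sel, , drop = FALSE]) - tgt_pair
    weights[1] * sum(dp^2) + weights[2] * sum(dm^2)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ## steepest-descent swap search from the best of several random starts;
  ## only improving swaps are accepted, so the objective trace is
  ## monotonically non-increasing and never worse than the best initial
  ## random subset
  n_restarts <- max(1L, ceiling(n_init / 4))
  overall_sel <- NULL
  overall_obj <- Inf
  overall_trace <- NULL
  for (restart in seq_len(n_restarts)) {
    best_sel <- NULL
    best_obj <- Inf
    for (t in seq_len(max(1L, n_init))) {
      sel <- sort(sample.int(n_cand, k))
      ob <- objective(sel)
      if (ob < best_obj) {
        best_obj <- ob
        best_sel <- sel
      }
    }
    trace <- best_obj
    if (k < n_cand) {
      for (sweep in seq_len(n_sweeps)) {
        improved <- FALSE
        for (pos_i in sample(seq_len(k))) {
          outside <- setdiff(seq_len(n_cand), best_sel)
          obs <- vapply(outside, function(cand_in) {
            prop <- best_sel
            prop[pos_i] <- cand_in
            objective(prop)
          }, numeric(1))
          if (min(obs) < best_obj) {
            prop <- best_sel
            prop[pos_i] <- outside[which.min(obs)]
            best_sel <- sort(prop)
            best_obj <- min(obs)
            trace <- c(trace, best_obj)
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    if (best_obj < overall_obj) {
      overall_obj <- best_obj
      overall_sel <- best_sel
      overall_trace <- trace
    }
  }
  list(selected = overall_sel, objective = overall_obj,
       trace = overall_trace)
}
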