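#' Constraint set: matched simulated/experimental ensemble averages
#'
#' The five constraint blocks mirror the tunable coupling blocks
#' one-to-one (maximum-entropy duality: each coupling is conjugate to its
#' own ensemble average):
#' \itemize{
#'   \item `ideal`: mean contact of intra-chain bead pairs by genomic
#'     separation `s` (pairs at `s >= s_max` pool into the last entry,
#'     matching the clamped ideal coupling);
#'   \item `compartment`: mean contact for the 6 unordered label pairs
#'     AA, AB, AC, BB, BC, CC over all chromatin bead pairs;
#'   \item `chrom_pair`: mean inter-chain contact per haploid chromosome
#'     pair, homolog-averaged (homolog-homolog pairs on the diagonal);
#'   \item `lamina`, `speckle`: per-haploid-bin landmark contact
#'     frequency (union weight over the landmark set, speckles counted
#'     in the dP state only) -- the in-silico DamID and TSA-Seq signals.
#' }
#' All entries lie in `[0, 1]`.
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param topology the matching `nucleus_topology`.
#' @param cf a [contact_function()].
#' @param discard_steps equilibration discard.
#' @param s_max largest tabulated separation (pairs beyond pool into the
#'   last entry); defaults to the longest chain minus one.
#' @return A `constraint_set`.
#' @export
constraints_from_trajectory <- function(trajectory, topology,
                                        cf = contact_function(),
                                        discard_steps = 0, s_max = NULL) {
  keep <- trajectory_frames(trajectory, discard_steps)
  if (length(keep) < 1) stop("no frames left after the equilibration discard")
  ann <- topology$annotation
  if (is.null(s_max)) s_max <- max(1L, max(ann$chains$n_beads) - 1L)
  idx_chr <- particle_indices(topology, "chromatin")
  nb <- length(idx_chr)
  chain <- bead_chain(ann)
  lab <- match(ann$labels, c("A", "B", "C"))
  hap <- ann$chains$hap_id[chain]
  bin <- ann$haploid_index

  ut <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  same <- chain[i] == chain[j]
  sep <- pmin(abs(bin[i] - bin[j]), s_max)
  lab_pair <- pmin(lab[i], lab[j]) * 10 + pmax(lab[i], lab[j])
  lab_codes <- c(11, 12, 13, 22, 23, 33)
  lab_names <- c("AA", "AB", "AC", "BB", "BC", "CC")
  lab_grp <- match(lab_pair, lab_codes)
  nhap <- nrow(ann$haploid)
  hp_i <- pmin(hap[i], hap[j]); hp_j <- pmax(hap[i], hap[j])
  hp_grp <- (hp_i - 1L) * nhap + hp_j  # linear index of unordered pair

  ideal_acc <- numeric(s_max)
  comp_acc <- numeric(6)
  chrom_acc <- numeric(nhap * nhap)
  for (k in keep) {
    D <- as.matrix(stats::dist(trajectory$frames[idx_chr, , k]))
    f <- contact_indicator(D[ut], cf)
    fi <- f[same]
    ideal_acc <- ideal_acc + {
      v <- numeric(s_max)
      t <- tapply(fi, sep[same], sum)
      v[as.integer(names(t))] <- t
      v
    }
    ct <- tapply(f, lab_grp, sum)
    cv <- numeric(6); cv[as.integer(names(ct))] <- ct
    comp_acc <- comp_acc + cv
    fe <- f[!same]
    ht <- tapply(fe, hp_grp[!same], sum)
    hv <- numeric(nhap * nhap); hv[as.integer(names(ht))] <- ht
    chrom_acc <- chrom_acc + hv
  }
  nfr <- length(keep)
  ideal_n <- {v <- numeric(s_max)
              t <- table(sep[same]); v[as.integer(names(t))] <- t; v}
  comp_n <- {v <- numeric(6); t <- table(lab_grp)
             v[as.integer(names(t))] <- t; v}
  chrom_n <- {v <- numeric(nhap * nhap); t <- table(hp_grp[!same])
              v[as.integer(names(t))] <- t; v}
  ideal <- ifelse(ideal_n > 0, ideal_acc / (nfr * ideal_n), NA_real_)
  compartment <- setNames(
    ifelse(comp_n > 0, comp_acc / (nfr * comp_n), NA_real_), lab_names)
  chrom_v <- ifelse(chrom_n > 0, chrom_acc / (nfr * chrom_n), NA_real_)
  chrom_pair <- matrix(NA_real_, nhap, nhap,
                       dimnames = list(ann$haploid$chrom, ann$haploid$chrom))
  for (a in seq_len(nhap)) for (b in a:nhap) {
    chrom_pair[a, b] <- chrom_pair[b, a] <- chrom_v[(a - 1L) * nhap + b]
  }

  lam <- if (topology$counts["lamina"] > 0) {
    insilico_profile(trajectory, topology, "damid", cf,
                     discard_steps = discard_steps,
                     standardize = FALSE)$signal
  } else NULL
  spk <- if (topology$counts["speckle"] > 0) {
    insilico_profile(trajectory, topology, "tsaseq", cf,
                     discard_steps = discard_steps,
                     standardize = FALSE)$signal
  } else NULL

  structure(
    list(ideal = ideal, compartment = compartment, chrom_pair = chrom_pair,
         lamina = lam, speckle = spk, s_max = s_max, n_frames = nfr),
    class = "constraint_set"
  )
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf(
    "constraint_set: ideal[%d], compartment[6], chrom_pair[%dx%d], lamina[%s], speckle[%s]; %d frames\n",
    length(x$ideal), nrow(x$chrom_pair), ncol(x$chrom_pair),
    if (is.null(x$lamina)) "-" else length(x$lamina),
    if (is.null(x$speckle)) "-" else length(x$speckle), x$n_frames))
  invisible(x)
}

#' Average several constraint sets (e.g. across independent trajectories)
#' @param sets list of `constraint_set`s with identical shapes.
#' @export
average_constraints <- function(sets) {
  out <- sets[[1]]
  avg <- function(get) {
    vals <- lapply(sets, get)
    if (is.null(vals[[1]])) return(NULL)
    Reduce(`+`, vals) / length(vals)
  }
  out$ideal <- avg(function(s) s$ideal)
  out$compartment <- avg(function(s) s$compartment)
  out$chrom_pair <- avg(function(s) s$chrom_pair)
  out$lamina <- avg(function(s) s$lamina)
  out$speckle <- avg(function(s) s$speckle)
  out$n_frames <- sum(vapply(sets, function(s) s$n_frames, numeric(1)))
  out
}

#' Adam optimizer state
#'
#' @param learning_rate step size.
#' @param beta1,beta2 exponential decay rates of the first and second
#'   moment estimates.
#' @param epsilon numerical floor.
#' @return An `adam_state` (moments are allocated on first use).
#' @export
adam_state <- function(learning_rate = 0.01, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8) {
  structure(list(lr = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = epsilon, m = NULL, v = NULL, t = 0L),
            class = "adam_state")
}

#' One Adam update with bias correction
#'
#' Standard adaptive-moment gradient descent: on the first step with any
#' non-zero gradient each parameter moves by approximately the learning
#' rate in magnitude.  A zero gradient leaves the parameters unchanged
#' while the moments decay towards zero.
#'
#' @param parameters numeric parameter vector.
#' @param gradient gradient vector (same shape).
#' @param state an [adam_state()].
#' @return list with updated `parameters` and `state`.
#' @export
adam_update <- function(parameters, gradient, state) {
  stopifnot(inherits(state, "adam_state"))
  if (length(gradient) != length(parameters)) {
    stop("gradient and parameter shapes differ")
  }
  if (is.null(state$m)) {
    state$m <- numeric(length(parameters))
    state$v <- numeric(length(parameters))
  }
  if (length(state$m) != length(parameters)) {
    stop("optimizer state shape does not match the parameters")
  }
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * gradient
  state$v <- state$beta2 * state$v + (1 - state$beta2) * gradient^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  parameters <- parameters - state$lr * mhat / (sqrt(vhat) + state$eps)
  list(parameters = parameters, state = state)
}

.block_names <- c("ideal", "compartment", "chrom_pair", "lamina", "speckle")

## extract a coupling block from forcefield parameters as a plain vector
.get_block <- function(params, block) {
  switch(block,
    ideal = params$alpha_ideal,
    compartment = params$compartment[upper.tri(params$compartment, diag = TRUE)],
    chrom_pair = params$chrom_pair[upper.tri(params$chrom_pair, diag = TRUE)],
    lamina = params$chi_lamina,
    speckle = params$chi_speckle
  )
}

.set_block <- function(params, block, value) {
  switch(block,
    ideal = { params$alpha_ideal <- value },
    compartment = {
      m <- params$compartment
      m[upper.tri(m, diag = TRUE)] <- value
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      params$compartment <- m
    },
    chrom_pair = {
      m <- params$chrom_pair
      m[upper.tri(m, diag = TRUE)] <- value
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      params$chrom_pair <- m
    },
    lamina = { params$chi_lamina <- value },
    speckle = { params$chi_speckle <- value }
  )
  params
}

## constraint block as a vector in the same order as the coupling block
.constraint_block <- function(cs, block) {
  if (is.null(cs[[block]])) return(NULL)
  switch(block,
    ideal = cs$ideal,
    compartment = {
      if (is.null(cs$compartment)) return(NULL)
      m <- matrix(NA_real_, 3, 3)
      m[1, 1] <- cs$compartment["AA"]; m[1, 2] <- cs$compartment["AB"]
      m[1, 3] <- cs$compartment["AC"]; m[2, 2] <- cs$compartment["BB"]
      m[2, 3] <- cs$compartment["BC"]; m[3, 3] <- cs$compartment["CC"]
      m[upper.tri(m, diag = TRUE)]
    },
    chrom_pair = cs$chrom_pair[upper.tri(cs$chrom_pair, diag = TRUE)],
    lamina = cs$lamina,
    speckle = cs$speckle
  )
}

#' One iteration of the maximum-entropy parameterization loop
#'
#' Runs a batch of independent simulations with the current couplings,
#' extracts the simulated constraint averages, and applies one Adam
#' update per constraint block.  The gradient of the maximum-entropy dual
#' for a coupling is the mismatch between its experimental and simulated
#' conjugate average, so each coupling is corrected by its own
#' constraint's deviation: if a contact is over-represented in the
#' simulation its coupling becomes more repulsive, and vice versa.
#' Constraint entries without sampled pairs (NA) contribute no gradient.
#'
#' @param params current `forcefield_parameters`.
#' @param targets experimental `constraint_set` (blocks may be `NULL` to
#'   skip them).
#' @param topology a `nucleus_topology`.
#' @param budget list with `n_traj`, `n_steps`, `record_interval`,
#'   `discard_steps` controlling the simulation batch.
#' @param opt_states named list of per-block [adam_state()]s (created on
#'   first use).
#' @param seed integer seed; trajectory seeds are derived from it.
#' @param integrator,reactions propagation specs.
#' @return list with updated `params`, `opt_states`, simulated
#'   `constraints` and `diagnostics` (per-block residual norms and
#'   Pearson correlations).
#' @export
maxent_iteration <- function(params, targets, topology, budget,
                             opt_states = NULL, seed = 1L,
                             integrator = integrator_spec("langevin"),
                             reactions = speckle_reaction_spec()) {
  stopifnot(budget$n_traj >= 1)
  if (is.null(opt_states)) opt_states <- list()
  sets <- vector("list", budget$n_traj)
  for (t in seq_len(budget$n_traj)) {
    tseed <- (as.numeric(seed) * 1000 + t * 7919) %% 2147483647
    traj <- tryCatch(
      run_simulation(topology, params, n_steps = budget$n_steps,
                     record_interval = budget$record_interval,
                     integrator = integrator, reactions = reactions,
                     seed = tseed),
      error = function(e) stop(sprintf(
        "simulation %d of the max-ent iteration failed: %s", t,
        conditionMessage(e)))
    )
    sets[[t]] <- constraints_from_trajectory(
      traj, topology, params$contact,
      discard_steps = budget$discard_steps,
      s_max = length(params$alpha_ideal)
    )
  }
  sim <- average_constraints(sets)

  diagnostics <- list()
  for (block in .block_names) {
    tgt <- .constraint_block(targets, block)
    if (is.null(tgt)) next
    cur <- .constraint_block(sim, block)
    ok <- is.finite(tgt) & is.finite(cur)
    mismatch <- ifelse(ok, cur - tgt, 0)  # simulated - experimental
    p <- .get_block(params, block)
    if (is.null(opt_states[[block]])) opt_states[[block]] <- adam_state()
    ## dual gradient: experimental - simulated (= -mismatch); descending it
    ## raises the coupling (more repulsion) where contacts are in excess
    upd <- adam_update(p, -mismatch, opt_states[[block]])
    params <- .set_block(params, block, upd$parameters)
    opt_states[[block]] <- upd$state
    diagnostics[[block]] <- list(
      residual_norm = sqrt(sum(mismatch[ok]^2)),
      pearson = if (sum(ok) > 2 && sd(tgt[ok]) > 0 && sd(cur[ok]) > 0)
        cor(tgt[ok], cur[ok]) else NA_real_
    )
  }
  list(params = params, opt_states = opt_states, constraints = sim,
       diagnostics = diagnostics)
}

#' Iterate the maximum-entropy loop to convergence
#'
#' Repeats simulate / compare / update for `n_iterations` rounds,
#' tracking the total residual norm and returning the best iterate.
#'
#' @inheritParams maxent_iteration
#' @param n_iterations number of rounds.
#' @param learning_rates optional named per-block learning rates.
#' @param verbose print per-iteration residuals.
#' @return list with `params` (best iterate), `final_params`, `history`
#'   (data.frame of per-iteration block residuals and Pearson
#'   correlations), `best_iteration`.
#' @export
run_optimization <- function(params, targets, topology, budget,
                             n_iterations = 10L, seed = 1L,
                             learning_rates = NULL,
                             integrator = integrator_spec("langevin"),
                             reactions = speckle_reaction_spec(),
                             verbose = FALSE) {
  opt_states <- list()
  if (!is.null(learning_rates)) {
    for (block in names(learning_rates)) {
      opt_states[[block]] <- adam_state(learning_rate = learning_rates[[block]])
    }
  }
  history <- list()
  best <- list(params = params, total = Inf, iteration = 0L)
  for (it in seq_len(n_iterations)) {
    res <- maxent_iteration(params, targets, topology, budget,
                            opt_states = opt_states,
                            seed = (as.numeric(seed) + it * 104729) %% 2147483647,
                            integrator = integrator, reactions = reactions)
    opt_states <- res$opt_states
    d <- res$diagnostics
    total <- sum(vapply(d, function(b) b$residual_norm^2, numeric(1)))
    total <- sqrt(total)
    row <- data.frame(iteration = it, total_residual = total)
    for (block in names(d)) {
      row[[paste0("residual_", block)]] <- d[[block]]$residual_norm
      row[[paste0("pearson_", block)]] <- d[[block]]$pearson
    }
    history[[it]] <- row
    if (verbose) {
      message(sprintf("iteration %d: total residual %.4g", it, total))
    }
    ## best iterate = parameters that *produced* the lowest residual
    if (total < best$total) {
      best <- list(params = params, total = total, iteration = it,
                   constraints = res$constraints)
    }
    params <- res$params
  }
  list(params = best$params, final_params = params,
       history = do.call(rbind, history), best_iteration = best$iteration,
       best_constraints = best$constraints, best_residual = best$total)
}
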