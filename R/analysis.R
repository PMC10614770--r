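#' Frame-averaged chromatin contact map
#'
#' Scores every chromatin bead pair in every retained frame with the
#' smooth contact weight and averages over frames.  With
#' `homolog_average = TRUE` the diploid map is collapsed onto haploid
#' 100-KB bins by averaging the four homolog copy-pair combinations
#' (two for bins on X or Y).
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param topology the matching `nucleus_topology`.
#' @param cf a [contact_function()] (defaults to the standard one).
#' @param homolog_average collapse homologs (default `TRUE`).
#' @param discard_steps equilibration discard before averaging.
#' @param hard_cutoff if non-`NULL`, use a 0/1 indicator at this distance
#'   instead of the smooth weight (fast variant).
#' @return A `contact_map`: `matrix` (symmetric, entries in `[0,1]`),
#'   `bins` (chrom/bin table), `homolog_averaged`, `n_frames`,
#'   `normalization` tag.
#' @export
compute_contact_map <- function(trajectory, topology, cf = contact_function(),
                                homolog_average = TRUE, discard_steps = 0,
                                hard_cutoff = NULL) {
  keep <- trajectory_frames(trajectory, discard_steps)
  if (length(keep) < 1) stop("no frames left after the equilibration discard")
  idx <- particle_indices(topology, "chromatin")
  nb <- length(idx)
  M <- matrix(0, nb, nb)
  for (k in keep) {
    D <- as.matrix(stats::dist(trajectory$frames[idx, , k]))
    W <- if (is.null(hard_cutoff)) contact_indicator(D, cf) else
      (D <= hard_cutoff) * 1
    M <- M + W
  }
  M <- M / length(keep)

  ann <- topology$annotation
  sat <- if (is.null(hard_cutoff)) contact_indicator(0, cf) else 1
  if (homolog_average) {
    A <- .homolog_collapse_matrix(ann)
    M <- t(A) %*% M %*% A
    ## a bin's self-entry mixes the bead-with-itself weight and the
    ## homolog-homolog contact; pin it at the saturation value
    diag(M) <- sat
    bins <- data.frame(
      chrom = rep(ann$haploid$chrom, ann$haploid$n_beads),
      bin = unlist(lapply(ann$haploid$n_beads, seq_len)) - 1L,
      stringsAsFactors = FALSE
    )
  } else {
    bins <- data.frame(
      chrom = rep(paste0(ann$chains$chrom, ".", ann$chains$copy),
                  ann$chains$n_beads),
      bin = unlist(lapply(ann$chains$n_beads, seq_len)) - 1L,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(matrix = unname(as.matrix(M)), bins = bins,
         homolog_averaged = homolog_average, n_frames = length(keep),
         normalization = if (is.null(hard_cutoff)) "smooth-indicator" else
           sprintf("hard-cutoff-%g", hard_cutoff)),
    class = "contact_map"
  )
}

## nb x nhb column-stochastic matrix: column u averages the diploid
## copies of haploid bin u
.homolog_collapse_matrix <- function(ann) {
  nb <- ann$n_beads
  nhb <- ann$n_haploid_bins
  A <- matrix(0, nb, nhb)
  A[cbind(seq_len(nb), ann$haploid_index)] <- 1
  sweep(A, 2, colSums(A), "/")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d x %d bins (%s), %d frames, %s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$homolog_averaged) "haploid" else "diploid",
              x$n_frames, x$normalization))
  invisible(x)
}

#' Mean contact probability versus genomic separation
#'
#' Averages the intra-chromosomal entries of a contact map at each
#' genomic separation `s` (in 100-KB beads) over all chromosomes.
#'
#' @param map a `contact_map`.
#' @param log_bins if `TRUE`, additionally return log-spaced separation
#'   bins (geometric means of the per-`s` values).
#' @return data.frame with `s` and `p` (and attribute `"log_binned"` when
#'   requested).
#' @export
contact_scaling <- function(map, log_bins = FALSE) {
  chroms <- unique(map$bins$chrom)
  acc <- list()
  for (ch in chroms) {
    rows <- which(map$bins$chrom == ch)
    n <- length(rows)
    if (n < 2) next
    B <- map$matrix[rows, rows]
    for (s in seq_len(n - 1)) {
      v <- B[cbind(seq_len(n - s), seq_len(n - s) + s)]
      acc[[length(acc) + 1L]] <- data.frame(s = s, sum = sum(v),
                                            n = length(v))
    }
  }
  d <- do.call(rbind, acc)
  agg <- aggregate(cbind(sum, n) ~ s, data = d, FUN = sum)
  out <- data.frame(s = agg$s, p = agg$sum / agg$n)
  out <- out[order(out$s), ]
  rownames(out) <- NULL
  if (log_bins) {
    brk <- unique(round(10^seq(0, log10(max(out$s)), length.out = 25)))
    grp <- cut(out$s, c(0, brk), labels = FALSE)
    lb <- aggregate(cbind(s = out$s, p = out$p), by = list(g = grp),
                    FUN = mean)
    attr(out, "log_binned") <- data.frame(s = lb$s, p = lb$p)
  }
  out
}

#' In-silico DamID / TSA-Seq profile
#'
#' Per haploid 100-KB bin, the frame- and homolog-averaged contact
#' frequency of the bead with nuclear landmarks: lamina particles
#' (`kind = "damid"`) or de-phosphorylated speckle particles
#' (`kind = "tsaseq"`; phosphorylated speckles never count).  Per frame a
#' bead's contact with a landmark set is the union weight
#' `1 - prod(1 - f(r))`, which stays in `[0,1]` and saturates when the
#' bead is permanently adjacent to a landmark.
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param topology the matching `nucleus_topology`.
#' @param kind `"damid"` or `"tsaseq"`.
#' @param cf a [contact_function()].
#' @param discard_steps equilibration discard.
#' @param standardize also return the z-scored profile.
#' @return A `linear_profile`: `signal` per haploid bin, `kind`, `bins`,
#'   `n_frames`, optional `zscore`.
#' @export
insilico_profile <- function(trajectory, topology,
                             kind = c("damid", "tsaseq"),
                             cf = contact_function(), discard_steps = 0,
                             standardize = TRUE) {
  kind <- match.arg(kind)
  keep <- trajectory_frames(trajectory, discard_steps)
  if (length(keep) < 1) stop("no frames left after the equilibration discard")
  idx_chr <- particle_indices(topology, "chromatin")
  lm_cat <- if (kind == "damid") "lamina" else "speckle"
  idx_lm_all <- particle_indices(topology, lm_cat)
  if (length(idx_lm_all) == 0) {
    stop(sprintf("topology has no %s particles for kind = '%s'", lm_cat, kind))
  }
  nb <- length(idx_chr)
  acc <- numeric(nb)
  spk_all <- particle_indices(topology, "speckle")
  for (k in keep) {
    idx_lm <- idx_lm_all
    if (kind == "tsaseq") {
      st <- trajectory$speckle_states[k, ]
      idx_lm <- spk_all[st == 1L]
    }
    if (length(idx_lm) == 0) next  # all speckles P: zero contribution
    P <- matrix(trajectory$frames[idx_chr, , k], ncol = 3)
    L <- matrix(trajectory$frames[idx_lm, , k], ncol = 3)
    ## union contact weight per bead over the landmark set
    prodterm <- rep(1, nb)
    for (j in seq_len(nrow(L))) {
      d <- sqrt((P[, 1] - L[j, 1])^2 + (P[, 2] - L[j, 2])^2 +
                  (P[, 3] - L[j, 3])^2)
      prodterm <- prodterm * (1 - contact_indicator(d, cf))
    }
    acc <- acc + (1 - prodterm)
  }
  per_bead <- acc / length(keep)
  ann <- topology$annotation
  A <- .homolog_collapse_matrix(ann)
  signal <- as.vector(t(A) %*% per_bead)
  bins <- data.frame(
    chrom = rep(ann$haploid$chrom, ann$haploid$n_beads),
    bin = unlist(lapply(ann$haploid$n_beads, seq_len)) - 1L,
    stringsAsFactors = FALSE
  )
  z <- if (standardize && sd(signal) > 0) (signal - mean(signal)) / sd(signal)
    else rep(NA_real_, length(signal))
  structure(
    list(signal = signal, zscore = z, kind = kind, bins = bins,
         resolution = ann$bin_size, n_frames = length(keep),
         per_bead_diploid = per_bead),
    class = "linear_profile"
  )
}

#' @export
print.linear_profile <- function(x, ...) {
  cat(sprintf("linear_profile (%s): %d haploid bins at %g bp, %d frames\n",
              x$kind, length(x$signal), x$resolution, x$n_frames))
  invisible(x)
}

#' Mean-squared displacement with anomalous-exponent fit
#'
#' Time-origin-averaged MSD of the selected particles, converted to
#' physical units (micrometres squared versus seconds) through the
#' reduced unit system, and fitted with the power law
#' `msd(dt) = D_alpha * dt^alpha` by linear regression on log-log axes
#' over the stated window.
#'
#' @param trajectory a `nucleus_trajectory` (Brownian dynamics
#'   recommended for the physical time mapping).
#' @param particle_ids particle indices to track (e.g. telomere beads).
#' @param units a [unit_system()].
#' @param fit_window physical-time window (seconds) for the power-law
#'   fit; defaults to 10-1000 s.
#' @param max_lag_frames largest lag in frames (default: half the
#'   trajectory).
#' @return An `msd_result`: `lag_s`, `msd_um2` (pooled), `per_particle`
#'   matrix, `alpha`, `D_alpha` (um^2 s^-alpha), `fit_window`.  The fit
#'   is refused (alpha = NA) when fewer than 5 lag points fall in the
#'   window.
#' @export
compute_msd <- function(trajectory, particle_ids, units = unit_system(),
                        fit_window = c(10, 1000), max_lag_frames = NULL) {
  nf <- n_frames(trajectory)
  if (nf < 2) stop("need at least 2 frames for an MSD")
  if (is.null(max_lag_frames)) max_lag_frames <- max(1L, nf %/% 2L)
  lags <- seq_len(min(max_lag_frames, nf - 1L))
  np <- length(particle_ids)
  per <- matrix(0, length(lags), np)
  for (li in seq_along(lags)) {
    lag <- lags[li]
    ## displacement over all time origins, per particle
    d <- trajectory$frames[particle_ids, , (1 + lag):nf, drop = FALSE] -
      trajectory$frames[particle_ids, , 1:(nf - lag), drop = FALSE]
    per[li, ] <- apply(d^2, 1, sum) / (nf - lag)
  }
  step_time <- trajectory$record_interval * trajectory$integrator$dt
  lag_s <- to_physical_time(units, lags * step_time)
  sigma_um <- units$sigma_nm / 1000
  per_um2 <- per * sigma_um^2
  pooled <- rowMeans(per_um2)

  in_win <- which(lag_s >= fit_window[1] & lag_s <= fit_window[2] &
                    pooled > 0)
  alpha <- NA_real_
  D_alpha <- NA_real_
  if (length(in_win) >= 5) {
    fit <- lm(log(pooled[in_win]) ~ log(lag_s[in_win]))
    alpha <- unname(coef(fit)[2])
    D_alpha <- unname(exp(coef(fit)[1]))
  }
  structure(
    list(lag_s = lag_s, msd_um2 = pooled, per_particle = per_um2,
         alpha = alpha, D_alpha = D_alpha, fit_window = fit_window,
         n_particles = np),
    class = "msd_result"
  )
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf(
    "msd_result: %d particles, %d lags; alpha = %s, D_alpha = %s um^2 s^-alpha\n",
    x$n_particles, length(x$lag_s),
    format(x$alpha, digits = 3), format(x$D_alpha, digits = 3)))
  invisible(x)
}

#' Chromosome radius of gyration and radial positions
#'
#' Equal-mass radius of gyration per chromosome chain and radial
#' positions (relative to the nucleus centre, normalized by the nuclear
#' radius), per frame and trajectory-averaged.
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param topology the matching `nucleus_topology`.
#' @param units a [unit_system()] (R_g reported in micrometres).
#' @param discard_steps equilibration discard.
#' @return A `chromosome_geometry`: `rg_um` (chains x frames),
#'   `mean_rg_um`, `radial_chain` (normalized chain centre-of-mass radius,
#'   chains x frames), `mean_radial_chain`, `mean_radial_bead`.
#' @export
chromosome_geometry <- function(trajectory, topology, units = unit_system(),
                                discard_steps = 0) {
  keep <- trajectory_frames(trajectory, discard_steps)
  ann <- topology$annotation
  nch <- nrow(ann$chains)
  R <- topology$radius
  sigma_um <- units$sigma_nm / 1000
  rg <- matrix(0, nch, length(keep))
  rad <- matrix(0, nch, length(keep))
  bead_rad <- numeric(ann$n_beads)
  for (fi in seq_along(keep)) {
    X <- trajectory$frames[, , keep[fi]]
    for (ci in seq_len(nch)) {
      rows <- ann$chains$offset[ci] + seq_len(ann$chains$n_beads[ci])
      P <- X[rows, , drop = FALSE]
      com <- colMeans(P)
      rg[ci, fi] <- sqrt(mean(rowSums(sweep(P, 2, com)^2)))
      rad[ci, fi] <- sqrt(sum(com^2)) / R
    }
    chr_rows <- seq_len(ann$n_beads)
    bead_rad <- bead_rad + sqrt(rowSums(X[chr_rows, , drop = FALSE]^2)) / R
  }
  structure(
    list(rg_um = rg * sigma_um, mean_rg_um = rowMeans(rg) * sigma_um,
         radial_chain = rad, mean_radial_chain = rowMeans(rad),
         mean_radial_bead = bead_rad / length(keep),
         chains = ann$chains, radius = R),
    class = "chromosome_geometry"
  )
}

#' Count phase-separated droplets by single-linkage clustering
#'
#' Particles of the chosen category (optionally restricted to a speckle
#' chemical state) are clustered by single-linkage under a distance
#' cutoff -- i.e. the connected components of the graph linking pairs
#' closer than the cutoff.  Clusters smaller than `min_size` are not
#' counted as droplets.
#'
#' @param configuration a `nucleus_configuration`.
#' @param topology the matching `nucleus_topology`.
#' @param category particle category to cluster (default `"nucleolus"`).
#' @param state_filter for speckles, `"dP"` or `"P"` restricts to that
#'   chemical state; `NULL` keeps all.
#' @param cutoff linkage distance; default 1.5 * sigma_LJ = 0.75.
#' @param min_size minimum droplet size (default 2).
#' @return list with `n_clusters`, `labels` (0 for unclustered singletons
#'   below `min_size`), `sizes`, `centroids`.
#' @export
cluster_droplets <- function(configuration, topology,
                             category = "nucleolus", state_filter = NULL,
                             cutoff = 0.75, min_size = 2L) {
  idx <- particle_indices(topology, category)
  if (!is.null(state_filter) && category == "speckle") {
    want <- if (identical(state_filter, "dP")) 1L else 0L
    idx <- idx[configuration$speckle_state == want]
  }
  if (length(idx) == 0) {
    return(list(n_clusters = 0L, labels = integer(0), sizes = integer(0),
                centroids = matrix(0, 0, 3)))
  }
  P <- configuration$positions[idx, , drop = FALSE]
  if (nrow(P) == 1) {
    memb <- 1L
  } else {
    hc <- stats::hclust(stats::dist(P), method = "single")
    memb <- stats::cutree(hc, h = cutoff)
  }
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- ifelse(memb %in% keep, match(memb, keep), 0L)
  labels[is.na(labels)] <- 0L
  nclust <- length(keep)
  centroids <- if (nclust > 0) {
    t(vapply(seq_len(nclust), function(g) {
      colMeans(P[labels == g, , drop = FALSE])
    }, numeric(3)))
  } else matrix(0, 0, 3)
  list(n_clusters = nclust, labels = as.integer(labels),
       sizes = as.integer(sizes[as.character(keep)]), centroids = centroids)
}

#' Pairwise Pearson correlations across an ensemble
#'
#' For contact maps the upper triangle (excluding the diagonal) is
#' flattened; for linear profiles (or plain vectors) the full vector is
#' used.  Returns the full Pearson matrix and the mean off-diagonal
#' correlation.
#'
#' @param inputs list of `contact_map`s, `linear_profile`s, matrices or
#'   numeric vectors, all the same shape.
#' @return list with `correlations` (symmetric matrix) and
#'   `mean_offdiagonal`.
#' @export
ensemble_correlations <- function(inputs) {
  if (length(inputs) < 2) stop("need at least two inputs")
  flatten <- function(x) {
    if (inherits(x, "contact_map")) return(x$matrix[upper.tri(x$matrix)])
    if (inherits(x, "linear_profile")) return(x$signal)
    if (is.matrix(x)) return(x[upper.tri(x)])
    as.numeric(x)
  }
  vecs <- lapply(inputs, flatten)
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1) stop("inputs have mismatched shapes")
  V <- do.call(cbind, vecs)
  C <- cor(V)
  list(correlations = C,
       mean_offdiagonal = mean(C[upper.tri(C)]))
}

#' Shape of the lamina envelope
#'
#' Principal semi-axes of the lamina vertex cloud in its centre-of-mass
#' frame (square roots of the covariance eigenvalues), averaged over the
#' requested frames.  `sphericity` is the max/min axis ratio (1 for a
#' perfect sphere) and `axial_ratio` compares the z extent with the
#' geometric mean of the x and y extents (< 1 for an oblate, z-compressed
#' envelope).
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param topology the matching `nucleus_topology`.
#' @param frames frame indices to average over (default: the last
#'   quarter of the trajectory).
#' @return list with `axes` (averaged semi-axes, ascending), `sphericity`,
#'   `axial_ratio`, and `max_edge_stretch` (largest mesh edge length over
#'   its rest length, final frame).
#' @export
lamina_shape <- function(trajectory, topology, frames = NULL) {
  lam <- particle_indices(topology, "lamina")
  if (length(lam) < 4) stop("topology has too few lamina particles")
  nf <- n_frames(trajectory)
  if (is.null(frames)) frames <- seq.int(max(1L, nf - nf %/% 4L), nf)
  C <- matrix(0, 3, 3)
  axial <- 0
  for (k in frames) {
    P <- matrix(trajectory$frames[lam, , k], ncol = 3)
    P <- sweep(P, 2, colMeans(P))
    C <- C + cov(P)
    axial <- axial + sd(P[, 3]) / sqrt(sd(P[, 1]) * sd(P[, 2]))
  }
  ax <- sort(sqrt(eigen(C / length(frames), symmetric = TRUE,
                        only.values = TRUE)$values))
  mesh_rows <- which(topology$bond_type == "mesh")
  stretch <- NA_real_
  if (length(mesh_rows)) {
    i <- topology$bonds[mesh_rows, 1]; j <- topology$bonds[mesh_rows, 2]
    d <- sqrt(rowSums((matrix(trajectory$frames[i, , nf], ncol = 3) -
                         matrix(trajectory$frames[j, , nf], ncol = 3))^2))
    stretch <- max(d / topology$bond_r0[mesh_rows])
  }
  list(axes = ax, sphericity = ax[3] / ax[1],
       axial_ratio = axial / length(frames), max_edge_stretch = stretch)
}
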