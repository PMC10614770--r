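#' Build a diploid genome annotation at 100-KB resolution
#'
#' Partitions each chromosome into 100-KB bins (one bead per bin, last
#' partial bin kept as a full bead) and assigns every bead a compartment
#' label: `A` (euchromatin), `B` (heterochromatin) or `C` (pericentromeric).
#' Bins are 0-based half-open: bin `i` covers `[i*1e5, (i+1)*1e5)`.
#' Each chromosome is instantiated `copies` times (homologous copies share
#' length and labels); with the default diploid table of 22 autosome pairs
#' plus X and Y this yields 46 chains.
#'
#' @param chrom_length_table data.frame with columns `chrom`, `length`
#'   (bp) and optionally `copies` (default `ploidy`; use 1 for X and Y in
#'   a male genome).
#' @param compartment_track either a data.frame with columns
#'   `chrom`, `start`, `end`, `label` (BED-like intervals, labels in
#'   A/B/C), or a list mapping chromosome name to a per-bin label vector.
#' @param bin_size bin width in bp (100 KB).
#' @param ploidy default copy number for chromosomes without a `copies`
#'   column.
#' @return A `genome_annotation` object: chain table (`chains`), haploid
#'   bin table (`haploid`), per-diploid-bead labels (`labels`), map from
#'   diploid bead to haploid bin (`haploid_index`), telomere bead indices
#'   (`telomeres`, 1-based) and centromeric (label C) runs.
#' @export
build_genome_annotation <- function(chrom_length_table, compartment_track,
                                    bin_size = 1e5, ploidy = 2L) {
  tab <- as.data.frame(chrom_length_table)
  stopifnot(all(c("chrom", "length") %in% names(tab)))
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names")
  if (is.null(tab$copies)) tab$copies <- as.integer(ploidy)
  tab$copies <- as.integer(tab$copies)
  stopifnot(all(tab$copies >= 1))

  n_beads_hap <- as.integer(ceiling(tab$length / bin_size))
  hap_offset <- c(0L, cumsum(n_beads_hap))[seq_len(nrow(tab))]
  haploid <- data.frame(
    chrom = tab$chrom, length = tab$length, n_beads = n_beads_hap,
    offset = hap_offset, stringsAsFactors = FALSE
  )

  hap_labels <- .resolve_compartment_labels(haploid, compartment_track, bin_size)

  ## expand to diploid chains: copy 1..copies of each chromosome, grouped
  ## by chromosome so homologs are adjacent
  chains <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(
      chrom = tab$chrom[i], copy = seq_len(tab$copies[i]),
      n_beads = n_beads_hap[i], hap_id = i, stringsAsFactors = FALSE
    )
  }))
  chains$chain <- seq_len(nrow(chains))
  chains$offset <- c(0L, cumsum(chains$n_beads))[seq_len(nrow(chains))]
  chains <- chains[, c("chain", "chrom", "copy", "hap_id", "n_beads", "offset")]

  labels <- unlist(lapply(seq_len(nrow(chains)), function(i) {
    hap_labels[[chains$hap_id[i]]]
  }), use.names = FALSE)
  haploid_index <- unlist(lapply(seq_len(nrow(chains)), function(i) {
    haploid$offset[chains$hap_id[i]] + seq_len(chains$n_beads[i])
  }), use.names = FALSE)

  telomeres <- as.integer(c(rbind(chains$offset + 1L,
                                  chains$offset + chains$n_beads)))

  ## centromeric runs: maximal runs of label C per chain
  cent <- do.call(rbind, lapply(seq_len(nrow(chains)), function(i) {
    lab <- labels[chains$offset[i] + seq_len(chains$n_beads[i])]
    r <- rle(lab == "C")
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chain = chains$chain[i],
               from = chains$offset[i] + starts[keep],
               to = chains$offset[i] + ends[keep])
  }))

  structure(
    list(
      chains = chains, haploid = haploid, labels = labels,
      haploid_index = haploid_index, telomeres = telomeres,
      centromeric = cent, bin_size = bin_size,
      n_beads = sum(chains$n_beads), n_haploid_bins = sum(n_beads_hap)
    ),
    class = "genome_annotation"
  )
}

## map a compartment track onto haploid bins; returns list of per-chrom
## label vectors. Interval labels are assigned by maximal overlap with the
## bead's bin; any uncovered bin is an error naming the offending bins.
.resolve_compartment_labels <- function(haploid, track, bin_size) {
  valid <- c("A", "B", "C")
  if (is.list(track) && !is.data.frame(track)) {
    out <- lapply(seq_len(nrow(haploid)), function(i) {
      v <- track[[haploid$chrom[i]]]
      if (is.null(v) || length(v) != haploid$n_beads[i]) {
        stop(sprintf("compartment labels missing or wrong length for %s",
                     haploid$chrom[i]))
      }
      v <- as.character(v)
      if (!all(v %in% valid)) {
        stop(sprintf("unknown compartment label(s) on %s: %s",
                     haploid$chrom[i],
                     paste(unique(v[!v %in% valid]), collapse = ", ")))
      }
      v
    })
    return(out)
  }
  track <- as.data.frame(track)
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(track)))
  track$label <- as.character(track$label)
  if (!all(track$label %in% valid)) {
    stop(sprintf("unknown compartment label(s): %s",
                 paste(unique(track$label[!track$label %in% valid]),
                       collapse = ", ")))
  }
  lapply(seq_len(nrow(haploid)), function(i) {
    tr <- track[track$chrom == haploid$chrom[i], , drop = FALSE]
    starts <- (seq_len(haploid$n_beads[i]) - 1) * bin_size
    ends <- starts + bin_size
    lab <- character(haploid$n_beads[i])
    for (b in seq_along(starts)) {
      ov <- pmin(tr$end, ends[b]) - pmax(tr$start, starts[b])
      hit <- which(ov > 0)
      if (length(hit) == 0) {
        miss <- which(vapply(seq_along(starts), function(bb) {
          all(pmin(tr$end, ends[bb]) - pmax(tr$start, starts[bb]) <= 0)
        }, logical(1)))
        stop(sprintf(
          "compartment track does not cover bin(s) %s of %s",
          paste(miss - 1L, collapse = ", "), haploid$chrom[i]
        ))
      }
      lab[b] <- tr$label[hit[which.max(ov[hit])]]
    }
    lab
  })
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d chains (%d chromosomes), %d beads (%d haploid bins) at %g bp\n",
    nrow(x$chains), nrow(x$haploid), x$n_beads, x$n_haploid_bins, x$bin_size
  ))
  invisible(x)
}

#' Chain membership of every chromatin bead
#'
#' @param annotation a `genome_annotation`.
#' @return integer vector of chain ids, one per diploid bead.
#' @export
bead_chain <- function(annotation) {
  rep(annotation$chains$chain, annotation$chains$n_beads)
}

#' Build a quasi-uniform spherical lamina mesh
#'
#' Places `n_vertices` points on a sphere with a deterministic generalized
#' spiral (golden-angle) layout and connects each vertex to its `k`
#' nearest neighbours; the edge set is symmetrized so each undirected edge
#' appears exactly once.
#'
#' @param radius sphere radius in reduced units (default: the 5-micron
#'   nuclear radius).
#' @param n_vertices number of mesh particles (>= 12).
#' @param k number of nearest neighbours per vertex before symmetrization.
#' @return A `lamina_mesh`: `vertices` (n x 3 matrix), `edges`
#'   (m x 2, `edges[,1] < edges[,2]`), `radius`, `rest_length` (mean edge
#'   length) and `frozen` flag.
#' @export
build_lamina_mesh <- function(radius = NUCLEUS_RADIUS_REDUCED,
                              n_vertices = 500L, k = 6L) {
  if (radius <= 0) stop("radius must be positive")
  if (n_vertices < 12) stop("need at least 12 mesh vertices")
  i <- seq_len(n_vertices) - 0.5
  phi <- acos(1 - 2 * i / n_vertices)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  verts <- radius * cbind(
    sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi)
  )
  colnames(verts) <- c("x", "y", "z")

  ## k nearest neighbours by brute-force distances (mesh sizes are small)
  d2 <- as.matrix(stats::dist(verts))^2
  diag(d2) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n_vertices), function(v) {
    nn <- order(d2[v, ])[seq_len(k)]
    cbind(pmin(v, nn), pmax(v, nn))
  }))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::components(g)$no != 1) {
    stop("lamina mesh edge graph is not connected; increase k")
  }
  elen <- sqrt(rowSums((verts[edges[, 1], , drop = FALSE] -
                          verts[edges[, 2], , drop = FALSE])^2))
  structure(
    list(vertices = verts, edges = edges, radius = radius,
         edge_lengths = elen, rest_length = mean(elen), frozen = TRUE),
    class = "lamina_mesh"
  )
}

#' @export
print.lamina_mesh <- function(x, ...) {
  cat(sprintf("lamina_mesh: %d vertices, %d edges, radius %.4f (%s)\n",
              nrow(x$vertices), nrow(x$edges), x$radius,
              if (x$frozen) "frozen" else "dynamic"))
  invisible(x)
}

## particle category codes shared with the compiled engine
CATEGORY_LEVELS <- c("chromatin", "nucleolus", "speckle", "lamina")

#' Assemble the nucleus particle topology
#'
#' Orders particles as chromatin beads (chain by chain), then nucleolus,
#' speckle, and lamina particles, and collects the bond list: chromatin
#' backbone bonds between consecutive beads of the same chain plus the
#' lamina mesh edges.
#'
#' @param annotation a `genome_annotation`.
#' @param n_nucleolus,n_speckle numbers of nuclear-body particles.
#' @param lamina_mesh a `lamina_mesh`, or `NULL` for no lamina particles.
#' @param radius nuclear radius in reduced units; defaults to the mesh
#'   radius (or the 5-micron value without a mesh).
#' @return A `nucleus_topology` with a `particles` data.frame (`index`,
#'   `category`, `chain`, `within`, `label`, `hap_bin`), integer matrix
#'   `bonds` (columns `i`, `j`; 1-based), `bond_type`
#'   (`"backbone"`/`"mesh"`), per-category counts, and the annotation.
#' @export
build_topology <- function(annotation, n_nucleolus = 0L, n_speckle = 0L,
                           lamina_mesh = NULL, radius = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  n_nucleolus <- as.integer(n_nucleolus)
  n_speckle <- as.integer(n_speckle)
  if (n_nucleolus < 0 || n_speckle < 0) stop("body counts must be non-negative")
  n_chr <- annotation$n_beads
  if (n_chr == 0) stop("topology requires at least one chromatin bead")
  n_lam <- if (is.null(lamina_mesh)) 0L else nrow(lamina_mesh$vertices)
  if (is.null(radius)) {
    radius <- if (is.null(lamina_mesh)) NUCLEUS_RADIUS_REDUCED else lamina_mesh$radius
  }

  n <- n_chr + n_nucleolus + n_speckle + n_lam
  category <- rep(CATEGORY_LEVELS, c(n_chr, n_nucleolus, n_speckle, n_lam))
  chain <- c(bead_chain(annotation), rep(NA_integer_, n - n_chr))
  within <- c(
    unlist(lapply(annotation$chains$n_beads, seq_len), use.names = FALSE),
    if (n_nucleolus) seq_len(n_nucleolus), if (n_speckle) seq_len(n_speckle),
    if (n_lam) seq_len(n_lam)
  )
  label <- c(annotation$labels, rep(NA_character_, n - n_chr))
  hap_bin <- c(annotation$haploid_index, rep(NA_integer_, n - n_chr))

  particles <- data.frame(
    index = seq_len(n), category = category, chain = chain,
    within = within, label = label, hap_bin = hap_bin,
    stringsAsFactors = FALSE
  )

  backbone <- do.call(rbind, lapply(seq_len(nrow(annotation$chains)), function(i) {
    nb <- annotation$chains$n_beads[i]
    if (nb < 2) return(NULL)
    off <- annotation$chains$offset[i]
    cbind(off + seq_len(nb - 1L), off + seq.int(2L, nb))
  }))
  if (is.null(backbone)) backbone <- matrix(integer(0), ncol = 2)
  mesh_edges <- if (n_lam) lamina_mesh$edges + (n - n_lam) else matrix(integer(0), ncol = 2)
  bonds <- rbind(backbone, mesh_edges)
  colnames(bonds) <- c("i", "j")
  bond_type <- rep(c("backbone", "mesh"), c(nrow(backbone), nrow(mesh_edges)))
  bond_r0 <- c(rep(1.0, nrow(backbone)),
               if (n_lam) lamina_mesh$edge_lengths else numeric(0))

  structure(
    list(
      particles = particles, bonds = bonds, bond_type = bond_type,
      bond_r0 = bond_r0, annotation = annotation, lamina_mesh = lamina_mesh,
      radius = radius,
      counts = c(chromatin = n_chr, nucleolus = n_nucleolus,
                 speckle = n_speckle, lamina = n_lam),
      n_particles = n
    ),
    class = "nucleus_topology"
  )
}

#' @export
print.nucleus_topology <- function(x, ...) {
  cat(sprintf(
    "nucleus_topology: %d particles (%d chromatin / %d nucleolus / %d speckle / %d lamina), %d bonds, radius %.3f\n",
    x$n_particles, x$counts["chromatin"], x$counts["nucleolus"],
    x$counts["speckle"], x$counts["lamina"], nrow(x$bonds), x$radius
  ))
  invisible(x)
}

#' Indices of particles of a given category
#' @param topology a `nucleus_topology`.
#' @param category one of `"chromatin"`, `"nucleolus"`, `"speckle"`,
#'   `"lamina"`.
#' @return 1-based particle indices.
#' @export
particle_indices <- function(topology, category) {
  which(topology$particles$category == category)
}
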