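## Chain-identifier pool for PDB output: 62 single-character ids.
.CHAIN_POOL <- c(LETTERS, letters, 0:9)

.pdb_limits_ok <- function(n_atoms, n_chains, max_resseq) {
  n_atoms <= 99999 && n_chains <= length(.CHAIN_POOL) && max_resseq <= 9999
}

## residue names encode the particle category in the coordinate file
.CAT_RESNAME <- c(chromatin = "CHR", nucleolus = "NUC", speckle = "SPK",
                  lamina = "LAM")

## polymer chains: one per chromosome chain, then one chain per body class
.chain_assignment <- function(topology) {
  pt <- topology$particles
  chain_key <- ifelse(pt$category == "chromatin",
                      paste0("chr", pt$chain), pt$category)
  keys <- unique(chain_key)
  list(key = chain_key, keys = keys, n_chains = length(keys))
}

#' Write a configuration to PDB or mmCIF with a JSON sidecar
#'
#' One polymer chain per chromosome plus one chain per particle class.
#' The particle category is encoded in the residue name (CHR / NUC /
#' SPK / LAM) and the within-chain index in the residue number.  When the
#' system exceeds the fixed-width PDB limits (99,999 atoms, 62 chain
#' identifiers, 9,999 residues per chain) the writer falls back to mmCIF
#' automatically.  Compartment labels, speckle chemical states and seed
#' provenance go into a JSON sidecar (`<path>.json`).
#'
#' @param configuration a `nucleus_configuration`.
#' @param topology the matching `nucleus_topology`.
#' @param path output file path (`.pdb` or `.cif` appended as needed).
#' @param format `"auto"` (default), `"pdb"` or `"cif"`.
#' @return the path written, invisibly; attribute `"format"` records the
#'   chosen format.
#' @export
write_configuration <- function(configuration, topology, path,
                                format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  pt <- topology$particles
  ca <- .chain_assignment(topology)
  resseq <- pt$within
  if (format == "auto") {
    format <- if (.pdb_limits_ok(nrow(pt), ca$n_chains, max(resseq)))
      "pdb" else "cif"
  }
  pos <- configuration$positions
  if (format == "pdb") {
    chain_id <- .CHAIN_POOL[match(ca$key, ca$keys)]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      pt$index, .CAT_RESNAME[pt$category], chain_id, resseq,
      pos[, 1], pos[, 2], pos[, 3], 1, 0
    )
    writeLines(c("REMARK   nucleus model configuration (reduced units)",
                 lines, "END"), path)
  } else {
    chain_id <- ca$key
    hdr <- c(
      "data_nucleus",
      "loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.label_atom_id",
      "_atom_site.label_comp_id", "_atom_site.label_asym_id",
      "_atom_site.label_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
      "_atom_site.Cartn_z"
    )
    lines <- sprintf("ATOM %d CA %s %s %d %.6f %.6f %.6f",
                     pt$index, .CAT_RESNAME[pt$category], chain_id, resseq,
                     pos[, 1], pos[, 2], pos[, 3])
    writeLines(c(hdr, lines), path)
  }
  sidecar <- list(
    format = format,
    category_counts = as.list(topology$counts),
    compartments = topology$annotation$labels,
    speckle_state = configuration$speckle_state,
    seed = configuration$seed,
    frame = configuration$frame
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  attr(path, "format") <- format
  invisible(path)
}

#' Read a configuration written by [write_configuration()]
#'
#' PDB files are parsed with `bio3d::read.pdb`; mmCIF files with a
#' whitespace-table reader of the `atom_site` loop.  Metadata comes from
#' the JSON sidecar.  Malformed coordinate records are rejected with the
#' line number.
#'
#' @param path coordinate file path.
#' @param topology the matching `nucleus_topology` (validates counts).
#' @return A `nucleus_configuration`.
#' @export
read_configuration <- function(path, topology) {
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else NULL
  fmt <- if (!is.null(sidecar)) sidecar$format else {
    if (grepl("\\.cif$", path)) "cif" else "pdb"
  }
  if (fmt == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  } else {
    lines <- readLines(path)
    atom_lines <- grep("^ATOM ", lines)
    fields <- strsplit(trimws(lines[atom_lines]), "\\s+")
    bad <- which(vapply(fields, length, integer(1)) != 9)
    if (length(bad)) {
      stop(sprintf("malformed atom_site record at line %d of %s",
                   atom_lines[bad[1]], path))
    }
    m <- do.call(rbind, fields)
    pos <- matrix(as.numeric(m[, 7:9]), ncol = 3)
    if (anyNA(pos)) {
      stop(sprintf("non-numeric coordinates at line %d of %s",
                   atom_lines[which(rowSums(is.na(pos)) > 0)[1]], path))
    }
  }
  if (nrow(pos) != topology$n_particles) {
    stop(sprintf("file has %d particles but topology expects %d",
                 nrow(pos), topology$n_particles))
  }
  nucleus_configuration(
    pos, topology,
    speckle_state = if (!is.null(sidecar)) as.integer(sidecar$speckle_state)
      else NULL,
    seed = if (!is.null(sidecar) && !is.null(sidecar$seed)) sidecar$seed
      else NA_integer_,
    frame = if (!is.null(sidecar) && !is.null(sidecar$frame)) sidecar$frame
      else 0
  )
}

#' Write / read a trajectory container
#'
#' Chunked binary layout: an 8-byte magic tag, a length-prefixed JSON
#' metadata block (dimensions, integrator and reaction specs, seed,
#' record interval), then the frame positions, speckle states, step
#' numbers and per-frame energies as raw little-endian doubles/integers.
#' The round trip is lossless (bit-exact doubles).
#'
#' @param trajectory a `nucleus_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(trajectory$frames)
  meta <- list(
    n_particles = d[1], n_frames = d[3],
    n_speckle = ncol(trajectory$speckle_states),
    record_interval = trajectory$record_interval,
    integrator = unclass(trajectory$integrator),
    reactions = if (!is.null(trajectory$reactions))
      unclass(trajectory$reactions) else NULL,
    seed = trajectory$seed, frozen_lamina = trajectory$frozen_lamina,
    topology_hash = trajectory$topology_hash,
    total_flips = trajectory$total_flips,
    total_sweeps = trajectory$total_sweeps
  )
  meta_raw <- charToRaw(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE))
  writeBin(charToRaw("NUCTRJ01"), con)
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(as.vector(trajectory$frames), con, size = 8L, endian = "little")
  writeBin(as.integer(trajectory$speckle_states), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(trajectory$steps), con, size = 8L, endian = "little")
  writeBin(as.numeric(trajectory$energy), con, size = 8L, endian = "little")
  writeBin(as.numeric(trajectory$kinetic_temperature), con, size = 8L,
           endian = "little")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (magic != "NUCTRJ01") stop("not a trajectory container: ", path)
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                             simplifyVector = TRUE)
  np <- meta$n_particles; nf <- meta$n_frames; ns <- meta$n_speckle
  frames <- array(readBin(con, "numeric", np * 3 * nf, size = 8L,
                          endian = "little"), dim = c(np, 3, nf))
  states <- matrix(readBin(con, "integer", nf * ns, size = 4L,
                           endian = "little"), nrow = nf, ncol = ns)
  steps <- readBin(con, "numeric", nf, size = 8L, endian = "little")
  energy <- readBin(con, "numeric", nf, size = 8L, endian = "little")
  ktemp <- readBin(con, "numeric", nf, size = 8L, endian = "little")
  integ <- structure(as.list(meta$integrator), class = "integrator_spec")
  reacts <- if (!is.null(meta$reactions))
    structure(as.list(meta$reactions), class = "speckle_reaction_spec")
  else NULL
  structure(
    list(frames = frames, speckle_states = states, steps = steps,
         energy = energy, kinetic_temperature = ktemp,
         record_interval = meta$record_interval, integrator = integ,
         reactions = reacts, total_flips = meta$total_flips,
         total_sweeps = meta$total_sweeps, seed = meta$seed,
         frozen_lamina = meta$frozen_lamina,
         topology_hash = meta$topology_hash, checkpoint = NULL),
    class = "nucleus_trajectory"
  )
}

#' Construct an experimental genomic track
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `value`
#'   (bedGraph-style; `NA` values mark missing bins).
#' @param resolution native bin width in bp.
#' @param provenance free-text provenance note.
#' @return An `experimental_track`.
#' @export
experimental_track <- function(intervals, resolution, provenance = "") {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  o <- order(intervals$chrom, intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  for (ch in unique(intervals$chrom)) {
    d <- intervals[intervals$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop(sprintf("overlapping intervals on %s", ch))
    }
  }
  structure(list(intervals = intervals, resolution = resolution,
                 provenance = provenance),
            class = "experimental_track")
}

#' @export
print.experimental_track <- function(x, ...) {
  cat(sprintf("experimental_track: %d intervals at %g bp [%s]\n",
              nrow(x$intervals), x$resolution, x$provenance))
  invisible(x)
}

#' Rebin a track to a coarser resolution by averaging
#'
#' The value of a coarse bin is the arithmetic mean of the covering
#' native bins, excluding missing (`NA`) native bins; a coarse bin whose
#' native bins are all missing stays missing.
#'
#' @param track an `experimental_track`.
#' @param target_resolution coarse bin width (must be a multiple of the
#'   native resolution; 100 KB for the model).
#' @return An `experimental_track` at the target resolution.
#' @export
rebin_track <- function(track, target_resolution = 1e5) {
  stopifnot(inherits(track, "experimental_track"))
  if (target_resolution %% track$resolution != 0) {
    stop("target resolution must be a multiple of the native resolution")
  }
  iv <- track$intervals
  out <- do.call(rbind, lapply(unique(iv$chrom), function(ch) {
    d <- iv[iv$chrom == ch, ]
    g <- floor(d$start / target_resolution)
    vals <- tapply(d$value, g, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    })
    gs <- as.numeric(names(vals))
    data.frame(chrom = ch, start = gs * target_resolution,
               end = (gs + 1) * target_resolution,
               value = as.numeric(vals), stringsAsFactors = FALSE)
  }))
  experimental_track(out, target_resolution,
                     provenance = sprintf("%s; rebinned to %g bp",
                                          track$provenance,
                                          target_resolution))
}

#' Merge replicate tracks by bin-wise averaging
#'
#' @param tracks list of `experimental_track`s on the same genome and
#'   resolution.
#' @return merged `experimental_track`; the provenance note records the
#'   inputs.
#' @export
merge_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]$intervals
  res <- tracks[[1]]$resolution
  for (t in tracks[-1]) {
    if (!identical(t$resolution, res) ||
        !identical(t$intervals[c("chrom", "start", "end")],
                   ref[c("chrom", "start", "end")])) {
      stop("replicates must share genome bins and resolution")
    }
  }
  vals <- rowMeans(do.call(cbind, lapply(tracks, function(t) t$intervals$value)))
  out <- ref
  out$value <- vals
  experimental_track(out, res,
                     provenance = sprintf("merged %d replicates (%s)",
                                          length(tracks),
                                          paste(vapply(tracks, function(t)
                                            t$provenance, character(1)),
                                            collapse = " + ")))
}

#' Read / write bedGraph tracks
#'
#' @param path file path.
#' @param resolution native resolution recorded on the track object.
#' @export
read_bedgraph <- function(path, resolution = NULL) {
  d <- read.table(path, header = FALSE, sep = "\t",
                  col.names = c("chrom", "start", "end", "value"),
                  stringsAsFactors = FALSE)
  if (is.null(resolution)) resolution <- min(d$end - d$start)
  experimental_track(d, resolution, provenance = basename(path))
}

#' @rdname read_bedgraph
#' @param track an `experimental_track` or `linear_profile`.
#' @export
write_bedgraph <- function(track, path) {
  if (inherits(track, "linear_profile")) {
    iv <- data.frame(chrom = track$bins$chrom,
                     start = track$bins$bin * track$resolution,
                     end = (track$bins$bin + 1) * track$resolution,
                     value = track$signal)
  } else {
    iv <- track$intervals
  }
  write.table(format(iv, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a chromosome length table
#'
#' Tab-separated columns: `chrom`, `length` and optionally `copies`.
#' @param path file path.
#' @export
read_chrom_table <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("chrom", "length", "copies")[seq_len(ncol(d))]
  d
}

#' Read a BED compartment track (chrom, start, end, label)
#' @param path file path.
#' @export
read_compartment_bed <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "label")[seq_len(ncol(d))]
  d
}

#' Export a contact map as dense or sparse text
#'
#' Dense: a whitespace matrix, one row per 100-KB bin.  Sparse: a
#' bin-pair table `bin_i bin_j value` (1-based, upper triangle including
#' the diagonal) preceded by `#chrom <name> <offset>` index lines giving
#' each chromosome's first bin.
#'
#' @param map a `contact_map`.
#' @param path output file.
#' @param format `"dense"` or `"sparse"`.
#' @param threshold sparse entries strictly below this are dropped.
#' @export
export_contact_map <- function(map, path, format = c("dense", "sparse"),
                               threshold = 0) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(map$matrix, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    chroms <- unique(map$bins$chrom)
    offsets <- vapply(chroms, function(ch)
      min(which(map$bins$chrom == ch)), integer(1))
    hdr <- sprintf("#chrom\t%s\t%d", chroms, offsets)
    ut <- which(upper.tri(map$matrix, diag = TRUE), arr.ind = TRUE)
    v <- map$matrix[ut]
    keep <- v >= threshold & v > 0
    body <- sprintf("%d\t%d\t%.10g", ut[keep, 1], ut[keep, 2], v[keep])
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Import a contact map from the dense or sparse text form
#' @param path file path.
#' @param n_bins number of bins (required for sparse input).
#' @export
import_contact_map <- function(path, n_bins = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#chrom")) {
    lines <- readLines(path)
    hdr <- grep("^#chrom", lines, value = TRUE)
    body <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
    if (is.null(n_bins)) n_bins <- max(body[[1]], body[[2]])
    M <- matrix(0, n_bins, n_bins)
    M[cbind(body[[1]], body[[2]])] <- body[[3]]
    M[cbind(body[[2]], body[[1]])] <- body[[3]]
    parts <- strsplit(hdr, "\t")
    bins <- data.frame(
      chrom = rep(vapply(parts, `[`, "", 2),
                  diff(c(as.integer(vapply(parts, `[`, "", 3)), n_bins + 1L))),
      stringsAsFactors = FALSE
    )
    bins$bin <- unlist(lapply(table(bins$chrom)[unique(bins$chrom)], seq_len)) - 1L
  } else {
    M <- as.matrix(read.table(path, sep = "\t"))
    dimnames(M) <- NULL
    bins <- NULL
  }
  structure(list(matrix = M, bins = bins, homolog_averaged = NA,
                 n_frames = NA_integer_, normalization = "imported"),
            class = "contact_map")
}
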