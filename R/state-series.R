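# The direct-determination step: convert a trajectory into per-molecule
# canonical-label and family time series, and summarize occupancies.

#' Label every molecule in every frame of a trajectory
#'
#' The central direct-analysis step: for each target molecule in each
#' recorded frame, measure the four conformation-defining torsions, bin them
#' into a raw four-letter label, and reduce to the symmetry-canonical label
#' and its family. Frames with degenerate (collinear) torsion geometry for a
#' molecule are marked missing (\code{NA}) rather than interpolated, so
#' lifetimes never bridge fabricated states.
#'
#' @param traj a \code{trajectory} (from [read_lammps_dump()], [read_xyz()]
#'   or [build_coordinates()]).
#' @param topology a [topology] mapping atom ids to molecular sites.
#' @return a \code{state_series}: list with \code{time} (ps),
#'   \code{stride_ps}, character matrices \code{raw}, \code{canonical},
#'   \code{family} (molecules x frames), \code{n_molecules}, \code{n_frames},
#'   and \code{n_conf} (number of non-missing molecule-frame configurations).
#' @export
label_trajectory <- function(traj, topology) {
  n_frames <- length(traj$frames)
  n_mol <- topology$n_molecules
  if (n_frames == 0L || n_mol == 0L) stop("empty trajectory or topology", call. = FALSE)
  quads <- matrix(NA_real_, nrow = n_mol * n_frames, ncol = 4L)
  row <- 0L
  for (f in traj$frames) {
    for (m in seq_len(n_mol)) {
      row <- row + 1L
      mol <- .site_coords(f, topology$molecules[[m]])
      quads[row, ] <- suppressWarnings(torsion_quad(mol, f$box))
    }
  }
  ok <- stats::complete.cases(quads)
  raw <- rep(NA_character_, nrow(quads))
  if (any(ok)) raw[ok] <- label_from_torsions(quads[ok, , drop = FALSE])
  canonical <- rep(NA_character_, length(raw))
  canonical[ok] <- canonicalize(raw[ok])
  family <- rep(NA_character_, length(raw))
  family[ok] <- family_of(canonical[ok])
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(n_skipped, " molecule-frame configuration(s) skipped (degenerate geometry)")
  }
  structure(list(
    time = vapply(traj$frames, `[[`, numeric(1L), "time"),
    stride_ps = traj$stride_ps,
    raw = matrix(raw, nrow = n_mol),
    canonical = matrix(canonical, nrow = n_mol),
    family = matrix(family, nrow = n_mol),
    n_molecules = n_mol, n_frames = n_frames,
    n_conf = sum(ok)
  ), class = "state_series")
}

#' Build a state series from a raw label log
#'
#' Constructs a \code{state_series} directly from per-molecule raw label
#' sequences (e.g. a generator's ground-truth log), computing canonical
#' labels and families. \code{NA} entries are treated as missing markers.
#'
#' @param raw character matrix of raw labels (molecules x frames), or a
#'   vector for a single molecule.
#' @param stride_ps recording stride in ps.
#' @param time optional explicit frame times.
#' @return a \code{state_series}.
#' @export
state_series_from_labels <- function(raw, stride_ps = 1, time = NULL) {
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  ok <- !is.na(raw)
  canonical <- raw
  canonical[ok] <- canonicalize(raw[ok])
  family <- raw
  family[ok] <- family_of(canonical[ok])
  structure(list(
    time = if (is.null(time)) (seq_len(ncol(raw)) - 1L) * stride_ps else time,
    stride_ps = stride_ps,
    raw = raw, canonical = canonical, family = family,
    n_molecules = nrow(raw), n_frames = ncol(raw), n_conf = sum(ok)
  ), class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("Conformation state series: %d molecule(s) x %d frame(s) at %g ps stride\n",
              x$n_molecules, x$n_frames, x$stride_ps))
  cat(sprintf("  N_conf = %d labeled configurations (%d missing)\n",
              x$n_conf, x$n_molecules * x$n_frames - x$n_conf))
  invisible(x)
}

#' Occupancy fractions of conformations and families
#'
#' The content phi of a conformation is the percentage of all labeled
#' molecule-frame configurations (N_conf) carrying its canonical label;
#' family fractions are the sums over member labels. All 25 unique labels
#' are reported, zeros included, in registry order. Missing (degenerate)
#' configurations are excluded from N_conf and reported separately.
#'
#' @param series a \code{state_series}.
#' @return an \code{occupancy_table}: list with data frames \code{labels}
#'   (index, label, family, count, phi) and \code{families}, plus
#'   \code{n_conf} and \code{missing_phi} (percent of raw molecule-frames
#'   that were unlabeled).
#' @export
occupancy <- function(series) {
  if (!inherits(series, "state_series") || series$n_conf == 0L) {
    stop("occupancy() needs a non-empty state_series", call. = FALSE)
  }
  reg <- enumerate_unique()
  lab <- series$canonical[!is.na(series$canonical)]
  counts <- table(factor(lab, levels = reg$label))
  labels <- data.frame(
    index = reg$index, label = reg$label, family = reg$family,
    count = as.integer(counts),
    phi = 100 * as.integer(counts) / series$n_conf,
    stringsAsFactors = FALSE
  )
  fam_counts <- tapply(labels$count, factor(labels$family, levels = .FAMILY_ORDER()), sum)
  families <- data.frame(
    family = .FAMILY_ORDER(),
    count = as.integer(fam_counts),
    phi = 100 * as.integer(fam_counts) / series$n_conf,
    stringsAsFactors = FALSE
  )
  total <- series$n_molecules * series$n_frames
  structure(list(labels = labels, families = families, n_conf = series$n_conf,
                 missing_phi = 100 * (total - series$n_conf) / total),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, digits = 2, ...) {
  cat(sprintf("Occupancy over %d configurations (missing %.2f%%)\n",
              x$n_conf, x$missing_phi))
  shown <- x$labels[x$labels$count > 0L, ]
  shown$phi <- round(shown$phi, digits)
  print.data.frame(shown, row.names = FALSE)
  cat("Families:\n")
  fam <- x$families
  fam$phi <- round(fam$phi, digits)
  print.data.frame(fam, row.names = FALSE)
  invisible(x)
}

#' Per-family averaged intramolecular O...O distance tracks
#'
#' For each frame and family, the mean intramolecular O1...O2 distance over
#' the molecules currently assigned to that family (NA when the family is
#' unoccupied at that time), plus the whole-system mean. These are the
#' R^av_intraOO tracks whose overlap between families motivates direct
#' labeling over distance-based conformation assignment.
#'
#' @param traj the \code{trajectory} that \code{series} was computed from.
#' @param topology the matching [topology].
#' @param series the \code{state_series} from [label_trajectory()].
#' @return data frame with columns \code{time_ps}, one column per family
#'   (\code{TT}, \code{TG}, \code{GG}, \code{GG.} with the prime mapped to
#'   a syntactic name), and \code{all}.
#' @export
family_distance_track <- function(traj, topology, series) {
  n_frames <- length(traj$frames)
  stopifnot(n_frames == series$n_frames,
            topology$n_molecules == series$n_molecules)
  fams <- .FAMILY_ORDER()
  out <- matrix(NA_real_, nrow = n_frames, ncol = length(fams) + 1L)
  for (k in seq_len(n_frames)) {
    f <- traj$frames[[k]]
    d <- vapply(topology$molecules, function(s) {
      intra_oo(.site_coords(f, s), f$box)
    }, numeric(1L))
    fam_k <- series$family[, k]
    for (j in seq_along(fams)) {
      sel <- !is.na(fam_k) & fam_k == fams[j]
      if (any(sel)) out[k, j] <- mean(d[sel])
    }
    out[k, length(fams) + 1L] <- mean(d)
  }
  df <- data.frame(time_ps = series$time, out)
  names(df) <- c("time_ps", fams, "all")
  df
}

#' Export a state series as tidy CSV
#'
#' One row per molecule per frame: \code{molecule}, \code{time_ps},
#' \code{raw}, \code{canonical}, \code{family}.
#'
#' @param series a \code{state_series}.
#' @param path output file path.
#' @param ascii write labels with the ASCII prime alias.
#' @return \code{path}, invisibly.
#' @export
write_state_series_csv <- function(series, path, ascii = FALSE) {
  df <- data.frame(
    molecule = rep(seq_len(series$n_molecules), times = series$n_frames),
    time_ps = rep(series$time, each = series$n_molecules),
    raw = as.vector(series$raw),
    canonical = as.vector(series$canonical),
    family = as.vector(series$family),
    stringsAsFactors = FALSE
  )
  if (ascii) {
    for (col in c("raw", "canonical", "family")) {
      df[[col]] <- gsub(.PRIME, "p", df[[col]], fixed = TRUE)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
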