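# Trajectory readers/writers (LAMMPS text dump, XYZ/extended-XYZ) and the
# site-topology map. Frames are parsed one at a time from a connection, so
# memory use is per-frame, not per-trajectory.

.new_frame <- function(time, box, ids, coords, box_lo = c(0, 0, 0), elements = NULL) {
  ord <- order(ids)
  list(time = time, box = box, box_lo = box_lo,
       ids = ids[ord], coords = coords[ord, , drop = FALSE],
       elements = if (is.null(elements)) NULL else elements[ord])
}

.new_trajectory <- function(frames, format, stride_ps = NA_real_, source = NA_character_) {
  times <- vapply(frames, `[[`, numeric(1L), "time")
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
    if (is.na(stride_ps)) stride_ps <- dt[1L]
    if (any(abs(dt - stride_ps) > 1e-9)) {
      stop("recording stride is not constant across frames", call. = FALSE)
    }
  }
  structure(list(frames = frames, format = format, stride_ps = stride_ps,
                 source = source),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("MD trajectory: %d frame(s), format '%s', stride %s ps\n",
              n, x$format, format(x$stride_ps)))
  if (n > 0L) {
    f <- x$frames[[1L]]
    cat(sprintf("  %d atoms, box %s Angstrom\n", length(f$ids),
                paste(format(f$box), collapse = " x ")))
  }
  invisible(x)
}

#' Read a LAMMPS text dump
#'
#' Parses the ITEM:-delimited LAMMPS \code{atom} dump dialect. Required
#' columns are \code{id} plus either unwrapped Cartesian coordinates
#' (\code{x y z}, also accepted as \code{xu yu zu}) or box-scaled fractions
#' (\code{xs ys zs}), which are converted to Angstrom via the box bounds.
#' Atoms are re-sorted by id. Only orthorhombic boxes are supported;
#' triclinic tilt factors are rejected.
#'
#' @param path dump file path.
#' @param topology optional [topology]; when given, every frame is checked to
#'   contain all mapped atom ids.
#' @param timestep_ps MD timestep in ps; frame time = TIMESTEP x
#'   \code{timestep_ps}. The default 1 treats the dump's TIMESTEP counter as
#'   picoseconds directly (the convention used by this package's writer).
#' @return a \code{trajectory} object (list of frames, constant stride).
#' @export
read_lammps_dump <- function(path, topology = NULL, timestep_ps = 1) {
  con <- file(path, "r")
  on.exit(close(con))
  frames <- list()
  line_no <- 0L
  repeat {
    header <- readLines(con, n = 1L)
    if (length(header) == 0L) break
    line_no <- line_no + 1L
    if (!grepl("^ITEM: TIMESTEP", header)) {
      stop(sprintf("%s:%d: expected 'ITEM: TIMESTEP', got '%s'",
                   path, line_no, header), call. = FALSE)
    }
    step <- as.numeric(readLines(con, n = 1L))
    natoms_hdr <- readLines(con, n = 1L)
    if (!grepl("^ITEM: NUMBER OF ATOMS", natoms_hdr)) {
      stop(sprintf("%s: malformed frame header near line %d", path, line_no),
           call. = FALSE)
    }
    natoms <- as.integer(readLines(con, n = 1L))
    bounds_hdr <- readLines(con, n = 1L)
    if (grepl("xy xz yz", bounds_hdr)) {
      stop(path, ": triclinic box bounds (xy xz yz tilt factors) are not supported",
           call. = FALSE)
    }
    bounds <- do.call(rbind, lapply(readLines(con, n = 3L), function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }))
    box_lo <- bounds[, 1L]
    box <- bounds[, 2L] - bounds[, 1L]
    if (any(!is.finite(box)) || any(box <= 0)) {
      stop(path, ": invalid box bounds", call. = FALSE)
    }
    atoms_hdr <- readLines(con, n = 1L)
    if (!grepl("^ITEM: ATOMS", atoms_hdr)) {
      stop(path, ": expected 'ITEM: ATOMS' header", call. = FALSE)
    }
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", atoms_hdr), "\\s+")[[1L]]
    body <- readLines(con, n = natoms)
    if (length(body) < natoms) stop(path, ": truncated frame body", call. = FALSE)
    vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"),
                                     use.names = FALSE)),
                   nrow = natoms, byrow = TRUE)
    if (ncol(vals) != length(cols)) {
      stop(path, ": atom line column count does not match ITEM: ATOMS header",
           call. = FALSE)
    }
    colnames(vals) <- cols
    if (!"id" %in% cols) stop(path, ": dump lacks an 'id' column", call. = FALSE)
    ids <- as.integer(vals[, "id"])
    if (anyDuplicated(ids)) stop(path, ": duplicate atom ids in frame", call. = FALSE)
    if (all(c("x", "y", "z") %in% cols)) {
      coords <- vals[, c("x", "y", "z"), drop = FALSE]
    } else if (all(c("xu", "yu", "zu") %in% cols)) {
      coords <- vals[, c("xu", "yu", "zu"), drop = FALSE]
    } else if (all(c("xs", "ys", "zs") %in% cols)) {
      coords <- sweep(sweep(vals[, c("xs", "ys", "zs"), drop = FALSE], 2L, box, "*"),
                      2L, box_lo, "+")
    } else {
      stop(path, ": dump lacks coordinate columns (x y z, xu yu zu, or xs ys zs)",
           call. = FALSE)
    }
    dimnames(coords) <- NULL
    frames[[length(frames) + 1L]] <-
      .new_frame(step * timestep_ps, box, ids, coords, box_lo)
  }
  traj <- .new_trajectory(frames, "lammps_dump", source = path)
  if (!is.null(topology)) .check_topology_coverage(traj, topology)
  traj
}

#' Write a trajectory as a LAMMPS text dump
#'
#' @param traj a \code{trajectory}.
#' @param path output file path.
#' @param timestep_ps ps per TIMESTEP count (TIMESTEP written as
#'   time / \code{timestep_ps}).
#' @param digits coordinate output precision.
#' @return \code{path}, invisibly.
#' @export
write_lammps_dump <- function(traj, path, timestep_ps = 1, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%d %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in traj$frames) {
    writeLines(c("ITEM: TIMESTEP",
                 format(round(f$time / timestep_ps), scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS",
                 as.character(length(f$ids)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.8f %.8f", f$box_lo, f$box_lo + f$box),
                 "ITEM: ATOMS id x y z",
                 sprintf(fmt, f$ids, f$coords[, 1L], f$coords[, 2L], f$coords[, 3L])),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ or extended-XYZ trajectory
#'
#' Plain XYZ needs the box passed via \code{box}; extended-XYZ frames may
#' instead carry a \code{Lattice="..."} comment, which must be diagonal
#' (orthorhombic). Frame times are assigned from \code{time_ps} in the
#' comment line when present, else as frame index x \code{stride_ps}.
#'
#' @param path XYZ file path.
#' @param box orthorhombic box edge lengths in Angstrom, or \code{NULL} if
#'   every frame has a Lattice comment.
#' @param topology optional [topology] for coverage validation.
#' @param stride_ps recording stride used when frames carry no time stamp.
#' @return a \code{trajectory} object.
#' @export
read_xyz <- function(path, box = NULL, topology = NULL, stride_ps = 1) {
  con <- file(path, "r")
  on.exit(close(con))
  frames <- list()
  repeat {
    hdr <- readLines(con, n = 1L)
    if (length(hdr) == 0L || !nzchar(trimws(hdr))) break
    natoms <- suppressWarnings(as.integer(trimws(hdr)))
    if (is.na(natoms)) stop(path, ": malformed atom-count line '", hdr, "'",
                            call. = FALSE)
    comment <- readLines(con, n = 1L)
    frame_box <- box
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1L]]
    if (length(m) == 2L) {
      lat <- as.numeric(strsplit(trimws(m[2L]), "\\s+")[[1L]])
      if (length(lat) != 9L) stop(path, ": Lattice must have 9 components",
                                  call. = FALSE)
      off <- lat[c(2, 3, 4, 6, 7, 8)]
      if (any(abs(off) > 1e-8)) {
        stop(path, ": non-orthorhombic Lattice is not supported", call. = FALSE)
      }
      frame_box <- lat[c(1, 5, 9)]
    }
    if (is.null(frame_box)) {
      stop(path, ": no box given (pass box= or use an extended-XYZ Lattice comment)",
           call. = FALSE)
    }
    tm <- regmatches(comment, regexec("time_ps=([-0-9.eE+]+)", comment))[[1L]]
    time <- if (length(tm) == 2L) as.numeric(tm[2L]) else length(frames) * stride_ps
    body <- readLines(con, n = natoms)
    if (length(body) < natoms) {
      stop(path, ": atom count in header exceeds remaining lines", call. = FALSE)
    }
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4L)) stop(path, ": malformed atom line", call. = FALSE)
    elements <- vapply(toks, `[[`, character(1L), 1L)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L)))
    frames[[length(frames) + 1L]] <-
      .new_frame(time, frame_box, seq_len(natoms), coords, elements = elements)
  }
  traj <- .new_trajectory(frames, "xyz", source = path)
  if (!is.null(topology)) .check_topology_coverage(traj, topology)
  traj
}

#' Write a trajectory as extended XYZ
#'
#' Emits a \code{Lattice} and \code{time_ps} comment per frame so the file
#' round-trips through [read_xyz()] without external metadata.
#'
#' @inheritParams write_lammps_dump
#' @export
write_xyz <- function(traj, path, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in traj$frames) {
    el <- if (is.null(f$elements)) rep("X", length(f$ids)) else f$elements
    writeLines(c(as.character(length(f$ids)),
                 sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 time_ps=%g',
                         f$box[1L], f$box[2L], f$box[3L], f$time),
                 sprintf(fmt, el, f$coords[, 1L], f$coords[, 2L], f$coords[, 3L])),
               con)
  }
  invisible(path)
}

.check_topology_coverage <- function(traj, topology) {
  ids <- unlist(topology$molecules, use.names = FALSE)
  for (k in seq_along(traj$frames)) {
    missing <- setdiff(ids, traj$frames[[k]]$ids)
    if (length(missing) > 0L) {
      stop(sprintf("frame %d lacks topology atom id(s): %s",
                   k, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a site topology for target 1,3-diol molecules
#'
#' A topology maps atom ids to the seven named sites H1, O1, C1, C2, C3, O2,
#' H2 of each target molecule, either explicitly (a list of named id
#' vectors) or via a repeating-offset template: the first molecule's site
#' ids plus a per-molecule atom stride and a molecule count.
#'
#' @param sites named vector/list of the first molecule's site ids (names
#'   H1, O1, C1, C2, C3, O2, H2), or a list of such vectors (one per
#'   molecule, used as-is).
#' @param stride_atoms atoms per molecule in the id numbering (template mode).
#' @param n_molecules number of target molecules (template mode).
#' @return a \code{topology} object.
#' @examples
#' top <- make_topology(c(H1 = 1, O1 = 2, C1 = 3, C2 = 4, C3 = 5, O2 = 6, H2 = 7),
#'                      stride_atoms = 11, n_molecules = 8)
#' @export
make_topology <- function(sites, stride_atoms = NULL, n_molecules = NULL) {
  if (is.list(sites) && is.null(names(sites))) {
    molecules <- lapply(sites, .validate_sites)
  } else {
    first <- .validate_sites(sites)
    if (is.null(stride_atoms) || is.null(n_molecules)) {
      molecules <- list(first)
    } else {
      molecules <- lapply(seq_len(n_molecules) - 1L, function(k) {
        first + as.integer(k * stride_atoms)
      })
    }
  }
  all_ids <- unlist(molecules, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("topology molecules share atom id(s): ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(molecules = molecules, n_molecules = length(molecules)),
            class = "topology")
}

.validate_sites <- function(sites) {
  s <- unlist(sites)
  if (!setequal(names(s), .SITE_NAMES) || length(s) != 7L) {
    stop("each molecule needs exactly the seven sites ",
         paste(.SITE_NAMES, collapse = ", "), call. = FALSE)
  }
  ids <- as.integer(s[.SITE_NAMES])
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("site ids must be distinct integers", call. = FALSE)
  }
  stats::setNames(ids, .SITE_NAMES)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Site topology: %d target molecule(s), 7 sites each\n",
              x$n_molecules))
  invisible(x)
}

#' Read a topology/run configuration document
#'
#' Reads a YAML document describing the analysis run. Recognized keys:
#' \code{sites} (map of the first molecule's seven site ids),
#' \code{stride_atoms}, \code{n_molecules} (repeating-offset template) or
#' \code{molecules} (explicit list of site maps); optional run keys
#' \code{format}, \code{timestep_ps}, \code{stride_ps}, \code{box}.
#'
#' @param path YAML file path.
#' @return a \code{topology} object; run-level keys are attached as the
#'   \code{"config"} attribute.
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  top <- if (!is.null(cfg$molecules)) {
    make_topology(lapply(cfg$molecules, unlist))
  } else if (!is.null(cfg$sites)) {
    make_topology(unlist(cfg$sites), stride_atoms = cfg$stride_atoms,
                  n_molecules = cfg$n_molecules)
  } else {
    stop(path, ": config must define 'molecules' or 'sites'", call. = FALSE)
  }
  attr(top, "config") <- cfg[setdiff(names(cfg),
                                     c("molecules", "sites", "stride_atoms",
                                       "n_molecules"))]
  top
}
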