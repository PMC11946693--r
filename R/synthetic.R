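# Ground-truth synthetic trajectories: per-slot (or joint) Markov torsion
# dynamics, truncated-Gaussian jitter about bin centers, and an
# internal-to-Cartesian chain builder, so every analysis stage can be
# exercised against known labels without running MD.

.BIN_CENTERS <- c(180, 60, 300)  # degrees, indexed by letter code T, G, G'

#' Markov torsion-chain model
#'
#' Defines the synthetic dynamics of the four torsion slots. By default the
#' slots evolve as independent three-state Markov chains (states T, G, G' in
#' that order) sharing one per-step 3 x 3 transition matrix; a list of four
#' matrices gives per-slot dynamics, and an 81 x 81 matrix over raw labels
#' gives fully correlated dynamics. Generated torsions sit at the bin center
#' of the current state plus truncated-Gaussian jitter; truncation (not
#' wrapping) guarantees the angle never crosses a bin boundary, so analyzer
#' labels match generator labels exactly.
#'
#' @param transition 3 x 3 matrix (shared by all four slots), list of four
#'   3 x 3 matrices, or 81 x 81 joint matrix over raw labels. Rows must be
#'   non-negative and sum to 1.
#' @param stride_ps recording stride in ps.
#' @param jitter_sd jitter standard deviation in degrees.
#' @param jitter_max truncation bound in degrees; must stay below 55 so
#'   angles keep a 5-degree margin from the 60-degree-half-width bin edges.
#' @return a \code{torsion_chain_model}.
#' @export
torsion_chain_model <- function(transition = diag(3), stride_ps = 1,
                                jitter_sd = 10, jitter_max = 30) {
  mats <- if (is.list(transition)) transition else list(transition)
  for (P in mats) {
    if (!is.matrix(P) || nrow(P) != ncol(P) || !nrow(P) %in% c(3L, 81L)) {
      stop("transition matrices must be 3 x 3 (per slot) or 81 x 81 (joint)",
           call. = FALSE)
    }
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
      stop("transition matrix rows must be non-negative and sum to 1", call. = FALSE)
    }
  }
  joint <- !is.list(transition) && nrow(transition) == 81L
  if (is.list(transition) && length(transition) != 4L) {
    stop("per-slot transition must be a single matrix or a list of four", call. = FALSE)
  }
  if (jitter_max >= 55) {
    stop("jitter_max must be below 55 degrees to keep angles clear of bin edges",
         call. = FALSE)
  }
  if (jitter_max <= 0 || jitter_sd < 0) stop("invalid jitter parameters", call. = FALSE)
  structure(list(transition = transition, joint = joint, stride_ps = stride_ps,
                 jitter_sd = jitter_sd, jitter_max = jitter_max),
            class = "torsion_chain_model")
}

#' Symmetric stay/switch transition matrix
#'
#' Convenience constructor: stay in the current state with probability
#' \code{stay}, otherwise switch to one of the other states uniformly. Its
#' stationary distribution is uniform and the dwell time per state is
#' geometric with mean \code{1 / (1 - stay)} steps.
#'
#' @param stay per-step stay probability in \code{[0, 1]}.
#' @param n_states number of states (3 for one torsion slot).
#' @return an \code{n_states} x \code{n_states} transition matrix.
#' @export
stay_transition <- function(stay, n_states = 3L) {
  stopifnot(stay >= 0, stay <= 1, n_states >= 2L)
  P <- matrix((1 - stay) / (n_states - 1L), n_states, n_states)
  diag(P) <- stay
  P
}

# one vectorized Markov step: states (int vector), cum = row-cumsum of P
.markov_step <- function(states, cum) {
  u <- stats::runif(length(states))
  rows <- cum[states, , drop = FALSE]
  1L + rowSums(u > rows[, -ncol(rows), drop = FALSE])
}

# truncated-Gaussian jitter, exact inverse-CDF truncation (never wraps)
.jitter <- function(n, sd, bound) {
  if (sd == 0) return(numeric(n))
  p <- stats::pnorm(c(-bound, bound) / sd)
  stats::qnorm(p[1L] + stats::runif(n) * (p[2L] - p[1L])) * sd
}

# raw-label joint-state index <-> code quadruple (slot 1 most significant)
.joint_to_codes <- function(idx) {
  i <- idx - 1L
  cbind(i %/% 27L, (i %/% 9L) %% 3L, (i %/% 3L) %% 3L, i %% 3L) + 1L
}

#' Simulate ground-truth label and torsion series
#'
#' Runs independent per-molecule Markov chains under \code{model}, starting
#' from uniformly sampled states, and attaches jittered torsion angles.
#'
#' @param model a [torsion_chain_model()].
#' @param n_molecules number of molecules.
#' @param n_frames number of recorded frames.
#' @param seed optional integer seed (\code{set.seed} is called when given).
#' @return a \code{synthetic_series}: list with \code{raw} (ground-truth raw
#'   label matrix, molecules x frames), \code{states} (n_molecules x
#'   n_frames x 4 letter codes), \code{quads} (same shape, degrees),
#'   \code{time}, \code{stride_ps}, \code{model}.
#' @export
simulate_labels <- function(model, n_molecules, n_frames, seed = NULL) {
  stopifnot(inherits(model, "torsion_chain_model"),
            n_molecules >= 1L, n_frames >= 1L)
  if (!is.null(seed)) set.seed(seed)
  states <- array(NA_integer_, dim = c(n_molecules, n_frames, 4L))
  if (model$joint) {
    cum <- t(apply(model$transition, 1L, cumsum))
    s <- sample.int(81L, n_molecules, replace = TRUE)
    states[, 1L, ] <- .joint_to_codes(s)
    if (n_frames > 1L) for (f in 2:n_frames) {
      s <- .markov_step(s, cum)
      states[, f, ] <- .joint_to_codes(s)
    }
  } else {
    mats <- if (is.list(model$transition)) model$transition else
      rep(list(model$transition), 4L)
    for (slot in 1:4) {
      cum <- t(apply(mats[[slot]], 1L, cumsum))
      s <- sample.int(3L, n_molecules, replace = TRUE)
      states[, 1L, slot] <- s
      if (n_frames > 1L) for (f in 2:n_frames) {
        s <- .markov_step(s, cum)
        states[, f, slot] <- s
      }
    }
  }
  quads <- .BIN_CENTERS[states] +
    .jitter(length(states), model$jitter_sd, model$jitter_max)
  dim(quads) <- dim(states)
  lo <- .LETTER_LO; up <- .LETTER_UP
  raw <- matrix(paste0(lo[states[, , 1L]], up[states[, , 2L]],
                       up[states[, , 3L]], lo[states[, , 4L]]),
                nrow = n_molecules)
  structure(list(raw = raw, states = states, quads = quads,
                 time = (seq_len(n_frames) - 1L) * model$stride_ps,
                 stride_ps = model$stride_ps, model = model),
            class = "synthetic_series")
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat(sprintf("Synthetic torsion series: %d molecule(s) x %d frame(s) at %g ps\n",
              nrow(x$raw), ncol(x$raw), x$stride_ps))
  invisible(x)
}

#' Geometry template for the seven-site diol chain
#'
#' Bond lengths and bond angles for sequential construction of the chain
#' H1-O1-C1-C2-C3-O2-H2. Defaults are standard organic-geometry values; the
#' conformational signal is carried entirely by the torsions.
#'
#' @param bonds six bond lengths in Angstrom, in chain order (H1-O1, O1-C1,
#'   C1-C2, C2-C3, C3-O2, O2-H2).
#' @param angles five bond angles in degrees, at sites O1, C1, C2, C3, O2.
#' @return a \code{geometry_template}.
#' @export
geometry_template <- function(bonds = c(0.96, 1.43, 1.53, 1.53, 1.43, 0.96),
                              angles = c(108.5, 110.0, 112.0, 110.0, 108.5)) {
  stopifnot(length(bonds) == 6L, all(bonds > 0),
            length(angles) == 5L, all(angles > 0), all(angles < 180))
  structure(list(bonds = bonds, angles = angles), class = "geometry_template")
}

# sequential internal-to-Cartesian chain extension (NeRF): each next site is
# positioned from the previous three using its bond length, bond angle and
# the prescribed torsion
.build_chain <- function(quad, template) {
  b <- template$bonds
  a <- template$angles * pi / 180
  s <- matrix(0, nrow = 7L, ncol = 3L)
  s[2L, ] <- c(b[1L], 0, 0)
  s[3L, ] <- s[2L, ] + b[2L] * c(-cos(a[1L]), sin(a[1L]), 0)
  for (k in 4:7) {
    A <- s[k - 3L, ]; B <- s[k - 2L, ]; C <- s[k - 1L, ]
    r <- b[k - 1L]; theta <- a[k - 2L]; phi <- quad[k - 3L] * pi / 180
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A; ab <- ab / sqrt(sum(ab^2))
    n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
    m <- .cross3(n, bc)
    local <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
    s[k, ] <- C + local[1L] * bc + local[2L] * m + local[3L] * n
  }
  rownames(s) <- .SITE_NAMES
  s
}

# uniform random rotation matrix (random unit quaternion)
.random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

# sample molecule centers with a minimum mutual (minimum-image) separation
.place_centers <- function(n, box, min_sep, max_tries = 200L * n) {
  centers <- matrix(NA_real_, nrow = n, ncol = 3L)
  placed <- 0L
  for (tr in seq_len(max_tries)) {
    cand <- stats::runif(3L) * box
    ok <- TRUE
    if (placed > 0L) {
      d <- sweep(centers[seq_len(placed), , drop = FALSE], 2L, cand, "-")
      for (k in 1:3) d[, k] <- .min_image(d[, k], box[k])
      ok <- all(rowSums(d^2) >= min_sep^2)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop(sprintf("failed to place %d molecules at %.1f Angstrom separation in the box",
               n, min_sep), call. = FALSE)
}

#' Build Cartesian trajectory frames from torsion series
#'
#' Constructs every molecule by sequential internal-to-Cartesian chain
#' extension from its prescribed torsion quadruple, then rigidly rotates and
#' translates it to a random non-overlapping pose in the periodic box.
#' Measured torsions round-trip to the prescribed values within 1e-6
#' degrees, so analyzer labels equal generator labels exactly.
#'
#' @param sim a \code{synthetic_series} from [simulate_labels()].
#' @param box orthorhombic box edge lengths in Angstrom (length 1 or 3).
#' @param template a [geometry_template()].
#' @param pose \code{"resample"} draws an independent pose per frame (frames
#'   are uncorrelated in space, convenient for RDF averaging);
#'   \code{"static"} fixes each molecule's pose over the whole trajectory.
#' @param min_sep minimum center-center separation when placing molecules.
#' @param stride_atoms atom-id stride per molecule (first molecule occupies
#'   ids 1..7, the next starts at \code{stride_atoms + 1}, ...).
#' @param seed optional integer seed.
#' @return list with \code{trajectory} (writable via [write_lammps_dump()] /
#'   [write_xyz()]) and the matching \code{topology}.
#' @export
build_coordinates <- function(sim, box = c(29, 29, 29),
                              template = geometry_template(),
                              pose = c("resample", "static"),
                              min_sep = 5, stride_atoms = 7L, seed = NULL) {
  pose <- match.arg(pose)
  stopifnot(inherits(sim, "synthetic_series"), inherits(template, "geometry_template"))
  if (!is.null(seed)) set.seed(seed)
  if (length(box) == 1L) box <- rep(box, 3L)
  n_mol <- nrow(sim$raw)
  n_frames <- ncol(sim$raw)
  if (min_sep * 2 > min(box)) stop("box too small for requested separation", call. = FALSE)
  topology <- make_topology(
    stats::setNames(1:7, .SITE_NAMES), stride_atoms = stride_atoms,
    n_molecules = n_mol)
  elements <- rep(c("H", "O", "C", "C", "C", "O", "H"), n_mol)
  ids <- unlist(topology$molecules, use.names = FALSE)
  if (pose == "static") {
    centers0 <- .place_centers(n_mol, box, min_sep)
    rots0 <- replicate(n_mol, .random_rotation(), simplify = FALSE)
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (pose == "resample") {
      centers <- .place_centers(n_mol, box, min_sep)
      rots <- replicate(n_mol, .random_rotation(), simplify = FALSE)
    } else {
      centers <- centers0
      rots <- rots0
    }
    coords <- matrix(NA_real_, nrow = 7L * n_mol, ncol = 3L)
    for (m in seq_len(n_mol)) {
      chain <- .build_chain(sim$quads[m, f, ], template)
      chain <- sweep(chain, 2L, colMeans(chain))
      posed <- chain %*% t(rots[[m]])
      coords[(m - 1L) * 7L + 1:7, ] <- sweep(posed, 2L, centers[m, ], "+")
    }
    frames[[f]] <- .new_frame(sim$time[f], box, ids, coords, elements = elements)
  }
  list(trajectory = .new_trajectory(frames, "synthetic", stride_ps = sim$stride_ps),
       topology = topology)
}

#' Simulate a complete synthetic trajectory with ground truth
#'
#' Convenience wrapper: [simulate_labels()] followed by
#' [build_coordinates()], under a single seed.
#'
#' @inheritParams simulate_labels
#' @inheritParams build_coordinates
#' @return list with \code{trajectory}, \code{topology} and \code{truth}
#'   (the \code{synthetic_series}).
#' @export
simulate_trajectory <- function(model, n_molecules, n_frames,
                                box = c(29, 29, 29),
                                template = geometry_template(),
                                pose = "resample", min_sep = 5,
                                stride_atoms = 7L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_labels(model, n_molecules, n_frames)
  built <- build_coordinates(sim, box = box, template = template, pose = pose,
                             min_sep = min_sep, stride_atoms = stride_atoms)
  c(built, list(truth = sim))
}

#' Reposition molecule pairs to form intermolecular O...O contacts
#'
#' Rigidly translates the second molecule of each chosen pair so that its O1
#' oxygen sits at exactly the target minimum-image distance from the first
#' molecule's O2 oxygen, in every frame. Internal torsions (and hence
#' conformation labels) are untouched: only the indirect RDF picture
#' changes. This is the constructed demonstration that short intermolecular
#' hydrogen-bond contacts inflate the first g_OO(r) peak without any change
#' in the direct conformational composition.
#'
#' @param traj a \code{trajectory}.
#' @param topology the matching [topology].
#' @param n_pairs number of molecule pairs to reposition (pairs (1,2),
#'   (3,4), ...; requires \code{2 * n_pairs <= n_molecules}).
#' @param distance target O...O distance in Angstrom (a hydrogen-bond
#'   contact by default).
#' @return the modified \code{trajectory}.
#' @export
inject_intermolecular_contacts <- function(traj, topology, n_pairs,
                                           distance = 2.8) {
  if (2L * n_pairs > topology$n_molecules) {
    stop("n_pairs exceeds the available molecules", call. = FALSE)
  }
  if (n_pairs == 0L) return(traj)
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    for (k in seq_len(n_pairs)) {
      a <- topology$molecules[[2L * k - 1L]]
      b <- topology$molecules[[2L * k]]
      o_a <- fr$coords[match(a[["O2"]], fr$ids), ]
      o_b <- fr$coords[match(b[["O1"]], fr$ids), ]
      # approach along the existing minimum-image separation, so the rest of
      # molecule b stays on its far side (no constructed atom overlap)
      v <- .min_image(o_b - o_a, fr$box)
      shift <- (distance / sqrt(sum(v^2)) - 1) * v
      b_idx <- match(b, fr$ids)
      fr$coords[b_idx, ] <- sweep(fr$coords[b_idx, , drop = FALSE], 2L, shift, "+")
    }
    traj$frames[[f]] <- fr
  }
  traj
}

#' Write the generator's ground-truth labels as CSV
#'
#' One row per molecule per frame: \code{molecule}, \code{time_ps},
#' \code{raw}, \code{canonical}, \code{family}.
#'
#' @param sim a \code{synthetic_series}.
#' @param path output file path.
#' @param ascii write labels with the ASCII prime alias.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth_csv <- function(sim, path, ascii = FALSE) {
  series <- state_series_from_labels(sim$raw, stride_ps = sim$stride_ps,
                                     time = sim$time)
  write_state_series_csv(series, path, ascii = ascii)
}
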