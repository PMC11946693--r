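# Independent oracles and small fixture builders shared across tests.

PRIME <- "′"

# Table-style frozen registry: the 25 unique conformation names in index
# order (hydroxyl letters lowercase, prime = U+2032).
REGISTRY_NAMES <- c(
  "tTTt", "tTTg", "gTTg", paste0("gTTg", PRIME),
  "tTGt", "tTGg", paste0("tTGg", PRIME), "gTGt", "gTGg",
  paste0("gTGg", PRIME), paste0("g", PRIME, "TGt"), paste0("g", PRIME, "TGg"),
  paste0("g", PRIME, "TGg", PRIME),
  "tGGt", "tGGg", paste0("tGGg", PRIME), "gGGg", paste0("gGGg", PRIME),
  paste0("g", PRIME, "GGg", PRIME),
  paste0("tGG", PRIME, "t"), paste0("tGG", PRIME, "g"),
  paste0("tGG", PRIME, "g", PRIME), paste0("gGG", PRIME, "g"),
  paste0("gGG", PRIME, "g", PRIME), paste0("g", PRIME, "GG", PRIME, "g")
)

# all 81 raw labels (codes 1=T, 2=G, 3=G' at each of the four positions)
all_raw_labels <- function() {
  up <- c("T", "G", paste0("G", PRIME))
  lo <- c("t", "g", paste0("g", PRIME))
  grid <- expand.grid(p1 = 1:3, p2 = 1:3, p3 = 1:3, p4 = 1:3)
  paste0(lo[grid$p1], up[grid$p2], up[grid$p3], lo[grid$p4])
}

# second, independent dihedral implementation: acos of normal-vector cosine
# with the sign taken from the triple product (textbook formula)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(pmax(cosphi, -1), 1)) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) phi <- -phi
  phi %% 360
}

# naive all-pairs minimum-image O-O histogram (double loop), the brute-force
# reference for compute_rdf's binned counts
brute_oo_counts <- function(traj, topology, breaks,
                            selection = c("all", "intra", "inter")) {
  selection <- match.arg(selection)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  for (f in traj$frames) {
    oo <- list()
    for (m in seq_along(topology$molecules)) {
      s <- topology$molecules[[m]]
      oo[[length(oo) + 1L]] <- list(mol = m, x = f$coords[match(s[["O1"]], f$ids), ])
      oo[[length(oo) + 1L]] <- list(mol = m, x = f$coords[match(s[["O2"]], f$ids), ])
    }
    for (i in seq_along(oo)) for (j in seq_along(oo)) {
      if (j <= i) next
      same <- oo[[i]]$mol == oo[[j]]$mol
      if (selection == "intra" && !same) next
      if (selection == "inter" && same) next
      d <- oo[[j]]$x - oo[[i]]$x
      d <- d - f$box * round(d / f$box)
      r <- sqrt(sum(d^2))
      k <- findInterval(r, breaks)
      if (k >= 1L && k <= nb) counts[k] <- counts[k] + 1
    }
  }
  counts
}

# frames with all atoms at independent uniform positions (ideal gas)
ideal_gas_trajectory <- function(n_molecules, n_frames, box) {
  topology <- make_topology(
    setNames(1:7, c("H1", "O1", "C1", "C2", "C3", "O2", "H2")),
    stride_atoms = 7, n_molecules = n_molecules)
  n_atoms <- 7L * n_molecules
  frames <- lapply(seq_len(n_frames), function(k) {
    list(time = k - 1, box = box, box_lo = c(0, 0, 0),
         ids = seq_len(n_atoms),
         coords = matrix(runif(3L * n_atoms) * rep(box, each = n_atoms),
                         ncol = 3L),
         elements = NULL)
  })
  traj <- structure(list(frames = frames, format = "synthetic", stride_ps = 1,
                         source = NA_character_), class = "trajectory")
  list(trajectory = traj, topology = topology)
}

# uniform random rotation for property tests
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

default_sites <- function() setNames(1:7, c("H1", "O1", "C1", "C2", "C3", "O2", "H2"))
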