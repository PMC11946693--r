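# Torsion-letter label algebra for 1,3-diol conformations.
#
# A conformation label is a four-letter word over {T, G, G'} in gauche/trans
# nomenclature: positions 1 and 4 are the hydroxyl torsions (rendered
# lowercase t/g/g'), positions 2 and 3 the carbon main chain (uppercase).
# Letters are coded internally as integers 1 = T/t, 2 = G/g, 3 = G'/g',
# which is also the lexicographic order used for canonical representatives.

.PRIME <- "′"
.LETTER_UP <- c("T", "G", paste0("G", .PRIME))
.LETTER_LO <- c("t", "g", paste0("g", .PRIME))

#' @keywords internal
.normalize_prime <- function(x) {
  # accept U+2032, ASCII apostrophe, or the shell-safe "p" alias (gp/Gp)
  x <- gsub("'", .PRIME, x, fixed = TRUE)
  x <- gsub("(?<=[gG])p", .PRIME, x, perl = TRUE)
  x
}

# parse one label string into an integer code vector
.parse_label <- function(label) {
  s <- .normalize_prime(as.character(label))
  chars <- strsplit(s, "")[[1]]
  codes <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    base <- toupper(chars[i])
    if (!base %in% c("T", "G")) {
      stop("invalid letter '", chars[i], "' in label '", label, "'", call. = FALSE)
    }
    primed <- (i < length(chars)) && chars[i + 1L] == .PRIME
    codes <- c(codes, if (base == "T") 1L else if (primed) 3L else 2L)
    i <- i + 1L + primed
  }
  codes
}

# render an integer code vector as a label string
.render_label <- function(codes, chain_positions = c(2L, 3L), ascii = FALSE) {
  up <- if (ascii) c("T", "G", "Gp") else .LETTER_UP
  lo <- if (ascii) c("t", "g", "gp") else .LETTER_LO
  out <- lo[codes]
  out[chain_positions] <- up[codes[chain_positions]]
  paste(out, collapse = "")
}

.label_codes_matrix <- function(labels) {
  t(vapply(labels, .parse_label, integer(4L)))
}

#' Bin a torsion angle into its gauche/trans letter
#'
#' The torsion range 0--360 degrees is divided into three equal segments:
#' \code{[0, 120)} is gauche (G/g), \code{[120, 240)} is trans (T/t) and
#' \code{[240, 360)} is gauche-prime (G'/g'). Angles are normalized into
#' \code{[0, 360)} first, so negative IUPAC-signed values are accepted
#' (e.g. -82.5 becomes 277.5 and bins to g'). Boundary values fall in the
#' upper interval (half-open bins).
#'
#' @param angle numeric vector of torsion angles in degrees.
#' @param position \code{"chain"} for main-chain torsions (uppercase letters)
#'   or \code{"hydroxyl"} for torsions involving a hydroxyl hydrogen
#'   (lowercase letters).
#' @param ascii render the prime as \code{"p"} instead of U+2032.
#' @return character vector of torsion letters.
#' @examples
#' bin_angle(67.6, "hydroxyl")   # "g"
#' bin_angle(180, "chain")       # "T"
#' bin_angle(-82.5, "hydroxyl")  # "g′"
#' @export
bin_angle <- function(angle, position = c("chain", "hydroxyl"), ascii = FALSE) {
  position <- match.arg(position)
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("torsion angles must be finite numbers", call. = FALSE)
  }
  codes <- .bin_codes(angle)
  letters <- if (position == "chain") {
    if (ascii) c("T", "G", "Gp") else .LETTER_UP
  } else {
    if (ascii) c("t", "g", "gp") else .LETTER_LO
  }
  letters[codes]
}

# angle (any finite, degrees) -> integer code
.bin_codes <- function(angle) {
  a <- angle %% 360
  seg <- pmin(floor(a / 120), 2)  # 0: [0,120) 1: [120,240) 2: [240,360)
  c(2L, 1L, 3L)[seg + 1L]
}

#' Label a molecule from its four torsion angles
#'
#' Bins the torsion quadruple (H1-O1-C1-C2, O1-C1-C2-C3, C1-C2-C3-O2,
#' C2-C3-O2-H2) into a raw four-letter conformation label. The result is not
#' yet reduced by molecular symmetry; see [canonicalize()].
#'
#' @param quad numeric vector of the four torsions in degrees, or a matrix
#'   with four columns (one row per molecule/frame).
#' @param ascii render primes as \code{"p"}.
#' @return character vector of raw labels.
#' @examples
#' label_from_torsions(c(67.6, 61.5, 69.4, -82.5))  # "gGGg′"
#' @export
label_from_torsions <- function(quad, ascii = FALSE) {
  if (is.null(dim(quad))) quad <- matrix(quad, nrow = 1L)
  if (ncol(quad) != 4L) stop("expected four torsion angles per molecule", call. = FALSE)
  if (any(!is.finite(quad))) stop("torsion angles must be finite numbers", call. = FALSE)
  codes <- matrix(.bin_codes(quad), nrow = nrow(quad))
  apply(codes, 1L, .render_label, ascii = ascii)
}

#' Apply a molecular symmetry operation to a label
#'
#' The symmetry group of the 1,3-diol label word has order four:
#' \code{identity}; \code{reverse} (end-for-end exchange of the two molecular
#' ends, flipping the letter tuple); \code{mirror} (reflection, exchanging
#' G and G' at every position while leaving T fixed); and their composition
#' \code{reverse_mirror}. Each operation is its own inverse.
#'
#' @param op one of \code{"identity"}, \code{"reverse"}, \code{"mirror"},
#'   \code{"reverse_mirror"}.
#' @param label character vector of labels.
#' @return character vector of transformed labels.
#' @examples
#' apply_symmetry("reverse", "tTTg")  # "gTTt"
#' @export
apply_symmetry <- function(op = c("identity", "reverse", "mirror", "reverse_mirror"),
                           label) {
  op <- match.arg(op)
  vapply(label, function(l) {
    codes <- .parse_label(l)
    .render_label(.apply_op_codes(op, codes))
  }, character(1L), USE.NAMES = FALSE)
}

.apply_op_codes <- function(op, codes) {
  mirror_map <- c(1L, 3L, 2L)  # T fixed, G <-> G'
  switch(op,
    identity = codes,
    reverse = rev(codes),
    mirror = mirror_map[codes],
    reverse_mirror = mirror_map[rev(codes)]
  )
}

.SYMMETRY_OPS <- c("identity", "reverse", "mirror", "reverse_mirror")

#' Symmetry orbit of a conformation label
#'
#' Returns the set of labels reachable from \code{label} under the order-4
#' symmetry group. Orbit sizes are 1, 2 or 4; summed over the 25 unique
#' conformations they recover all 81 raw letter combinations.
#'
#' @param label a single label string.
#' @return character vector of the distinct orbit members, sorted in
#'   lexicographic letter order (t < g < g').
#' @examples
#' orbit("tTTg")  # four symmetry-related variants
#' orbit("tTTt")  # a single self-symmetric label
#' @export
orbit <- function(label) {
  codes <- .parse_label(label)
  members <- unique(vapply(.SYMMETRY_OPS, function(op) {
    .render_label(.apply_op_codes(op, codes))
  }, character(1L), USE.NAMES = FALSE))
  members[order(vapply(members, function(m) {
    paste(sprintf("%d", .parse_label(m)), collapse = "")
  }, character(1L)))]
}

# family-canonical chain word: lex-min over the chain word's own orbit
.canonical_chain <- function(chain) {
  mirror_map <- c(1L, 3L, 2L)
  variants <- list(chain, rev(chain), mirror_map[chain], mirror_map[rev(chain)])
  keys <- vapply(variants, function(v) paste(v, collapse = ""), character(1L))
  variants[[which.min(keys)]]
}

.canonicalize_codes <- function(codes, chain_positions = c(2L, 3L)) {
  chain_canon <- .canonical_chain(codes[chain_positions])
  images <- lapply(.SYMMETRY_OPS, .apply_op_codes, codes = codes)
  keep <- Filter(function(v) all(v[chain_positions] == chain_canon), images)
  keys <- vapply(keep, function(v) paste(v, collapse = ""), character(1L))
  keep[[which.min(keys)]]
}

# memoized canonical/family lookup over all 81 raw labels
.label_cache <- new.env(parent = emptyenv())

.canonical_map <- function() {
  if (is.null(.label_cache$map)) {
    grid <- as.matrix(expand.grid(1:3, 1:3, 1:3, 1:3))[, 4:1]
    raw <- apply(grid, 1L, .render_label)
    canon <- apply(grid, 1L, function(codes) .render_label(.canonicalize_codes(codes)))
    fam <- apply(grid, 1L, function(codes) {
      chain <- .canonical_chain(codes[c(2L, 3L)])
      paste(.LETTER_UP[chain], collapse = "")
    })
    .label_cache$map <- stats::setNames(canon, raw)
    .label_cache$family <- stats::setNames(fam, raw)
  }
  .label_cache$map
}

#' Canonical representative of a label's symmetry orbit
#'
#' Reduces a raw label to the unique representative of its symmetry orbit in
#' two stages: (1) keep the orbit members whose main-chain letter pair is the
#' family-canonical one (TT, TG, GG or GG'); (2) among those, take the
#' lexicographic minimum under the letter order t < g < g', compared position
#' by position. The map is idempotent and constant on orbits.
#'
#' @param label character vector of labels (raw or already canonical).
#' @return character vector of canonical labels.
#' @examples
#' canonicalize("gTTt")  # "tTTg"
#' @export
canonicalize <- function(label) {
  map <- .canonical_map()
  key <- vapply(label, function(l) .render_label(.parse_label(l)), character(1L),
                USE.NAMES = FALSE)
  out <- unname(map[key])
  if (anyNA(out)) stop("invalid conformation label(s): ",
                       paste(unique(label[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Conformation family of a label
#'
#' The family is the main-chain letter pair of the canonical form: one of
#' TT, TG, GG, GG'. Labels differing only in hydroxyl-hydrogen torsions
#' belong to the same family.
#'
#' @param label character vector of labels; non-canonical input is
#'   canonicalized first.
#' @param ascii render the prime as \code{"p"}.
#' @return character vector of family names.
#' @examples
#' family_of("gTGg′")  # "TG"
#' @export
family_of <- function(label, ascii = FALSE) {
  .canonical_map()
  key <- vapply(label, function(l) .render_label(.parse_label(l)), character(1L),
                USE.NAMES = FALSE)
  out <- unname(.label_cache$family[key])
  if (anyNA(out)) stop("invalid conformation label(s): ",
                       paste(unique(label[is.na(out)]), collapse = ", "), call. = FALSE)
  if (ascii) gsub(.PRIME, "p", out, fixed = TRUE) else out
}

.FAMILY_ORDER <- function() c("TT", "TG", "GG", paste0("GG", .PRIME))

#' Enumerate the unique conformations of a 1,3-diol
#'
#' Sequential variation of the three torsion letters over the four torsions
#' yields 3^4 = 81 raw combinations; reduction by the order-4 symmetry group
#' (end exchange and mirror) leaves 25 unique conformations, indexed c_1 to
#' c_25. Ordering is family-major (TT, TG, GG, GG') and lexicographic within
#' a family (letter order t < g < g').
#'
#' @return a \code{conformer_registry} data frame with columns \code{index}
#'   (\code{"c_1"}...\code{"c_25"}), \code{label}, \code{family},
#'   \code{orbit_size}, \code{orbit} (comma-separated members), and the
#'   standard torsion angles \code{chi1}...\code{chi4} in degrees.
#' @examples
#' reg <- enumerate_unique()
#' nrow(reg)           # 25
#' table(reg$family)   # 4 families of sizes 4, 9, 6, 6
#' @export
enumerate_unique <- function() {
  map <- .canonical_map()
  canon <- unique(unname(map))
  codes <- .label_codes_matrix(canon)
  fam <- family_of(canon)
  fam_rank <- match(fam, .FAMILY_ORDER())
  key <- apply(codes, 1L, function(v) paste(v, collapse = ""))
  ord <- order(fam_rank, key)
  canon <- canon[ord]
  orbits <- lapply(canon, orbit)
  std <- t(vapply(canon, standard_torsions, numeric(4L)))
  reg <- data.frame(
    index = paste0("c_", seq_along(canon)),
    label = canon,
    family = fam[ord],
    orbit_size = lengths(orbits),
    orbit = vapply(orbits, paste, character(1L), collapse = ","),
    chi1 = std[, 1L], chi2 = std[, 2L], chi3 = std[, 3L], chi4 = std[, 4L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(reg) <- c("conformer_registry", "data.frame")
  reg
}

#' @export
print.conformer_registry <- function(x, ...) {
  cat(sprintf("Unique 1,3-diol conformations: %d labels in %d families\n",
              nrow(x), length(unique(x$family))))
  print.data.frame(x[, c("index", "label", "family", "orbit_size")], ...)
  invisible(x)
}

#' Standard torsion angles for a label
#'
#' Maps each letter to the idealized staggered torsion: T/t to 180, G/g to
#' 60 and G'/g' to 300 degrees (-60 normalized). Binning the result
#' recovers the label, so \code{label_from_torsions(standard_torsions(x))}
#' equals \code{canonicalize(x)} for canonical \code{x}.
#'
#' @param label a single label string.
#' @return numeric vector of the four torsions in degrees.
#' @examples
#' standard_torsions("tGG′g")  # 180 60 300 60
#' @export
standard_torsions <- function(label) {
  codes <- .parse_label(label)
  c(180, 60, 300)[codes]
}

#' Write the conformer registry to CSV
#'
#' @param path output file path.
#' @param ascii write labels with the ASCII prime alias (\code{gp}/\code{Gp})
#'   instead of U+2032.
#' @return the registry, invisibly.
#' @export
write_registry_csv <- function(path, ascii = FALSE) {
  reg <- enumerate_unique()
  out <- as.data.frame(reg)
  if (ascii) {
    for (col in c("label", "family", "orbit")) {
      out[[col]] <- gsub(.PRIME, "p", out[[col]], fixed = TRUE)
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(reg)
}
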