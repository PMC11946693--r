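# Hydroxyl-oxygen radial distribution function and multi-peak area
# decomposition — the indirect conformation estimate the direct labeling
# method is contrasted with.

#' Hydroxyl-oxygen radial distribution function
#'
#' Frame-averaged histogram of O-O minimum-image distances among the
#' hydroxyl oxygens of the target molecules, normalized by shell volume and
#' the pair density of the selected pair set, so an ideal-gas arrangement
#' gives g(r) = 1 at all r. The selection tag makes the pair universe
#' explicit: all O-O pairs, intermolecular only, or intramolecular only
#' (each normalized against its own pair count, so the three curves are
#' directly comparable).
#'
#' @param traj a \code{trajectory}.
#' @param topology the matching [topology].
#' @param selection \code{"all"}, \code{"inter"} or \code{"intra"}.
#' @param bin_width histogram bin width in Angstrom.
#' @param r_max histogram range; defaults to \code{min(10, half the smallest
#'   box edge)} and must not exceed half the smallest box edge.
#' @return an \code{rdf_curve}: list with \code{r} (bin centers), \code{g},
#'   \code{counts} (raw pair counts per bin), \code{bin_width},
#'   \code{r_max}, \code{n_frames}, \code{selection}.
#' @export
compute_rdf <- function(traj, topology, selection = c("all", "inter", "intra"),
                        bin_width = 0.05, r_max = NULL) {
  selection <- match.arg(selection)
  boxes <- vapply(traj$frames, `[[`, numeric(3L), "box")
  half_min_edge <- min(boxes) / 2
  if (is.null(r_max)) r_max <- min(10, half_min_edge)
  if (r_max > half_min_edge + 1e-9) {
    stop(sprintf("r_max (%.2f) exceeds half the smallest box edge (%.2f)",
                 r_max, half_min_edge), call. = FALSE)
  }
  breaks <- seq(0, r_max, by = bin_width)
  if (abs(breaks[length(breaks)] - r_max) > 1e-12) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  expected <- numeric(nb)
  shell_vol <- 4 / 3 * pi * (breaks[-1L]^3 - breaks[-(nb + 1L)]^3)
  for (f in traj$frames) {
    d <- pair_distances_oo(f, topology, selection)
    n_pairs <- length(d)
    idx <- findInterval(d, breaks, rightmost.closed = FALSE)
    idx <- idx[idx >= 1L & idx <= nb]
    counts <- counts + tabulate(idx, nbins = nb)
    expected <- expected + n_pairs * shell_vol / prod(f$box)
  }
  g <- ifelse(expected > 0, counts / expected, 0)
  structure(list(r = (breaks[-1L] + breaks[-(nb + 1L)]) / 2, g = g,
                 counts = counts, bin_width = bin_width, r_max = r_max,
                 n_frames = length(traj$frames), selection = selection),
            class = "rdf_curve")
}

#' @export
print.rdf_curve <- function(x, ...) {
  cat(sprintf("g_OO(r): %d bins of %g Angstrom to r_max = %g (%s pairs, %d frames)\n",
              length(x$r), x$bin_width, x$r_max, x$selection, x$n_frames))
  invisible(x)
}

#' Export an RDF curve as CSV
#'
#' @param curve an \code{rdf_curve}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_rdf_csv <- function(curve, path) {
  utils::write.csv(data.frame(r = curve$r, g = curve$g, counts = curve$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.peak_shape <- function(shape) {
  switch(shape,
    gaussian = list(
      f = function(r, center, width, amp) amp * exp(-(r - center)^2 / (2 * width^2)),
      area = function(center, width, amp) amp * width * sqrt(2 * pi)
    ),
    lorentzian = list(
      f = function(r, center, width, amp) amp * width^2 / ((r - center)^2 + width^2),
      area = function(center, width, amp) amp * width * pi
    )
  )
}

# local maxima (strictly above both neighbours) of a lightly smoothed curve
.local_maxima <- function(r, g) {
  if (length(g) >= 5L) {
    gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
  } else {
    gs <- g
  }
  i <- which(diff(sign(diff(gs))) < 0) + 1L
  i[order(gs[i], decreasing = TRUE)]
}

#' Decompose an RDF curve into Lorentzian or Gaussian peaks
#'
#' Least-squares fit of a sum of \code{n_components} Gaussian or Lorentzian
#' peaks to g(r) over a fit window, with per-component areas integrated
#' analytically and normalized to area fractions summing to 100 percent.
#' Initial centers come from the local maxima of the (lightly smoothed)
#' curve; the default window runs from the first bin with g > 0 to the
#' first local minimum after the last fitted component, excluding the
#' long-range g = 1 plateau.
#'
#' @param curve an \code{rdf_curve}.
#' @param n_components number of peaks to fit.
#' @param shape \code{"gaussian"} or \code{"lorentzian"}.
#' @param window optional numeric length-2 fit window in Angstrom.
#' @param centers optional starting centers (overrides peak detection);
#'   each fitted center is confined between the midpoints to its
#'   neighbours, keeping components ordered and local.
#' @param baseline \code{"none"} fits peaks only; \code{"constant"} adds a
#'   free additive offset, useful when narrow structural peaks sit on the
#'   flat g = 1 intermolecular background. The offset is excluded from the
#'   peak areas.
#' @return a \code{peak_decomposition}: list with \code{components} (data
#'   frame: center, width, amplitude, area, area_frac in percent, ordered by
#'   center), \code{shape}, \code{window}, \code{rss}, \code{r_squared}.
#'   Non-convergence of the fit is an error.
#' @export
decompose_peaks <- function(curve, n_components = 3,
                            shape = c("gaussian", "lorentzian"),
                            window = NULL, centers = NULL,
                            baseline = c("none", "constant")) {
  shape <- match.arg(shape)
  baseline <- match.arg(baseline)
  sh <- .peak_shape(shape)
  r <- curve$r
  g <- curve$g
  if (is.null(centers)) {
    cand <- .local_maxima(r, g)
    if (!is.null(window)) cand <- cand[r[cand] >= window[1L] & r[cand] <= window[2L]]
    if (length(cand) < n_components) {
      stop(sprintf("found only %d resolvable maxima for a %d-component fit",
                   length(cand), n_components), call. = FALSE)
    }
    centers <- sort(r[cand[seq_len(n_components)]])
  } else {
    centers <- sort(centers)
    if (length(centers) != n_components) {
      stop("length(centers) must equal n_components", call. = FALSE)
    }
  }
  if (is.null(window)) {
    lo <- r[which(g > 0)[1L]]
    after <- which(r > centers[n_components])
    gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
    mins <- after[which(diff(sign(diff(gs)))[pmax(after - 1L, 1L)] > 0)]
    hi <- if (length(mins) > 0L) r[mins[1L] + 1L] else max(r)
    window <- c(lo, hi)
  }
  sel <- r >= window[1L] & r <= window[2L]
  rf <- r[sel]; gf <- g[sel]
  amp0 <- vapply(centers, function(cc) max(gf[abs(rf - cc) <= 2 * curve$bin_width],
                                           na.rm = TRUE), numeric(1L))
  amp0[!is.finite(amp0) | amp0 <= 0] <- max(gf) / 2
  width0 <- rep(min(max(4 * curve$bin_width, diff(range(rf)) / (6 * n_components)),
                    diff(window) / 3.5),
                n_components)
  start <- c(centers, width0, amp0)
  # each center is confined between the midpoints to its neighbours, which
  # keeps the components ordered and local to their initial peak
  mids <- (centers[-1L] + centers[-n_components]) / 2
  c_lo <- c(window[1L], mids)
  c_hi <- c(mids, window[2L])
  lower <- c(c_lo, rep(curve$bin_width / 2, n_components), rep(0, n_components))
  upper <- c(c_hi, rep(diff(window) / 3, n_components), rep(Inf, n_components))
  if (baseline == "constant") {
    start <- c(start, stats::quantile(gf, 0.25, names = FALSE))
    lower <- c(lower, 0)
    upper <- c(upper, max(gf))
  }
  model_fun <- function(p) {
    peaks <- rowSums(vapply(seq_len(n_components), function(k) {
      sh$f(rf, p[k], p[n_components + k], p[2 * n_components + k])
    }, numeric(length(rf))))
    if (baseline == "constant") peaks + p[3L * n_components + 1L] else peaks
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) gf - model_fun(p),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error") || fit$info %in% c(0L, 5L)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    stop("peak decomposition did not converge: ", msg, call. = FALSE)
  }
  p <- fit$par
  ord <- order(p[seq_len(n_components)])
  comp <- data.frame(
    center = p[seq_len(n_components)][ord],
    width = p[n_components + seq_len(n_components)][ord],
    amplitude = p[2 * n_components + seq_len(n_components)][ord]
  )
  comp$area <- sh$area(comp$center, comp$width, comp$amplitude)
  comp$area_frac <- 100 * comp$area / sum(comp$area)
  rss <- sum(fit$fvec^2)
  tss <- sum((gf - mean(gf))^2)
  structure(list(components = comp, shape = shape, window = window,
                 baseline = if (baseline == "constant") p[3L * n_components + 1L] else 0,
                 rss = rss, r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n_components = n_components),
            class = "peak_decomposition")
}

#' @export
print.peak_decomposition <- function(x, ...) {
  cat(sprintf("%d-%s decomposition over r in [%.2f, %.2f] (R^2 = %.4f)\n",
              x$n_components, x$shape, x$window[1L], x$window[2L], x$r_squared))
  comp <- x$components
  comp[] <- lapply(comp, round, 3)
  print.data.frame(comp, row.names = FALSE)
  invisible(x)
}

#' Naive RDF-based conformer-family fraction estimate
#'
#' Maps the fitted peak area fractions to conformation-family hypotheses
#' (e.g. first peak near 2.8 Angstrom to GG', second to TG, third to TT).
#' This is the indirect estimate the direct labeling method is contrasted
#' with: intermolecular hydrogen-bonded O...O contacts populate the same
#' short-distance peak as intramolecularly bonded GG' conformations, so the
#' first-peak fraction overstates the GG' family whenever intermolecular
#' contacts are present. Report it side by side with [occupancy()].
#'
#' @param decomp a \code{peak_decomposition}.
#' @param family_map character vector of family names, one per component
#'   (in order of increasing center).
#' @return data frame with columns \code{family}, \code{center},
#'   \code{phi_rdf} (area fraction in percent).
#' @export
rdf_conformer_estimate <- function(decomp, family_map) {
  comp <- decomp$components
  if (length(family_map) != nrow(comp)) {
    stop("family_map must name one family per fitted component", call. = FALSE)
  }
  data.frame(family = .normalize_prime(family_map), center = comp$center,
             phi_rdf = comp$area_frac, stringsAsFactors = FALSE)
}
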