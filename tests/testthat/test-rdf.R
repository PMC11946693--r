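# RDF computation, normalization, and multi-peak decomposition.

gauss_curve <- function(r, areas, centers, widths, noise = 0, seed = 1) {
  g <- rowSums(mapply(function(a, c0, s) a * exp(-(r - c0)^2 / (2 * s^2)) /
                        (s * sqrt(2 * pi)),
                      areas, centers, widths))
  if (noise > 0) {
    set.seed(seed)
    g <- g + rnorm(length(g), 0, noise * max(g))
  }
  structure(list(r = r, g = pmax(g, 0), counts = g, bin_width = diff(r[1:2]),
                 r_max = max(r), n_frames = 1, selection = "all"),
            class = "rdf_curve")
}

test_that("ideal-gas frames give g(r) = 1 within sampling tolerance", {
  set.seed(51)
  ig <- ideal_gas_trajectory(8, 120, c(20, 20, 20))
  curve <- compute_rdf(ig$trajectory, ig$topology, "all", bin_width = 0.25)
  sel <- curve$r > 2  # skip the first few poorly-populated shells
  expect_lt(abs(mean(curve$g[sel]) - 1), 0.03)
  expect_lt(max(abs(curve$g[sel] - 1)), 0.35)
  # intermolecular-only selection is normalized to 1 as well
  inter <- compute_rdf(ig$trajectory, ig$topology, "inter", bin_width = 0.25)
  expect_lt(abs(mean(inter$g[inter$r > 2]) - 1), 0.03)
})

test_that("two fixed oxygens populate exactly their distance bin", {
  ig <- ideal_gas_trajectory(1, 1, c(30, 30, 30))
  f <- ig$trajectory$frames[[1]]
  f$coords[2, ] <- c(5, 5, 5)    # O1
  f$coords[6, ] <- c(8, 5, 5)    # O2 at 3.0
  ig$trajectory$frames[[1]] <- f
  curve <- compute_rdf(ig$trajectory, ig$topology, "intra", bin_width = 0.05,
                       r_max = 10)
  occupied <- which(curve$counts > 0)
  expect_length(occupied, 1L)
  expect_lt(abs(curve$r[occupied] - 3.0), 0.05)
})

test_that("binned counts equal the brute-force all-pairs oracle", {
  set.seed(52)
  ig <- ideal_gas_trajectory(4, 3, c(15, 15, 15))
  for (sel in c("all", "intra", "inter")) {
    curve <- compute_rdf(ig$trajectory, ig$topology, sel, bin_width = 0.25)
    breaks <- seq(0, curve$r_max, by = 0.25)
    ref <- brute_oo_counts(ig$trajectory, ig$topology, breaks, sel)
    expect_equal(curve$counts, ref)
  }
})

test_that("r_max beyond half the smallest box edge is rejected", {
  ig <- ideal_gas_trajectory(2, 1, c(12, 20, 20))
  expect_error(compute_rdf(ig$trajectory, ig$topology, "all", r_max = 7),
               "half the smallest box edge")
})

test_that("three-Gaussian curves with known areas are recovered within 2 points", {
  r <- seq(0.025, 7.975, by = 0.05)
  curve <- gauss_curve(r, areas = c(10, 30, 60), centers = c(2.8, 3.7, 4.8),
                       widths = c(0.15, 0.2, 0.25), noise = 0.01)
  dec <- decompose_peaks(curve, 3, "gaussian")
  expect_equal(dec$components$center, c(2.8, 3.7, 4.8), tolerance = 0.02)
  expect_lt(max(abs(dec$components$area_frac - c(10, 30, 60))), 2)
  expect_gt(dec$r_squared, 0.99)
})

test_that("a single-component fit assigns the full area to one peak", {
  r <- seq(0.025, 7.975, by = 0.05)
  curve <- gauss_curve(r, areas = 40, centers = 3.5, widths = 0.3)
  dec <- decompose_peaks(curve, 1, "gaussian")
  expect_equal(dec$components$area_frac, 100)
  expect_equal(dec$components$center, 3.5, tolerance = 0.02)
})

test_that("Lorentzian and Gaussian fits of one curve agree qualitatively", {
  r <- seq(0.025, 7.975, by = 0.05)
  curve <- gauss_curve(r, areas = c(10, 30, 60), centers = c(2.8, 3.7, 4.8),
                       widths = c(0.15, 0.2, 0.25), noise = 0.01)
  dg <- decompose_peaks(curve, 3, "gaussian")
  dl <- decompose_peaks(curve, 3, "lorentzian")
  # shape-dependent but both close to truth: the fat Lorentzian tails shift
  # a few points of area between neighbours
  expect_lt(max(abs(dg$components$area_frac - c(10, 30, 60))), 2)
  expect_lt(max(abs(dl$components$area_frac - c(10, 30, 60))), 10)
  expect_false(isTRUE(all.equal(dg$components$area_frac,
                                dl$components$area_frac)))
})

test_that("too few resolvable maxima is an explicit error", {
  r <- seq(0.025, 7.975, by = 0.05)
  curve <- gauss_curve(r, areas = 40, centers = 3.5, widths = 0.3)
  expect_error(decompose_peaks(curve, 3, "gaussian"), "resolvable maxima")
})

test_that("the naive RDF family estimate reports the mapped area fractions", {
  r <- seq(0.025, 7.975, by = 0.05)
  curve <- gauss_curve(r, areas = c(8, 28, 64), centers = c(2.8, 3.7, 4.8),
                       widths = c(0.15, 0.2, 0.25))
  dec <- decompose_peaks(curve, 3, "gaussian")
  est <- rdf_conformer_estimate(dec, c("GG'", "TG", "TT"))
  expect_equal(est$family, c(paste0("GG", PRIME), "TG", "TT"))
  expect_equal(est$phi_rdf, c(8, 28, 64), tolerance = 0.02)
  expect_error(rdf_conformer_estimate(dec, c("TT", "TG")), "one family per")
})

test_that("injected short contacts inflate first-peak counts, not direct fractions", {
  pT <- c(0.8, 0.1, 0.1)
  chainP <- matrix(rep(pT, each = 3), 3)
  model <- torsion_chain_model(list(stay_transition(0.75), chainP, chainP,
                                    stay_transition(0.75)))
  run <- simulate_trajectory(model, 8, 120, box = c(29, 29, 29), seed = 53)
  base_series <- label_trajectory(run$trajectory, run$topology)
  first_peak_counts <- function(traj) {
    curve <- compute_rdf(traj, run$topology, "all", bin_width = 0.05, r_max = 6)
    sum(curve$counts[curve$r > 2.5 & curve$r < 3.1])
  }
  counts <- vapply(0:3, function(np) {
    tr <- inject_intermolecular_contacts(run$trajectory, run$topology, np)
    series <- label_trajectory(tr, run$topology)
    expect_identical(series$canonical, base_series$canonical)
    first_peak_counts(tr)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})
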