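# Markov torsion generator and internal-to-Cartesian builder.

test_that("transition matrices are validated", {
  expect_error(torsion_chain_model(matrix(1, 2, 2)), "3 x 3")
  bad <- diag(3); bad[1, 1] <- 0.5
  expect_error(torsion_chain_model(bad), "sum to 1")
  expect_error(torsion_chain_model(diag(3), jitter_max = 60), "below 55")
  expect_error(torsion_chain_model(list(diag(3), diag(3))), "list of four")
})

test_that("an identity transition matrix freezes every molecule", {
  model <- torsion_chain_model(diag(3))
  sim <- simulate_labels(model, 6, 50, seed = 61)
  expect_true(all(apply(sim$raw, 1, function(x) length(unique(x)) == 1L)))
})

test_that("uniform rows give each torsion letter about a third of frames", {
  model <- torsion_chain_model(stay_transition(1 / 3))
  sim <- simulate_labels(model, 1, 3e4, seed = 62)
  for (slot in 1:4) {
    freq <- tabulate(sim$states[1, , slot], 3) / 3e4
    # i.i.d. draws: se = sqrt(p(1-p)/n) ~ 0.0027
    expect_lt(max(abs(freq - 1 / 3)), 3 * sqrt(2 / 9 / 3e4) + 1e-9)
  }
})

test_that("stay probability 0.75 gives a mean per-slot dwell near 4 steps", {
  model <- torsion_chain_model(stay_transition(0.75))
  sim <- simulate_labels(model, 2, 2e4, seed = 63)
  dwells <- unlist(lapply(1:2, function(m) {
    lapply(1:4, function(slot) rle(sim$states[m, , slot])$lengths)
  }))
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 4), 3 * se)
})

test_that("jitter stays inside the truncation bound and preserves labels", {
  model <- torsion_chain_model(stay_transition(0.5), jitter_sd = 10,
                               jitter_max = 30)
  sim <- simulate_labels(model, 4, 200, seed = 64)
  centers <- c(180, 60, 300)[sim$states]
  dev <- sim$quads - array(centers, dim = dim(sim$states))
  expect_true(all(abs(dev) <= 30))
  expect_identical(label_from_torsions(matrix(aperm(sim$quads, c(3, 1, 2)),
                                              ncol = 4, byrow = TRUE)),
                   as.vector(sim$raw))
})

test_that("built coordinates reproduce prescribed torsions to 1e-6 degrees", {
  model <- torsion_chain_model(stay_transition(0.5))
  run <- simulate_trajectory(model, 3, 5, box = c(20, 20, 20), seed = 65)
  for (k in c(1, 3, 5)) {
    f <- run$trajectory$frames[[k]]
    for (m in 1:3) {
      mol <- f$coords[match(run$topology$molecules[[m]], f$ids), ]
      rownames(mol) <- names(run$topology$molecules[[m]])
      expect_equal(torsion_quad(mol, f$box), run$truth$quads[m, k, ],
                   tolerance = 1e-6)
    }
  }
})

test_that("the crystal-structure torsions build and measure back to gGGg-prime", {
  tpl <- geometry_template()
  chain <- dioltraj:::.build_chain(c(67.6, 61.5, 69.4, 277.5), tpl)
  expect_equal(label_from_torsions(torsion_quad(chain)), paste0("gGGg", PRIME))
  # bonded neighbours stay within the 2 Angstrom sanity bound
  bonds <- sqrt(rowSums((chain[-1, ] - chain[-7, ])^2))
  expect_true(all(bonds < 2))
})

test_that("a written-and-reread trajectory agrees with ground truth end to end", {
  model <- torsion_chain_model(stay_transition(0.8))
  run <- simulate_trajectory(model, 8, 60, box = c(29, 29, 29), seed = 66)
  path <- tempfile(fileext = ".dump")
  write_lammps_dump(run$trajectory, path)
  series <- label_trajectory(read_lammps_dump(path, run$topology), run$topology)
  expect_equal(series$n_conf, 480L)
  expect_identical(series$raw, run$truth$raw)
  truth_series <- state_series_from_labels(run$truth$raw,
                                           stride_ps = run$truth$stride_ps)
  expect_identical(series$canonical, truth_series$canonical)
})

test_that("identical seeds reproduce trajectories bit for bit", {
  model <- torsion_chain_model(stay_transition(0.7))
  a <- simulate_trajectory(model, 2, 10, box = c(18, 18, 18), seed = 67)
  b <- simulate_trajectory(model, 2, 10, box = c(18, 18, 18), seed = 67)
  expect_identical(a$truth$raw, b$truth$raw)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  c <- simulate_trajectory(model, 2, 10, box = c(18, 18, 18), seed = 68)
  expect_false(identical(a$trajectory$frames, c$trajectory$frames))
})

test_that("the joint 81-state mode is consistent with its raw labels", {
  P <- stay_transition(0.9, n_states = 81L)
  model <- torsion_chain_model(P)
  expect_true(model$joint)
  sim <- simulate_labels(model, 3, 100, seed = 69)
  expect_identical(label_from_torsions(matrix(aperm(sim$quads, c(3, 1, 2)),
                                              ncol = 4, byrow = TRUE)),
                   as.vector(sim$raw))
  # dwell of the joint label ~ 1/(1-0.9) = 10 steps
  dwell <- mean(unlist(lapply(1:3, function(m) rle(sim$raw[m, ])$lengths)))
  expect_gt(dwell, 4)
})

test_that("contact injection hits the target distance without touching labels", {
  model <- torsion_chain_model(stay_transition(0.8))
  run <- simulate_trajectory(model, 4, 6, box = c(25, 25, 25), seed = 70)
  injected <- inject_intermolecular_contacts(run$trajectory, run$topology, 1)
  for (f in injected$frames) {
    o_a <- f$coords[match(run$topology$molecules[[1]][["O2"]], f$ids), ]
    o_b <- f$coords[match(run$topology$molecules[[2]][["O1"]], f$ids), ]
    d <- o_b - o_a
    d <- d - f$box * round(d / f$box)
    expect_equal(sqrt(sum(d^2)), 2.8, tolerance = 1e-6)
  }
  series <- label_trajectory(injected, run$topology)
  expect_identical(series$raw, run$truth$raw)
  # zero pairs is the identity; too many pairs is an error
  same <- inject_intermolecular_contacts(run$trajectory, run$topology, 0)
  expect_identical(same$frames, run$trajectory$frames)
  expect_error(inject_intermolecular_contacts(run$trajectory, run$topology, 3),
               "exceeds")
})

test_that("ground-truth CSV export matches the analyzer's view of the labels", {
  model <- torsion_chain_model(stay_transition(0.8))
  sim <- simulate_labels(model, 2, 5, seed = 71)
  path <- tempfile(fileext = ".csv")
  write_ground_truth_csv(sim, path, ascii = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 10L)
  expect_identical(matrix(canonicalize(df$raw), nrow = 2),
                   matrix(canonicalize(as.vector(sim$raw)), nrow = 2))
})
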