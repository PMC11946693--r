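# Run-length lifetime statistics at label and family level.

test_that("run-length encoding finds maximal constant runs", {
  labs <- matrix(c("tTTt", "tTTt", "tTTg", "tTTt", "tTTt", "tTTt"), nrow = 1)
  series <- state_series_from_labels(labs)
  runs <- run_length_encode(series, "label")
  expect_equal(runs$state, c("tTTt", "tTTg", "tTTt"))
  expect_equal(runs$duration_ps, c(2, 1, 3))
  expect_equal(runs$boundary, c(TRUE, FALSE, TRUE))
  # single constant run spans the whole trajectory
  const <- state_series_from_labels(matrix("gTGt", nrow = 1, ncol = 60))
  runs2 <- run_length_encode(const, "label")
  expect_equal(nrow(runs2), 1L)
  expect_equal(runs2$duration_ps, 60)
})

test_that("family runs pool hydroxyl rotations and symmetry variants", {
  labs <- matrix(c("tTTt", "tTTg", "tTTg"), nrow = 1)
  series <- state_series_from_labels(labs)
  fam_runs <- run_length_encode(series, "family")
  expect_equal(nrow(fam_runs), 1L)
  expect_equal(fam_runs$state, "TT")
  expect_equal(fam_runs$duration_ps, 3)
  # raw symmetry variants share a canonical label, so they never break a run
  variants <- matrix(c("tTTg", "gTTt", paste0("tTTg", PRIME)), nrow = 1)
  series2 <- state_series_from_labels(variants)
  runs2 <- run_length_encode(series2, "label")
  expect_equal(nrow(runs2), 1L)
  expect_equal(runs2$state, "tTTg")
  expect_equal(runs2$duration_ps, 3)
})

test_that("lifetime tables report mean and maximum run durations", {
  labs <- matrix(c("tTTt", "tTTt", "tTTg", "tTTt", "tTTt", "tTTt"), nrow = 1)
  tab <- lifetime_table(run_length_encode(state_series_from_labels(labs), "label"))
  expect_equal(tab$t_av_ps[tab$state == "tTTt"], 2.5)
  expect_equal(tab$t_max_ps[tab$state == "tTTt"], 3)
  expect_equal(tab$t_av_ps[tab$state == "tTTg"], 1)
  expect_equal(tab$t_av_ps[tab$state == "tTTg"],
               tab$t_max_ps[tab$state == "tTTg"])  # single run
  # unobserved labels report zero
  expect_equal(tab$t_av_ps[tab$state == "tGGt"], 0)
  expect_equal(nrow(tab), 25L)
})

test_that("boundary truncation policy filters trajectory-edge runs", {
  labs <- matrix(c("tTTt", "tTTt", "tTTg"), nrow = 1)
  runs <- run_length_encode(state_series_from_labels(labs), "label")
  expect_equal(nrow(truncation_policy(runs, "include")), 2L)
  expect_equal(nrow(truncation_policy(runs, "exclude_boundary")), 0L)
  # interior runs are unaffected
  labs2 <- matrix(c("tTTt", "tTTg", "tTTt"), nrow = 1)
  runs2 <- run_length_encode(state_series_from_labels(labs2), "label")
  kept <- truncation_policy(runs2, "exclude_boundary")
  expect_equal(kept$state, "tTTg")
})

test_that("run durations conserve the observed span per molecule", {
  set.seed(41)
  model <- torsion_chain_model(stay_transition(0.6))
  sim <- simulate_labels(model, 5, 200)
  series <- state_series_from_labels(sim$raw)
  runs <- run_length_encode(series, "label")
  per_mol <- tapply(runs$duration_ps, runs$molecule, sum)
  expect_true(all(per_mol == 200 * series$stride_ps))
  fam_runs <- run_length_encode(series, "family")
  expect_true(all(tapply(fam_runs$duration_ps, fam_runs$molecule, sum) == 200))
})

test_that("a single-slot chain with stay 0.75 dwells about 4 ps", {
  # only the last hydroxyl slot moves, so label dwell = slot dwell = 1/(1-p);
  # the tTG chain prefix breaks the end-exchange/mirror symmetry, so the
  # three slot letters stay three distinct canonical labels
  model <- torsion_chain_model(list(diag(3), diag(3), diag(3),
                                    stay_transition(0.75)))
  n <- 2e4
  set.seed(42)
  sim <- simulate_labels(model, 1, n)
  labs <- paste0("tTG", c("t", "g", paste0("g", PRIME))[sim$states[1, , 4]])
  runs <- run_length_encode(state_series_from_labels(matrix(labs, nrow = 1)),
                            "label")
  t_av <- mean(runs$duration_ps)
  se <- sd(runs$duration_ps) / sqrt(nrow(runs))
  expect_lt(abs(t_av - 4), 3 * se)
})

test_that("boundary policies converge for long chains", {
  set.seed(43)
  model <- torsion_chain_model(stay_transition(0.75))
  sim <- simulate_labels(model, 1, 2e4)
  series <- state_series_from_labels(sim$raw)
  runs <- run_length_encode(series, "label")
  inc <- mean(truncation_policy(runs, "include")$duration_ps)
  exc <- mean(truncation_policy(runs, "exclude_boundary")$duration_ps)
  expect_lt(abs(inc - exc), 0.01)
})

test_that("slow chain torsions give family lifetimes far above label lifetimes", {
  # fast hydroxyl rotation inside a family, slow main-chain rearrangement
  model <- torsion_chain_model(list(stay_transition(0.5), stay_transition(0.99),
                                    stay_transition(0.99), stay_transition(0.5)))
  set.seed(44)
  sim <- simulate_labels(model, 4, 5000)
  series <- state_series_from_labels(sim$raw)
  lab_tab <- lifetime_table(run_length_encode(series, "label"))
  fam_tab <- lifetime_table(run_length_encode(series, "family"))
  lab_mean <- with(as.data.frame(lab_tab),
                   sum(t_av_ps * n_runs) / sum(n_runs))
  fam_mean <- with(as.data.frame(fam_tab),
                   sum(t_av_ps * n_runs) / sum(n_runs))
  expect_gt(fam_mean, 10 * lab_mean)
  # every family run concatenates at least one member-label run
  expect_gte(sum(lab_tab$n_runs), sum(fam_tab$n_runs))
})

test_that("the summary combines occupancy with lifetimes in registry order", {
  set.seed(45)
  model <- torsion_chain_model(stay_transition(0.7))
  sim <- simulate_labels(model, 3, 300)
  series <- state_series_from_labels(sim$raw)
  summ <- conformation_summary(series)
  expect_equal(summ$labels$label, enumerate_unique()$label)
  expect_equal(sum(summ$labels$phi), 100)
  expect_equal(sum(summ$families$phi), 100)
  expect_true(all(summ$labels$t_max_ps >= summ$labels$t_av_ps))
  observed <- summ$labels$count > 0
  expect_true(all(summ$labels$t_av_ps[observed] >= series$stride_ps))
  paths <- tempfile(); write_summary_csv(summ, paths, ascii = TRUE)
  lab_csv <- read.csv(paste0(paths, "_labels.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(lab_csv), 25L)
})
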