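test_that("FAM cutoff lands midway between the generating cluster means", {
  p <- simulation_params(crosstalk_alpha = 0, competition_kappa = 1)
  rx <- simulate_reaction(p, true_concentrations(400, 100), seed = 21)
  th <- fit_thresholds(rx)
  # generating means 700 and 9,603 -> midpoint 5,151.5
  expect_lt(abs(th$fam_cutoff - (700 + 9603) / 2), 3 * p$fam_pos_sd)
  expect_false(th$fam_single_cluster)
})

test_that("all-negative wells get a cutoff above every droplet", {
  p <- simulation_params(ntc_contamination_rate = 0)
  rx <- simulate_ntc(p, seed = 8)
  th <- fit_thresholds(rx)
  expect_true(th$fam_single_cluster)
  expect_true(th$hex_single_cluster)
  expect_equal(sum(rx$droplets$fam_amplitude > th$fam_cutoff), 0)
  cl <- classify_droplets(rx, th)
  expect_equal(cl$n_negative, p$n_droplets)
})

test_that("threshold fitting needs at least 100 droplets", {
  rx <- droplet_reaction(rnorm(50, 700, 20), rnorm(50, 1000, 30))
  expect_error(fit_thresholds(rx), "100 droplets")
})

test_that("crosstalk compensation prevents FAM-only -> double misassignment", {
  # cifB/spike-like well: crosstalk only, no competition
  p <- simulation_params(crosstalk_alpha = 0.05, competition_kappa = 1)
  rx <- simulate_reaction(p, true_concentrations(400, 100), seed = 31)
  th <- fit_thresholds(rx)
  expect_lt(abs(th$crosstalk_alpha_hat - 0.05), 0.02)
  cl <- classify_droplets(rx, th)
  truth <- rx$truth$label
  fam_only_true <- truth == "fam_only"
  misrate <- mean(cl$labels[fam_only_true] == "double")
  expect_lt(misrate, 0.01)
})

test_that("four-cluster wells are recovered at the simulator's truth", {
  # default artefacts: competition kappa = 0.5 AND crosstalk alpha = 0.05
  p <- simulation_params()
  rx <- simulate_reaction(p, true_concentrations(468.6, 100), seed = 42)
  th <- fit_thresholds(rx)
  cl <- classify_droplets(rx, th)
  truth <- rx$truth$label
  # per-class counts within 0.5% of the occupancy-derived truth
  for (lab in levels(truth)) {
    expect_lt(abs(cl[[paste0("n_", lab)]] - sum(truth == lab)),
              max(5, 0.005 * p$n_droplets))
  }
  # the competed double-positive HEX cluster sits strictly between the
  # negative and positive HEX means (the intermediate cluster)
  dbl_hex <- rx$droplets$hex_amplitude[truth == "double"]
  expect_gt(mean(dbl_hex), p$hex_neg_mean)
  expect_lt(mean(dbl_hex), p$hex_pos_mean)
})

test_that("class counts always sum to the droplet total", {
  p <- simulation_params(n_droplets = 2000)
  for (s in 1:5) {
    rx <- simulate_reaction(p, true_concentrations(s * 100, 50), seed = s)
    cl <- classify_droplets(rx, fit_thresholds(rx))
    expect_equal(cl$n_negative + cl$n_fam_only + cl$n_hex_only + cl$n_double,
                 cl$n_total)
  }
})

test_that("quadrant rule applies for user-supplied thresholds", {
  rx <- droplet_reaction(c(9600, 700, 700, 9600),
                         c(1050, 1050, 4300, 4300))
  th <- channel_thresholds(fam_cutoff = 5150, hex_cutoff = 2600)
  cl <- classify_droplets(rx, th)
  expect_equal(as.character(cl$labels),
               c("fam_only", "negative", "hex_only", "double"))
})

test_that("out-of-range cutoffs are rejected unless flagged single-cluster", {
  rx <- droplet_reaction(rnorm(200, 700, 20), rnorm(200, 1000, 30))
  bad <- channel_thresholds(fam_cutoff = 1e6, hex_cutoff = 1500)
  expect_error(classify_droplets(rx, bad), "outside the observed")
  ok <- channel_thresholds(fam_cutoff = 1e6, hex_cutoff = 1500,
                           fam_single_cluster = TRUE, hex_single_cluster = TRUE)
  cl <- classify_droplets(rx, ok)
  expect_equal(cl$n_negative + cl$n_hex_only, 200)
})

test_that("amplitude separation ranks annealing temperatures correctly", {
  # positive-cluster amplitude varies with temperature; argmax recovered
  p0 <- simulation_params(crosstalk_alpha = 0, competition_kappa = 1)
  pos_means <- c(8200, 9603, 9100, 8800)
  seps <- vapply(seq_along(pos_means), function(i) {
    p <- simulation_params(fam_pos_mean = pos_means[i],
                           crosstalk_alpha = 0, competition_kappa = 1)
    rx <- simulate_reaction(p, true_concentrations(300, 0), seed = 50 + i)
    amplitude_separation(rx, fit_thresholds(rx))$fam
  }, numeric(1))
  expect_equal(which.max(seps), which.max(pos_means))
  # default clusters at ~9,603 and ~700 separate by ~8,903
  expect_lt(abs(seps[2] - (9603 - 700)), 100)

  # an all-negative well has no separation to report
  rx <- simulate_ntc(simulation_params(ntc_contamination_rate = 0), seed = 1)
  sep <- amplitude_separation(rx, fit_thresholds(rx))
  expect_true(is.na(sep$fam))
  expect_true(is.na(sep$hex))
})
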