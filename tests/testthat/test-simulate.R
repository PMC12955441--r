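test_that("zero-concentration reactions contain only negative droplets", {
  p <- simulation_params(ntc_contamination_rate = 0)
  rx <- simulate_reaction(p, true_concentrations(0, 0), seed = 7)
  expect_equal(nrow(rx$droplets), p$n_droplets)
  expect_false(any(rx$truth$fam_occupied))
  expect_false(any(rx$truth$hex_occupied))
  # all FAM amplitudes within the negative cluster
  expect_true(all(abs(rx$droplets$fam_amplitude - p$fam_neg_mean) <
                    6 * p$fam_neg_sd))
})

test_that("positive-droplet counts follow 1 - exp(-lambda) occupancy", {
  # closed-form binomial oracle at lambda = 0.1, n = 20,000
  n <- 20000
  lam <- 0.1
  p <- simulation_params(n_droplets = n)
  conc <- lam / (p$droplet_volume_nl * 1e-3)
  rx <- simulate_reaction(p, true_concentrations(conc, 0), seed = 11)
  k <- sum(rx$truth$fam_occupied)
  bounds <- qbinom(c(0.005, 0.995), n, 1 - exp(-lam))
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])

  # occupancy marginals across a lambda grid
  for (lam in c(0.01, 0.1, 1, 3)) {
    conc <- lam / (p$droplet_volume_nl * 1e-3)
    rx <- simulate_reaction(p, true_concentrations(0, conc), seed = 100 + lam * 10)
    k <- sum(rx$truth$hex_occupied)
    bounds <- qbinom(c(0.0005, 0.9995), n, 1 - exp(-lam))
    expect_gte(k, bounds[1])
    expect_lte(k, bounds[2])
  }
})

test_that("FAM negative amplitudes stay in the expected band at high load", {
  # with both targets abundant, simulated FAM-negative droplets should
  # average inside the 692-713 a.u. band (within 3 SE)
  p <- simulation_params()
  rx <- simulate_reaction(p, true_concentrations(800, 800), seed = 5)
  neg <- rx$droplets$fam_amplitude[!rx$truth$fam_occupied]
  se <- sd(neg) / sqrt(length(neg))
  expect_gt(mean(neg), 691.89 - 3 * se)
  expect_lt(mean(neg), 712.72 + 3 * se)
})

test_that("FAM and HEX occupancy are generated independently", {
  p <- simulation_params(n_droplets = 15000)
  conc <- lambda_of(1) # lambda = 1 on both channels
  pvals <- vapply(1:20, function(s) {
    rx <- simulate_reaction(p, true_concentrations(1 / (p$droplet_volume_nl * 1e-3) * 0.5,
                                                   1 / (p$droplet_volume_nl * 1e-3) * 0.5),
                            seed = s)
    tab <- table(rx$truth$fam_occupied, rx$truth$hex_occupied)
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  # Bonferroni over the 20 seeds at alpha = 0.01
  expect_true(all(pvals > 0.01 / 20))
})

test_that("simulation is deterministic given params, truth and seed", {
  p <- simulation_params()
  tr <- true_concentrations(100, 50)
  a <- simulate_reaction(p, tr, seed = 99)
  b <- simulate_reaction(p, tr, seed = 99)
  expect_identical(a$droplets, b$droplets)
  s1 <- simulate_dilution_series(p, tr, 5, 0:-2, 2, seed = 3)
  s2 <- simulate_dilution_series(p, tr, 5, 0:-2, 2, seed = 3)
  expect_identical(lapply(s1, `[[`, "droplets"), lapply(s2, `[[`, "droplets"))
})

test_that("dilution series scales concentrations geometrically", {
  p <- simulation_params(n_droplets = 1000)
  tr <- true_concentrations(500, 200)
  series <- simulate_dilution_series(p, tr, 5, c(0, -1, -2), 2, seed = 1)
  expect_length(series, 6)
  lvl2 <- series[[5]] # first replicate of exponent -2
  expect_equal(lvl2$dilution_exponent, -2)
  expect_equal(lvl2$truth$concentrations$fam_target_copies_per_ul, 500 / 25)
  expect_equal(lvl2$truth$concentrations$hex_target_copies_per_ul, 200 / 25)
  expect_error(simulate_dilution_series(p, tr, 5, c(0, 1), 2),
               "non-positive")
  expect_error(simulate_dilution_series(p, tr, 1, c(0, -1), 2), ">= 2")

  # a 1:2 design with six levels keeps the HEX target fixed when asked
  held <- simulate_dilution_series(p, tr, 2, 0:-5, 1, hold_hex_constant = TRUE,
                                   seed = 2)
  expect_length(held, 6)
  expect_equal(held[[6]]$truth$concentrations$fam_target_copies_per_ul, 500 / 32)
  expect_equal(held[[6]]$truth$concentrations$hex_target_copies_per_ul, 200)
})

test_that("NTC wells show the expected rare-contamination behavior", {
  p <- simulation_params(ntc_contamination_rate = 0)
  rx <- simulate_ntc(p, seed = 4)
  expect_true(rx$is_ntc)
  expect_equal(sum(rx$truth$fam_occupied) + sum(rx$truth$hex_occupied), 0)

  # Monte-Carlo check of the closed-form positive rate at the default
  # contamination (expected positives/well ~ 15,000 * (1 - e^-lam) ~ 0.064)
  p <- simulation_params()
  lam <- lambda_of(p$ntc_contamination_rate)
  n_mc <- 400
  pos <- vapply(seq_len(n_mc), function(s) {
    r <- simulate_ntc(p, seed = 10000 + s)
    sum(r$truth$fam_occupied)
  }, numeric(1))
  expected <- p$n_droplets * (1 - exp(-lam))
  total_bounds <- qpois(c(0.0025, 0.9975), n_mc * expected)
  expect_gte(sum(pos), total_bounds[1])
  expect_lte(sum(pos), total_bounds[2])
})

test_that("processing loss is proportional and invertible", {
  tr <- true_concentrations(100, 0)
  out <- simulate_processing(tr, spike_input = 200, efficiency = 1)
  expect_equal(out$truth$fam_target_copies_per_ul, 100)
  expect_equal(out$realized_spike_copies_per_ul, 200)

  out <- simulate_processing(tr, spike_input = 200, efficiency = 0.5)
  expect_equal(out$truth$fam_target_copies_per_ul, 50)
  expect_equal(out$realized_spike_copies_per_ul, 100)
  expect_error(simulate_processing(tr, 200, 0), "efficiency")
  expect_error(simulate_processing(tr, 200, 1.2), "efficiency")
})

test_that("parameter constructors reject invalid inputs", {
  expect_error(simulation_params(n_droplets = 0), "positive")
  expect_error(simulation_params(competition_kappa = 0), "competition_kappa")
  expect_error(simulation_params(crosstalk_alpha = 1), "crosstalk_alpha")
  expect_error(simulation_params(fam_pos_mean = 100, fam_neg_mean = 700),
               "exceed")
  expect_error(true_concentrations(-1, 0), "finite")
  expect_error(true_concentrations(Inf, 0), "finite")
  expect_error(simulate_reaction(simulation_params(),
                                 structure(list(), class = "true_concentrations")))
})
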