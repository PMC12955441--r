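# Build a classified_droplets object with given counts without simulating.
fake_classified <- function(n_fam_pos, n_total, n_hex_pos = 0,
                            vr = 20, vd = 0.85, is_ntc = FALSE) {
  structure(
    list(labels = NULL, n_total = n_total,
         n_negative = n_total - n_fam_pos - n_hex_pos,
         n_fam_only = n_fam_pos, n_hex_only = n_hex_pos, n_double = 0,
         thresholds = NULL, well_id = "W", assay_name = "fake",
         reaction_volume_ul = vr, droplet_volume_nl = vd, is_ntc = is_ntc),
    class = "classified_droplets"
  )
}

test_that("zero positives give a zero estimate with a zero lower bound", {
  e <- estimate_concentration(fake_classified(0, 15000), "FAM")
  expect_equal(e$lambda_hat, 0)
  expect_equal(e$copies_per_reaction, 0)
  expect_equal(e$ci95_low, 0)
  expect_gt(e$ci95_high, 0)
})

test_that("Poisson correction matches the closed form exactly", {
  # 2,000 of 20,000 positive, Vd = 0.85 nL, Vr = 20 µL
  e <- estimate_concentration(fake_classified(2000, 20000), "FAM")
  expect_equal(e$lambda_hat, -log(0.9), tolerance = 1e-12)
  expect_equal(e$copies_per_ul, -log(0.9) / 0.00085, tolerance = 1e-12)
  expect_equal(e$copies_per_reaction, -log(0.9) / 0.00085 * 20,
               tolerance = 1e-12)
  # frozen value from independent evaluation: 2479.070956654736
  expect_equal(e$copies_per_reaction, 2479.070956654736, tolerance = 1e-9)
})

test_that("lambda is strictly monotone in the positive count", {
  lams <- vapply(c(10, 100, 1000, 5000, 14000), function(x)
    estimate_concentration(fake_classified(x, 15000), "FAM")$lambda_hat,
    numeric(1))
  expect_true(all(diff(lams) > 0))
})

test_that("Poisson correction vanishes in the small-occupancy limit", {
  n <- 200000
  x <- 100 # p = 5e-4
  e <- estimate_concentration(fake_classified(x, n), "FAM")
  uncorrected <- (x / n) / 0.00085 * 20
  expect_lt(abs(e$copies_per_reaction - uncorrected) / uncorrected, 0.01)
})

test_that("saturated wells are flagged, not errored", {
  e <- estimate_concentration(fake_classified(15000, 15000), "FAM")
  expect_true(e$saturated)
  expect_true(is.infinite(e$lambda_hat))
  expect_true(is.infinite(e$ci95_high))
  expect_true(is.finite(e$ci95_low))
  expect_error(estimate_concentration(fake_classified(0, 0), "FAM"),
               "zero droplets")
})

test_that("CI construction switches to Clopper-Pearson at extreme counts", {
  # x = 2: exact bounds, checked against direct beta quantiles
  n <- 15000; x <- 2
  e <- estimate_concentration(fake_classified(x, n), "FAM")
  lam_lo <- -log(1 - qbeta(0.025, x, n - x + 1))
  lam_hi <- -log(1 - qbeta(0.975, x + 1, n - x))
  scale <- 20 / 0.00085
  expect_equal(e$ci95_low, lam_lo * scale, tolerance = 1e-12)
  expect_equal(e$ci95_high, lam_hi * scale, tolerance = 1e-12)
  expect_lte(e$ci95_low, e$copies_per_reaction)
  expect_gte(e$ci95_high, e$copies_per_reaction)
})

test_that("droplet-count QC applies the fewer-than-10,000 exclusion", {
  p <- simulation_params(n_droplets = 9999)
  rx <- simulate_reaction(p, true_concentrations(10, 0), seed = 1)
  expect_false(qc_reaction(rx))
  p <- simulation_params(n_droplets = 10000)
  expect_true(qc_reaction(simulate_reaction(p, true_concentrations(10, 0), seed = 1)))
  p <- simulation_params(n_droplets = 15000)
  expect_true(qc_reaction(simulate_reaction(p, true_concentrations(10, 0), seed = 1)))
  # the flag propagates into estimates
  e <- estimate_concentration(fake_classified(5, 9999), "FAM")
  expect_false(e$qc_pass)
})

test_that("single-molecule detection probability matches the closed form", {
  # ~1 true copy per 20 µL reaction: conc = 0.05 copies/µL
  p <- simulation_params()
  conc <- 1 / 20
  lam <- conc * p$droplet_volume_nl * 1e-3
  p_detect <- 1 - exp(-p$n_droplets * lam) # P(at least one positive droplet)
  hits <- vapply(1:500, function(s) {
    rx <- simulate_reaction(p, true_concentrations(conc, 0), seed = 2000 + s)
    sum(rx$truth$fam_occupied) > 0
  }, logical(1))
  bounds <- qbinom(c(0.0025, 0.9975), 500, p_detect)
  expect_gte(sum(hits), bounds[1])
  expect_lte(sum(hits), bounds[2])
})
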