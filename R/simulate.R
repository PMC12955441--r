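#' Simulate one duplex droplet reaction with known ground truth
#'
#' Generates per-droplet FAM/HEX amplitudes under the standard digital-PCR
#' partition model: each target's copies fall into droplets independently,
#' so a droplet's occupancy for target *t* is Poisson with mean
#' `lambda_t = conc_t (copies/µL) x droplet volume (nL) x 1e-3`. Endpoint
#' PCR saturates, so any droplet with occupancy >= 1 joins the positive
#' amplitude cluster on that channel; amplitudes are then drawn from
#' Gaussian clusters. Two duplex artefacts are layered on top (see
#' [simulation_params()]): the HEX positive mean is multiplied by
#' `competition_kappa` in double-positive droplets, and
#' `crosstalk_alpha * max(0, fam - fam_neg_mean)` is added to every
#' droplet's HEX amplitude.
#'
#' The returned reaction carries the ground truth (per-droplet occupancy
#' and the generating concentrations) in its `truth` field, so classifiers
#' and estimators can be scored against it.
#'
#' @param params A [simulation_params()].
#' @param truth A [true_concentrations()].
#' @param well_id,assay_name,dilution_exponent,replicate_id,is_ntc,annealing_temp_c
#'   Metadata passed through to [droplet_reaction()].
#' @param reaction_volume_ul Reaction volume in µL.
#' @param seed Integer seed; defaults to `params$seed`. Identical
#'   `(params, truth, seed)` give bit-identical output.
#' @return A [droplet_reaction()] with `params$n_droplets` droplets.
#' @export
simulate_reaction <- function(params, truth,
                              well_id = "A01", assay_name = "sim",
                              reaction_volume_ul = 20,
                              dilution_exponent = NULL, replicate_id = NULL,
                              is_ntc = FALSE, annealing_temp_c = NULL,
                              seed = params$seed) {
  validate_simulation_params(params)
  stopifnot(inherits(truth, "true_concentrations"))
  if (is.null(truth$fam_target_copies_per_ul) ||
      is.null(truth$hex_target_copies_per_ul) ||
      !is.finite(truth$fam_target_copies_per_ul) ||
      !is.finite(truth$hex_target_copies_per_ul))
    stop("ground-truth concentrations must be finite", call. = FALSE)
  n <- params$n_droplets
  set.seed(as.integer(seed))

  lam_fam <- truth$fam_target_copies_per_ul * params$droplet_volume_nl * 1e-3
  lam_hex <- truth$hex_target_copies_per_ul * params$droplet_volume_nl * 1e-3

  fam_occ <- stats::rpois(n, lam_fam) >= 1
  hex_occ <- stats::rpois(n, lam_hex) >= 1
  dbl <- fam_occ & hex_occ

  fam_amp <- ifelse(fam_occ,
                    stats::rnorm(n, params$fam_pos_mean, params$fam_pos_sd),
                    stats::rnorm(n, params$fam_neg_mean, params$fam_neg_sd))

  hex_mean <- ifelse(hex_occ,
                     ifelse(dbl, params$competition_kappa * params$hex_pos_mean,
                            params$hex_pos_mean),
                     params$hex_neg_mean)
  hex_sd <- ifelse(hex_occ, params$hex_pos_sd, params$hex_neg_sd)
  hex_amp <- stats::rnorm(n, hex_mean, hex_sd)

  if (params$rain_fraction > 0) {
    is_rain <- stats::runif(n) < params$rain_fraction
    fam_amp[is_rain] <- stats::runif(sum(is_rain), params$fam_neg_mean,
                                     params$fam_pos_mean)
    hex_amp[is_rain] <- stats::runif(sum(is_rain), params$hex_neg_mean,
                                     params$hex_pos_mean)
  }

  # spectral bleed acts on the final FAM amplitude of every droplet
  hex_amp <- hex_amp + params$crosstalk_alpha * pmax(0, fam_amp - params$fam_neg_mean)

  droplet_reaction(
    fam_amplitudes = fam_amp, hex_amplitudes = hex_amp,
    well_id = well_id, assay_name = assay_name,
    reaction_volume_ul = reaction_volume_ul,
    droplet_volume_nl = params$droplet_volume_nl,
    dilution_exponent = dilution_exponent, replicate_id = replicate_id,
    is_ntc = is_ntc, annealing_temp_c = annealing_temp_c,
    truth = list(
      fam_occupied = fam_occ, hex_occupied = hex_occ,
      label = factor(ifelse(dbl, "double",
                     ifelse(fam_occ, "fam_only",
                     ifelse(hex_occ, "hex_only", "negative"))),
                     levels = c("negative", "fam_only", "hex_only", "double")),
      concentrations = truth, seed = as.integer(seed)
    )
  )
}

#' Simulate a serial dilution series with technical replicates
#'
#' For each exponent `k` (non-positive), both target concentrations are
#' scaled by `dilution_base^k` and `replicates_per_level` wells are drawn.
#' Replicate `r` at level index `i` (0-based) uses sub-seed
#' `seed + 1000 * i + r`, so any individual well can be regenerated.
#'
#' @param params A [simulation_params()].
#' @param base_truth [true_concentrations()] at the undiluted (`k = 0`)
#'   level.
#' @param dilution_base Integer dilution factor, >= 2 (5 for a 1:5 series,
#'   2 for a 1:2 series).
#' @param exponents Non-positive integers, e.g. `0:-5` for six levels.
#' @param replicates_per_level Technical replicates per level (>= 1).
#' @param hold_hex_constant If `TRUE` the HEX target concentration is not
#'   diluted, emulating a constant spike input added per reaction; default
#'   `FALSE` (the spike is diluted along with the template).
#' @param seed Master seed; defaults to `params$seed`.
#' @param assay_name Metadata passed to each well.
#' @return A list of [droplet_reaction()]s, ordered by level then replicate,
#'   each carrying `dilution_exponent` and `replicate_id`.
#' @export
simulate_dilution_series <- function(params, base_truth,
                                     dilution_base, exponents,
                                     replicates_per_level = 2,
                                     hold_hex_constant = FALSE,
                                     seed = params$seed,
                                     assay_name = "sim") {
  validate_simulation_params(params)
  stopifnot(inherits(base_truth, "true_concentrations"))
  if (dilution_base < 2) stop("dilution_base must be >= 2", call. = FALSE)
  if (any(exponents > 0)) stop("exponents must be non-positive", call. = FALSE)
  if (replicates_per_level < 1)
    stop("replicates_per_level must be >= 1", call. = FALSE)

  out <- list()
  for (i in seq_along(exponents)) {
    k <- exponents[[i]]
    scale <- dilution_base^k
    level_truth <- true_concentrations(
      base_truth$fam_target_copies_per_ul * scale,
      if (hold_hex_constant) base_truth$hex_target_copies_per_ul
      else base_truth$hex_target_copies_per_ul * scale
    )
    for (r in seq_len(replicates_per_level)) {
      out[[length(out) + 1L]] <- simulate_reaction(
        params, level_truth,
        well_id = sprintf("L%02d_R%d", i, r),
        assay_name = assay_name,
        dilution_exponent = k, replicate_id = r,
        seed = as.integer(seed) + 1000L * (i - 1L) + r
      )
    }
  }
  out
}

#' Simulate a no-template control well
#'
#' An NTC is an ordinary reaction whose only template is background
#' contamination at `params$ntc_contamination_rate` copies/µL on both
#' channels; the well is flagged `is_ntc`.
#'
#' @inheritParams simulate_reaction
#' @return A [droplet_reaction()] with `is_ntc = TRUE`.
#' @export
simulate_ntc <- function(params, seed = params$seed, well_id = "NTC1",
                         assay_name = "sim") {
  r <- params$ntc_contamination_rate
  simulate_reaction(params, true_concentrations(r, r),
                    well_id = well_id, assay_name = assay_name,
                    is_ntc = TRUE, seed = seed)
}

#' Apply a sample-processing efficiency to ground-truth concentrations
#'
#' Spike-in RNA is added before extraction, so any loss during downstream
#' processing (purification, DNase treatment, cDNA synthesis) hits the
#' spike and the endogenous target proportionally. This helper applies
#' that proportional loss, returning the post-processing truth to feed
#' [simulate_reaction()] together with the realized spike concentration,
#' enabling end-to-end tests of [spike_recovery()] and
#' [correct_by_efficiency()].
#'
#' @param truth Pre-loss [true_concentrations()]; the HEX slot is replaced
#'   by the spike.
#' @param spike_input Spike-in concentration added to the sample,
#'   copies/µL (> 0).
#' @param efficiency Processing efficiency in `(0, 1]`.
#' @param seed Accepted for interface symmetry; the proportional-loss model
#'   is deterministic and does not consume randomness.
#' @return A list with `truth` (post-loss [true_concentrations()], FAM =
#'   cif, HEX = spike), `realized_spike_copies_per_ul`, and `efficiency`.
#' @export
simulate_processing <- function(truth, spike_input, efficiency, seed = NULL) {
  stopifnot(inherits(truth, "true_concentrations"))
  if (!is.finite(spike_input) || spike_input <= 0)
    stop("spike_input must be > 0", call. = FALSE)
  if (!is.finite(efficiency) || efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]", call. = FALSE)
  realized_spike <- spike_input * efficiency
  list(
    truth = true_concentrations(
      truth$fam_target_copies_per_ul * efficiency,
      realized_spike
    ),
    realized_spike_copies_per_ul = realized_spike,
    efficiency = efficiency
  )
}
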