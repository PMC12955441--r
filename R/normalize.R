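#' Spike-in recovery (processing efficiency)
#'
#' The spike-in RNA is added to each sample before extraction, so the
#' fraction of it recovered by RT-ddPCR measures the per-sample processing
#' efficiency: `efficiency = measured / expected`. Values above 1 are
#' allowed (they indicate a suspect expected-input calibration) but raise
#' a warning.
#'
#' @param measured_spike Measured spike copies/reaction (>= 0).
#' @param expected_spike Expected spike copies/reaction (> 0); either an
#'   absolute calibration or, in batch-relative mode, the batch mean
#'   recovery.
#' @return The efficiency as a plain number.
#' @export
spike_recovery <- function(measured_spike, expected_spike) {
  if (!is.finite(expected_spike) || expected_spike <= 0)
    stop("expected_spike must be > 0", call. = FALSE)
  if (!is.finite(measured_spike) || measured_spike < 0)
    stop("measured_spike must be >= 0", call. = FALSE)
  eff <- measured_spike / expected_spike
  if (eff > 1)
    warning("spike recovery > 1: expected-input calibration suspect",
            call. = FALSE)
  eff
}

#' Correct a raw count for processing losses
#'
#' Losses during purification, DNase treatment and cDNA synthesis hit the
#' spike-in and the endogenous target proportionally, so dividing the raw
#' count by the measured processing efficiency recovers the pre-loss
#' quantity: `corrected = raw / efficiency`.
#'
#' @param raw Raw copies/reaction (>= 0).
#' @param efficiency Processing efficiency (> 0), e.g. from
#'   [spike_recovery()].
#' @return Corrected copies/reaction.
#' @export
correct_by_efficiency <- function(raw, efficiency) {
  if (!is.finite(efficiency) || efficiency <= 0)
    stop("efficiency must be > 0", call. = FALSE)
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("raw must be finite and >= 0", call. = FALSE)
  raw / efficiency
}

#' Normalize a target count to an endogenous reference gene
#'
#' Expresses the target as a ratio to a stably expressed reference gene
#' measured in the same reaction, controlling for biological input. When
#' standard errors of both estimates are supplied, a 95% CI is propagated
#' by the delta method for a ratio of independent estimates:
#' `SE(ratio)/ratio = sqrt((SE_t/t)^2 + (SE_r/r)^2)`.
#'
#' @param cif Target copies/reaction (>= 0).
#' @param reference Reference-gene copies/reaction. A zero reference gives
#'   an undefined-result flag, not an infinity.
#' @param cif_se,reference_se Optional standard errors on the
#'   copies/reaction scale for CI propagation.
#' @return A list: `ratio`, `ci95_low`, `ci95_high` (NA when no SEs
#'   given), and `undefined` (TRUE when `reference == 0`).
#' @export
normalize_to_reference <- function(cif, reference,
                                   cif_se = NULL, reference_se = NULL) {
  if (!is.finite(cif) || cif < 0)
    stop("cif must be finite and >= 0", call. = FALSE)
  if (!is.finite(reference) || reference < 0)
    stop("reference must be finite and >= 0", call. = FALSE)
  if (reference == 0) {
    return(list(ratio = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
                undefined = TRUE))
  }
  ratio <- cif / reference
  lo <- hi <- NA_real_
  if (!is.null(cif_se) && !is.null(reference_se) && cif > 0) {
    rel_se <- sqrt((cif_se / cif)^2 + (reference_se / reference)^2)
    z <- stats::qnorm(0.975)
    lo <- max(0, ratio * (1 - z * rel_se))
    hi <- ratio * (1 + z * rel_se)
  }
  list(ratio = ratio, ci95_low = lo, ci95_high = hi, undefined = FALSE)
}

#' RNA sample metadata
#'
#' @param sample_id Identifier.
#' @param n_testis_pairs Number of testis pairs the RNA was extracted from
#'   (>= 1).
#' @param conc_ng_per_ul Measured RNA concentration, ng/µL.
#' @param elution_volume_ul Elution volume, µL (default 25).
#' @param a260_280,a260_230 Optional purity ratios.
#' @return An object of class `rna_sample`.
#' @export
rna_sample <- function(sample_id, n_testis_pairs, conc_ng_per_ul,
                       elution_volume_ul = 25,
                       a260_280 = NA_real_, a260_230 = NA_real_) {
  if (n_testis_pairs < 1) stop("n_testis_pairs must be >= 1", call. = FALSE)
  if (conc_ng_per_ul < 0 || elution_volume_ul < 0)
    stop("concentration and volume must be >= 0", call. = FALSE)
  structure(
    list(sample_id = sample_id, n_testis_pairs = n_testis_pairs,
         conc_ng_per_ul = conc_ng_per_ul,
         elution_volume_ul = elution_volume_ul,
         a260_280 = a260_280, a260_230 = a260_230),
    class = "rna_sample"
  )
}

#' Per-input-unit RNA yield
#'
#' Normalizes an RNA sample's yield to the number of testis pairs it was
#' extracted from.
#'
#' @param sample An [rna_sample()].
#' @return A list: `ng_per_ul_per_pair` (= concentration / pairs) and
#'   `total_ng` (= concentration x elution volume).
#' @export
per_unit_yield <- function(sample) {
  stopifnot(inherits(sample, "rna_sample"))
  list(
    ng_per_ul_per_pair = sample$conc_ng_per_ul / sample$n_testis_pairs,
    total_ng = sample$conc_ng_per_ul * sample$elution_volume_ul
  )
}

#' Testis-pair equivalents of a dilution level
#'
#' A dilution of cDNA derived from `n` testis pairs corresponds to
#' `n x base^exponent` pair-equivalents of input; e.g. the 5^-2 dilution of
#' a 20-pair sample is equivalent to 0.8 testis pairs.
#'
#' @param n_pairs_at_full_strength Pairs in the undiluted sample.
#' @param dilution_base Integer dilution factor (>= 2).
#' @param exponent Non-positive integer dilution exponent.
#' @return Testis-pair equivalents.
#' @export
equivalent_input <- function(n_pairs_at_full_strength, dilution_base, exponent) {
  if (dilution_base < 2) stop("dilution_base must be >= 2", call. = FALSE)
  if (exponent > 0) stop("exponent must be <= 0", call. = FALSE)
  n_pairs_at_full_strength * dilution_base^exponent
}
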