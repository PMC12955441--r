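#' Simulator parameters for a duplex droplet reaction
#'
#' Bundles the cluster amplitude model, droplet geometry and artefact
#' coefficients that drive [simulate_reaction()]. Defaults reproduce the
#' amplitude structure typical of the cifA/spike duplex assay on a QX200
#' reader: FAM negatives near 700 a.u. and positives near 9,600 a.u., HEX
#' negatives near 1,030 a.u. and positives near 4,280 a.u., with amplitude
#' SDs of 3% of the respective cluster mean.
#'
#' Two droplet-level artefacts of duplex assays are modelled:
#' * *amplitude competition*: in double-positive droplets the two targets
#'   compete for reagents, pulling the HEX positive mean down by the factor
#'   `competition_kappa` (an intermediate HEX cluster);
#' * *spectral crosstalk*: a fraction `crosstalk_alpha` of the FAM signal
#'   above the FAM negative baseline bleeds into the HEX channel of every
#'   droplet.
#'
#' @param n_droplets Number of droplets in the reaction (QX200 wells
#'   typically partition into 10,000-20,000 droplets).
#' @param droplet_volume_nl Droplet volume in nanoliters.
#' @param fam_neg_mean,fam_neg_sd,fam_pos_mean,fam_pos_sd FAM cluster
#'   amplitude means/SDs (arbitrary units).
#' @param hex_neg_mean,hex_neg_sd,hex_pos_mean,hex_pos_sd HEX cluster
#'   amplitude means/SDs.
#' @param crosstalk_alpha Fraction of FAM-above-baseline amplitude added to
#'   the HEX amplitude of every droplet; in `[0, 1)`.
#' @param competition_kappa Multiplier in `(0, 1]` applied to the HEX
#'   positive mean in double-positive droplets.
#' @param ntc_contamination_rate Background contamination in no-template
#'   controls, copies/µL.
#' @param rain_fraction Fraction of droplets whose amplitudes are redrawn
#'   uniformly between the cluster means ("rain"), for threshold
#'   robustness testing. Default 0 (no rain).
#' @param seed Default integer seed used when a simulation call does not
#'   supply one.
#'
#' @return An object of class `simulation_params`.
#' @seealso [true_concentrations()], [simulate_reaction()]
#' @export
simulation_params <- function(n_droplets = 15000,
                              droplet_volume_nl = 0.85,
                              fam_neg_mean = 700, fam_neg_sd = 0.03 * fam_neg_mean,
                              fam_pos_mean = 9603, fam_pos_sd = 0.03 * fam_pos_mean,
                              hex_neg_mean = 1032, hex_neg_sd = 0.03 * hex_neg_mean,
                              hex_pos_mean = 4284, hex_pos_sd = 0.03 * hex_pos_mean,
                              crosstalk_alpha = 0.05,
                              competition_kappa = 0.5,
                              ntc_contamination_rate = 0.005,
                              rain_fraction = 0,
                              seed = 1L) {
  p <- list(
    n_droplets = as.integer(n_droplets),
    droplet_volume_nl = droplet_volume_nl,
    fam_neg_mean = fam_neg_mean, fam_neg_sd = fam_neg_sd,
    fam_pos_mean = fam_pos_mean, fam_pos_sd = fam_pos_sd,
    hex_neg_mean = hex_neg_mean, hex_neg_sd = hex_neg_sd,
    hex_pos_mean = hex_pos_mean, hex_pos_sd = hex_pos_sd,
    crosstalk_alpha = crosstalk_alpha,
    competition_kappa = competition_kappa,
    ntc_contamination_rate = ntc_contamination_rate,
    rain_fraction = rain_fraction,
    seed = as.integer(seed)
  )
  class(p) <- "simulation_params"
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  stopifnot(inherits(p, "simulation_params"))
  if (!is.finite(p$n_droplets) || p$n_droplets <= 0)
    stop("n_droplets must be a positive integer", call. = FALSE)
  if (!is.finite(p$droplet_volume_nl) || p$droplet_volume_nl <= 0)
    stop("droplet_volume_nl must be > 0", call. = FALSE)
  sds <- c(p$fam_neg_sd, p$fam_pos_sd, p$hex_neg_sd, p$hex_pos_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("amplitude SDs must be finite and >= 0", call. = FALSE)
  if (p$fam_pos_mean <= p$fam_neg_mean || p$hex_pos_mean <= p$hex_neg_mean)
    stop("positive cluster means must exceed negative cluster means", call. = FALSE)
  if (!(p$competition_kappa > 0 && p$competition_kappa <= 1))
    stop("competition_kappa must be in (0, 1]", call. = FALSE)
  if (!(p$crosstalk_alpha >= 0 && p$crosstalk_alpha < 1))
    stop("crosstalk_alpha must be in [0, 1)", call. = FALSE)
  if (!(p$rain_fraction >= 0 && p$rain_fraction < 1))
    stop("rain_fraction must be in [0, 1)", call. = FALSE)
  if (!is.finite(p$ntc_contamination_rate) || p$ntc_contamination_rate < 0)
    stop("ntc_contamination_rate must be >= 0", call. = FALSE)
  invisible(p)
}

#' Ground-truth target concentrations for the simulator
#'
#' Carrier of the true concentrations (copies/µL in the assembled reaction
#' mix) of the FAM-channel target (cif transcript) and the HEX-channel
#' target (spike-in RNA or reference gene); used to drive
#' [simulate_reaction()] and score parameter recovery.
#'
#' @param fam_target_copies_per_ul,hex_target_copies_per_ul True
#'   concentrations, copies/µL; must be finite and >= 0.
#' @return An object of class `true_concentrations`.
#' @export
true_concentrations <- function(fam_target_copies_per_ul,
                                hex_target_copies_per_ul) {
  if (!is.finite(fam_target_copies_per_ul) || fam_target_copies_per_ul < 0 ||
      !is.finite(hex_target_copies_per_ul) || hex_target_copies_per_ul < 0)
    stop("target concentrations must be finite and >= 0", call. = FALSE)
  structure(
    list(fam_target_copies_per_ul = fam_target_copies_per_ul,
         hex_target_copies_per_ul = hex_target_copies_per_ul),
    class = "true_concentrations"
  )
}
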