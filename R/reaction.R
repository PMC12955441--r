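#' Per-droplet two-channel amplitude data for one reaction well
#'
#' The atomic observable of the pipeline: one row per droplet with FAM and
#' HEX fluorescence amplitudes, plus the reaction metadata needed to turn
#' droplet counts into copies/reaction.
#'
#' @param fam_amplitudes,hex_amplitudes Numeric vectors of equal length,
#'   one entry per droplet; all values must be finite.
#' @param well_id,assay_name Identifiers carried through to outputs.
#' @param reaction_volume_ul Assembled reaction volume in µL (default 20).
#' @param droplet_volume_nl Droplet volume in nanoliters (default 0.85).
#' @param dilution_exponent,replicate_id Optional dilution-series metadata.
#' @param is_ntc Flag marking a no-template control well.
#' @param annealing_temp_c Optional annealing temperature, carried as
#'   metadata only.
#' @param truth Optional ground-truth attachment from the simulator: a list
#'   with per-droplet occupancy logicals and the generating
#'   [true_concentrations()].
#'
#' @return An object of class `droplet_reaction`: a list with a `droplets`
#'   tibble (`droplet_index`, `fam_amplitude`, `hex_amplitude`) and the
#'   metadata fields.
#' @export
droplet_reaction <- function(fam_amplitudes, hex_amplitudes,
                             well_id = "A01", assay_name = "assay",
                             reaction_volume_ul = 20,
                             droplet_volume_nl = 0.85,
                             dilution_exponent = NULL,
                             replicate_id = NULL,
                             is_ntc = FALSE,
                             annealing_temp_c = NULL,
                             truth = NULL) {
  if (length(fam_amplitudes) != length(hex_amplitudes))
    stop("fam and hex amplitude vectors must have equal length", call. = FALSE)
  if (length(fam_amplitudes) == 0)
    stop("a reaction must contain at least one droplet", call. = FALSE)
  if (any(!is.finite(fam_amplitudes)) || any(!is.finite(hex_amplitudes)))
    stop("all amplitudes must be finite", call. = FALSE)
  if (!is.finite(reaction_volume_ul) || reaction_volume_ul <= 0)
    stop("reaction_volume_ul must be > 0", call. = FALSE)
  if (!is.finite(droplet_volume_nl) || droplet_volume_nl <= 0)
    stop("droplet_volume_nl must be > 0", call. = FALSE)
  structure(
    list(
      well_id = well_id,
      assay_name = assay_name,
      droplets = tibble::tibble(
        droplet_index = seq_along(fam_amplitudes),
        fam_amplitude = as.numeric(fam_amplitudes),
        hex_amplitude = as.numeric(hex_amplitudes)
      ),
      reaction_volume_ul = reaction_volume_ul,
      droplet_volume_nl = droplet_volume_nl,
      dilution_exponent = dilution_exponent,
      replicate_id = replicate_id,
      is_ntc = isTRUE(is_ntc),
      annealing_temp_c = annealing_temp_c,
      truth = truth
    ),
    class = "droplet_reaction"
  )
}

#' @export
print.droplet_reaction <- function(x, ...) {
  cat(sprintf("<droplet_reaction> well %s, assay %s: %d droplets%s\n",
              x$well_id, x$assay_name, nrow(x$droplets),
              if (x$is_ntc) " [NTC]" else ""))
  if (!is.null(x$dilution_exponent))
    cat(sprintf("  dilution exponent %d, replicate %s\n",
                x$dilution_exponent, format(x$replicate_id)))
  invisible(x)
}

n_droplets <- function(reaction) nrow(reaction$droplets)

#' Droplet-count quality control for a reaction well
#'
#' Wells that partition into too few droplets give unstable Poisson
#' estimates and are excluded; the conventional floor is 10,000 droplets
#' per well.
#'
#' @param reaction A [droplet_reaction()].
#' @param min_droplets Minimum droplet count to pass (default 10,000).
#'   A well with *fewer* than this many droplets fails; the boundary
#'   count itself passes.
#' @return `TRUE` if the well passes, `FALSE` otherwise.
#' @export
qc_reaction <- function(reaction, min_droplets = 10000) {
  stopifnot(inherits(reaction, "droplet_reaction"))
  n_droplets(reaction) >= min_droplets
}
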