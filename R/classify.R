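#' Channel thresholds for droplet classification
#'
#' Container for the FAM and HEX amplitude cutoffs plus the estimated
#' crosstalk coefficient. Two HEX cutoffs are carried: `hex_cutoff` applies
#' to FAM-negative droplets, and `hex_cutoff_fampos` to FAM-positive ones.
#' The split exists because amplitude competition in double-positive
#' droplets pulls the HEX positive cluster towards the baseline, so the
#' HEX boundary that separates negatives from single positives is too high
#' for the competed double-positive cluster; fitting the boundary within
#' each FAM stratum resolves this, and the two cutoffs coincide when no
#' competition is present.
#'
#' @param fam_cutoff,hex_cutoff Amplitude cutoffs.
#' @param hex_cutoff_fampos HEX cutoff applied to FAM-positive droplets
#'   (defaults to `hex_cutoff`).
#' @param crosstalk_alpha_hat Estimated spectral bleed coefficient
#'   (HEX units gained per FAM unit above baseline); 0 when not estimable.
#' @param fam_neg_mean_hat Estimated FAM negative-cluster mean, the
#'   baseline used in crosstalk compensation.
#' @param fam_single_cluster,hex_single_cluster Flags set when a channel
#'   shows only one amplitude cluster (e.g. an all-negative NTC); the
#'   corresponding cutoff then sits above all observations by design.
#' @return An object of class `channel_thresholds`.
#' @export
channel_thresholds <- function(fam_cutoff, hex_cutoff,
                               hex_cutoff_fampos = hex_cutoff,
                               crosstalk_alpha_hat = 0,
                               fam_neg_mean_hat = NA_real_,
                               fam_single_cluster = FALSE,
                               hex_single_cluster = FALSE) {
  stopifnot(is.finite(fam_cutoff), is.finite(hex_cutoff),
            is.finite(hex_cutoff_fampos))
  structure(
    list(fam_cutoff = unname(fam_cutoff), hex_cutoff = unname(hex_cutoff),
         hex_cutoff_fampos = unname(hex_cutoff_fampos),
         crosstalk_alpha_hat = unname(crosstalk_alpha_hat),
         fam_neg_mean_hat = unname(fam_neg_mean_hat),
         fam_single_cluster = isTRUE(fam_single_cluster),
         hex_single_cluster = isTRUE(hex_single_cluster)),
    class = "channel_thresholds"
  )
}

# Deterministic 1D two-cluster split: Lloyd's k-means initialized at the
# 5th/95th amplitude percentiles. Declares a single cluster when the two
# means are closer than 4x the pooled within-cluster SD, in which case the
# cutoff is placed at mean + 5 SD so an all-negative channel yields zero
# positives.
split_two_clusters <- function(x, max_iter = 100) {
  q <- unname(stats::quantile(x, c(0.05, 0.95)))
  if (diff(q) <= 0 || stats::sd(x) == 0) {
    return(list(cutoff = mean(x) + 5 * max(stats::sd(x), 1e-8),
                low_mean = mean(x), high_mean = NA_real_,
                single_cluster = TRUE, assignment = rep(1L, length(x))))
  }
  km <- stats::kmeans(x, centers = matrix(q, ncol = 1), iter.max = max_iter,
                      algorithm = "Lloyd")
  ord <- order(km$centers[, 1])
  m_lo <- km$centers[ord[1], 1]
  m_hi <- km$centers[ord[2], 1]
  cl <- ifelse(km$cluster == ord[1], 1L, 2L)
  n1 <- sum(cl == 1L); n2 <- sum(cl == 2L)
  pooled_sd <- sqrt(km$tot.withinss / max(length(x) - 2, 1))
  if (n1 == 0 || n2 == 0 || (m_hi - m_lo) < 4 * pooled_sd) {
    list(cutoff = mean(x) + 5 * stats::sd(x), low_mean = mean(x),
         high_mean = NA_real_, single_cluster = TRUE,
         assignment = rep(1L, length(x)))
  } else {
    list(cutoff = (m_lo + m_hi) / 2, low_mean = m_lo, high_mean = m_hi,
         single_cluster = FALSE, assignment = cl)
  }
}

#' Fit classification thresholds for a droplet reaction
#'
#' Fits a deterministic amplitude cutoff per channel, estimates the
#' spectral crosstalk coefficient, and (when resolvable) a separate HEX
#' cutoff for the FAM-positive stratum to handle amplitude competition.
#'
#' Procedure:
#' 1. FAM cutoff from a two-cluster split of all FAM amplitudes (1D
#'    k-means initialized at the 5th/95th percentiles; midpoint of the two
#'    cluster means; single-cluster rule: if the means differ by less than
#'    4x the pooled within-cluster SD, cutoff = mean + 5 SD).
#' 2. HEX cutoff from the same split applied to the FAM-negative droplets
#'    (which carry essentially no crosstalk); falls back to all droplets
#'    when the FAM-negative stratum is small.
#' 3. Among FAM-positive droplets, a two-cluster split of the HEX
#'    amplitudes identifies the FAM-only cloud; the crosstalk coefficient
#'    is the least-squares slope of HEX on FAM within that cloud when it
#'    has at least 50 members, else 0. The FAM-positive HEX cutoff is the
#'    midpoint of the two crosstalk-compensated cluster means, or the
#'    global HEX cutoff when the stratum does not resolve two clusters.
#'
#' @param reaction A [droplet_reaction()] with at least 100 droplets.
#' @param min_crosstalk_n Minimum FAM-positive/HEX-negative droplets
#'   required to estimate the crosstalk slope (default 50).
#' @return A [channel_thresholds()].
#' @export
fit_thresholds <- function(reaction, min_crosstalk_n = 50) {
  stopifnot(inherits(reaction, "droplet_reaction"))
  d <- reaction$droplets
  if (nrow(d) < 100)
    stop("cannot fit thresholds on fewer than 100 droplets", call. = FALSE)

  fam_fit <- split_two_clusters(d$fam_amplitude)
  fam_pos <- d$fam_amplitude > fam_fit$cutoff
  fam_neg_mean_hat <- fam_fit$low_mean

  hex_base <- if (sum(!fam_pos) >= 100) d$hex_amplitude[!fam_pos] else d$hex_amplitude
  hex_fit <- split_two_clusters(hex_base)

  alpha_hat <- 0
  hex_cutoff_fampos <- hex_fit$cutoff
  if (sum(fam_pos) >= 100) {
    fp_fam <- d$fam_amplitude[fam_pos]
    fp_hex <- d$hex_amplitude[fam_pos]
    fp_fit <- split_two_clusters(fp_hex)
    low <- fp_fit$assignment == 1L
    if (fp_fit$single_cluster) {
      # all FAM-positive droplets share one HEX cluster: either all
      # FAM-only or all double-positive; regress on the whole stratum
      low <- rep(TRUE, length(fp_hex))
    }
    if (sum(low) >= min_crosstalk_n && stats::sd(fp_fam[low]) > 0) {
      alpha_hat <- unname(stats::coef(stats::lm(fp_hex[low] ~ fp_fam[low]))[2])
      alpha_hat <- max(0, alpha_hat)
    }
    if (!fp_fit$single_cluster) {
      comp <- fp_hex - alpha_hat * pmax(0, fp_fam - fam_neg_mean_hat)
      m_lo <- mean(comp[low]); m_hi <- mean(comp[!low])
      hex_cutoff_fampos <- (m_lo + m_hi) / 2
    } else {
      hex_cutoff_fampos <- hex_fit$cutoff
    }
  }

  channel_thresholds(
    fam_cutoff = fam_fit$cutoff, hex_cutoff = hex_fit$cutoff,
    hex_cutoff_fampos = hex_cutoff_fampos,
    crosstalk_alpha_hat = alpha_hat,
    fam_neg_mean_hat = fam_neg_mean_hat,
    fam_single_cluster = fam_fit$single_cluster,
    hex_single_cluster = hex_fit$single_cluster
  )
}

#' Classify droplets into the four duplex classes
#'
#' Assigns every droplet exactly one of `negative`, `fam_only`,
#' `hex_only`, `double`. FAM positivity is raw amplitude vs `fam_cutoff`
#' and never depends on the HEX state. HEX amplitudes are first
#' crosstalk-compensated (`hex - alpha_hat * max(0, fam - fam_neg_mean)`),
#' then compared against `hex_cutoff` (FAM-negative droplets) or
#' `hex_cutoff_fampos` (FAM-positive droplets, where amplitude competition
#' lowers the positive cluster).
#'
#' @param reaction A [droplet_reaction()].
#' @param thresholds A [channel_thresholds()], typically from
#'   [fit_thresholds()]. A cutoff outside the observed amplitude range is
#'   rejected unless its channel is flagged single-cluster.
#' @return An object of class `classified_droplets`: per-droplet `labels`
#'   plus class counts `n_total`, `n_negative`, `n_fam_only`, `n_hex_only`,
#'   `n_double`, and the thresholds used.
#' @export
classify_droplets <- function(reaction, thresholds) {
  stopifnot(inherits(reaction, "droplet_reaction"),
            inherits(thresholds, "channel_thresholds"))
  d <- reaction$droplets
  check_range <- function(cutoff, x, single, channel) {
    if (!single && (cutoff <= min(x) || cutoff >= max(x)))
      stop(sprintf("%s cutoff %.1f lies outside the observed amplitude range [%.1f, %.1f]",
                   channel, cutoff, min(x), max(x)), call. = FALSE)
  }
  check_range(thresholds$fam_cutoff, d$fam_amplitude,
              thresholds$fam_single_cluster, "FAM")
  check_range(thresholds$hex_cutoff, d$hex_amplitude,
              thresholds$hex_single_cluster, "HEX")

  fam_pos <- d$fam_amplitude > thresholds$fam_cutoff
  baseline <- thresholds$fam_neg_mean_hat
  if (!is.finite(baseline)) baseline <- min(d$fam_amplitude)
  comp_hex <- d$hex_amplitude -
    thresholds$crosstalk_alpha_hat * pmax(0, d$fam_amplitude - baseline)
  hex_pos <- ifelse(fam_pos,
                    comp_hex > thresholds$hex_cutoff_fampos,
                    comp_hex > thresholds$hex_cutoff)

  labels <- factor(ifelse(fam_pos & hex_pos, "double",
                   ifelse(fam_pos, "fam_only",
                   ifelse(hex_pos, "hex_only", "negative"))),
                   levels = c("negative", "fam_only", "hex_only", "double"))
  counts <- table(labels)
  structure(
    list(labels = labels,
         n_total = nrow(d),
         n_negative = unname(counts[["negative"]]),
         n_fam_only = unname(counts[["fam_only"]]),
         n_hex_only = unname(counts[["hex_only"]]),
         n_double = unname(counts[["double"]]),
         thresholds = thresholds,
         well_id = reaction$well_id,
         assay_name = reaction$assay_name,
         reaction_volume_ul = reaction$reaction_volume_ul,
         droplet_volume_nl = reaction$droplet_volume_nl,
         is_ntc = reaction$is_ntc),
    class = "classified_droplets"
  )
}

#' @export
print.classified_droplets <- function(x, ...) {
  cat(sprintf("<classified_droplets> well %s: %d droplets (neg %d, FAM-only %d, HEX-only %d, double %d)\n",
              x$well_id, x$n_total, x$n_negative, x$n_fam_only,
              x$n_hex_only, x$n_double))
  invisible(x)
}
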