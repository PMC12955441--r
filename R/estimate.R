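#' Poisson absolute concentration estimate for one channel
#'
#' Converts droplet counts into an absolute concentration by the digital
#' PCR Poisson correction. With `p = n_positive / n_total` the mean
#' occupancy per droplet is `lambda = -ln(1 - p)`, which corrects for
#' droplets containing more than one target molecule; then
#' `copies/µL = lambda / (droplet volume in µL)` and
#' `copies/reaction = copies/µL x reaction volume`. Both single- and
#' double-positive droplets count as positive for a channel.
#'
#' The 95% CI uses the delta method on lambda,
#' `SE(lambda) = sqrt(p / (n (1 - p)))`, switching to exact
#' Clopper-Pearson bounds on `p` (transformed through `-ln(1 - p)`) when
#' `n_positive <= 5` or `n_negative <= 5`. A fully positive well
#' (`n_positive == n_total`) has no finite estimate and is returned with
#' `saturated = TRUE` and infinite `lambda_hat`/upper bound.
#'
#' @param classified A [classified_droplets()].
#' @param channel `"FAM"` or `"HEX"`.
#' @param reaction_volume_ul,droplet_volume_nl Volumes; default to the
#'   values carried by `classified`.
#' @param target_name Label for the estimate; defaults to the channel.
#' @param min_droplets QC floor forwarded to the `qc_pass` flag.
#' @return An object of class `concentration_estimate` with fields
#'   `target_name`, `n_droplets`, `n_positive`, `lambda_hat`,
#'   `copies_per_ul`, `copies_per_reaction`, `ci95_low`, `ci95_high`
#'   (copies/reaction scale), `se_lambda`, `saturated`, `qc_pass`, plus the
#'   volumes used.
#' @export
estimate_concentration <- function(classified, channel = c("FAM", "HEX"),
                                   reaction_volume_ul = classified$reaction_volume_ul,
                                   droplet_volume_nl = classified$droplet_volume_nl,
                                   target_name = NULL,
                                   min_droplets = 10000) {
  stopifnot(inherits(classified, "classified_droplets"))
  channel <- match.arg(channel)
  n <- classified$n_total
  if (n == 0) stop("cannot estimate from zero droplets", call. = FALSE)
  x <- if (channel == "FAM") classified$n_fam_only + classified$n_double
       else classified$n_hex_only + classified$n_double
  if (is.null(target_name)) target_name <- channel

  vd_ul <- droplet_volume_nl * 1e-3
  scale <- reaction_volume_ul / vd_ul   # lambda -> copies/reaction
  p_hat <- x / n
  saturated <- x == n

  if (saturated) {
    lambda_hat <- Inf
    lam_lo <- -log(1 - stats::qbeta(0.025, x, n - x + 1))
    lam_hi <- Inf
  } else {
    lambda_hat <- -log(1 - p_hat)
    if (x <= 5 || (n - x) <= 5) {
      p_lo <- if (x == 0) 0 else stats::qbeta(0.025, x, n - x + 1)
      p_hi <- stats::qbeta(0.975, x + 1, n - x)
      lam_lo <- -log(1 - p_lo)
      lam_hi <- -log(1 - p_hi)
    } else {
      se <- sqrt(p_hat / (n * (1 - p_hat)))
      z <- stats::qnorm(0.975)
      lam_lo <- max(0, lambda_hat - z * se)
      lam_hi <- lambda_hat + z * se
    }
  }
  se_lambda <- if (saturated) Inf else sqrt(p_hat / (n * (1 - p_hat)))

  structure(
    list(
      target_name = target_name,
      well_id = classified$well_id,
      assay_name = classified$assay_name,
      channel = channel,
      n_droplets = n,
      n_positive = x,
      lambda_hat = lambda_hat,
      se_lambda = se_lambda,
      copies_per_ul = lambda_hat / vd_ul,
      copies_per_reaction = lambda_hat * scale,
      ci95_low = lam_lo * scale,
      ci95_high = lam_hi * scale,
      saturated = saturated,
      reaction_volume_ul = reaction_volume_ul,
      droplet_volume_nl = droplet_volume_nl,
      qc_pass = n >= min_droplets,
      is_ntc = isTRUE(classified$is_ntc)
    ),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("<concentration_estimate> %s (%s) well %s: %d/%d positive\n",
              x$target_name, x$channel, x$well_id, x$n_positive, x$n_droplets))
  if (x$saturated) {
    cat("  saturated well: all droplets positive, no finite estimate\n")
  } else {
    cat(sprintf("  %.2f copies/reaction (95%% CI %.2f-%.2f), %.3f copies/µL%s\n",
                x$copies_per_reaction, x$ci95_low, x$ci95_high,
                x$copies_per_ul, if (x$qc_pass) "" else " [QC FAIL]"))
  }
  invisible(x)
}

#' One-call quantification of a droplet reaction
#'
#' Convenience wrapper: fits thresholds, classifies, and estimates both
#' channels of a well.
#'
#' @param reaction A [droplet_reaction()].
#' @param thresholds Optional [channel_thresholds()]; fitted from the well
#'   when missing.
#' @param min_droplets QC floor (default 10,000).
#' @return A list with elements `FAM` and `HEX`, each a
#'   [estimate_concentration()] result, plus `classified`.
#' @export
quantify_reaction <- function(reaction, thresholds = NULL,
                              min_droplets = 10000) {
  if (is.null(thresholds)) thresholds <- fit_thresholds(reaction)
  cl <- classify_droplets(reaction, thresholds)
  list(
    FAM = estimate_concentration(cl, "FAM", min_droplets = min_droplets),
    HEX = estimate_concentration(cl, "HEX", min_droplets = min_droplets),
    classified = cl
  )
}

#' Limit of detection from no-template controls
#'
#' The LOD of an assay is the upper limit of the 95% confidence interval
#' of the no-template controls, rounded up to whole copies/reaction;
#' signals below it are indistinguishable from background.
#'
#' With two or more NTC wells the LOD is the across-replicate t-interval
#' upper bound, `mean + t(0.975, n-1) * SD / sqrt(n)` on copies/reaction.
#' With a single well it is that well's own `ci95_high`. When every NTC
#' measured exactly zero copies the across-replicate interval degenerates
#' to zero, so the wells are pooled and the exact Clopper-Pearson upper
#' bound on the pooled positive fraction is converted to copies/reaction;
#' the LOD is therefore never exactly zero.
#'
#' @param ntc_estimates List of [estimate_concentration()] results from
#'   NTC wells; all must share a target name and pass droplet-count QC.
#' @return An object of class `lod_result`: `target_name`,
#'   `lod_copies_per_reaction` (continuous), `lod_rounded_up` (integer
#'   ceiling), `n_ntc_reactions`, `method_note`.
#' @export
compute_lod <- function(ntc_estimates) {
  if (length(ntc_estimates) == 0)
    stop("at least one NTC estimate is required", call. = FALSE)
  stopifnot(all(vapply(ntc_estimates, inherits, logical(1),
                       "concentration_estimate")))
  targets <- unique(vapply(ntc_estimates, `[[`, character(1), "target_name"))
  if (length(targets) > 1)
    stop("NTC estimates mix target names: ", paste(targets, collapse = ", "),
         call. = FALSE)
  if (!all(vapply(ntc_estimates, `[[`, logical(1), "qc_pass")))
    stop("all NTC estimates must pass droplet-count QC", call. = FALSE)

  copies <- vapply(ntc_estimates, `[[`, numeric(1), "copies_per_reaction")
  n <- length(copies)

  pooled_upper <- function() {
    x <- sum(vapply(ntc_estimates, `[[`, numeric(1), "n_positive"))
    nd <- sum(vapply(ntc_estimates, `[[`, numeric(1), "n_droplets"))
    p_hi <- stats::qbeta(0.975, x + 1, nd - x)
    vd_ul <- ntc_estimates[[1]]$droplet_volume_nl * 1e-3
    -log(1 - p_hi) / vd_ul * ntc_estimates[[1]]$reaction_volume_ul
  }

  if (n == 1) {
    lod <- ntc_estimates[[1]]$ci95_high
    note <- "single NTC well: within-reaction 95% CI upper bound"
    if (lod <= 0) {
      lod <- pooled_upper()
      note <- "single all-zero NTC well: Clopper-Pearson upper bound"
    }
  } else {
    m <- mean(copies); s <- stats::sd(copies)
    if (s == 0 && m == 0) {
      lod <- pooled_upper()
      note <- sprintf("%d all-zero NTC wells: pooled Clopper-Pearson upper bound", n)
    } else {
      lod <- m + stats::qt(0.975, n - 1) * s / sqrt(n)
      note <- sprintf("across-replicate t-interval upper bound over %d NTC wells", n)
    }
  }

  structure(
    list(target_name = targets, lod_copies_per_reaction = lod,
         lod_rounded_up = as.integer(ceiling(lod)),
         n_ntc_reactions = n, method_note = note),
    class = "lod_result"
  )
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> %s: LOD %.3f copies/reaction (rounded up: %d) from %d NTC well(s)\n  %s\n",
              x$target_name, x$lod_copies_per_reaction, x$lod_rounded_up,
              x$n_ntc_reactions, x$method_note))
  invisible(x)
}
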