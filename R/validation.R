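#' Percent reduction between paired measurements
#'
#' Used e.g. for genomic-DNA carryover audits: the percent of pre-DNase
#' signal removed by a treatment, `100 * (pre - post) / pre`.
#'
#' @param pre_copies Pre-treatment copies/reaction (> 0).
#' @param post_copies Post-treatment copies/reaction (>= 0).
#' @return Percent reduction (full precision; round to two decimals for
#'   display).
#' @export
percent_reduction <- function(pre_copies, post_copies) {
  if (!is.finite(pre_copies) || pre_copies <= 0)
    stop("pre_copies must be > 0", call. = FALSE)
  if (!is.finite(post_copies) || post_copies < 0)
    stop("post_copies must be >= 0", call. = FALSE)
  100 * (pre_copies - post_copies) / pre_copies
}

#' Coefficient of variation between technical replicates
#'
#' `100 * sample SD / mean` with the n-1 denominator; the standard
#' precision statistic for technical replicates of one reaction type.
#'
#' @param estimates Numeric vector of copies/reaction, length >= 2.
#' @return CV in percent, or `NA` (with a warning) when the mean is zero.
#' @export
replicate_cv <- function(estimates) {
  if (length(estimates) < 2)
    stop("replicate_cv needs at least 2 estimates", call. = FALSE)
  m <- mean(estimates)
  if (m == 0) {
    warning("replicate mean is zero: CV undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * stats::sd(estimates) / m
}

#' Linearity and precision of a serial dilution series
#'
#' Assesses dilution-series accuracy the way digital-PCR validations do:
#' Pearson correlation of `log10(copies/reaction)` against
#' `log10(base^exponent)` (log-log scale, since a 1:5 series spans several
#' orders of magnitude and a raw-scale correlation would be dominated by
#' the top level), together with the raw-scale least-squares slope of
#' copies on nominal fraction and the per-level replicate CV. Levels
#' containing any zero estimate cannot enter the log fit and are excluded
#' from it (reported in `excluded_exponents`).
#'
#' @param estimates A data frame (or tibble) with columns `exponent`
#'   (non-positive integers) and `copies_per_reaction`, one row per
#'   technical replicate; or a list of [estimate_concentration()] results
#'   whose wells carry `dilution_exponent` metadata is first converted via
#'   [estimates_to_tibble()].
#' @param base_factor Integer dilution base (>= 2).
#' @param target_name Label carried into the result.
#' @return An object of class `dilution_series_result`: `pearson_r2_log`,
#'   `pearson_p_log`, `slope_loglog`, `slope_raw` (copies/reaction per
#'   unit nominal fraction), `cv_by_level` tibble (`exponent`, `n`,
#'   `mean_copies`, `cv_percent`), `excluded_exponents`, `n_levels_used`.
#' @export
dilution_linearity <- function(estimates, base_factor, target_name = "target") {
  if (base_factor < 2) stop("base_factor must be >= 2", call. = FALSE)
  df <- as.data.frame(estimates)
  if (!all(c("exponent", "copies_per_reaction") %in% names(df)))
    stop("estimates must have columns 'exponent' and 'copies_per_reaction'",
         call. = FALSE)

  exps <- sort(unique(df$exponent), decreasing = TRUE)
  if (length(exps) < 3)
    stop("dilution_linearity needs >= 3 dilution levels", call. = FALSE)

  cv_by_level <- do.call(rbind, lapply(exps, function(k) {
    v <- df$copies_per_reaction[df$exponent == k]
    data.frame(exponent = k, n = length(v), mean_copies = mean(v),
               cv_percent = if (length(v) >= 2 && mean(v) > 0)
                 100 * stats::sd(v) / mean(v) else NA_real_)
  }))
  cv_by_level <- tibble::as_tibble(cv_by_level)

  has_zero <- vapply(exps, function(k)
    any(df$copies_per_reaction[df$exponent == k] <= 0), logical(1))
  excluded <- exps[has_zero]
  usable <- df[df$exponent %in% exps[!has_zero], , drop = FALSE]
  if (length(unique(usable$exponent)) < 3)
    stop("fewer than 3 usable (zero-free) dilution levels", call. = FALSE)

  lx <- log10(base_factor^usable$exponent)
  ly <- log10(usable$copies_per_reaction)
  ct <- stats::cor.test(lx, ly, method = "pearson")
  fit_log <- stats::lm(ly ~ lx)

  frac <- base_factor^df$exponent
  fit_raw <- stats::lm(df$copies_per_reaction ~ frac)

  structure(
    list(target_name = target_name, base_factor = base_factor,
         pearson_r2_log = unname(ct$estimate)^2,
         pearson_p_log = ct$p.value,
         slope_loglog = unname(stats::coef(fit_log)[2]),
         slope_raw = unname(stats::coef(fit_raw)[2]),
         cv_by_level = cv_by_level,
         excluded_exponents = excluded,
         n_levels_used = length(unique(usable$exponent))),
    class = "dilution_series_result"
  )
}

#' @export
print.dilution_series_result <- function(x, ...) {
  cat(sprintf("<dilution_series_result> %s (1:%d series, %d levels in log fit)\n",
              x$target_name, x$base_factor, x$n_levels_used))
  cat(sprintf("  log-log Pearson R^2 = %.4f (p = %.3g), slope = %.4f; raw slope = %.4g\n",
              x$pearson_r2_log, x$pearson_p_log, x$slope_loglog, x$slope_raw))
  if (length(x$excluded_exponents))
    cat("  levels excluded from log fit (zero estimates): ",
        paste(x$excluded_exponents, collapse = ", "), "\n")
  invisible(x)
}

#' Collect per-well estimates into a tidy table
#'
#' @param estimates List of [estimate_concentration()] results.
#' @return A tibble with one row per estimate: well, assay, target,
#'   channel, droplet counts, lambda, concentrations, CI bounds, flags,
#'   and dilution metadata when present.
#' @export
estimates_to_tibble <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  rows <- lapply(estimates, function(e) {
    tibble::tibble(
      well = e$well_id, assay = e$assay_name, target = e$target_name,
      channel = e$channel, n_droplets = e$n_droplets,
      n_positive = e$n_positive, lambda = e$lambda_hat,
      copies_per_ul = e$copies_per_ul,
      copies_per_reaction = e$copies_per_reaction,
      ci_low = e$ci95_low, ci_high = e$ci95_high,
      saturated = e$saturated, qc_pass = e$qc_pass,
      is_ntc = e$is_ntc
    )
  })
  do.call(rbind, rows)
}

#' Test RNA-extraction yield against the expected per-pair slope
#'
#' Fits the least-squares slope of RNA concentration on the number of
#' testis pairs and tests whether the per-sample per-pair yields
#' (`conc_i / pairs_i`) are consistent with that slope (one-sample
#' t-test), i.e. whether recovery is accurate across biomass levels.
#'
#' @param samples List of [rna_sample()]s spanning at least two distinct
#'   pair counts, length >= 3.
#' @return A list: `slope` (fitted, ng/µL per pair), `expected_slope`
#'   (mean per-pair yield), `p_value` (one-sample t-test of per-pair
#'   yields against the fitted slope; 1 with `zero_variance = TRUE` when
#'   the yields are exactly constant), `n`.
#' @export
yield_slope_test <- function(samples) {
  stopifnot(length(samples) >= 3,
            all(vapply(samples, inherits, logical(1), "rna_sample")))
  pairs <- vapply(samples, `[[`, numeric(1), "n_testis_pairs")
  conc <- vapply(samples, `[[`, numeric(1), "conc_ng_per_ul")
  if (length(unique(pairs)) < 2)
    stop("samples must span at least two distinct pair counts", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(conc ~ pairs))[2])
  per_pair <- conc / pairs
  expected <- mean(per_pair)
  if (stats::sd(per_pair) == 0) {
    return(list(slope = slope, expected_slope = expected, p_value = 1,
                zero_variance = TRUE, n = length(samples)))
  }
  tt <- stats::t.test(per_pair, mu = slope)
  list(slope = slope, expected_slope = expected, p_value = tt$p.value,
       zero_variance = FALSE, n = length(samples))
}

#' Paired test of purity improvement
#'
#' Paired t-test of before/after purity ratios (e.g. A260/A280 before and
#' after an ethanol reprecipitation step).
#'
#' @param before,after Numeric vectors of equal length (>= 2 pairs).
#' @return A list: `mean_before`, `mean_after` (full precision; display to
#'   two decimals), `p_value`, `improved` (TRUE when the mean increased),
#'   `zero_variance` flag when all differences are identical.
#' @export
purity_improvement <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must have equal length", call. = FALSE)
  if (length(before) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    return(list(mean_before = mean(before), mean_after = mean(after),
                p_value = if (all(d == 0)) 1 else 0, zero_variance = TRUE,
                improved = mean(d) > 0))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  list(mean_before = mean(before), mean_after = mean(after),
       p_value = tt$p.value, zero_variance = FALSE,
       improved = mean(d) > 0)
}

#' Amplitude separation between positive and negative clusters
#'
#' Difference of the mean amplitudes of positive and negative droplets on
#' each channel; the criterion used to rank annealing temperatures (the
#' optimal temperature maximizes this separation).
#'
#' @param reaction A [droplet_reaction()].
#' @param thresholds A [channel_thresholds()].
#' @return A list with `fam` and `hex` separations (positive mean minus
#'   negative mean); `NA` for a channel whose positive or negative class
#'   is empty.
#' @export
amplitude_separation <- function(reaction, thresholds) {
  cl <- classify_droplets(reaction, thresholds)
  d <- reaction$droplets
  fam_pos <- cl$labels %in% c("fam_only", "double")
  hex_pos <- cl$labels %in% c("hex_only", "double")
  sep <- function(amp, pos) {
    if (!any(pos) || all(pos)) return(NA_real_)
    mean(amp[pos]) - mean(amp[!pos])
  }
  list(fam = sep(d$fam_amplitude, fam_pos),
       hex = sep(d$hex_amplitude, hex_pos))
}
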