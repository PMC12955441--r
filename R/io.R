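#' Write droplet reactions to a CSV (with JSON sidecar for ground truth)
#'
#' One row per droplet with columns `well`, `assay`, `droplet_index`,
#' `fam_amplitude`, `hex_amplitude` plus any dilution metadata; a comment
#' header records the package version. When simulated reactions carry
#' ground truth, the generating concentrations and seeds are serialized to
#' a `<path>.json` sidecar.
#'
#' @param reactions A [droplet_reaction()] or list of them.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar when truth is present (default
#'   TRUE).
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(reactions, path, sidecar = TRUE) {
  if (inherits(reactions, "droplet_reaction")) reactions <- list(reactions)
  stopifnot(length(reactions) >= 1)
  tabs <- lapply(reactions, function(r) {
    tibble::tibble(
      well = r$well_id, assay = r$assay_name,
      droplet_index = r$droplets$droplet_index,
      fam_amplitude = r$droplets$fam_amplitude,
      hex_amplitude = r$droplets$hex_amplitude,
      dilution_exponent = if (is.null(r$dilution_exponent)) NA_integer_
                          else r$dilution_exponent,
      replicate_id = if (is.null(r$replicate_id)) NA_integer_
                     else r$replicate_id,
      is_ntc = r$is_ntc,
      reaction_volume_ul = r$reaction_volume_ul,
      droplet_volume_nl = r$droplet_volume_nl
    )
  })
  out <- do.call(rbind, tabs)
  writeLines(sprintf("# cifquant %s droplet table",
                     as.character(utils::packageVersion("cifquant"))), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  if (sidecar) {
    truths <- lapply(reactions, function(r) {
      if (is.null(r$truth)) return(NULL)
      list(well = r$well_id,
           fam_target_copies_per_ul = r$truth$concentrations$fam_target_copies_per_ul,
           hex_target_copies_per_ul = r$truth$concentrations$hex_target_copies_per_ul,
           seed = r$truth$seed)
    })
    truths <- Filter(Negate(is.null), truths)
    if (length(truths))
      jsonlite::write_json(truths, paste0(path, ".json"), auto_unbox = TRUE,
                           digits = NA)
  }
  invisible(path)
}

#' Read per-droplet amplitude CSVs into droplet reactions
#'
#' Reads a droplet table (as written by [write_droplet_csv()], or any
#' two-channel amplitude export) and groups rows into one
#' [droplet_reaction()] per well. Lines starting with `#` are ignored.
#' Alternative column headers (e.g. `Ch1 Amplitude` / `Ch2 Amplitude`)
#' are mapped via `column_map`.
#'
#' @param path CSV path.
#' @param column_map Named character vector mapping the standard names
#'   (`fam_amplitude`, `hex_amplitude`, `well`, ...) to the file's
#'   headers, e.g. `c(fam_amplitude = "Ch1 Amplitude", hex_amplitude =
#'   "Ch2 Amplitude")`. Files without a well column become a single well
#'   `"A01"`.
#' @param reaction_volume_ul,droplet_volume_nl Defaults for files that do
#'   not carry volume columns.
#' @return A named list of [droplet_reaction()]s, one per well.
#' @export
read_droplet_csv <- function(path, column_map = NULL,
                             reaction_volume_ul = 20,
                             droplet_volume_nl = 0.85) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stop("mapped column not found in file: ", src, call. = FALSE)
      names(df)[names(df) == src] <- std
    }
  }
  needed <- c("fam_amplitude", "hex_amplitude")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("file contains no droplet rows", call. = FALSE)

  for (col in needed) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s at data line %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing %s at data line %d", col, which(is.na(v))[1]),
           call. = FALSE)
    df[[col]] <- v
  }

  if (!"well" %in% names(df)) df$well <- "A01"
  num_or <- function(col, default) {
    if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else
      rep(default, nrow(df))
  }
  df$reaction_volume_ul <- num_or("reaction_volume_ul", reaction_volume_ul)
  df$droplet_volume_nl <- num_or("droplet_volume_nl", droplet_volume_nl)

  wells <- split(df, df$well)
  out <- lapply(wells, function(w) {
    droplet_reaction(
      fam_amplitudes = w$fam_amplitude, hex_amplitudes = w$hex_amplitude,
      well_id = w$well[1],
      assay_name = if ("assay" %in% names(w)) w$assay[1] else "unknown",
      reaction_volume_ul = w$reaction_volume_ul[1],
      droplet_volume_nl = w$droplet_volume_nl[1],
      dilution_exponent = if ("dilution_exponent" %in% names(w) &&
                              !is.na(w$dilution_exponent[1]))
        as.integer(w$dilution_exponent[1]) else NULL,
      replicate_id = if ("replicate_id" %in% names(w) &&
                         !is.na(w$replicate_id[1]))
        as.integer(w$replicate_id[1]) else NULL,
      is_ntc = if ("is_ntc" %in% names(w)) isTRUE(as.logical(w$is_ntc[1]))
               else FALSE
    )
  })
  out[order(names(out))]
}

#' Write a per-well estimates table
#'
#' Deterministic CSV (rows ordered by well then target, full numeric
#' precision, comment header with the package version); two runs on the
#' same inputs produce byte-identical files.
#'
#' @param estimates Non-empty list of [estimate_concentration()] results.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (length(estimates) == 0)
    stop("refusing to write an empty estimates table", call. = FALSE)
  tab <- estimates_to_tibble(estimates)
  tab <- tab[order(tab$well, tab$target), , drop = FALSE]
  writeLines(sprintf("# cifquant %s estimates table",
                     as.character(utils::packageVersion("cifquant"))), path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read an estimates table written by [write_estimates_csv()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_estimates_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
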