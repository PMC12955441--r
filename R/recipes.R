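#' Duplex reaction recipe
#'
#' Volume bookkeeping for an assembled ddPCR reaction: named component
#' volumes in µL, of which `water` and `template` are the displaceable
#' ones (template can grow at the expense of water; everything else is
#' fixed chemistry).
#'
#' @param name Recipe name.
#' @param total_volume_ul Total reaction volume (default 20).
#' @param components Named numeric vector/list of component volumes in µL;
#'   should include `water` and `template` entries.
#' @return An object of class `reaction_recipe`.
#' @export
reaction_recipe <- function(name, total_volume_ul = 20, components) {
  components <- unlist(components)
  if (is.null(names(components)) || any(names(components) == ""))
    stop("all components must be named", call. = FALSE)
  structure(
    list(name = name, total_volume_ul = total_volume_ul,
         components = components),
    class = "reaction_recipe"
  )
}

#' Bundled duplex recipes
#'
#' The two standard 20 µL duplex compositions: the cif/spike recipe
#' (10 µL supermix, 1 µL cif oligo set, 1 µL spike primer mix, 0.5 µL
#' spike probe, water, template) and the cif/reference-gene recipe
#' (10 µL supermix, 1 µL of each of the two oligo sets, water, template).
#'
#' @param template_ul Template volume in µL (default 2); water absorbs
#'   the slack.
#' @return A [reaction_recipe()].
#' @export
cif_spike_recipe <- function(template_ul = 2) {
  fixed <- c(supermix = 10, cif_oligo_set = 1, spike_primer_mix = 1,
             spike_probe = 0.5)
  reaction_recipe("cif/spike duplex", 20,
                  c(fixed, water = 20 - sum(fixed) - template_ul,
                    template = template_ul))
}

#' @rdname cif_spike_recipe
#' @export
cif_bspec_recipe <- function(template_ul = 2) {
  fixed <- c(supermix = 10, cif_oligo_set = 1, bspec_oligo_set = 1)
  reaction_recipe("cif/beta-Spec duplex", 20,
                  c(fixed, water = 20 - sum(fixed) - template_ul,
                    template = template_ul))
}

#' Maximum template volume a recipe allows
#'
#' The template can displace all of the water, so the maximum is the total
#' volume minus the fixed (non-water, non-template) components.
#'
#' @param recipe A [reaction_recipe()].
#' @return Maximum template volume in µL.
#' @export
max_template_volume <- function(recipe) {
  stopifnot(inherits(recipe, "reaction_recipe"))
  fixed <- recipe$components[!names(recipe$components) %in% c("water", "template")]
  m <- recipe$total_volume_ul - sum(fixed)
  if (m < 0)
    stop("fixed components exceed the total reaction volume", call. = FALSE)
  m
}

#' Validate a reaction recipe
#'
#' Checks that no component volume is negative and that the components
#' sum to the declared total within 1e-9 µL.
#'
#' @param recipe A [reaction_recipe()].
#' @return A list: `pass` and a `discrepancies` tibble (`component`,
#'   `issue`, `value`).
#' @export
validate_recipe <- function(recipe) {
  stopifnot(inherits(recipe, "reaction_recipe"))
  disc <- list()
  neg <- recipe$components[recipe$components < 0]
  for (nm in names(neg))
    disc[[length(disc) + 1L]] <- tibble::tibble(
      component = nm, issue = "negative volume", value = unname(neg[nm]))
  gap <- recipe$total_volume_ul - sum(recipe$components)
  if (abs(gap) > 1e-9)
    disc[[length(disc) + 1L]] <- tibble::tibble(
      component = "(sum)", issue = sprintf("components sum to %.9g, not %.9g (deficit %.9g)",
                                           sum(recipe$components),
                                           recipe$total_volume_ul, gap),
      value = gap)
  list(pass = length(disc) == 0,
       discrepancies = if (length(disc)) do.call(rbind, disc)
                       else tibble::tibble(component = character(),
                                           issue = character(),
                                           value = numeric()))
}
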