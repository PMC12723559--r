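#' Published per-year loss rates for the modeled aging mechanisms
#'
#' Container for the per-year decline rates that parameterize the three
#' aging mechanisms: interneuron loss (SST, VIP, PV, from age regressions of
#' human single-cell RNA-seq cell-type proportions), NMDA conductance loss
#' (from GluN2A/B western blots of human L2/3 pyramidal neurons), and
#' dendritic spine loss (from Golgi staining).
#'
#' @param sst_per_year Fraction of SST interneurons lost per year.
#' @param vip_per_year Fraction of VIP interneurons lost per year.
#' @param pv_per_year Fraction of PV interneurons lost per year.
#' @param nmda_per_year Fraction of NMDA conductance lost per year.
#' @param spine_per_year Fraction of spines lost per year.
#'
#' @return An object of class `loss_rates` (named list of the five rates).
#' @examples
#' loss_rates()
#' @export
loss_rates <- function(sst_per_year = 0.0121,
                       vip_per_year = 0.0088,
                       pv_per_year = 0.0052,
                       nmda_per_year = 0.025,
                       spine_per_year = 0.01) {
  rates <- list(
    sst_per_year = sst_per_year, vip_per_year = vip_per_year,
    pv_per_year = pv_per_year, nmda_per_year = nmda_per_year,
    spine_per_year = spine_per_year
  )
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("rate '", nm, "' must be a single value in [0, 1]")
  }
  structure(rates, class = "loss_rates")
}

#' Pyramidal-neuron spine geometry used in the passive-parameter derivation
#'
#' Morphometric constants for the thin-spine surface-area calculation:
#' total spine count and aggregate surface areas from reconstructed young
#' monkey pyramidal neurons, thin-spine dimensions from human dendritic
#' imaging, and the fraction of spines that are thin in older individuals.
#'
#' @param n_spines_total Total spine count per pyramidal neuron.
#' @param thin_fraction_old Fraction of spines that are thin in older
#'   individuals.
#' @param thin_length Thin-spine length, micrometers.
#' @param tip_diameter Thin-spine tip (head) diameter, micrometers.
#' @param base_to_tip_ratio Base diameter as a fraction of tip diameter for
#'   the truncated-cone spine shape.
#' @param total_spine_area Total spine surface area per neuron, square
#'   micrometers.
#' @param total_dendrite_area Total dendritic surface area per neuron,
#'   square micrometers.
#'
#' @return An object of class `spine_geometry`.
#' @examples
#' spine_geometry()
#' @export
spine_geometry <- function(n_spines_total = 8169,
                           thin_fraction_old = 0.25,
                           thin_length = 1.2,
                           tip_diameter = 0.35,
                           base_to_tip_ratio = 0.5,
                           total_spine_area = 11954,
                           total_dendrite_area = 20410) {
  geom <- list(
    n_spines_total = n_spines_total, thin_fraction_old = thin_fraction_old,
    thin_length = thin_length, tip_diameter = tip_diameter,
    base_to_tip_ratio = base_to_tip_ratio, total_spine_area = total_spine_area,
    total_dendrite_area = total_dendrite_area
  )
  for (nm in setdiff(names(geom), "n_spines_total")) {
    v <- geom[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry field '", nm, "' must be a single positive value")
  }
  if (geom$n_spines_total < 0) stop("n_spines_total must be non-negative")
  structure(geom, class = "spine_geometry")
}

#' Interneuron loss fractions after a given number of years of aging
#'
#' Applies the linear per-year loss rates to an age offset, clamping each
#' loss at 100%. At the reference offset of +20 years (middle age to older)
#' the defaults give 24.2% SST, 17.6% VIP and 10.4% PV loss.
#'
#' @param rates A [loss_rates()] object.
#' @param years Age offset in years (non-negative).
#'
#' @return Named list with `loss` and `survival`, each a named numeric
#'   vector over `c("sst", "vip", "pv")`.
#' @examples
#' interneuron_loss(loss_rates(), 20)
#' @export
interneuron_loss <- function(rates = loss_rates(), years) {
  stopifnot(inherits(rates, "loss_rates"))
  if (!is.numeric(years) || length(years) != 1L || !is.finite(years) || years < 0)
    stop("'years' must be a single non-negative number")
  per_year <- c(
    sst = rates$sst_per_year, vip = rates$vip_per_year, pv = rates$pv_per_year
  )
  loss <- pmin(1, per_year * years)
  names(loss) <- names(per_year)
  list(loss = loss, survival = 1 - loss)
}

#' NMDA conductance multiplier after a given number of years of aging
#'
#' Linear decline in NMDA conductance onto pyramidal neurons, clamped at
#' zero. Defaults give a 50% decline over 20 years.
#'
#' @inheritParams interneuron_loss
#' @return Single multiplier in `[0, 1]` applied to NMDA conductance.
#' @examples
#' nmda_multiplier(loss_rates(), 20) # 0.5
#' @export
nmda_multiplier <- function(rates = loss_rates(), years) {
  stopifnot(inherits(rates, "loss_rates"))
  if (!is.numeric(years) || length(years) != 1L || !is.finite(years) || years < 0)
    stop("'years' must be a single non-negative number")
  max(0, 1 - rates$nmda_per_year * years)
}

#' Pyramidal-to-pyramidal connection-probability multiplier under spine loss
#'
#' Spine loss is translated into a proportional loss of Pyr to Pyr
#' connection probability, clamped at zero. Defaults give a 20% loss over
#' 20 years.
#'
#' @inheritParams interneuron_loss
#' @return Single multiplier in `[0, 1]` applied to the Pyr to Pyr
#'   connection probability.
#' @examples
#' spine_connection_multiplier(loss_rates(), 20) # 0.8
#' @export
spine_connection_multiplier <- function(rates = loss_rates(), years) {
  stopifnot(inherits(rates, "loss_rates"))
  if (!is.numeric(years) || length(years) != 1L || !is.finite(years) || years < 0)
    stop("'years' must be a single non-negative number")
  max(0, 1 - rates$spine_per_year * years)
}

#' Middle-age thin-spine fraction back-projected from the old fraction
#'
#' Older individuals retain `thin_fraction_old` of spines as thin spines
#' after losing `spine_loss_20y` of all spines (a loss assumed to fall on
#' thin spines). Back-projecting gives the middle-age thin fraction
#' `thin_fraction_old / (1 - spine_loss_20y)`; defaults give 31.25%.
#'
#' @param thin_fraction_old Thin-spine fraction in older individuals, in
#'   (0, 1).
#' @param spine_loss_20y Total spine loss over the aging interval, in
#'   `[0, 1)`.
#' @return Middle-age thin-spine fraction.
#' @examples
#' thin_fraction_middle_age(0.25, 0.20) # 0.3125
#' @export
thin_fraction_middle_age <- function(thin_fraction_old, spine_loss_20y) {
  if (!is.numeric(thin_fraction_old) || thin_fraction_old <= 0 ||
      thin_fraction_old >= 1)
    stop("'thin_fraction_old' must be in (0, 1)")
  if (!is.numeric(spine_loss_20y) || spine_loss_20y < 0 || spine_loss_20y >= 1)
    stop("'spine_loss_20y' must be in [0, 1)")
  thin_fraction_old / (1 - spine_loss_20y)
}

#' Total surface area contributed by thin spines
#'
#' Models a thin spine as a truncated cone with base diameter equal to
#' `base_to_tip_ratio` times the tip diameter, plus the flat tip end-cap.
#' The per-spine area (lateral cone area + tip disc) is multiplied by the
#' spine count and the middle-age thin fraction. Defaults reproduce
#' approximately 2782.57 square micrometers.
#'
#' @param geom A [spine_geometry()] object.
#' @param thin_fraction_mid Middle-age thin-spine fraction.
#' @return Total thin-spine surface area, square micrometers.
#' @examples
#' thin_spine_surface_area(spine_geometry(), 0.3125)
#' @export
thin_spine_surface_area <- function(geom = spine_geometry(),
                                    thin_fraction_mid) {
  stopifnot(inherits(geom, "spine_geometry"))
  if (!is.numeric(thin_fraction_mid) || thin_fraction_mid < 0 ||
      thin_fraction_mid > 1)
    stop("'thin_fraction_mid' must be in [0, 1]")
  r_tip <- geom$tip_diameter / 2
  r_base <- geom$base_to_tip_ratio * r_tip
  slant <- sqrt(geom$thin_length^2 + (r_tip - r_base)^2)
  lateral <- pi * (r_tip + r_base) * slant
  cap <- pi * r_tip^2
  (lateral + cap) * geom$n_spines_total * thin_fraction_mid
}

#' Passive-parameter reduction implied by thin-spine loss
#'
#' The membrane area lost when `spine_loss_20y` of spines (all thin) is
#' removed, as a fraction of total (spine + dendritic) membrane area, gives
#' the fractional reduction applied to dendritic leak conductance and
#' membrane capacitance. Defaults give an 8.6% area fraction and a 1.72%
#' reduction.
#'
#' @param geom A [spine_geometry()] object.
#' @param thin_area Total thin-spine surface area (square micrometers), as
#'   from [thin_spine_surface_area()].
#' @param spine_loss_20y Total spine loss over the aging interval.
#' @return Named list with `area_fraction`, `reduction` and
#'   `passive_multiplier` (`1 - reduction`).
#' @examples
#' passive_reduction(spine_geometry(), 2782.57, 0.20)
#' @export
passive_reduction <- function(geom = spine_geometry(), thin_area,
                              spine_loss_20y) {
  stopifnot(inherits(geom, "spine_geometry"))
  if (!is.numeric(thin_area) || thin_area < 0)
    stop("'thin_area' must be non-negative")
  if (!is.numeric(spine_loss_20y) || spine_loss_20y < 0 || spine_loss_20y > 1)
    stop("'spine_loss_20y' must be in [0, 1]")
  area_fraction <- thin_area / (geom$total_spine_area + geom$total_dendrite_area)
  reduction <- area_fraction * spine_loss_20y
  list(
    area_fraction = area_fraction,
    reduction = reduction,
    passive_multiplier = 1 - reduction
  )
}

#' The five experimental condition labels
#'
#' `middle_age` (reference), `older` (all three mechanisms combined), and
#' the single-mechanism conditions `inhib_loss`, `nmda_loss`,
#' `spine_loss`.
#' @export
AGING_CONDITIONS <- c("middle_age", "older", "inhib_loss", "nmda_loss",
                      "spine_loss")

#' Compose an aging profile for one experimental condition
#'
#' Builds the full set of aging multipliers for one of the five conditions:
#' `middle_age` (identity), `older` (all three mechanisms at the given age
#' offset), or one of the single-mechanism conditions `inhib_loss`,
#' `nmda_loss`, `spine_loss`.
#'
#' @param label Condition name, one of `middle_age`, `older`, `inhib_loss`,
#'   `nmda_loss`, `spine_loss`.
#' @param years Age offset in years (default 20, middle age to older).
#' @param rates A [loss_rates()] object.
#' @param geom A [spine_geometry()] object.
#'
#' @return An object of class `aging_profile`: named list with `label`,
#'   `years`, survival fractions `sst_survival`, `vip_survival`,
#'   `pv_survival`, and multipliers `nmda_multiplier`,
#'   `pyr_pyr_connection_multiplier`, `passive_multiplier`.
#' @examples
#' make_profile("older", 20)
#' @export
make_profile <- function(label, years = 20, rates = loss_rates(),
                         geom = spine_geometry()) {
  label <- match.arg(label, AGING_CONDITIONS)
  profile <- list(
    label = label, years = years,
    sst_survival = 1, vip_survival = 1, pv_survival = 1,
    nmda_multiplier = 1, pyr_pyr_connection_multiplier = 1,
    passive_multiplier = 1
  )
  if (label %in% c("older", "inhib_loss")) {
    surv <- interneuron_loss(rates, years)$survival
    profile$sst_survival <- unname(surv["sst"])
    profile$vip_survival <- unname(surv["vip"])
    profile$pv_survival <- unname(surv["pv"])
  }
  if (label %in% c("older", "nmda_loss")) {
    profile$nmda_multiplier <- nmda_multiplier(rates, years)
  }
  if (label %in% c("older", "spine_loss")) {
    spine_loss <- 1 - spine_connection_multiplier(rates, years)
    profile$pyr_pyr_connection_multiplier <- 1 - spine_loss
    # back-projection saturates once the implied thin fraction reaches 1
    thin_mid <- if (spine_loss >= 1) 1 else
      min(1, thin_fraction_middle_age(geom$thin_fraction_old, spine_loss))
    thin_area <- thin_spine_surface_area(geom, thin_mid)
    profile$passive_multiplier <-
      passive_reduction(geom, thin_area, spine_loss)$passive_multiplier
  }
  structure(profile, class = "aging_profile")
}

#' @export
print.aging_profile <- function(x, ...) {
  cat("Aging profile:", x$label, sprintf("(+%g years)\n", x$years))
  cat(sprintf("  interneuron survival  SST %.4f  VIP %.4f  PV %.4f\n",
              x$sst_survival, x$vip_survival, x$pv_survival))
  cat(sprintf("  NMDA conductance multiplier       %.4f\n", x$nmda_multiplier))
  cat(sprintf("  Pyr->Pyr connection multiplier    %.4f\n",
              x$pyr_pyr_connection_multiplier))
  cat(sprintf("  passive (G_pas, c_m) multiplier   %.4f\n",
              x$passive_multiplier))
  invisible(x)
}

#' Write an aging profile to a flat YAML or JSON file
#'
#' @param profile An [make_profile()] object.
#' @param path Output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "aging_profile"))
  x <- unclass(profile)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported profile format: ", path)
  invisible(path)
}

#' Read an aging profile written by [write_profile()]
#'
#' @param path Profile file (`.yaml`/`.yml` or `.json`).
#' @return An `aging_profile` object.
#' @export
read_profile <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported profile format: ", path)
  structure(x, class = "aging_profile")
}
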