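#' Filter design request
#'
#' @param kvp Tube potential in kVp.
#' @param material_id Filter material.
#' @param target_transmission Desired flux transmission in (0, 1]; e.g. 0.30
#'   for a 70% flux reduction.
#' @return A list of class `filter_design_request`.
#' @export
filter_design_request <- function(kvp, material_id, target_transmission) {
  stopifnot(is.numeric(target_transmission), length(target_transmission) == 1L)
  if (target_transmission <= 0 || target_transmission > 1) {
    stop("target_transmission must be in (0, 1]")
  }
  structure(list(kvp = kvp, material_id = .resolve_material_id(material_id),
                 target_transmission = target_transmission),
            class = "filter_design_request")
}

#' Solve a filter thickness for a target flux reduction
#'
#' Bisection (tolerance 0.1 um) for the thickness at which the filtered beam
#' transmits `target_transmission` of the inherent-filtered beam's flux.
#'
#' @param req A [filter_design_request()].
#' @param inherent Filtration already in the beam; defaults to the scanner
#'   stack ([scanner_inherent_filtration()]).
#' @param tube A [tube_model()].
#' @param weighting Flux weighting, as in [beam_transmission()].
#' @param max_thickness_mm Search limit; an unreachable target errors.
#' @return Thickness in mm, with attribute `achieved_transmission`.
#' @examples
#' \donttest{
#' solve_thickness(filter_design_request(90, "Cu", 0.30))  # ~0.55-0.6 mm
#' }
#' @export
solve_thickness <- function(req, inherent = scanner_inherent_filtration(),
                            tube = tube_model(),
                            weighting = c("detected", "photons"),
                            max_thickness_mm = 10) {
  stopifnot(inherits(req, "filter_design_request"))
  weighting <- match.arg(weighting)
  if (req$target_transmission == 1) {
    return(structure(0, achieved_transmission = 1))
  }
  s <- simulate_spectrum(req$kvp, inherent = inherent, tube = tube)
  trans <- function(t_mm) beam_transmission(
    s, filter_layer(req$material_id, thickness_mm = t_mm), weighting)
  if (trans(max_thickness_mm) > req$target_transmission) {
    stop("target transmission ", req$target_transmission,
         " not reachable within ", max_thickness_mm, " mm of ",
         req$material_id)
  }
  lo <- 0; hi <- max_thickness_mm
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (trans(mid) > req$target_transmission) lo <- mid else hi <- mid
  }
  t_mm <- (lo + hi) / 2
  structure(t_mm, achieved_transmission = trans(t_mm))
}

#' Annular filter geometry
#'
#' Geometry of a cylindrical annular filter surrounding the scan bed.  The
#' beam crosses the annulus wall twice (pre- and post-object), so the default
#' `passes = 2`; the combination is equivalent to a pre-object filter of the
#' same total path length.
#'
#' @param outer_diameter_cm,height_cm,wall_thickness_cm Dimensions in cm
#'   (defaults: 8.2 x 6.4 x 0.3).
#' @param passes Number of wall crossings, 1 or 2.
#' @return A list of class `annular_filter_geometry`.
#' @export
annular_filter_geometry <- function(outer_diameter_cm = 8.2, height_cm = 6.4,
                                    wall_thickness_cm = 0.3, passes = 2) {
  stopifnot(outer_diameter_cm > 0, height_cm > 0, wall_thickness_cm > 0,
            passes %in% c(1L, 2L))
  structure(list(outer_diameter_cm = outer_diameter_cm, height_cm = height_cm,
                 wall_thickness_cm = wall_thickness_cm,
                 passes = as.integer(passes)),
            class = "annular_filter_geometry")
}

#' Nanopowder mass loading for a resin-cast filter
#'
#' Converts a designed foil-equivalent thickness of a pure element into the
#' mass of compound powder (e.g. Er2O3) to disperse in a resin volume cast
#' into an annular filter, assuming the element alone carries the attenuation
#' and the powder distributes uniformly through the resin:
#' \deqn{m = \frac{t_{eq}\,\rho_{foil}}{w_{el}\; L}\; V_{resin},}
#' with \eqn{L} = passes x wall thickness the beam's path through the wall.
#'
#' @param foil_equiv_thickness_um Foil-equivalent thickness in um.
#' @param foil_density_g_cm3 Density of the pure element foil in g/cm^3.
#' @param element_mass_fraction Element mass fraction of the powder compound
#'   (Er in Er2O3: 0.8745).
#' @param geometry An [annular_filter_geometry()].
#' @param resin_volume_ml Volume of resin to be loaded, in mL.
#' @return A list of class `mass_loading_report` with `mass_g` and every
#'   assumption echoed.
#' @export
mass_loading <- function(foil_equiv_thickness_um, foil_density_g_cm3,
                         element_mass_fraction, geometry, resin_volume_ml) {
  stopifnot(inherits(geometry, "annular_filter_geometry"),
            foil_equiv_thickness_um > 0, foil_density_g_cm3 > 0,
            element_mass_fraction > 0, element_mass_fraction <= 1,
            resin_volume_ml > 0)
  path_cm <- geometry$passes * geometry$wall_thickness_cm
  if (path_cm <= 0) stop("zero beam path through the filter wall")
  t_cm <- foil_equiv_thickness_um * 1e-4
  conc <- t_cm * foil_density_g_cm3 / (element_mass_fraction * path_cm)
  structure(list(
    mass_g = conc * resin_volume_ml,
    concentration_g_per_ml = conc,
    foil_equiv_thickness_um = foil_equiv_thickness_um,
    foil_density_g_cm3 = foil_density_g_cm3,
    element_mass_fraction = element_mass_fraction,
    beam_path_cm = path_cm,
    passes = geometry$passes,
    resin_volume_ml = resin_volume_ml,
    assumptions = c(
      "element alone carries the attenuation (compound partners neglected)",
      "powder uniformly dispersed through the stated resin volume",
      "beam path = passes x wall thickness (annulus equivalent to a pre-object filter)")
  ), class = "mass_loading_report")
}

#' @export
print.mass_loading_report <- function(x, ...) {
  cat(sprintf(
    "<mass_loading_report> %.3g g powder (%.4g g/mL in %.3g mL resin)\n",
    x$mass_g, x$concentration_g_per_ml, x$resin_volume_ml))
  cat(sprintf("  foil equivalent: %.3g um at %.4g g/cm3, element fraction %.4g\n",
              x$foil_equiv_thickness_um, x$foil_density_g_cm3,
              x$element_mass_fraction))
  cat(sprintf("  beam path: %d pass(es) x %.3g cm wall = %.3g cm\n",
              x$passes, x$beam_path_cm / x$passes, x$beam_path_cm))
  for (a in x$assumptions) cat("  - ", a, "\n", sep = "")
  invisible(x)
}

#' Total beam path through layered foil
#'
#' @param n_layers Number of foil layers wrapped on the filter core.
#' @param foil_thickness_mm Single-foil thickness in mm.
#' @param passes Wall crossings (1 or 2).
#' @return Total path length in mm (`n_layers * foil_thickness_mm * passes`).
#' @examples
#' layered_foil_path(3, 0.08, 2)  # 0.48 mm
#' @export
layered_foil_path <- function(n_layers, foil_thickness_mm, passes) {
  stopifnot(n_layers >= 0, foil_thickness_mm > 0, passes %in% c(1, 2))
  n_layers * foil_thickness_mm * passes
}
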