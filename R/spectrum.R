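#' X-ray tube source model parameters
#'
#' Parameters of the tungsten-anode bremsstrahlung model used by
#' [simulate_spectrum()].  The continuum follows a Kramers thick-target law
#' with depth-dependent self-filtration in the anode: electrons penetrate the
#' target according to the Thomson-Whiddington relation
#' \eqn{\rho x = (T_0^2 - T^2)/C}, and photons produced at depth \eqn{x}
#' escape through a tungsten path \eqn{x/\sin\theta} for take-off angle
#' \eqn{\theta}.  W K-characteristic lines (57.98, 59.32, 67.24, 69.07 keV)
#' are added above the K-shell threshold with intensity proportional to
#' \eqn{(E_0/E_K - 1)^{1.63}}, normalised so that characteristic photons are
#' 6% of the continuum output at 100 kVp.  A thin always-present exit-window
#' filter (Al equivalent) represents the tube port; the scanner's additional
#' inherent filtration is supplied separately.
#'
#' Geometry metadata (source-to-isocenter 39.84 cm, source-to-detector
#' 45.19 cm) is carried in the spectrum provenance only; the model is a
#' fluence-shape model and does not simulate the heel effect.
#'
#' @param target_angle_deg Anode take-off angle in degrees.
#' @param tw_constant Thomson-Whiddington constant in keV^2 cm^2/g.
#' @param k_fraction Characteristic-to-continuum photon ratio at 100 kVp.
#' @param window_mm_al Tube exit-window thickness in mm Al equivalent.
#' @param source_to_isocenter_cm,source_to_detector_cm Geometry metadata.
#' @return A list of class `tube_model`.
#' @export
tube_model <- function(target_angle_deg = 15, tw_constant = 1.6e6,
                       k_fraction = 0.06, window_mm_al = 1.0,
                       source_to_isocenter_cm = 39.84,
                       source_to_detector_cm = 45.19) {
  structure(list(target_angle_deg = target_angle_deg,
                 tw_constant = tw_constant,
                 k_fraction = k_fraction,
                 window_mm_al = window_mm_al,
                 source_to_isocenter_cm = source_to_isocenter_cm,
                 source_to_detector_cm = source_to_detector_cm),
            class = "tube_model")
}

#' Scanner inherent filtration
#'
#' The scanner's inherent filtration stack: 1.6 mm Al plus 2 cm Lexan
#' (polycarbonate).
#'
#' @return A list of [filter_layer()] objects.
#' @export
scanner_inherent_filtration <- function() {
  list(filter_layer("Al", thickness_mm = 1.6),
       filter_layer("polycarbonate", thickness_mm = 20))
}

#' Define a filter layer
#'
#' @param material_id Material name (see [load_attenuation()]).
#' @param thickness_mm Thickness in mm, or
#' @param areal_density_g_cm2 areal density in g/cm^2; exactly one of the two
#'   must be given (the other is derived through the bulk density).
#' @return A list of class `filter_layer` with both representations filled in.
#' @export
filter_layer <- function(material_id, thickness_mm = NULL,
                         areal_density_g_cm2 = NULL) {
  if (is.null(thickness_mm) == is.null(areal_density_g_cm2)) {
    stop("give exactly one of thickness_mm or areal_density_g_cm2")
  }
  tab <- load_attenuation(material_id)
  if (is.null(thickness_mm)) {
    if (areal_density_g_cm2 < 0) stop("areal density must be >= 0")
    thickness_mm <- areal_density_g_cm2 / tab$density * 10
  } else {
    if (thickness_mm < 0) stop("thickness must be >= 0")
    areal_density_g_cm2 <- thickness_mm / 10 * tab$density
  }
  structure(list(material_id = tab$material_id, thickness_mm = thickness_mm,
                 areal_density_g_cm2 = areal_density_g_cm2),
            class = "filter_layer")
}

#' Simulate a filtered tungsten-anode spectrum
#'
#' Photon fluence per 1-keV energy bin (bin centers at 1, 2, ... keV,
#' relative units) for a given tube potential, after the tube window and the
#' supplied inherent filtration.
#'
#' @param kvp Tube potential in kVp; 30-140 in steps of 0.5.
#' @param inherent List of [filter_layer()]s applied after the tube window;
#'   defaults to the scanner stack of [scanner_inherent_filtration()].  Use
#'   `list()` for the unfiltered tube output.
#' @param tube A [tube_model()].
#' @return An object of class `xray_spectrum`: list with `kvp`, `energies`
#'   (keV bin centers), `fluence` (photons per bin, relative), `provenance`
#'   (list of applied filters and model parameters).
#' @examples
#' s <- simulate_spectrum(90, inherent = list())
#' flux_and_mean_energy(s)$mean_energy   # ~42-43 keV
#' @export
simulate_spectrum <- function(kvp, inherent = scanner_inherent_filtration(),
                              tube = tube_model()) {
  stopifnot(is.numeric(kvp), length(kvp) == 1L)
  if (kvp < 30 || kvp > 140) stop("kvp must be within 30-140")
  if (abs(kvp * 2 - round(kvp * 2)) > 1e-9) {
    stop("kvp must be a multiple of 0.5")
  }
  energies <- seq_len(floor(kvp - 1e-9))
  w_tab <- load_attenuation("W")
  mu_w <- mu_at(w_tab, energies)
  sin_t <- sin(tube$target_angle_deg * pi / 180)
  fl <- vapply(seq_along(energies), function(i) {
    e <- energies[i]
    if (e >= kvp) return(0)
    tt <- seq(e, kvp, length.out = 80L)
    depth <- (kvp^2 - tt^2) / tube$tw_constant     # g/cm^2 into the anode
    att <- exp(-mu_w[i] * depth / sin_t)
    # Kramers production is flat in electron energy under Thomson-Whiddington
    sum((att[-1L] + att[-length(att)]) / 2 * diff(tt)) / e
  }, numeric(1))
  # W K lines: energies and relative intensities
  e_k <- 69.525
  if (kvp > e_k && tube$k_fraction > 0) {
    lines <- c(`57.98` = 0.576, `59.32` = 1.0, `67.24` = 0.33, `69.07` = 0.089)
    u <- kvp / e_k
    scale <- tube$k_fraction / (100 / e_k - 1)^1.63
    total <- scale * (u - 1)^1.63 * sum(fl)
    for (j in seq_along(lines)) {
      bin <- round(as.numeric(names(lines)[j]))
      fl[bin] <- fl[bin] + total * lines[[j]] / sum(lines)
    }
  }
  s <- structure(list(kvp = kvp, energies = energies, fluence = fl,
                      provenance = list(list(stage = "tube", model = unclass(tube)))),
                 class = "xray_spectrum")
  if (tube$window_mm_al > 0) {
    s <- apply_filter(s, filter_layer("Al", thickness_mm = tube$window_mm_al))
  }
  for (layer in inherent) s <- apply_filter(s, layer)
  s
}

#' @export
print.xray_spectrum <- function(x, ...) {
  fm <- flux_and_mean_energy(x)
  filters <- vapply(x$provenance[-1L], function(p)
    sprintf("%.3g mm %s", p$thickness_mm, p$material_id), character(1))
  cat(sprintf("<xray_spectrum> %g kVp | mean %.1f keV | filters: %s\n",
              x$kvp, fm$mean_energy,
              if (length(filters)) paste(filters, collapse = " + ") else "none"))
  invisible(x)
}

#' Attenuate a spectrum by a filter layer
#'
#' Beer-Lambert attenuation per bin:
#' \eqn{\Phi'(E) = \Phi(E)\,e^{-(\mu/\rho)(E)\,\rho t}}.
#'
#' @param s An `xray_spectrum`.
#' @param layer A [filter_layer()].
#' @return The filtered spectrum, with the layer appended to the provenance.
#' @export
apply_filter <- function(s, layer) {
  stopifnot(inherits(s, "xray_spectrum"), inherits(layer, "filter_layer"))
  if (layer$thickness_mm < 0) stop("thickness must be >= 0")
  tab <- load_attenuation(layer$material_id)
  tr <- exp(-mu_at(tab, s$energies) * layer$areal_density_g_cm2)
  s$fluence <- s$fluence * tr
  s$provenance <- c(s$provenance, list(unclass(layer)))
  s
}

#' Total flux and mean energy of a spectrum
#'
#' The total is the photon count \eqn{\sum \Phi(E)} (or the detected-energy
#' signal \eqn{\sum E\,\Phi(E)} under `weighting = "detected"`); the mean
#' energy is always the photon-fluence-weighted mean
#' \eqn{\sum E\,\Phi / \sum \Phi}.
#'
#' @param s An `xray_spectrum`.
#' @param weighting `"photons"` (default) or `"detected"` for the flux total.
#' @return List with `flux` and `mean_energy` (keV).
#' @export
flux_and_mean_energy <- function(s, weighting = c("photons", "detected")) {
  stopifnot(inherits(s, "xray_spectrum"))
  weighting <- match.arg(weighting)
  tot_n <- sum(s$fluence)
  if (tot_n <= 0) stop("all-zero spectrum: mean energy undefined")
  list(flux = if (weighting == "photons") tot_n else sum(s$energies * s$fluence),
       mean_energy = sum(s$energies * s$fluence) / tot_n)
}

.beam_weights <- function(s, weighting) {
  if (weighting == "detected") s$fluence * s$energies else s$fluence
}

#' Beam transmission through filter layers
#'
#' Fraction of beam flux surviving a filtration stack.  The default
#' `"detected"` weighting integrates energy fluence, which is what an
#' energy-integrating flat-panel detector registers and what the packaged
#' filter-design thicknesses are defined against; `"photons"` counts photons.
#'
#' @param s An `xray_spectrum`.
#' @param layers A [filter_layer()] or list of them.
#' @param weighting `"detected"` (default) or `"photons"`.
#' @return Transmission fraction in (0, 1].
#' @export
beam_transmission <- function(s, layers, weighting = c("detected", "photons")) {
  weighting <- match.arg(weighting)
  if (inherits(layers, "filter_layer")) layers <- list(layers)
  s2 <- s
  for (layer in layers) s2 <- apply_filter(s2, layer)
  sum(.beam_weights(s2, weighting)) / sum(.beam_weights(s, weighting))
}

#' Half-value layer of a beam
#'
#' Absorber thickness reducing the beam to half.  `method = "direct"`
#' root-finds transmission\eqn{(t) - 0.5} by bisection (tolerance 0.1 um).
#' `method = "slope_fit"` reproduces the step-wedge analysis: least-squares
#' slope \eqn{\hat\mu} of \eqn{\ln(I/I_0)} against thickness over
#' `thickness_grid`, then \eqn{HVL = \ln 2 / \hat\mu}.  For a polychromatic
#' beam the slope fit linearises a convex curve, so the two methods agree
#' exactly only for monoenergetic beams.
#'
#' @param s An `xray_spectrum`.
#' @param absorber Absorber material (default "Al").
#' @param method `"direct"` or `"slope_fit"`.
#' @param thickness_grid Thicknesses in mm for the slope fit (>= 3 values).
#' @param weighting Flux weighting, as in [beam_transmission()].
#' @param max_mm Upper end of the bisection search interval.
#' @return HVL in mm.
#' @export
hvl <- function(s, absorber = "Al", method = c("direct", "slope_fit"),
                thickness_grid = NULL, weighting = c("detected", "photons"),
                max_mm = 100) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  trans <- function(t_mm) beam_transmission(
    s, filter_layer(absorber, thickness_mm = t_mm), weighting)
  if (method == "direct") {
    if (trans(max_mm) > 0.5) {
      stop("transmission does not fall below 0.5 within ", max_mm, " mm")
    }
    lo <- 0; hi <- max_mm
    while (hi - lo > 1e-4) {           # 0.1 um
      mid <- (lo + hi) / 2
      if (trans(mid) > 0.5) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  } else {
    if (is.null(thickness_grid) || length(thickness_grid) < 3L) {
      stop("slope_fit needs a thickness_grid with >= 3 thicknesses")
    }
    log_t <- log(vapply(thickness_grid, trans, numeric(1)))
    mu_hat <- -unname(stats::coef(stats::lm(log_t ~ thickness_grid))[2L])
    if (mu_hat <= 0) stop("fitted attenuation coefficient is not positive")
    log(2) / mu_hat
  }
}
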