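#' Mass-attenuation tables
#'
#' The package ships mass-attenuation-coefficient tables for the elements and
#' compounds needed to model the scanner beam and its filters: H, C, O, F, Al,
#' Cu, Er, W, water, PTFE and polycarbonate (Lexan).  Each table holds a log
#' energy grid in keV, \eqn{\mu/\rho} in cm^2/g, the bulk density, and the
#' absorption-edge energies falling inside the tabulated range.  Edge
#' positions are stored as doublet rows a fraction of an eV apart so that
#' interpolation can resolve the discontinuity; the erbium K edge is placed at
#' 57.5 keV.
#'
#' Interpolation between grid points is linear in log-log space and is carried
#' out separately on each side of every absorption edge, so an interpolated
#' value never bridges an edge.  Queries outside the grid are clamped to the
#' first/last tabulated value.
#'
#' @param material_id Material name.  Element symbols are case sensitive
#'   ("Er", "Cu", ...); compound names are lower case ("water", "ptfe",
#'   "polycarbonate").  The aliases "Lexan", "lexan", "PTFE" and "Teflon" are
#'   accepted.
#' @return An object of class `attenuation_table`: a list with elements
#'   `material_id`, `energies` (keV, strictly increasing), `mu_over_rho`
#'   (cm^2/g), `density` (g/cm^3) and `edges` (keV).
#' @examples
#' er <- load_attenuation("Er")
#' er$edges            # contains 57.5
#' mu_at(er, c(50, 60))
#' @export
load_attenuation <- function(material_id) {
  stopifnot(is.character(material_id), length(material_id) == 1L)
  id <- .resolve_material_id(material_id)
  dir <- system.file("extdata", "attenuation", package = "dectk")
  csv <- file.path(dir, paste0(id, ".csv"))
  meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(csv)
  out <- structure(list(
    material_id = id,
    energies = tab$energy_keV,
    mu_over_rho = tab$mu_over_rho_cm2_g,
    density = meta$density_g_cm3,
    edges = as.numeric(meta$edges_keV)
  ), class = "attenuation_table")
  stopifnot(all(diff(out$energies) > 0), all(out$mu_over_rho > 0))
  out
}

.material_aliases <- c(Lexan = "polycarbonate", lexan = "polycarbonate",
                       PTFE = "ptfe", Teflon = "ptfe", teflon = "ptfe",
                       Water = "water")

.available_materials <- function() {
  dir <- system.file("extdata", "attenuation", package = "dectk")
  sort(sub("\\.csv$", "", list.files(dir, pattern = "\\.csv$")))
}

.resolve_material_id <- function(material_id) {
  id <- material_id
  if (id %in% names(.material_aliases)) id <- .material_aliases[[id]]
  avail <- .available_materials()
  if (!id %in% avail) {
    stop("unknown material '", material_id, "'; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  id
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat("<attenuation_table>", x$material_id,
      sprintf("| %d knots %.3g-%.3g keV | density %.4g g/cm3",
              length(x$energies), min(x$energies), max(x$energies),
              x$density))
  if (length(x$edges)) cat(" | edges:", paste(x$edges, collapse = ", "), "keV")
  cat("\n")
  invisible(x)
}

#' Evaluate a mass-attenuation table
#'
#' Log-log interpolation of \eqn{\mu/\rho} at arbitrary energies, never
#' bridging an absorption edge.  At exactly an edge energy the above-edge
#' branch is returned.
#'
#' @param table An [attenuation_table][load_attenuation].
#' @param energy Energies in keV (vectorised).
#' @return \eqn{\mu/\rho} in cm^2/g.
#' @export
mu_at <- function(table, energy) {
  stopifnot(inherits(table, "attenuation_table"), is.numeric(energy),
            all(is.finite(energy)), all(energy > 0))
  e <- table$energies
  mu <- table$mu_over_rho
  # segment boundaries at edges: the stored doublets already pin both sides,
  # so interpolating within a segment can never mix sides of an edge;
  # a query at exactly an edge energy falls in the above-edge segment
  seg_q <- findInterval(energy, table$edges) + 1L
  seg_t <- findInterval(e, table$edges) + 1L
  out <- numeric(length(energy))
  for (s in unique(seg_q)) {
    qi <- seg_q == s
    ti <- seg_t == s
    if (!any(ti)) { # query beyond the tabulated range of this segment
      out[qi] <- mu[if (s == 1L) 1L else length(mu)]
      next
    }
    xs <- log(e[ti]); ys <- log(mu[ti])
    xq <- pmin(pmax(log(energy[qi]), xs[1L]), xs[length(xs)])
    out[qi] <- exp(stats::approx(xs, ys, xout = xq, ties = "ordered")$y)
  }
  out
}

#' Mass-attenuation coefficient of a mixture
#'
#' Applies the mixture rule \eqn{\sum_i w_i (\mu/\rho)_i(E)} for a set of
#' mass fractions, e.g. to model Er2O3 nanopowder from the elemental tables.
#'
#' @param weights Named numeric vector or list of mass fractions; must be
#'   positive and sum to 1 within 1e-6.
#' @param energy Energies in keV (vectorised).
#' @return \eqn{\mu/\rho} of the mixture in cm^2/g.
#' @examples
#' # erbium oxide from atomic masses: Er 0.8745, O 0.1255
#' mixture_mu_over_rho(c(Er = 0.8745, O = 0.1255), 100)
#' @export
mixture_mu_over_rho <- function(weights, energy) {
  w <- unlist(weights)
  stopifnot(length(w) >= 1L, !is.null(names(w)), all(nzchar(names(w))))
  if (any(w <= 0)) stop("mass fractions must be positive")
  if (abs(sum(w) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", format(sum(w)), ")")
  }
  out <- 0
  for (i in seq_along(w)) {
    out <- out + w[[i]] * mu_at(load_attenuation(names(w)[i]), energy)
  }
  out
}

#' Mass fractions of erbium oxide
#'
#' Er2O3 mass fractions from atomic masses (Er 167.259, O 15.999):
#' Er 0.8745, O 0.1255.
#'
#' @return Named numeric vector of mass fractions.
#' @export
er2o3_mass_fractions <- function() {
  m_er <- 2 * 167.259
  m_o <- 3 * 15.999
  c(Er = m_er, O = m_o) / (m_er + m_o)
}
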