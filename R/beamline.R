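# Bending-magnet source spectrum, filter transmission, scintillator response,
# detected spectrum and beam-hardening diagnostics.

#' Universal bending-magnet spectral function G1
#'
#' \eqn{G_1(y) = y \int_y^\infty K_{5/3}(x)\,dx}, the universal synchrotron
#' spectral shape as a function of \eqn{y = E/E_c}. Evaluated by numerical
#' quadrature of the modified Bessel function; peaks near \eqn{y \approx 0.29}.
#'
#' @param y Ratio of photon energy to critical energy (vectorised, > 0).
#' @return G1 values (dimensionless).
#' @export
synchrotron_g1 <- function(y) {
  stopifnot(is.numeric(y), all(y > 0))
  vapply(y, function(yi) {
    if (besselK(yi, nu = 5 / 3) == 0) return(0)  # far tail underflows
    yi * stats::integrate(function(x) besselK(x, nu = 5 / 3),
                          lower = yi, upper = Inf,
                          rel.tol = 1e-8)$value
  }, numeric(1))
}

#' Relative photon flux of a bending magnet
#'
#' Photon flux per unit energy interval, proportional to
#' \eqn{G_1(E/E_c)/E}; returned rescaled so the maximum over the grid is 1.
#'
#' @param energies Photon energy grid in keV.
#' @param critical_energy Critical energy in keV.
#' @return Relative flux on the grid (unitless).
#' @export
bending_magnet_flux <- function(energies, critical_energy) {
  stopifnot(critical_energy > 0, all(energies > 0))
  flux <- synchrotron_g1(energies / critical_energy) / energies
  if (max(flux) > 0) flux <- flux / max(flux)
  flux
}

#' Critical energy of a bending magnet
#'
#' \eqn{E_c[\mathrm{keV}] = 0.665\, E^2[\mathrm{GeV}]\, B[\mathrm{T}]}.
#'
#' @param ring_energy_gev Electron energy in GeV.
#' @param field_t Magnetic field in tesla.
#' @return Critical energy in keV.
#' @export
critical_energy <- function(ring_energy_gev, field_t) {
  stopifnot(ring_energy_gev > 0, field_t > 0)
  0.665 * ring_energy_gev^2 * field_t
}

#' Describe a beamline (source, filters, scintillator)
#'
#' @param critical_energy_keV Critical energy of the bend in keV; may be
#'   omitted if \code{ring_energy_gev} and \code{field_t} are given.
#' @param filters List of filters, each \code{list(material =, thickness_mm =)};
#'   materials may be bundled names (e.g. \code{"copper"}) or
#'   \code{material} objects.
#' @param scintillator \code{list(material =, thickness_um =)}.
#' @param energies Energy grid in keV (default 10-400 keV in 0.5 keV steps,
#'   which resolves the filtered spectrum peak).
#' @param ring_energy_gev,field_t Alternative source specification.
#' @inheritParams parse_formula
#' @return A \code{beamline} object.
#' @export
#' @examples
#' bl <- beamline(filters = list(list(material = "molybdenum", thickness_mm = 0.3),
#'                               list(material = "copper", thickness_mm = 12)),
#'                scintillator = list(material = "luag", thickness_um = 2000),
#'                ring_energy_gev = 6.03, field_t = 0.85)
#' average_energy(detected_spectrum(bl))
beamline <- function(critical_energy_keV = NULL, filters = list(),
                     scintillator = NULL, energies = seq(10, 400, by = 0.5),
                     ring_energy_gev = NULL, field_t = NULL,
                     table = default_attenuation_table()) {
  if (is.null(critical_energy_keV)) {
    if (is.null(ring_energy_gev) || is.null(field_t)) {
      stop("give either critical_energy_keV or both ring_energy_gev and field_t")
    }
    critical_energy_keV <- critical_energy(ring_energy_gev, field_t)
  }
  stopifnot(critical_energy_keV > 0, all(diff(energies) > 0))
  filters <- lapply(filters, function(f) {
    stopifnot(is.list(f), !is.null(f$material), !is.null(f$thickness_mm),
              f$thickness_mm >= 0)
    f$material <- resolve_material(f$material, table)
    stopifnot(inherits(f$material, "material"))
    f
  })
  if (!is.null(scintillator)) {
    stopifnot(is.list(scintillator), !is.null(scintillator$material),
              !is.null(scintillator$thickness_um), scintillator$thickness_um >= 0)
    scintillator$material <- resolve_material(scintillator$material, table)
    stopifnot(inherits(scintillator$material, "material"))
  }
  structure(list(critical_energy = critical_energy_keV, filters = filters,
                 scintillator = scintillator, energies = energies,
                 table = table),
            class = "beamline")
}

#' @export
print.beamline <- function(x, ...) {
  cat("<beamline> Ec =", format(x$critical_energy, digits = 4), "keV;",
      length(x$filters), "filter(s);",
      if (is.null(x$scintillator)) "no scintillator" else
        paste0(x$scintillator$material$name, " ", x$scintillator$thickness_um,
               " um"),
      "\n")
  invisible(x)
}

#' Transmission of a filter stack
#'
#' \eqn{\exp(-\sum_i \mu_i(E) t_i)}; multiplicative across filters and
#' therefore independent of filter order.
#'
#' @param filters As in [beamline()].
#' @param energies keV grid.
#' @inheritParams parse_formula
#' @return Per-energy transmission in \[0, 1\].
#' @export
filter_transmission <- function(filters, energies,
                                table = default_attenuation_table()) {
  att <- numeric(length(energies))
  for (f in filters) {
    mat <- resolve_material(f$material, table)
    att <- att + linear_attenuation(mat, energies, table = table) *
      (f$thickness_mm / 10)  # mm -> cm
  }
  exp(-att)
}

#' Detection weight of an energy-integrating scintillator detector
#'
#' Absorbed fraction \eqn{1 - \exp(-\mu_{sc}(E) t)} multiplied by \eqn{E}:
#' the camera integrates deposited energy, so the detected signal per photon
#' is proportional to the photon energy times its absorption probability.
#'
#' @param scintillator \code{list(material =, thickness_um =)}.
#' @param energies keV grid.
#' @inheritParams parse_formula
#' @return Per-energy detection weight (unitless scale).
#' @export
scintillator_response <- function(scintillator, energies,
                                  table = default_attenuation_table()) {
  mat <- resolve_material(scintillator$material, table)
  t_cm <- scintillator$thickness_um * 1e-4
  (1 - exp(-linear_attenuation(mat, energies, table = table) * t_cm)) * energies
}

#' Detected spectrum of a beamline
#'
#' Pointwise product of source flux, filter transmission and scintillator
#' response, normalised to unit sum.
#'
#' @param model A \code{beamline}.
#' @return A \code{detected_spectrum}: list with \code{energy} (keV) and
#'   \code{weight} (sums to 1).
#' @export
detected_spectrum <- function(model) {
  stopifnot(inherits(model, "beamline"))
  e <- model$energies
  w <- bending_magnet_flux(e, model$critical_energy)
  w <- w * filter_transmission(model$filters, e, table = model$table)
  if (!is.null(model$scintillator)) {
    w <- w * scintillator_response(model$scintillator, e, table = model$table)
  }
  if (!any(w > 0) || sum(w) < .Machine$double.xmin) {
    stop("degenerate spectrum: the filter stack is opaque on this energy grid")
  }
  structure(list(energy = e, weight = w / sum(w)), class = "detected_spectrum")
}

#' Average energy of a detected spectrum
#'
#' @param s A \code{detected_spectrum}.
#' @return Weighted mean energy in keV.
#' @export
average_energy <- function(s) {
  stopifnot(inherits(s, "detected_spectrum"))
  sum(s$energy * s$weight)
}

#' @export
print.detected_spectrum <- function(x, ...) {
  cat("<detected_spectrum> ", length(x$energy), " energies, mean ",
      format(average_energy(x), digits = 4), " keV, peak at ",
      x$energy[which.max(x$weight)], " keV\n", sep = "")
  invisible(x)
}

#' @export
plot.detected_spectrum <- function(x, ...) {
  graphics::plot(x$energy, x$weight, type = "l", xlab = "energy (keV)",
                 ylab = "detected weight", ...)
  graphics::abline(v = average_energy(x), lty = 2)
  invisible(x)
}

#' Beam-hardening curve of a material under a polychromatic spectrum
#'
#' Effective attenuation per unit path,
#' \eqn{\mu_{eff}(L) = -\ln(\sum_i w_i e^{-\mu(E_i) L})/L}, with the
#' monochromatic-like limit \eqn{\sum_i w_i \mu(E_i)} at \eqn{L = 0}.
#' For any spectrum this is non-increasing in L (the beam hardens).
#'
#' @param s A \code{detected_spectrum}.
#' @param mat A \code{material}.
#' @param path_lengths Path lengths in cm (>= 0).
#' @inheritParams parse_formula
#' @return A data.frame with \code{path_length_cm} and \code{mu_eff_cm1},
#'   with attribute \code{max_rel_dev}: the maximum relative deviation of
#'   \code{mu_eff} from its zero-path limit across the list.
#' @export
#' @examples
#' bl <- beamline(critical_energy_keV = 20.5,
#'                filters = list(list(material = "copper", thickness_mm = 12)),
#'                scintillator = list(material = "luag", thickness_um = 2000))
#' bh <- beam_hardening_curve(detected_spectrum(bl),
#'                            material("water", "H2O", 1.0), seq(0, 6, 1))
#' attr(bh, "max_rel_dev")
beam_hardening_curve <- function(s, mat, path_lengths,
                                 table = default_attenuation_table()) {
  stopifnot(inherits(s, "detected_spectrum"), all(path_lengths >= 0))
  mu <- linear_attenuation(mat, s$energy, table = table)
  mu0 <- sum(s$weight * mu)
  mu_eff <- vapply(path_lengths, function(L) {
    if (L == 0) return(mu0)
    -log(sum(s$weight * exp(-mu * L))) / L
  }, numeric(1))
  out <- data.frame(path_length_cm = path_lengths, mu_eff_cm1 = mu_eff)
  attr(out, "max_rel_dev") <- max(abs(mu_eff - mu0)) / mu0
  out
}

#' Bundled beamline presets
#'
#' Four acquisition configurations mirroring the scan setups of the source
#' study (body and head overview scans plus two detail settings), read from
#' the packaged YAML file.
#'
#' @param name Preset name; one of the names in the bundled file. With
#'   \code{name = NULL} the list of preset definitions is returned.
#' @param energies Optional energy grid override (keV).
#' @inheritParams parse_formula
#' @return A \code{beamline} (or a named list of preset definitions).
#' @export
#' @examples
#' bl <- beamline_preset("body_24um")
beamline_preset <- function(name = NULL, energies = seq(10, 400, by = 0.5),
                            table = default_attenuation_table()) {
  path <- system.file("extdata", "beamline_presets.yaml", package = "natronid",
                      mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  beamline(ring_energy_gev = p$source$ring_energy_gev,
           field_t = p$source$field_t,
           filters = p$filters, scintillator = p$scintillator,
           energies = energies, table = table)
}
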