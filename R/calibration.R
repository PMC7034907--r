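# Effective-energy calibration against a reference material and
# attenuation-based candidate scoring/classification.

#' Effective monochromatic energy from a reference material
#'
#' Inverts a measured linear attenuation coefficient of a reference material
#' (typically cortical bone modelled as hydroxyapatite at its measured
#' mineral density) to the monochromatic energy at which the theoretical
#' attenuation matches it. The attenuation curve is strictly decreasing over
#' the default bracket for edge-free materials, so the root is unique; it is
#' found with [stats::uniroot()] (Brent) to a residual below \code{tol}.
#'
#' @param measured_mu Measured linear attenuation in cm^-1.
#' @param reference A \code{material} (or bundled material name).
#' @param bracket Energy search bracket in keV (default 50-300).
#' @param tol Residual tolerance in cm^-1 (default 1e-6).
#' @inheritParams parse_formula
#' @return An \code{energy_calibration}: effective energy (keV), reference,
#'   measured value, residual and bracket.
#' @export
#' @examples
#' bone <- material("hydroxyapatite", "Ca10(PO4)6(OH)2", 1.8)
#' cal <- effective_energy_from_reference(0.274, bone)
#' cal$effective_energy
effective_energy_from_reference <- function(measured_mu, reference,
                                            bracket = c(50, 300), tol = 1e-6,
                                            table = default_attenuation_table()) {
  reference <- resolve_material(reference, table)
  stopifnot(inherits(reference, "material"),
            is.numeric(measured_mu), length(measured_mu) == 1L, measured_mu > 0,
            length(bracket) == 2L, bracket[1] < bracket[2])
  mu_hi <- linear_attenuation(reference, bracket[1], table = table)
  mu_lo <- linear_attenuation(reference, bracket[2], table = table)
  if (mu_lo >= mu_hi) {
    stop("reference attenuation is not decreasing over the bracket; ",
         "calibration requires an edge-free reference material")
  }
  if (measured_mu > mu_hi || measured_mu < mu_lo) {
    stop(sprintf(paste0("measured mu = %.6g cm^-1 is outside the attainable ",
                        "range [%.6g, %.6g] cm^-1 for %s over %g-%g keV"),
                 measured_mu, mu_lo, mu_hi, reference$name,
                 bracket[1], bracket[2]))
  }
  root <- stats::uniroot(
    function(e) linear_attenuation(reference, e, table = table) - measured_mu,
    interval = bracket, tol = 1e-8
  )
  res <- linear_attenuation(reference, root$root, table = table) - measured_mu
  if (abs(res) > tol) {
    stop("root finding did not reach the requested residual tolerance")
  }
  structure(list(effective_energy = root$root, reference = reference,
                 measured_mu = measured_mu, residual = res, bracket = bracket),
            class = "energy_calibration")
}

#' @export
print.energy_calibration <- function(x, ...) {
  cat(sprintf("<energy_calibration> %.1f keV (reference %s, mu = %.4g cm^-1, residual %.2g)\n",
              x$effective_energy, x$reference$name, x$measured_mu, x$residual))
  invisible(x)
}

#' @export
summary.energy_calibration <- function(object, ...) {
  cat("Effective-energy calibration\n")
  cat(sprintf("  reference      : %s (rho = %g g/cm^3)\n",
              object$reference$name, object$reference$density))
  cat(sprintf("  measured mu    : %g cm^-1\n", object$measured_mu))
  cat(sprintf("  effective energy: %.2f keV (bracket %g-%g keV)\n",
              object$effective_energy, object$bracket[1], object$bracket[2]))
  cat(sprintf("  residual       : %.3g cm^-1\n", object$residual))
  invisible(object)
}

#' Theoretical attenuation of candidate minerals at one energy
#'
#' Tabulates the linear attenuation coefficient of each candidate at the
#' given energy. Hydration series contribute an interval (anhydrous and
#' hydrate endpoints); plain materials a single value (\code{mu_min ==
#' mu_max}).
#'
#' @param candidates List of \code{material}/\code{hydration_series} objects
#'   (default: the natron constituents).
#' @param energy Energy in keV (scalar).
#' @inheritParams parse_formula
#' @return A data.frame with \code{name}, \code{density} (g/cm^3; \code{NA}
#'   for series, which carry two), \code{mu_min}, \code{mu_max} (cm^-1).
#' @export
#' @examples
#' candidate_table(energy = 146.1)
candidate_table <- function(candidates = natron_candidates(), energy,
                            table = default_attenuation_table()) {
  stopifnot(is.list(candidates), is.numeric(energy), length(energy) == 1L)
  if (length(candidates) == 0) {
    return(data.frame(name = character(0), density = numeric(0),
                      mu_min = numeric(0), mu_max = numeric(0)))
  }
  rows <- lapply(candidates, function(m) {
    if (inherits(m, "hydration_series")) {
      mu <- hydration_series_mu(m, energy, table = table)
      data.frame(name = m$name, density = NA_real_,
                 mu_min = min(mu), mu_max = max(mu))
    } else {
      mu <- linear_attenuation(m, energy, table = table)
      data.frame(name = m$name, density = m$density, mu_min = mu, mu_max = mu)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "energy_keV") <- energy
  out
}

#' Classify measured inclusion attenuation against candidate minerals
#'
#' A candidate is compatible when its theoretical attenuation value (or
#' endpoint interval, for a hydration series) intersects the measured band
#' \code{[avg - tolerance, max + tolerance]}. Widening the tolerance can only
#' add compatible candidates, never remove one. The verdict is "consistent
#' with natron" as soon as at least one natron candidate is compatible.
#'
#' @param measured Either a numeric vector of per-inclusion mean attenuations
#'   (cm^-1) or a list/vector with elements \code{average} and \code{maximum}.
#' @param scores A candidate table from [candidate_table()] (or a candidate
#'   list plus \code{energy}).
#' @param tolerance Symmetric absolute tolerance in cm^-1 (default 0.01,
#'   about 3\% of the typical inclusion attenuation).
#' @param energy Energy in keV, required when \code{scores} is a candidate
#'   list rather than a table.
#' @inheritParams parse_formula
#' @return A \code{natron_classification}: the score table with a
#'   \code{compatible} flag and attributes \code{measured} and \code{verdict}.
#' @export
#' @examples
#' cls <- classify_measurements(c(average = 0.297, maximum = 0.334),
#'                              candidate_table(energy = 146.1))
#' attr(cls, "verdict")
classify_measurements <- function(measured, scores, tolerance = 0.01,
                                  energy = NULL,
                                  table = default_attenuation_table()) {
  stopifnot(tolerance >= 0)
  if (is.list(scores) && !is.data.frame(scores)) {
    if (is.null(energy)) stop("give 'energy' when passing a candidate list")
    scores <- candidate_table(scores, energy, table = table)
  }
  stopifnot(is.data.frame(scores),
            all(c("name", "mu_min", "mu_max") %in% names(scores)))
  if (is.list(measured)) measured <- unlist(measured)
  if (length(measured) == 0 || !is.numeric(measured) || any(is.na(measured))) {
    stop("empty or non-numeric measurement set")
  }
  if (!is.null(names(measured)) && all(c("average", "maximum") %in% names(measured))) {
    lo <- measured[["average"]]; hi <- measured[["maximum"]]
  } else {
    lo <- mean(measured); hi <- max(measured)
  }
  if (hi < lo) stop("measured maximum is below measured average")
  band <- c(lo - tolerance, hi + tolerance)
  scores$delta_avg <- pmax(scores$mu_min - lo, lo - scores$mu_max, 0)
  scores$delta_max <- pmax(scores$mu_min - hi, hi - scores$mu_max, 0)
  scores$compatible <- scores$mu_max >= band[1] & scores$mu_min <= band[2]
  verdict <- if (any(scores$compatible)) {
    "consistent with natron constituents"
  } else {
    "not consistent with any candidate"
  }
  structure(scores, measured = c(average = lo, maximum = hi),
            tolerance = tolerance, verdict = verdict,
            class = c("natron_classification", "data.frame"))
}

#' @export
print.natron_classification <- function(x, ...) {
  m <- attr(x, "measured")
  cat(sprintf("Measured inclusion mu: average %.4g, maximum %.4g cm^-1 (tolerance %.3g)\n",
              m[["average"]], m[["maximum"]], attr(x, "tolerance")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat("Verdict:", attr(x, "verdict"), "\n")
  invisible(x)
}
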