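# End-to-end analysis: spectrum diagnostics -> volume (synthetic or measured
# values) -> effective-energy calibration -> inclusion measurement ->
# candidate classification.

#' Assemble and validate a pipeline configuration
#'
#' All referenced materials and presets are resolved immediately so that a
#' misconfigured run fails before any computation starts.
#'
#' @param mode \code{"synthetic"} (generate a phantom, measure the reference
#'   region and the inclusions) or \code{"measured"} (use supplied
#'   attenuation values, as when reading numbers off a real scan).
#' @param reference Reference material for energy calibration (bundled name
#'   or \code{material}).
#' @param measured For \code{mode = "measured"}: list with
#'   \code{reference_mu}, \code{average}, \code{maximum} (cm^-1).
#' @param synthetic For \code{mode = "synthetic"}: list with \code{energy}
#'   (generation energy in keV), and optionally \code{phantom} (a
#'   \code{phantom_spec}; default [mummy_phantom_spec()] with the run seed),
#'   \code{threshold} (default 0.25 cm^-1), \code{min_size} (default 27),
#'   \code{reference_label} (default 1).
#' @param candidates Candidate materials (default: natron constituents).
#' @param tolerance Classification tolerance in cm^-1.
#' @param bracket Calibration bracket in keV.
#' @param beamline Optional beamline preset name (adds a detected-spectrum
#'   summary and beam-hardening diagnostic to the report).
#' @param seed Integer seed for the synthetic stage.
#' @return A validated \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("synthetic", "measured"),
                            reference = "hydroxyapatite",
                            measured = NULL, synthetic = NULL,
                            candidates = NULL, tolerance = 0.01,
                            bracket = c(50, 300), beamline = NULL,
                            seed = 42L) {
  mode <- match.arg(mode)
  table <- default_attenuation_table()
  reference <- resolve_material(reference, table)
  if (!inherits(reference, "material")) {
    stop("the calibration reference must be a single-density material")
  }
  if (is.null(candidates)) {
    candidates <- natron_candidates(table)
  } else if (is.character(candidates)) {
    candidates <- stats::setNames(lapply(candidates, resolve_material,
                                         table = table), candidates)
  }
  if (mode == "measured") {
    if (is.null(measured) ||
        !all(c("reference_mu", "average", "maximum") %in% names(measured))) {
      stop("mode 'measured' needs measured$reference_mu, $average, $maximum")
    }
  } else {
    if (is.null(synthetic) || is.null(synthetic$energy)) {
      stop("mode 'synthetic' needs synthetic$energy (keV)")
    }
    synthetic$threshold <- synthetic$threshold %||% 0.25
    synthetic$min_size <- synthetic$min_size %||% 27L
    synthetic$reference_label <- synthetic$reference_label %||% 1L
  }
  if (!is.null(beamline)) beamline_preset(beamline)  # fail fast on bad preset
  stopifnot(tolerance > 0, length(bracket) == 2L, bracket[1] < bracket[2])
  structure(list(mode = mode, reference = reference, measured = measured,
                 synthetic = synthetic, candidates = candidates,
                 tolerance = tolerance, bracket = bracket,
                 beamline = beamline, seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean attenuation over the n-fold eroded interior of one labelled region
.region_mean <- function(mu, labels, label, erode = 2L) {
  mask <- labels == label
  d <- dim(mask)
  for (i in seq_len(erode)) {
    er <- mask
    er[c(1, d[1]), , ] <- FALSE; er[, c(1, d[2]), ] <- FALSE
    er[, , c(1, d[3])] <- FALSE
    idx <- which(er)
    if (length(idx) == 0) break
    co <- arrayInd(idx, d)
    keep <- rep(TRUE, length(idx))
    for (k in seq_len(nrow(.offsets26))) {
      nb <- sweep(co, 2, .offsets26[k, ], "+")
      keep <- keep & mask[.lin_idx(nb, d)]
    }
    er[idx[!keep]] <- FALSE
    if (!any(er)) break  # erosion would empty the region: stop one step early
    mask <- er
  }
  mean(mu[mask])
}

#' Run the end-to-end identification pipeline
#'
#' Stages: (1) optional detected-spectrum summary with a water
#' beam-hardening diagnostic; (2) obtain measurements -- either generate a
#' labelled phantom, read the reference-region attenuation off its
#' ground-truth label and segment the inclusions, or take the supplied
#' measured values; (3) invert the reference attenuation to an effective
#' energy; (4) tabulate candidate attenuations at that energy; (5) classify
#' the measured inclusion band against the candidates.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Optional output directory; when given, writes
#'   \code{report.json}, \code{candidates.csv}, \code{inclusions.csv} and
#'   (synthetic mode) the phantom TIFF stack.
#' @return A \code{natron_report}.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(mode = "measured",
#'                        measured = list(reference_mu = 0.274,
#'                                        average = 0.297, maximum = 0.334))
#' rep <- run_pipeline(cfg)
#' rep$calibration$effective_energy
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(config = config, package_version =
                   as.character(utils::packageVersion("natronid")))

  if (!is.null(config$beamline)) {
    report$spectrum <- stage("spectrum", {
      bl <- beamline_preset(config$beamline)
      s <- detected_spectrum(bl)
      bh <- beam_hardening_curve(s, resolve_material("water"), seq(0, 6, by = 1))
      list(preset = config$beamline, average_energy_keV = average_energy(s),
           peak_energy_keV = s$energy[which.max(s$weight)],
           water_hardening_max_rel_dev = attr(bh, "max_rel_dev"),
           spectrum = s)
    })
  }

  vol <- NULL
  if (config$mode == "synthetic") {
    syn <- config$synthetic
    vol <- stage("phantom", {
      sp <- syn$phantom %||% mummy_phantom_spec(seed = config$seed)
      generate_phantom(sp, energy = syn$energy)
    })
    meas <- stage("measure", {
      ref_mu <- .region_mean(vol$mu, vol$labels, syn$reference_label)
      masked <- vol$mu
      masked[vol$labels == syn$reference_label] <- min(vol$mu)
      seg <- segment_inclusions(masked, threshold = syn$threshold,
                                min_size = syn$min_size)
      if (seg$summary$n_inclusions == 0) {
        stop("no inclusions found above threshold ", syn$threshold)
      }
      truth <- vol$ground_truth[vol$ground_truth$label != syn$reference_label, ]
      list(reference_mu = ref_mu, average = seg$summary$mean_of_means,
           maximum = seg$summary$max_mu, segmentation = seg,
           recovery = recovery_report(seg, truth))
    })
    report$measurement <- meas
  } else {
    report$measurement <- list(reference_mu = config$measured$reference_mu,
                               average = config$measured$average,
                               maximum = config$measured$maximum)
  }

  report$calibration <- stage("calibrate", {
    effective_energy_from_reference(report$measurement$reference_mu,
                                    config$reference, bracket = config$bracket)
  })
  e_eff <- report$calibration$effective_energy

  report$candidates <- stage("candidates", {
    candidate_table(config$candidates, energy = e_eff)
  })

  report$classification <- stage("classify", {
    classify_measurements(c(average = report$measurement$average,
                            maximum = report$measurement$maximum),
                          report$candidates, tolerance = config$tolerance)
  })
  report$verdict <- attr(report$classification, "verdict")

  class(report) <- "natron_report"
  if (!is.null(out_dir)) write_report(report, out_dir, volume = vol)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A \code{natron_report}.
#' @param out_dir Output directory (created if missing).
#' @param volume Optional \code{phantom_volume} to save alongside.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir, volume = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(as.data.frame(report$candidates),
                         compatible = report$classification$compatible),
                   file.path(out_dir, "candidates.csv"), row.names = FALSE)
  if (!is.null(report$measurement$segmentation)) {
    utils::write.csv(report$measurement$segmentation$stats,
                     file.path(out_dir, "inclusions.csv"), row.names = FALSE)
  }
  if (!is.null(volume)) {
    write_volume(volume, file.path(out_dir, "phantom.tif"))
  }
  json <- list(
    package_version = report$package_version,
    mode = report$config$mode,
    seed = report$config$seed,
    tolerance_cm1 = report$config$tolerance,
    reference = report$config$reference$name,
    spectrum = if (!is.null(report$spectrum)) {
      report$spectrum[c("preset", "average_energy_keV", "peak_energy_keV",
                        "water_hardening_max_rel_dev")]
    },
    measurement = report$measurement[c("reference_mu", "average", "maximum")],
    effective_energy_keV = report$calibration$effective_energy,
    calibration_residual = report$calibration$residual,
    candidates = as.data.frame(report$candidates),
    compatible = report$classification$compatible,
    verdict = report$verdict)
  if (!is.null(report$measurement$recovery)) {
    json$recovery <- report$measurement$recovery[c("precision", "recall")]
  }
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.natron_report <- function(x, ...) {
  cat("== natronid pipeline report ==\n")
  if (!is.null(x$spectrum)) {
    cat(sprintf("spectrum (%s): average detected energy %.1f keV, water hardening %.2f%% over 0-6 cm\n",
                x$spectrum$preset, x$spectrum$average_energy_keV,
                100 * x$spectrum$water_hardening_max_rel_dev))
  }
  m <- x$measurement
  cat(sprintf("measured: reference mu %.4g; inclusions average %.4g, maximum %.4g cm^-1\n",
              m$reference_mu, m$average, m$maximum))
  cat(sprintf("effective energy: %.1f keV (reference %s)\n",
              x$calibration$effective_energy, x$config$reference$name))
  if (!is.null(m$recovery)) {
    cat(sprintf("recovery: precision %.2f, recall %.2f\n",
                m$recovery$precision, m$recovery$recall))
  }
  print(x$classification)
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; see the bundled
#' example in \code{system.file("extdata", "demo_config.yaml", package =
#' "natronid")}.
#'
#' @param path YAML file path.
#' @return A validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}
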