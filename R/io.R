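# Volume I/O: multi-page TIFF stacks (one page per z slice) with a JSON
# sidecar carrying voxel size, energy, the affine intensity scaling and any
# ground truth; labels as a 16-bit integer stack.

#' Write an attenuation volume as a TIFF stack
#'
#' Writes \code{<path>} (attenuation, 32-bit, one page per slice),
#' \code{<path>.json} (sidecar: voxel size, energy, offset/scale mapping
#' stored values back to cm^-1, ground truth) and, when labels are present,
#' \code{<path base>_labels.tif} (16-bit). TIFF pages store values in [0, 1];
#' attenuation is mapped affinely and the mapping recorded in the sidecar.
#'
#' @param vol A \code{phantom_volume} (or 3D array, in which case voxel size
#'   and energy default to NA).
#' @param path Output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "phantom_volume")) {
    vol <- structure(list(mu = vol, labels = NULL, ground_truth = NULL,
                          voxel_size_um = NA_real_, energy_keV = NA_real_),
                     class = "phantom_volume")
  }
  mu <- vol$mu
  lo <- min(mu); hi <- max(mu)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(mu)[3]), function(z) (mu[, , z] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(voxel_size_um = vol$voxel_size_um,
                  energy_keV = vol$energy_keV,
                  mu_offset = lo, mu_scale = scale,
                  dim = dim(mu))
  labels_path <- NULL
  if (!is.null(vol$labels)) {
    labels_path <- sub("\\.tiff?$", "", path)
    labels_path <- paste0(labels_path, "_labels.tif")
    lp <- lapply(seq_len(dim(vol$labels)[3]),
                 function(z) vol$labels[, , z] / 65535)
    tiff::writeTIFF(lp, labels_path, bits.per.sample = 16L)
    sidecar$labels_file <- basename(labels_path)
  }
  if (!is.null(vol$ground_truth)) sidecar$ground_truth <- vol$ground_truth
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an attenuation volume written by [write_volume()]
#'
#' @param path TIFF path (the sidecar \code{<path>.json} must sit next to it).
#' @return A \code{phantom_volume}.
#' @export
read_volume <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop("missing sidecar file ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  mu <- array(unlist(pages), dim = d)
  mu <- mu * side$mu_scale + side$mu_offset
  labels <- NULL
  if (!is.null(side$labels_file)) {
    lp <- file.path(dirname(path), side$labels_file)
    lpages <- tiff::readTIFF(lp, all = TRUE, as.is = TRUE)
    labels <- array(as.integer(unlist(lpages)), dim = d)
  }
  gt <- if (!is.null(side$ground_truth)) as.data.frame(side$ground_truth)
  structure(list(mu = mu, labels = labels, ground_truth = gt,
                 voxel_size_um = side$voxel_size_um,
                 energy_keV = side$energy_keV),
            class = "phantom_volume")
}

#' Export a detected spectrum as two-column CSV
#'
#' @param s A \code{detected_spectrum}.
#' @param path Output CSV path (columns \code{energy_keV}, \code{weight}).
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "detected_spectrum"))
  utils::write.csv(data.frame(energy_keV = s$energy, weight = s$weight),
                   path, row.names = FALSE)
  invisible(path)
}
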