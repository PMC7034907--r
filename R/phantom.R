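# Synthetic mu-volume phantoms with ground-truth labels: geometry, detector
# blur + noise degradation, and a single-distance phase-retrieval toy.

#' Specify a synthetic phantom
#'
#' A phantom is a uniform background with ellipsoid/box primitives stamped
#' into it; later primitives overwrite earlier ones where they overlap.
#' Materials are resolved to linear attenuation values when the phantom is
#' generated at a chosen energy; the background may instead fix its
#' attenuation directly (organic balm has no single chemical formula).
#'
#' @param dim Integer vector of 3 voxel counts.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param background Either \code{list(mu = )} (cm^-1) or a
#'   material/bundled material name.
#' @param shapes List of primitives: each a list with \code{type}
#'   ("ellipsoid" or "box"), \code{center} (voxel coords, may be fractional),
#'   \code{radii} (3 half-axes in voxels; for a box the half-widths), and
#'   \code{material} (material object or bundled name).
#' @param psf_sigma Detector point-spread sigma in voxels (Gaussian blur).
#' @param noise_sigma Additive Gaussian noise sigma in cm^-1.
#' @param seed Integer seed driving the noise (determinism contract: equal
#'   spec + energy gives bit-identical volumes).
#' @return A \code{phantom_spec}.
#' @export
phantom_spec <- function(dim, voxel_size_um, background, shapes = list(),
                         psf_sigma = 0, noise_sigma = 0, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0), voxel_size_um > 0,
            psf_sigma >= 0, noise_sigma >= 0)
  for (s in shapes) {
    stopifnot(is.list(s), s$type %in% c("ellipsoid", "box"),
              length(s$center) == 3L, length(s$radii) == 3L,
              all(s$radii > 0))
    if (any(s$center - s$radii < 0.5) || any(s$center + s$radii > dim + 0.5)) {
      stop("shape at center (", paste(s$center, collapse = ","),
           ") extends outside the grid")
    }
  }
  structure(list(dim = dim, voxel_size_um = voxel_size_um,
                 background = background, shapes = shapes,
                 psf_sigma = psf_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.shape_mu <- function(x, energy, table) {
  if (is.list(x) && !inherits(x, "material") && !is.null(x$mu)) return(x$mu)
  mat <- resolve_material(if (is.list(x) && !is.null(x$material)) x$material else x,
                          table)
  if (inherits(mat, "hydration_series")) {
    stop("phantom primitives need a single-density material, not a series")
  }
  linear_attenuation(mat, energy, table = table)
}

.shape_name <- function(x) {
  if (is.list(x) && !inherits(x, "material")) {
    if (!is.null(x$material)) x <- x$material else return(if (!is.null(x$name)) x$name else "fixed-mu")
  }
  if (inherits(x, "material")) x$name else as.character(x)
}

#' Generate a labelled phantom volume at a given energy
#'
#' @param spec A \code{phantom_spec}.
#' @param energy Photon energy in keV at which material attenuations are
#'   evaluated.
#' @inheritParams parse_formula
#' @return A \code{phantom_volume}: list with \code{mu} (3D array, cm^-1),
#'   \code{labels} (3D integer array; 0 = background, k = k-th primitive),
#'   \code{ground_truth} (data.frame: label, material, true_mu, center,
#'   radius), \code{voxel_size_um}, \code{energy_keV}.
#' @export
#' @examples
#' sp <- phantom_spec(c(32, 32, 32), 50, background = list(mu = 0.18),
#'                    shapes = list(list(type = "ellipsoid",
#'                                       center = c(16, 16, 16),
#'                                       radii = c(6, 6, 6),
#'                                       material = "halite")))
#' vol <- generate_phantom(sp, energy = 146.1)
#' table(vol$labels)
generate_phantom <- function(spec, energy,
                             table = default_attenuation_table()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  bg_mu <- .shape_mu(spec$background, energy, table)
  mu <- array(bg_mu, dim = d)
  labels <- array(0L, dim = d)
  gt <- data.frame(label = integer(0), material = character(0),
                   true_mu = numeric(0), cx = numeric(0), cy = numeric(0),
                   cz = numeric(0), radius = numeric(0))
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  for (k in seq_along(spec$shapes)) {
    s <- spec$shapes[[k]]
    val <- .shape_mu(s, energy, table)
    ctr <- s$center; r <- s$radii
    ix <- ax[abs(ax - ctr[1]) <= r[1]]
    iy <- ay[abs(ay - ctr[2]) <= r[2]]
    iz <- az[abs(az - ctr[3]) <= r[3]]
    if (identical(s$type, "ellipsoid")) {
      q <- outer(outer(((ix - ctr[1]) / r[1])^2, ((iy - ctr[2]) / r[2])^2, "+"),
                 ((iz - ctr[3]) / r[3])^2, "+")
      inside <- q <= 1
    } else {
      inside <- array(TRUE, dim = c(length(ix), length(iy), length(iz)))
    }
    mu[ix, iy, iz][inside] <- val
    labels[ix, iy, iz][inside] <- k
    gt <- rbind(gt, data.frame(label = k, material = .shape_name(s),
                               true_mu = val, cx = ctr[1], cy = ctr[2],
                               cz = ctr[3], radius = max(r)))
  }
  vol <- structure(list(mu = mu, labels = labels, ground_truth = gt,
                        voxel_size_um = spec$voxel_size_um,
                        energy_keV = energy),
                   class = "phantom_volume")
  if (spec$psf_sigma > 0 || spec$noise_sigma > 0) {
    vol <- degrade(vol, spec$psf_sigma, spec$noise_sigma, seed = spec$seed)
  }
  vol
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume> ", paste(dim(x$mu), collapse = "x"), " voxels @ ",
      x$voxel_size_um, " um, ", nrow(x$ground_truth), " primitive(s), mu in [",
      format(min(x$mu), digits = 3), ", ", format(max(x$mu), digits = 3),
      "] cm^-1 at ", x$energy_keV, " keV\n", sep = "")
  invisible(x)
}

#' @export
plot.phantom_volume <- function(x, slice = NULL, ...) {
  if (is.null(slice)) slice <- ceiling(dim(x$mu)[3] / 2)
  graphics::image(x$mu[, , slice], asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(256),
                  main = paste0("slice z=", slice), ...)
  invisible(x)
}

# 1-D Gaussian blur operator with mirror boundary; columns sum to 1 so that
# K %*% x redistributes (conserves) mass exactly.
.blur_matrix <- function(n, sigma) {
  m <- max(1L, ceiling(4 * sigma))
  off <- -m:m
  k <- exp(-off^2 / (2 * sigma^2)); k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- j + off
    i <- ifelse(i < 1L, 1L - i, i)       # mirror: 0 -> 1, -1 -> 2
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    for (t in seq_along(i)) K[i[t], j] <- K[i[t], j] + k[t]
  }
  K
}

.gaussian_blur3d <- function(a, sigma) {
  d <- dim(a)
  K1 <- .blur_matrix(d[1], sigma)
  a <- array(K1 %*% matrix(a, d[1]), dim = d)
  K2 <- .blur_matrix(d[2], sigma)
  a <- aperm(array(K2 %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                   dim = d[c(2, 1, 3)]), c(2, 1, 3))
  K3 <- .blur_matrix(d[3], sigma)
  aperm(array(K3 %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
              dim = d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Degrade a phantom with detector blur and noise
#'
#' Gaussian blur (separable, mirror boundary -- conserves the volume mean)
#' followed by additive Gaussian noise on the reconstructed attenuation
#' values. Labels and ground truth pass through unchanged. The caller's RNG
#' state is left untouched.
#'
#' @param vol A \code{phantom_volume}.
#' @param psf_sigma Blur sigma in voxels.
#' @param noise_sigma Noise sigma in cm^-1.
#' @param seed Integer seed for the noise draw.
#' @return The degraded \code{phantom_volume}.
#' @export
degrade <- function(vol, psf_sigma, noise_sigma, seed = 1L) {
  stopifnot(inherits(vol, "phantom_volume"), psf_sigma >= 0, noise_sigma >= 0)
  mu <- vol$mu
  if (psf_sigma > 0) mu <- .gaussian_blur3d(mu, psf_sigma)
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    mu <- mu + array(stats::rnorm(length(mu), 0, noise_sigma), dim = dim(mu))
  }
  vol$mu <- mu
  vol
}

#' Default mummified-specimen phantom
#'
#' Emulates the imaging situation inside the first balm layer: a low
#' attenuation organic matrix (balm, mu = 0.18 cm^-1 by default), one
#' bone-like reference ellipsoid (hydroxyapatite at 1.8 g/cm^3, label 1) and
#' \code{n_inclusions} small dense mineral spheres (alternating halite and
#' nahcolite, radii 3-10 voxels), with detector blur (sigma 0.7 voxel) and
#' additive noise (sigma 0.01 cm^-1). Inclusions are placed without mutual
#' overlap by rejection sampling, reproducibly from the seed.
#'
#' @param seed Integer seed (placement and noise).
#' @param dim Voxel grid (default 96^3).
#' @param n_inclusions Number of mineral spheres (default 20).
#' @param balm_mu Background attenuation in cm^-1.
#' @param psf_sigma,noise_sigma Degradation parameters.
#' @param voxel_size_um Voxel size (default 53.19 um, the overview-scan size).
#' @return A \code{phantom_spec}; generate with [generate_phantom()].
#' @export
#' @examples
#' vol <- generate_phantom(mummy_phantom_spec(seed = 42), energy = 146.1)
mummy_phantom_spec <- function(seed = 42L, dim = c(96, 96, 96),
                               n_inclusions = 20L, balm_mu = 0.18,
                               psf_sigma = 0.7, noise_sigma = 0.01,
                               voxel_size_um = 53.19) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ref_radii <- pmin(c(10, 14, 18), (dim - 3) / 2)
  shapes <- list(list(type = "ellipsoid",
                      center = c(2 + ref_radii[1], dim[2] / 2, dim[3] / 2),
                      radii = ref_radii, material = "hydroxyapatite"))
  x0 <- 2 + 2 * ref_radii[1] + 2  # inclusions live right of the reference
  r_max <- min(10, (dim[1] - x0 - 2) / 2, (min(dim[2:3]) - 3) / 2)
  if (r_max < 3) stop("grid too small for the default inclusion radii (3-10 voxels)")
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  tries <- 0L
  while (length(radii) < n_inclusions && tries < 20000L) {
    tries <- tries + 1L
    r <- stats::runif(1, 3, r_max)
    ctr <- c(stats::runif(1, x0 + r, dim[1] - r - 1),
             stats::runif(1, 1 + r, dim[2] - r - 1),
             stats::runif(1, 1 + r, dim[3] - r - 1))
    if (nrow(centers) > 0) {
      d2 <- sqrt(colSums((t(centers) - ctr)^2))
      if (any(d2 < radii + r + 2)) next
    }
    centers <- rbind(centers, ctr)
    radii <- c(radii, r)
  }
  if (length(radii) < n_inclusions) {
    stop("could not place ", n_inclusions, " non-overlapping inclusions")
  }
  for (i in seq_len(n_inclusions)) {
    shapes[[i + 1L]] <- list(type = "ellipsoid", center = centers[i, ],
                             radii = rep(radii[i], 3),
                             material = if (i %% 2 == 1) "halite" else "nahcolite")
  }
  phantom_spec(dim, voxel_size_um, background = list(name = "balm", mu = balm_mu),
               shapes = shapes, psf_sigma = psf_sigma,
               noise_sigma = noise_sigma, seed = seed)
}

#' Single-distance phase retrieval (homogeneous-object low-pass filter)
#'
#' Converts one propagation-distance intensity image \eqn{I/I_0} into a
#' projected-thickness map for a homogeneous object:
#' \deqn{t = -\frac{1}{\mu}\ln \mathcal{F}^{-1}\!\left[
#'   \frac{\mathcal{F}(I/I_0)}{1 + \pi\lambda D(\delta/\beta)|k|^2}\right]}
#' with \eqn{|k|} the spatial frequency in cycles per metre. With
#' \eqn{\delta/\beta = 0} or \eqn{D = 0} the filter is the identity and the
#' result is the plain Beer-Lambert log conversion.
#'
#' @param intensity 2D matrix of flat-field-normalised intensities (> 0).
#' @param delta_beta Ratio of refractive index decrement to absorption index.
#' @param distance_m Propagation distance in metres.
#' @param energy_keV Photon energy in keV.
#' @param pixel_um Detector pixel size in micrometres.
#' @param mu Linear attenuation of the (assumed homogeneous) object, cm^-1.
#' @return Projected thickness map in cm (same shape as \code{intensity}).
#' @export
paganin_retrieve <- function(intensity, delta_beta, distance_m, energy_keV,
                             pixel_um, mu) {
  stopifnot(is.matrix(intensity), all(intensity > 0), delta_beta >= 0,
            distance_m >= 0, energy_keV > 0, pixel_um > 0, mu > 0)
  lambda_m <- 1.239841984e-9 / energy_keV
  d <- dim(intensity)
  fx <- c(0:floor(d[1] / 2), -(ceiling(d[1] / 2) - 1):-1) / (d[1] * pixel_um * 1e-6)
  fy <- c(0:floor(d[2] / 2), -(ceiling(d[2] / 2) - 1):-1) / (d[2] * pixel_um * 1e-6)
  k2 <- outer(fx^2, fy^2, "+")
  filt <- 1 / (1 + pi * lambda_m * distance_m * delta_beta * k2)
  sm <- Re(stats::fft(stats::fft(intensity) * filt, inverse = TRUE)) / length(intensity)
  if (any(sm <= 0)) stop("filtered intensity is not positive; inputs are inconsistent")
  -log(sm) / mu
}
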