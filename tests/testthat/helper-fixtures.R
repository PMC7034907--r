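# Shared fixtures and independent oracles.

halite_mat <- function() material("halite", "NaCl", 2.17)
water_mat <- function() material("water", "H2O", 1.0)
bone_mat <- function() material("hydroxyapatite", "Ca10(PO4)6(OH)2", 1.8)

# tiny phantom with one or more spheres on a uniform background
sphere_phantom <- function(dim = c(40, 40, 40), centers, radii,
                           materials = "halite", mu_bg = 0.18,
                           energy = 146.1, psf = 0, noise = 0, seed = 1L) {
  centers <- if (is.matrix(centers)) centers else matrix(centers, ncol = 3,
                                                         byrow = TRUE)
  materials <- rep(materials, length.out = nrow(centers))
  radii <- rep(radii, length.out = nrow(centers))
  shapes <- lapply(seq_len(nrow(centers)), function(i) {
    list(type = "ellipsoid", center = centers[i, ], radii = rep(radii[i], 3),
         material = materials[i])
  })
  sp <- phantom_spec(dim, 50, background = list(mu = mu_bg), shapes = shapes,
                     psf_sigma = psf, noise_sigma = noise, seed = seed)
  generate_phantom(sp, energy = energy)
}

# independent 26-connected component labelling oracle: plain BFS flood fill
flood_fill_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}
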