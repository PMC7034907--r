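# 3D segmentation of dense inclusions and recovery statistics against
# ground truth.

# 26-neighbourhood offsets (excluding the origin)
.offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# linear index for coordinate matrix (n x 3), 1-based
.lin_idx <- function(co, d) {
  (co[, 3] - 1L) * (d[1] * d[2]) + (co[, 2] - 1L) * d[1] + co[, 1]
}

#' Segment dense inclusions in an attenuation volume
#'
#' Thresholds the volume, labels 26-connected components, discards those
#' smaller than \code{min_size}, and computes per-inclusion statistics on the
#' erosion-by-1 interior (every retained voxel has all 26 neighbours inside
#' the same component). Erosion suppresses partial-volume rims that would
#' otherwise bias mean attenuation low; when it empties a small component the
#' full component is used instead.
#'
#' @param vol A \code{phantom_volume} or a 3D numeric array of attenuation
#'   values (cm^-1).
#' @param threshold Attenuation threshold in cm^-1; voxels strictly above it
#'   are foreground.
#' @param min_size Minimum component size in voxels (default 27, a 3x3x3
#'   block).
#' @param erode Use the eroded interior for mean/max statistics (default TRUE).
#' @return A list of class \code{inclusion_stats}: \code{labels} (3D integer
#'   array, 0 = background), \code{stats} (data.frame: id, voxels,
#'   interior_voxels, mean_mu, max_mu, cx, cy, cz) and \code{summary}
#'   (average of per-inclusion means, voxel-weighted mean, overall maximum,
#'   count). An empty result (no voxel above threshold, or all components
#'   too small) is returned as zero inclusions, not an error.
#' @export
#' @examples
#' sp <- phantom_spec(c(40, 40, 40), 50, background = list(mu = 0.18),
#'                    shapes = list(list(type = "ellipsoid",
#'                                       center = c(20, 20, 20),
#'                                       radii = c(6, 6, 6),
#'                                       material = "halite")))
#' seg <- segment_inclusions(generate_phantom(sp, 146.1), threshold = 0.25)
#' seg$stats
segment_inclusions <- function(vol, threshold, min_size = 27L, erode = TRUE) {
  mu <- if (inherits(vol, "phantom_volume")) vol$mu else vol
  stopifnot(is.array(mu), length(dim(mu)) == 3L, is.numeric(threshold))
  d <- dim(mu)
  fg <- which(mu > threshold)
  empty <- list(labels = array(0L, d),
                stats = data.frame(id = integer(0), voxels = integer(0),
                                   interior_voxels = integer(0),
                                   mean_mu = numeric(0), max_mu = numeric(0),
                                   cx = numeric(0), cy = numeric(0),
                                   cz = numeric(0)),
                summary = list(mean_of_means = NA_real_,
                               voxel_weighted_mean = NA_real_,
                               max_mu = NA_real_, n_inclusions = 0L))
  class(empty) <- "inclusion_stats"
  if (length(fg) == 0) return(empty)

  co <- arrayInd(fg, d)
  vox_id <- array(0L, d)
  vox_id[fg] <- seq_along(fg)
  edges <- vector("list", 13L)
  e_i <- 0L
  for (k in seq_len(nrow(.offsets26))) {
    off <- .offsets26[k, ]
    if (off[1] < 0 || (off[1] == 0 && (off[2] < 0 || (off[2] == 0 && off[3] < 0)))) {
      next  # each unordered pair once: forward offsets only
    }
    nb <- sweep(co, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nid <- vox_id[.lin_idx(nb[ok, , drop = FALSE], d)]
    hit <- nid > 0L
    if (!any(hit)) next
    e_i <- e_i + 1L
    edges[[e_i]] <- rbind(which(ok)[hit], nid[hit])
  }
  g <- igraph::make_graph(edges = if (e_i > 0) c(do.call(cbind, edges[seq_len(e_i)])) else integer(0),
                          n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  keep <- which(sizes >= min_size)
  if (length(keep) == 0) return(empty)
  new_id <- integer(length(sizes))
  new_id[keep] <- seq_along(keep)
  lab_fg <- new_id[memb]

  labels <- array(0L, d)
  labels[fg] <- lab_fg

  # erosion-by-1: keep voxels whose 26 neighbours all exist and share the label
  interior <- rep(lab_fg > 0L, length.out = length(fg))
  inner_ok <- co[, 1] > 1 & co[, 1] < d[1] & co[, 2] > 1 & co[, 2] < d[2] &
    co[, 3] > 1 & co[, 3] < d[3]
  interior <- interior & inner_ok
  for (k in seq_len(nrow(.offsets26))) {
    if (!any(interior)) break
    idx <- which(interior)
    nb <- sweep(co[idx, , drop = FALSE], 2, .offsets26[k, ], "+")
    same <- labels[.lin_idx(nb, d)] == lab_fg[idx]
    interior[idx[!same]] <- FALSE
  }

  ids <- seq_along(keep)
  stats <- do.call(rbind, lapply(ids, function(i) {
    sel <- lab_fg == i
    use <- if (erode && any(interior & sel)) interior & sel else sel
    data.frame(id = i, voxels = sum(sel), interior_voxels = sum(interior & sel),
               mean_mu = mean(mu[fg[use]]), max_mu = max(mu[fg[use]]),
               cx = mean(co[sel, 1]), cy = mean(co[sel, 2]), cz = mean(co[sel, 3]))
  }))
  # voxel-weighted global mean over the voxels actually used per inclusion
  wts <- ifelse(erode & stats$interior_voxels > 0, stats$interior_voxels,
                stats$voxels)
  out <- list(labels = labels, stats = stats,
              summary = list(mean_of_means = mean(stats$mean_mu),
                             voxel_weighted_mean =
                               sum(stats$mean_mu * wts) / sum(wts),
                             max_mu = max(stats$max_mu),
                             n_inclusions = nrow(stats)))
  class(out) <- "inclusion_stats"
  out
}

#' @export
print.inclusion_stats <- function(x, ...) {
  s <- x$summary
  cat("<inclusion_stats> ", s$n_inclusions, " inclusion(s)", sep = "")
  if (s$n_inclusions > 0) {
    cat(sprintf(": mean-of-means %.4g, voxel-weighted mean %.4g, max %.4g cm^-1",
                s$mean_of_means, s$voxel_weighted_mean, s$max_mu))
  }
  cat("\n")
  invisible(x)
}

#' Compare segmented inclusions against phantom ground truth
#'
#' Matches each segmented inclusion to the nearest ground-truth primitive
#' whose centre lies within \code{match_factor} times the primitive's radius
#' (greedy nearest-neighbour, each truth entry used once); unmatched
#' segmentations count as false positives, unmatched truth entries as
#' misses. Matching is purely geometric, so label permutations do not change
#' precision or recall.
#'
#' @param stats An \code{inclusion_stats} (or its \code{stats} data.frame).
#' @param truth Ground-truth data.frame with columns \code{label},
#'   \code{material}, \code{true_mu}, \code{cx}, \code{cy}, \code{cz},
#'   \code{radius} (as produced by [generate_phantom()]).
#' @param match_factor Matching radius as a multiple of the truth radius
#'   (default 2).
#' @return A list: \code{per_material} data.frame (material, n_matched,
#'   bias, rmse of interior mean attenuation), \code{precision},
#'   \code{recall}, \code{matches} data.frame.
#' @export
recovery_report <- function(stats, truth, match_factor = 2) {
  st <- if (inherits(stats, "inclusion_stats")) stats$stats else stats
  stopifnot(is.data.frame(st), is.data.frame(truth), nrow(truth) >= 0)
  n_pred <- nrow(st); n_true <- nrow(truth)
  matches <- data.frame(pred_id = integer(0), truth_label = integer(0),
                        dist = numeric(0))
  if (n_pred > 0 && n_true > 0) {
    used <- logical(n_true)
    ord <- order(-st$voxels)  # large components claim their truth first
    for (i in ord) {
      dd <- sqrt((truth$cx - st$cx[i])^2 + (truth$cy - st$cy[i])^2 +
                   (truth$cz - st$cz[i])^2)
      cand <- which(!used & dd <= match_factor * truth$radius)
      if (length(cand) == 0) next
      j <- cand[which.min(dd[cand])]
      used[j] <- TRUE
      matches <- rbind(matches, data.frame(pred_id = st$id[i],
                                           truth_label = truth$label[j],
                                           dist = dd[j]))
    }
  }
  per_mat <- NULL
  if (nrow(matches) > 0) {
    m <- merge(matches, truth, by.x = "truth_label", by.y = "label")
    m <- merge(m, st[, c("id", "mean_mu")], by.x = "pred_id", by.y = "id")
    err <- m$mean_mu - m$true_mu
    per_mat <- do.call(rbind, lapply(split(err, m$material), function(e) {
      data.frame(n_matched = length(e), bias = mean(e),
                 rmse = sqrt(mean(e^2)))
    }))
    per_mat <- cbind(material = rownames(per_mat), per_mat)
    rownames(per_mat) <- NULL
  }
  list(per_material = per_mat,
       precision = if (n_pred > 0) nrow(matches) / n_pred else NA_real_,
       recall = if (n_true > 0) nrow(matches) / n_true else NA_real_,
       matches = matches)
}
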