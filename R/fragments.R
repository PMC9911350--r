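#' Per-voxel boundary evidence from direct-neighbor affinities
#'
#' Averages, at every voxel, the valid direct-neighbor affinity values
#' incident to it: channel `j` at `v` (the pair `v`, `v + n_j`) and channel
#' `j` at `v - n_j` (the pair `v - n_j`, `v`). High values mean object
#' interior, low values mean boundary or background; the map lies in
#' `[0, 1]` and is the quantity thresholded to obtain the watershed mask.
#'
#' @param affs an [annotated_volume()] of kind `"affinities"` whose first
#'   three channels are the direct neighborhood `(-1,0,0), (0,-1,0),
#'   (0,0,-1)`; extra (long-range) channels are ignored.
#' @return a scalar [annotated_volume()] of kind `"raw"` in `[0, 1]`.
#' @export
boundary_map <- function(affs) {
  stopifnot(inherits(affs, "annotated_volume"), affs$kind == "affinities")
  if (vol_channels(affs) < 3L)
    stop("need at least the 3 direct-neighbor affinity channels")
  d <- vol_shape(affs)
  direct <- rbind(c(-1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 0L, -1L))
  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (j in 1:3) {
    a <- array(affs$data[j, , , ], dim = d)
    m <- if (!is.null(affs$mask)) array(affs$mask[j, , , ], dim = d)
         else array(1, dim = d)
    acc <- acc + a * m
    cnt <- cnt + m
    # the same channel, seen from the lower-index voxel of each pair
    acc <- acc + shift_array(a * m, -direct[j, ])
    cnt <- cnt + shift_array(m, -direct[j, ])
  }
  out <- acc / pmax(cnt, 1)
  annotated_volume(out, affs$voxel_size, affs$offset, kind = "raw")
}

#' 6-connected components of equal nonzero labels
#'
#' @param vol an [annotated_volume()] with integer labels (0 = background).
#' @return an [annotated_volume()] of the same kind with components
#'   relabeled `1..k` in scan order.
#' @export
connected_components <- function(vol) {
  a <- vol$data
  storage.mode(a) <- "integer"
  cc <- .cc_labels_cpp(a, dim(a))
  annotated_volume(cc, vol$voxel_size, vol$offset, kind = vol$kind)
}

#' Anisotropy-aware Euclidean distance transform
#'
#' Distance (nm) from every in-mask voxel to the nearest background voxel,
#' with per-axis voxel sizes taken into account (exact squared-distance
#' transform computed separably).
#'
#' @param mask logical/0-1 3D array.
#' @param voxel_size nm per voxel `(z, y, x)`.
#' @return numeric 3D array of distances in nm (0 outside the mask).
#' @export
distance_transform <- function(mask, voxel_size) {
  m <- array(as.integer(mask != 0), dim = dim(mask))
  sqrt(.edt_sq_cpp(m, dim(m), as.numeric(voxel_size)))
}

# seeds from the distance transform: plateau-collapsed local maxima followed
# by non-maximum suppression at a world-unit radius; deterministic
# (ties by DT value, then lexicographic (z, y, x))
.extract_seeds <- function(dt, mask, voxel_size, seed_min_distance) {
  d <- dim(dt)
  is_max <- mask
  for (off in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                   c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
    nb <- shift_array(dt, off, fill = -Inf)
    is_max <- is_max & (dt >= nb)
  }
  if (!any(is_max)) return(matrix(integer(0), 0L, 3L))
  # collapse plateaus (connected equal-valued maxima) to their centroid voxel
  vals <- dt
  vals[!is_max] <- 0
  ranks <- array(match(vals, sort(unique(as.vector(vals)))), dim = d)
  ranks[!is_max] <- 0L
  storage.mode(ranks) <- "integer"
  comp <- .cc_labels_cpp(ranks, d)
  idx <- which(comp > 0L, arr.ind = TRUE)
  cid <- comp[comp > 0L]
  cand <- do.call(rbind, lapply(split(seq_len(nrow(idx)), cid), function(rows) {
    sub <- idx[rows, , drop = FALSE]
    ctr <- colMeans(sub)
    best <- which.min(colSums((t(sub) - ctr)^2))
    sub[best, ]
  }))
  # order candidates by decreasing DT, then (z, y, x)
  dvals <- dt[cand]
  ord <- order(-dvals, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  pos <- sweep(cand - 0.5, 2L, voxel_size, "*")
  keep <- logical(nrow(cand))
  kept_pos <- matrix(0, 0L, 3L)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept_pos) == 0L ||
        min(sqrt(colSums((t(kept_pos) - pos[i, ])^2))) >= seed_min_distance) {
      keep[i] <- TRUE
      kept_pos <- rbind(kept_pos, pos[i, ])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Seeded watershed over-segmentation (supervoxels)
#'
#' The standard affinity post-processing front end: threshold the boundary
#' map to a foreground mask, compute the anisotropy-aware distance transform
#' inside it, take distance maxima (plateau-collapsed, non-max suppressed at
#' `seed_min_distance`) as seeds, and flood the mask in order of decreasing
#' distance. Every seed yields one fragment with a unique positive id,
#' assigned in seed scan order so runs are reproducible; voxels outside the
#' mask stay 0.
#'
#' @param affs an [annotated_volume()] of kind `"affinities"`.
#' @param mask_threshold boundary-map threshold in (0, 1); default 0.5.
#' @param seed_min_distance minimum world-space distance between seeds, nm;
#'   default 10.
#' @param extra_mask optional user-supplied 0/1 array (e.g. a neuropil mask)
#'   intersected with the affinity-derived mask before watershed.
#' @return an [annotated_volume()] of kind `"fragments"`.
#' @export
watershed_fragments <- function(affs, mask_threshold = 0.5,
                                seed_min_distance = 10,
                                extra_mask = NULL) {
  if (mask_threshold <= 0 || mask_threshold >= 1)
    stop("mask_threshold must be in (0, 1)")
  bm <- boundary_map(affs)
  mask <- bm$data > mask_threshold
  if (!is.null(extra_mask)) mask <- mask & (extra_mask != 0)
  d <- dim(mask)
  if (!any(mask)) {
    warning("empty mask: no voxels above mask_threshold")
    return(annotated_volume(array(0L, dim = d), affs$voxel_size,
                            affs$offset, kind = "fragments"))
  }
  dt <- distance_transform(mask, affs$voxel_size)
  seeds_idx <- .extract_seeds(dt, mask, affs$voxel_size, seed_min_distance)
  seed_arr <- array(0L, dim = d)
  seed_arr[seeds_idx] <- seq_len(nrow(seeds_idx))
  frag <- .watershed_flood_cpp(dt, array(as.integer(mask), dim = d),
                               seed_arr, d)
  annotated_volume(frag, affs$voxel_size, affs$offset, kind = "fragments")
}

#' Remove fragments with weak interior affinity
#'
#' Fragments whose mean boundary-map value falls below `min_avg_aff` are
#' relabeled to background — the filtering step used to drop supervoxels in
#' low-affinity regions such as glia before agglomeration.
#'
#' @param fragments an [annotated_volume()] of kind `"fragments"`.
#' @param affs the affinities the fragments were computed from.
#' @param min_avg_aff threshold on the per-fragment mean boundary map.
#' @return filtered fragments volume.
#' @export
filter_fragments <- function(fragments, affs, min_avg_aff) {
  stopifnot(inherits(fragments, "annotated_volume"),
            fragments$kind == "fragments")
  bm <- boundary_map(affs)$data
  fg <- fragments$data != 0L
  means <- tapply(bm[fg], fragments$data[fg], mean)
  drop_ids <- as.numeric(names(means))[means < min_avg_aff]
  out <- fragments$data
  out[out %in% drop_ids] <- 0L
  annotated_volume(out, fragments$voxel_size, fragments$offset,
                   kind = "fragments")
}
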