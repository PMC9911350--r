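#' Synthetic fixture specification
#'
#' Describes a toy labeled volume: non-overlapping spheres, or smooth
#' random-walk tubes that stand in for neuron processes. The defaults (a
#' 64^3 grid at 20 x 9 x 9 nm) exercise the anisotropy typical of serial
#' block-face EM. All generation is deterministic under `seed`.
#'
#' @param shape volume shape in voxels `(z, y, x)`; default `c(64, 64, 64)`.
#' @param voxel_size nm per voxel; default `c(20, 9, 9)`.
#' @param style `"spheres"` or `"tubes"`.
#' @param count number of objects; default 5.
#' @param seed RNG seed; default 42.
#' @param min_separation minimum world-space gap between object surfaces,
#'   nm; default 40 (a couple of voxels, enough that ground-truth affinities
#'   never bridge objects).
#' @param radius object radius in nm: for spheres a length-2 range to sample
#'   from (default `c(60, 110)`), for tubes a scalar (default 35).
#' @param tube_step,tube_steps centerline step length (nm) and step count
#'   for tubes; defaults 12 nm and 90 steps.
#' @param tube_wobble standard deviation of the per-step direction
#'   perturbation (radians-equivalent, default 0.25); 0 gives straight
#'   tubes.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(shape = c(64L, 64L, 64L),
                         voxel_size = c(20, 9, 9),
                         style = c("spheres", "tubes"),
                         count = 5L,
                         seed = 42L,
                         min_separation = 40,
                         radius = NULL,
                         tube_step = 12,
                         tube_steps = 90L,
                         tube_wobble = 0.25) {
  style <- match.arg(style)
  if (count < 1L) stop("count must be >= 1")
  if (is.null(radius))
    radius <- if (style == "spheres") c(60, 110) else 35
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 style = style, count = as.integer(count),
                 seed = as.integer(seed), min_separation = min_separation,
                 radius = radius, tube_step = tube_step,
                 tube_steps = as.integer(tube_steps),
                 tube_wobble = tube_wobble),
            class = "fixture_spec")
}

# distance (nm) of every voxel to the nearest foreground voxel of `lab`
.dist_to_foreground <- function(lab, voxel_size) {
  distance_transform(lab == 0, voxel_size)
}

#' Generate a toy label volume
#'
#' Spheres are sampled with rejection until all pairs are separated by at
#' least `min_separation` surface-to-surface; tubes are grown as smooth
#' random walks (reflected at the volume boundary) and rasterized at the
#' tube radius, each rejected and regrown if it comes closer than
#' `min_separation` to previously placed objects. Tube centerlines are
#' retained (attribute `"centerlines"`, world nm) so matched skeletons can
#' be derived.
#'
#' @param spec a [fixture_spec()].
#' @param max_retries placement attempts per object before giving up.
#' @return an [annotated_volume()] of kind `"labels"` with labels
#'   `1..count`.
#' @export
make_toy_labels <- function(spec, max_retries = 200L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  vs <- spec$voxel_size
  extent <- d * vs
  lab <- array(0L, dim = d)

  # voxel-center world coordinate arrays
  cz <- axis_coords(d[1], vs[1])
  cy <- axis_coords(d[2], vs[2])
  cx <- axis_coords(d[3], vs[3])

  if (spec$style == "spheres") {
    centers <- matrix(0, 0, 3)
    radii <- numeric(0)
    for (i in seq_len(spec$count)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        r <- stats::runif(1, min(spec$radius), max(spec$radius))
        ctr <- vapply(1:3, function(k)
          stats::runif(1, r + vs[k], extent[k] - r - vs[k]), numeric(1))
        ok <- !nrow(centers) ||
          all(sqrt(colSums((t(centers) - ctr)^2)) >=
                radii + r + spec$min_separation)
        if (ok) {
          centers <- rbind(centers, ctr)
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", spec$count, " spheres at min_separation ",
             spec$min_separation, " nm after ", max_retries, " retries")
    }
    for (i in seq_len(spec$count)) {
      dz2 <- (cz - centers[i, 1])^2
      dy2 <- (cy - centers[i, 2])^2
      dx2 <- (cx - centers[i, 3])^2
      inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= radii[i]^2
      lab[inside] <- i
    }
    vol <- annotated_volume(lab, vs, kind = "labels")
    attr(vol, "centers") <- centers
    attr(vol, "radii") <- radii
    return(vol)
  }

  # tubes
  centerlines <- vector("list", spec$count)
  r <- spec$radius[1]
  margin <- r + vs
  for (i in seq_len(spec$count)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      p <- vapply(1:3, function(k)
        stats::runif(1, margin[k], extent[k] - margin[k]), numeric(1))
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(0, spec$tube_steps + 1L, 3L)
      pts[1, ] <- p
      for (s in seq_len(spec$tube_steps)) {
        dir <- dir + stats::rnorm(3, sd = spec$tube_wobble)
        dir <- dir / sqrt(sum(dir^2))
        p_new <- p + dir * spec$tube_step
        # reflect at the (margin-shrunk) boundary
        for (k in 1:3) {
          if (p_new[k] < margin[k]) {
            p_new[k] <- 2 * margin[k] - p_new[k]
            dir[k] <- -dir[k]
          } else if (p_new[k] > extent[k] - margin[k]) {
            p_new[k] <- 2 * (extent[k] - margin[k]) - p_new[k]
            dir[k] <- -dir[k]
          }
        }
        p <- p_new
        pts[s + 1L, ] <- p
      }
      # rasterize: voxels within r (nm) of the centerline
      cl_mask <- array(0L, dim = d)
      # dense samples along the polyline so no voxel is skipped
      samp <- .resample_polyline(pts, min(vs) / 2)
      vidx <- cbind(pmin(pmax(floor(samp[, 1] / vs[1]) + 1L, 1L), d[1]),
                    pmin(pmax(floor(samp[, 2] / vs[2]) + 1L, 1L), d[2]),
                    pmin(pmax(floor(samp[, 3] / vs[3]) + 1L, 1L), d[3]))
      storage.mode(vidx) <- "integer"
      cl_mask[vidx] <- 1L
      dist_cl <- distance_transform(cl_mask == 0, vs)
      tube <- dist_cl <= r
      # enforce separation from existing objects
      if (any(lab != 0L)) {
        dist_fg <- .dist_to_foreground(lab, vs)
        if (min(dist_fg[tube]) < spec$min_separation) next
      }
      lab[tube] <- i
      centerlines[[i]] <- pts
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place tube ", i, " at min_separation ",
           spec$min_separation, " nm after ", max_retries, " retries")
  }
  vol <- annotated_volume(lab, vs, kind = "labels")
  attr(vol, "centerlines") <- centerlines
  vol
}

# resample a polyline at exactly `spacing` arc-length intervals (plus the
# final vertex)
.resample_arclength <- function(pts, spacing) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  L <- sum(seglen)
  targets <- seq(0, L, by = spacing)
  if (L - targets[length(targets)] > spacing / 2) targets <- c(targets, L)
  cum <- c(0, cumsum(seglen))
  out <- matrix(0, length(targets), 3L)
  for (i in seq_along(targets)) {
    t <- min(targets[i], L)
    j <- findInterval(t, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(pts) - 1L)
    f <- if (seglen[j] > 0) (t - cum[j]) / seglen[j] else 0
    out[i, ] <- pts[j, ] + f * (pts[j + 1L, ] - pts[j, ])
  }
  out
}

# resample a polyline at (at most) `step` nm spacing, keeping the vertices
.resample_polyline <- function(pts, step) {
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    t <- seq_len(nseg) / nseg
    out[[i + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                           a[2] + t * (b[2] - a[2]),
                           a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Skeletons matching a tube fixture
#'
#' One skeleton per tube, following the generating centerline with nodes at
#' (approximately) `spacing` nm arc-length intervals; `skeleton_id` equals
#' the tube's label. Only available for `style = "tubes"` volumes produced
#' by [make_toy_labels()].
#'
#' @param labels a tube fixture with the `"centerlines"` attribute.
#' @param spacing node spacing in nm; default 30.
#' @return a [skeleton_set()].
#' @export
toy_skeletons <- function(labels, spacing = 30) {
  cls <- attr(labels, "centerlines")
  if (is.null(cls))
    stop("skeletons are only defined for tube fixtures (missing centerlines)")
  nodes <- list()
  edges <- list()
  next_id <- 0L
  for (i in seq_along(cls)) {
    pts <- .resample_arclength(cls[[i]], spacing)
    n <- nrow(pts)
    ids <- next_id + seq_len(n)
    next_id <- next_id + n
    nodes[[i]] <- data.frame(node_id = ids, skeleton_id = i,
                             z = pts[, 1], y = pts[, 2], x = pts[, 3])
    if (n > 1L)
      edges[[i]] <- data.frame(from = ids[-n], to = ids[-1])
  }
  skeleton_set(do.call(rbind, nodes),
               if (length(edges)) do.call(rbind, edges)
               else data.frame(from = numeric(0), to = numeric(0)))
}

#' Inject controlled errors into affinities
#'
#' Corrupts ground-truth affinities with exactly known errors so metric
#' behavior can be asserted against a manifest: planar low-affinity cuts
#' inside objects (false splits), high-affinity bridges across chosen
#' object pairs at their closest approach (false merges), and optional
#' Gaussian smoothing. Each object is cut with probability
#' `false_split_rate`; each sufficiently close object pair is bridged with
#' probability `false_merge_rate`.
#'
#' @param affs direct-neighbor affinities (from [compute_affinities()]).
#' @param labels the generating label volume.
#' @param false_split_rate,false_merge_rate probabilities in `[0, 1]`.
#' @param blur_sigma Gaussian smoothing sigma in nm (0 = none).
#' @param seed RNG seed.
#' @param bridge_radius radius (nm) of injected merge bridges; default 30.
#' @param max_pair_distance only object pairs closer (surface-to-surface)
#'   than this are candidates for bridging; default 250 nm.
#' @return the corrupted affinities, with a `data.frame` manifest of
#'   injected errors attached as attribute `"manifest"` (columns: `type`
#'   (`"split"`/`"merge"`), `label_a`, `label_b` (NA for splits), `axis`,
#'   `index` (NA for merges)).
#' @export
perturb_affinities <- function(affs, labels,
                               false_split_rate = 0,
                               false_merge_rate = 0,
                               blur_sigma = 0,
                               seed = 1L,
                               bridge_radius = 30,
                               max_pair_distance = 250) {
  stopifnot(false_split_rate >= 0, false_split_rate <= 1,
            false_merge_rate >= 0, false_merge_rate <= 1)
  set.seed(seed)
  d <- vol_shape(affs)
  lab <- labels$data
  out <- affs$data
  manifest <- list()
  direct <- rbind(c(-1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 0L, -1L))

  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids != 0]

  # false splits: one axis-aligned planar cut per selected object
  for (o in ids) {
    if (stats::runif(1) >= false_split_rate) next
    w <- which(lab == o, arr.ind = TRUE)
    # cut perpendicular to the object's longest world-space extent, in the
    # middle half of its range, so one plane crosses an elongated object once
    ext <- (apply(w, 2, max) - apply(w, 2, min)) * affs$voxel_size
    ax <- which.max(ext)
    rng <- range(w[, ax])
    span <- rng[2] - rng[1]
    if (span < 4L) next                     # too thin to cut
    lo <- rng[1] + max(1L, span %/% 4L)
    hi <- rng[2] - max(1L, span %/% 4L)
    cpos <- if (lo >= hi) rng[1] + span %/% 2L else sample(lo:hi, 1)
    # a one-voxel slab of the object acts as a spurious membrane: zero every
    # affinity incident to it, so the boundary map drops below the mask
    # threshold there and the object falls apart into two fragments
    slab <- array(FALSE, dim = d)
    wsel <- w[w[, ax] == cpos, , drop = FALSE]
    if (!nrow(wsel)) next
    slab[wsel] <- TRUE
    for (j in 1:3) {
      hit <- slab | shift_array(slab, direct[j, ], fill = FALSE)
      ch <- array(out[j, , , ], dim = d)
      ch[hit] <- 0
      out[j, , , ] <- ch
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      type = "split", label_a = o, label_b = NA, axis = ax, index = cpos)
  }

  # false merges: bridge selected close pairs at their closest approach
  if (false_merge_rate > 0 && length(ids) >= 2) {
    dist_maps <- lapply(ids, function(o)
      distance_transform(lab != o, affs$voxel_size))
    names(dist_maps) <- as.character(ids)
    pairs <- utils::combn(ids, 2)
    for (pi in seq_len(ncol(pairs))) {
      a <- pairs[1, pi]; b <- pairs[2, pi]
      da <- dist_maps[[as.character(a)]]
      gap <- min(da[lab == b])
      if (gap > max_pair_distance) next
      if (stats::runif(1) >= false_merge_rate) next
      wb <- which(lab == b, arr.ind = TRUE)
      bi <- which.min(da[lab == b])
      pb <- (wb[bi, ] - 0.5) * affs$voxel_size
      wa <- which(lab == a, arr.ind = TRUE)
      pa_all <- sweep(wa - 0.5, 2L, affs$voxel_size, "*")
      ai <- which.min(colSums((t(pa_all) - pb)^2))
      pa <- pa_all[ai, ]
      # voxels within bridge_radius of the segment pa-pb
      samp <- .resample_polyline(rbind(pa, pb), min(affs$voxel_size) / 2)
      bm <- array(0L, dim = d)
      vidx <- cbind(
        pmin(pmax(floor(samp[, 1] / affs$voxel_size[1]) + 1L, 1L), d[1]),
        pmin(pmax(floor(samp[, 2] / affs$voxel_size[2]) + 1L, 1L), d[2]),
        pmin(pmax(floor(samp[, 3] / affs$voxel_size[3]) + 1L, 1L), d[3]))
      storage.mode(vidx) <- "integer"
      bm[vidx] <- 1L
      bridge <- distance_transform(bm == 0, affs$voxel_size) <= bridge_radius
      for (j in 1:3) {
        pshift <- shift_array(bridge, direct[j, ], fill = FALSE)
        sel <- bridge & pshift
        ch <- array(out[j, , , ], dim = d)
        ch[sel] <- 1
        out[j, , , ] <- ch
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        type = "merge", label_a = a, label_b = b, axis = NA, index = NA)
    }
  }

  if (blur_sigma > 0) {
    bspec <- lsd_spec(sigma = blur_sigma, kernel = "gaussian", truncate = 2)
    win <- make_window(bspec, affs$voxel_size)
    kern <- win$kernel / win$mass
    ones <- array(1, dim = d)
    norm <- conv3_same(list(ones), kern)[[1]]
    for (j in seq_len(dim(out)[1])) {
      ch <- conv3_same(list(array(out[j, , , ], dim = d)), kern)[[1]] / norm
      out[j, , , ] <- pmin(pmax(ch, 0), 1)
    }
  }

  res <- annotated_volume(out, affs$voxel_size, affs$offset,
                          kind = "affinities", mask = affs$mask)
  attr(res, "manifest") <- if (length(manifest))
    do.call(rbind, manifest)
  else data.frame(type = character(0), label_a = numeric(0),
                  label_b = numeric(0), axis = numeric(0),
                  index = numeric(0))
  res
}
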