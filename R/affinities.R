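#' Affinity neighborhoods
#'
#' An affinity neighborhood is an ordered list of nonzero integer voxel
#' offsets; each offset defines one affinity channel. The direct-neighbor
#' default is `(-1,0,0), (0,-1,0), (0,0,-1)` in `(z, y, x)`: offsets are
#' negative, so the affinity of a voxel pair is stored at the higher-index
#' voxel of the pair.
#'
#' @param offsets integer matrix `n x 3` (or list of length-3 vectors) of
#'   unique, nonzero voxel offsets.
#' @return object of class `affinity_neighborhood` (an `n x 3` integer
#'   matrix).
#' @export
affinity_neighborhood <- function(offsets = NULL) {
  if (is.null(offsets))
    offsets <- rbind(c(-1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 0L, -1L))
  if (is.list(offsets)) offsets <- do.call(rbind, offsets)
  offsets <- as.matrix(offsets)
  storage.mode(offsets) <- "integer"
  if (ncol(offsets) != 3L) stop("offsets must be 3-vectors (z, y, x)")
  if (any(rowSums(offsets != 0L) == 0L)) stop("offsets must be nonzero")
  if (anyDuplicated(offsets)) stop("offsets must be unique")
  colnames(offsets) <- c("z", "y", "x")
  structure(offsets, class = c("affinity_neighborhood", "matrix"))
}

#' Long-range affinity neighborhood
#'
#' Extends the direct neighborhood with `extra_per_direction` additional
#' offsets per axis at the given strides (multiples of the unit step), the
#' auxiliary-task neighborhood used by long-range affinity training. With
#' the defaults, `extra_per_direction = 3` yields 12 channels: per axis the
#' unit offset plus offsets at 2x, 4x and 8x.
#'
#' @param extra_per_direction non-negative integer.
#' @param strides strides of the extra offsets; default `2^(1:extra)`.
#' @return an [affinity_neighborhood()] with `3 * (1 + extra_per_direction)`
#'   offsets, ordered axis-major (all z offsets, then y, then x).
#' @export
make_long_range_neighborhood <- function(extra_per_direction = 3L,
                                         strides = NULL) {
  extra <- as.integer(extra_per_direction)
  if (extra < 0L) stop("extra_per_direction must be >= 0")
  if (is.null(strides)) strides <- if (extra > 0L) 2L^(1:extra) else integer(0)
  if (length(strides) != extra) stop("need one stride per extra offset")
  steps <- c(1L, as.integer(strides))
  rows <- list()
  for (ax in 1:3) for (s in steps) {
    off <- c(0L, 0L, 0L)
    off[ax] <- -s
    rows[[length(rows) + 1L]] <- off
  }
  affinity_neighborhood(rows)
}

#' Ground-truth affinities of a label volume
#'
#' Channel `j` at voxel `v` is 1 exactly when `v` and `v + n_j` carry the
#' same nonzero label, 0 otherwise — in particular 0 whenever either voxel is
#' background, so background never connects to anything. Pairs whose partner
#' falls outside the volume get affinity 0 and are flagged invalid in the
#' accompanying mask channel, so downstream consumers can ignore the border.
#'
#' @param labels an [annotated_volume()] of kind `"labels"` (or
#'   `"segmentation"`/`"fragments"`).
#' @param nbhd an [affinity_neighborhood()]; default direct neighbors.
#' @return an [annotated_volume()] of kind `"affinities"` with `|N|`
#'   channels and a matching 0/1 `mask` array (0 where the partner voxel is
#'   outside the volume).
#' @export
compute_affinities <- function(labels, nbhd = affinity_neighborhood()) {
  stopifnot(inherits(labels, "annotated_volume"),
            labels$kind %in% c("labels", "segmentation", "fragments"))
  d <- dim(labels$data)
  n <- nrow(nbhd)
  affs <- array(0, dim = c(n, d))
  mask <- array(0, dim = c(n, d))
  lab <- labels$data
  for (j in seq_len(n)) {
    off <- nbhd[j, ]
    partner <- shift_array(lab, off, fill = -1L)  # -1 marks out-of-volume
    valid <- partner != -1L
    same <- (lab == partner) & (lab != 0L) & valid
    affs[j, , , ] <- as.numeric(same)
    mask[j, , , ] <- as.numeric(valid)
  }
  annotated_volume(affs, labels$voxel_size, labels$offset,
                   kind = "affinities", mask = mask)
}
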