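#' Annotated 3D volume
#'
#' The basic container used throughout the package: a scalar 3D grid or a
#' channel-major 4D grid over `(z, y, x)`, together with world-space metadata.
#' Axis order is `(z, y, x)` everywhere, matching the sectioning convention of
#' anisotropic volume electron microscopy (z is the cutting axis and usually
#' the coarsest). `voxel_size` and `offset` are in nanometres; `offset` is the
#' world position of the corner of the first voxel, so a world point `p` falls
#' into 0-based voxel `floor((p - offset) / voxel_size)`.
#'
#' @param data numeric or integer array; 3D `(z, y, x)` or 4D channel-major
#'   `(c, z, y, x)`.
#' @param voxel_size numeric length-3, nm per voxel along `(z, y, x)`; all
#'   components strictly positive.
#' @param offset numeric length-3, nm, world position of the first voxel's
#'   corner. Default `c(0, 0, 0)`.
#' @param kind one of `"raw"`, `"labels"`, `"affinities"`, `"lsds"`,
#'   `"fragments"`, `"segmentation"`. Label-like kinds must hold non-negative
#'   integers with 0 meaning background.
#' @param mask optional logical/0-1 array matching `data`, marking valid
#'   entries (used by affinity volumes at the volume border).
#'
#' @return An object of class `annotated_volume`: a list with elements
#'   `data`, `voxel_size`, `offset`, `kind` and optionally `mask`.
#' @export
annotated_volume <- function(data,
                             voxel_size,
                             offset = c(0, 0, 0),
                             kind = c("raw", "labels", "affinities", "lsds",
                                      "fragments", "segmentation"),
                             mask = NULL) {
  kind <- match.arg(kind)
  if (is.null(dim(data))) stop("`data` must be a 3D or 4D array")
  nd <- length(dim(data))
  if (nd != 3L && nd != 4L)
    stop("`data` must be 3D (z, y, x) or channel-major 4D (c, z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  offset <- as.numeric(offset)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers (nm)")
  if (length(offset) != 3L || any(!is.finite(offset)))
    stop("`offset` must be 3 finite numbers (nm)")
  if (kind %in% c("labels", "fragments", "segmentation")) {
    if (nd != 3L) stop(kind, " volumes must be 3D")
    rng <- range(data)
    if (rng[1] < 0 || any(data != floor(data)))
      stop(kind, " volumes must hold non-negative integers (0 = background)")
  }
  if (!is.null(mask) && !identical(dim(mask), dim(data)))
    stop("`mask` must match the shape of `data`")
  structure(
    list(data = data, voxel_size = voxel_size, offset = offset,
         kind = kind, mask = mask),
    class = "annotated_volume"
  )
}

#' @export
print.annotated_volume <- function(x, ...) {
  d <- dim(x$data)
  ch <- if (length(d) == 4L) sprintf("%d channels x ", d[1]) else ""
  cat(sprintf(
    "<annotated_volume [%s]> %s%s voxels (z,y,x), voxel size (%s) nm, offset (%s) nm\n",
    x$kind, ch, paste(vol_shape(x), collapse = " x "),
    paste(x$voxel_size, collapse = ", "),
    paste(x$offset, collapse = ", ")))
  invisible(x)
}

#' Spatial shape of an annotated volume
#'
#' @param vol an [annotated_volume()].
#' @return integer length-3 spatial shape `(z, y, x)`, dropping any channel
#'   axis.
#' @export
vol_shape <- function(vol) {
  d <- dim(vol$data)
  if (length(d) == 4L) d[-1L] else d
}

#' Number of channels (0 for scalar volumes)
#' @param vol an [annotated_volume()].
#' @return integer channel count; 0 when the volume has no channel axis.
#' @export
vol_channels <- function(vol) {
  d <- dim(vol$data)
  if (length(d) == 4L) d[1L] else 0L
}

#' Map world positions (nm) to 1-based voxel indices
#'
#' Voxel ownership is half-open: a point on the low face of a voxel belongs to
#' it. Points are mapped as `floor((p - offset) / voxel_size)` (0-based) and
#' returned 1-based for R indexing.
#'
#' @param pos numeric matrix `n x 3` of world positions `(z, y, x)` in nm, or
#'   a length-3 vector.
#' @param vol an [annotated_volume()] supplying `offset` and `voxel_size`.
#' @return integer matrix `n x 3` of 1-based voxel indices; indices may fall
#'   outside the volume (callers check against [vol_shape()]).
#' @export
world_to_voxel <- function(pos, vol) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  idx <- floor(sweep(sweep(pos, 2L, vol$offset, "-"), 2L,
                     vol$voxel_size, "/"))
  storage.mode(idx) <- "integer"
  idx + 1L
}

#' World position (nm) of voxel centers
#'
#' @param idx integer matrix `n x 3` of 1-based voxel indices, or length-3
#'   vector.
#' @param vol an [annotated_volume()].
#' @return numeric matrix `n x 3`, the world position of each voxel's center.
#' @export
voxel_to_world <- function(idx, vol) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  sweep(sweep(idx - 0.5, 2L, vol$voxel_size, "*"), 2L, vol$offset, "+")
}

# world coordinate of voxel centers along one axis, relative to volume start
axis_coords <- function(n, voxel_size_axis) {
  (seq_len(n) - 0.5) * voxel_size_axis
}

# shift a 3D array by an integer offset (z,y,x), filling with `fill`;
# result[v] = a[v + off] where in bounds
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src_lo <- pmax(1L, 1L + off)
  src_hi <- pmin(d, d + off)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - off
  dst_hi <- src_hi - off
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}
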