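#' Shape descriptor specification
#'
#' Describes the local window and output conventions used when computing
#' local shape descriptors (LSDs). The descriptor of a voxel summarizes the
#' piece of its object that falls inside a window centered on the voxel: the
#' (weighted) size of that piece, the offset of its center of mass from the
#' voxel, and the covariance of its voxel coordinates. All world quantities
#' are in nanometres, so `sigma` keeps its physical meaning under anisotropic
#' voxel grids.
#'
#' @param sigma window scale in nm; scalar or per-axis `(z, y, x)` 3-vector.
#'   For the ball kernel this is the (ellipsoid) radius; for the Gaussian the
#'   standard deviation per axis.
#' @param kernel `"gaussian"` (smooth window, the default used for network
#'   targets) or `"ball"` (uniform window, the definition-faithful variant).
#' @param truncate Gaussian support cutoff in multiples of `sigma`
#'   (default 3); ignored for the ball.
#' @param normalize map all ten channels into `[0, 1]` (commensurate network
#'   targets): size is divided by the kernel mass; each offset component is
#'   clipped to `[-sigma, sigma]` and mapped to `[0, 1]`; covariance entries
#'   are divided by `sigma_k * sigma_l`, diagonals clipped to `[0, 1]` and
#'   off-diagonals mapped from `[-1, 1]` to `[0, 1]`. Background voxels stay
#'   all-zero.
#' @param downsample positive integer stride: statistics are computed on a
#'   `downsample`-strided grid (label volume subsampled, voxel size scaled)
#'   and nearest-neighbor upsampled back. 1 = exact dense computation.
#' @param channel_order `"figure"` (default: offset 0-2, covariance diagonal
#'   3-5, covariance off-diagonals 6-8, size 9) or `"equation"` (size first,
#'   then offset, then covariance).
#' @return an object of class `lsd_spec`.
#' @export
lsd_spec <- function(sigma,
                     kernel = c("gaussian", "ball"),
                     truncate = 3,
                     normalize = FALSE,
                     downsample = 1L,
                     channel_order = c("figure", "equation")) {
  kernel <- match.arg(kernel)
  channel_order <- match.arg(channel_order)
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive (nm), scalar or length 3 (z, y, x)")
  if (truncate < 1) stop("`truncate` must be >= 1")
  downsample <- as.integer(downsample)
  if (downsample < 1L) stop("`downsample` must be >= 1")
  structure(list(sigma = sigma, kernel = kernel, truncate = truncate,
                 normalize = normalize, downsample = downsample,
                 channel_order = channel_order),
            class = "lsd_spec")
}

#' LSD channel names in the order produced by a spec
#' @param spec an [lsd_spec()].
#' @return character vector of 10 channel names.
#' @export
lsd_channel_names <- function(spec) {
  nm <- c("moff_z", "moff_y", "moff_x",
          "cov_zz", "cov_yy", "cov_xx",
          "cov_zy", "cov_zx", "cov_yx",
          "size")
  if (spec$channel_order == "equation") nm <- nm[c(10, 1:9)]
  nm
}

#' Discretize the local window kernel on a voxel grid
#'
#' Builds the discrete window `w` over integer voxel offsets for a given
#' anisotropic voxel size. The ball kernel is the indicator of the ellipsoid
#' `|off * voxel_size / sigma|_2 <= 1` (a ball of radius `sigma` when `sigma`
#' is isotropic); the Gaussian kernel is separable with per-axis standard
#' deviation `sigma / voxel_size` voxels, truncated at `truncate * sigma`,
#' and carries weight 1 at the center (unnormalized, so the "kernel mass" is
#' the maximum attainable size).
#'
#' @param spec an [lsd_spec()].
#' @param voxel_size nm per voxel, `(z, y, x)`.
#' @return a list of class `lsd_window`: `offsets` (n x 3 integer voxel
#'   offsets), `weights` (length n, all > 0), `half_width` (per-axis integer
#'   support), `kernel` (dense array of dim `2 * half_width + 1`), `mass`
#'   (sum of weights) and `radius_nm` (support radius per axis, nm).
#' @export
make_window <- function(spec, voxel_size) {
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (any(spec$sigma < voxel_size)) {
    warning("sigma below one voxel on some axis; using a degenerate ",
            "single-voxel window")
    kern <- array(1, dim = c(1L, 1L, 1L))
    return(structure(list(offsets = matrix(0L, 1L, 3L), weights = 1,
                          half_width = c(0L, 0L, 0L), kernel = kern,
                          mass = 1, radius_nm = voxel_size / 2),
                     class = "lsd_window"))
  }
  if (spec$kernel == "ball") {
    h <- as.integer(floor(spec$sigma / voxel_size))
    ax <- lapply(1:3, function(k) (-h[k]):(h[k]))
    g <- expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]])
    d2 <- (g$z * voxel_size[1] / spec$sigma[1])^2 +
      (g$y * voxel_size[2] / spec$sigma[2])^2 +
      (g$x * voxel_size[3] / spec$sigma[3])^2
    keep <- d2 <= 1
    w <- rep(1, sum(keep))
    off <- as.matrix(g[keep, , drop = FALSE])
    radius <- spec$sigma
  } else {
    h <- as.integer(floor(spec$truncate * spec$sigma / voxel_size))
    ax <- lapply(1:3, function(k) (-h[k]):(h[k]))
    wax <- lapply(1:3, function(k)
      exp(-((ax[[k]] * voxel_size[k])^2) / (2 * spec$sigma[k]^2)))
    g <- expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]])
    w <- as.vector(outer(outer(wax[[1]], wax[[2]]), wax[[3]]))
    off <- as.matrix(g)
    radius <- spec$truncate * spec$sigma
  }
  storage.mode(off) <- "integer"
  kern <- array(0, dim = 2L * h + 1L)
  kern[cbind(off[, 1] + h[1] + 1L, off[, 2] + h[2] + 1L,
             off[, 3] + h[3] + 1L)] <- w
  structure(list(offsets = off, weights = w, half_width = h, kernel = kern,
                 mass = sum(w), radius_nm = radius),
            class = "lsd_window")
}

#' Shape descriptor of a single voxel, by direct enumeration
#'
#' Evaluates the descriptor definition literally: collect the voxels inside
#' the window at `v` that carry `v`'s label (clipped to the volume), then
#' compute their weighted size, center-of-mass offset and coordinate
#' covariance in world units. This is the reference against which the dense
#' convolutional route is validated; it is exact but slow.
#'
#' @param labels an [annotated_volume()] of kind `"labels"`.
#' @param v 1-based voxel index `(z, y, x)`.
#' @param spec an [lsd_spec()] (its `downsample` is ignored here).
#' @param window optional precomputed [make_window()] result.
#' @return named numeric length-10 descriptor in the spec's channel order; a
#'   background voxel yields all zeros.
#' @export
lsd_at_voxel_bruteforce <- function(labels, v, spec, window = NULL) {
  stopifnot(inherits(labels, "annotated_volume"))
  v <- as.integer(v)
  d <- dim(labels$data)
  if (any(v < 1L) || any(v > d)) stop("voxel index out of bounds")
  out <- stats::setNames(numeric(10), lsd_channel_names(spec))
  lab <- labels$data[v[1], v[2], v[3]]
  if (lab == 0) return(out)
  if (is.null(window)) window <- make_window(spec, labels$voxel_size)

  vv <- sweep(window$offsets, 2L, v, "+")
  inb <- vv[, 1] >= 1L & vv[, 1] <= d[1] &
    vv[, 2] >= 1L & vv[, 2] <= d[2] &
    vv[, 3] >= 1L & vv[, 3] <= d[3]
  vv <- vv[inb, , drop = FALSE]
  w <- window$weights[inb]
  same <- labels$data[vv] == lab
  vv <- vv[same, , drop = FALSE]
  w <- w[same]

  p <- sweep(vv - 0.5, 2L, labels$voxel_size, "*")   # world coords, nm
  pv <- (v - 0.5) * labels$voxel_size
  s <- sum(w)
  m <- colSums(p * w) / s
  dc <- sweep(p, 2L, m, "-")
  cov <- crossprod(dc * w, dc) / s                   # 3x3, nm^2
  stats <- list(moff = m - pv,
                cdiag = diag(cov),
                coff = c(cov[1, 2], cov[1, 3], cov[2, 3]),
                size = s)
  .assemble_lsd(stats, spec, window)
}

# order + optionally normalize one descriptor (vector form)
.assemble_lsd <- function(stats, spec, window) {
  if (spec$normalize) {
    sg <- spec$sigma
    stats$size <- min(stats$size / window$mass, 1)
    stats$moff <- (pmin(pmax(stats$moff / sg, -1), 1) + 1) / 2
    stats$cdiag <- pmin(pmax(stats$cdiag / sg^2, 0), 1)
    den <- c(sg[1] * sg[2], sg[1] * sg[3], sg[2] * sg[3])
    stats$coff <- (pmin(pmax(stats$coff / den, -1), 1) + 1) / 2
  }
  v <- c(stats$moff, stats$cdiag, stats$coff, stats$size)
  if (spec$channel_order == "equation") v <- v[c(10, 1:9)]
  stats::setNames(v, lsd_channel_names(spec))
}

# ---- dense computation -----------------------------------------------------

# linear "same" convolution of several arrays with one odd-sized kernel,
# via zero-padded FFTs (kernel FFT computed once)
conv3_same <- function(arrs, kern) {
  n <- dim(arrs[[1]])
  kd <- dim(kern)
  h <- (kd - 1L) %/% 2L
  P <- vapply(n + kd - 1L, stats::nextn, integer(1), factors = c(2, 3, 5))
  K <- array(0, dim = P)
  K[1:kd[1], 1:kd[2], 1:kd[3]] <- kern
  FK <- stats::fft(K)
  lapply(arrs, function(a) {
    A <- array(0, dim = P)
    A[1:n[1], 1:n[2], 1:n[3]] <- a
    C <- Re(stats::fft(stats::fft(A) * FK, inverse = TRUE)) / prod(P)
    C[(h[1] + 1):(h[1] + n[1]),
      (h[2] + 1):(h[2] + n[2]),
      (h[3] + 1):(h[3] + n[3])]
  })
}

#' Dense local shape descriptors of a label volume
#'
#' Computes the 10-channel LSD volume by the convolutional route: for every
#' label, the binary mask and its coordinate-weighted variants are convolved
#' with the window kernel, giving the per-voxel weighted size, center of mass
#' and second moments; the covariance follows by the usual moment identity,
#' and per-label results are stitched onto the dense grid. This equals
#' [lsd_at_voxel_bruteforce()] at every voxel (up to FFT round-off).
#' Statistics near the volume border use only in-volume voxels.
#'
#' @param labels an [annotated_volume()] of kind `"labels"`.
#' @param spec an [lsd_spec()].
#' @param max_labels refuse volumes with more unique labels than this
#'   (process such volumes block-wise instead); default 256.
#' @return an [annotated_volume()] of kind `"lsds"` with a 10-channel
#'   channel-major data array in the spec's channel order.
#' @export
compute_lsds <- function(labels, spec, max_labels = 256L) {
  stopifnot(inherits(labels, "annotated_volume"),
            labels$kind %in% c("labels", "segmentation", "fragments"))
  if (spec$downsample > 1L) {
    ds <- spec$downsample
    d <- dim(labels$data)
    sub <- labels$data[seq(1L, d[1], by = ds),
                       seq(1L, d[2], by = ds),
                       seq(1L, d[3], by = ds), drop = FALSE]
    coarse <- annotated_volume(sub, labels$voxel_size * ds, labels$offset,
                               kind = "labels")
    spec_full <- spec
    spec_full$downsample <- 1L
    lo <- compute_lsds(coarse, spec_full, max_labels = max_labels)
    up <- lo$data[, rep(seq_len(dim(sub)[1]), each = ds)[seq_len(d[1])],
                  rep(seq_len(dim(sub)[2]), each = ds)[seq_len(d[2])],
                  rep(seq_len(dim(sub)[3]), each = ds)[seq_len(d[3])],
                  drop = FALSE]
    return(annotated_volume(up, labels$voxel_size, labels$offset,
                            kind = "lsds"))
  }

  ids <- sort(unique(as.vector(labels$data)))
  ids <- ids[ids != 0]
  if (length(ids) > max_labels)
    stop(length(ids), " unique labels exceed max_labels = ", max_labels,
         "; process the volume in blocks (see blockwise_segment) or raise ",
         "the cap")
  window <- make_window(spec, labels$voxel_size)
  h <- window$half_width
  d <- dim(labels$data)
  out <- array(0, dim = c(10L, d))
  vs <- labels$voxel_size
  coords_full <- lapply(1:3, function(k) axis_coords(d[k], vs[k]))

  for (id in ids) {
    w_idx <- which(labels$data == id, arr.ind = TRUE)
    lo <- pmax(apply(w_idx, 2, min) - h, 1L)
    hi <- pmin(apply(w_idx, 2, max) + h, d)
    b <- array(0, dim = hi - lo + 1L)
    b[sweep(w_idx, 2L, lo - 1L, "-")] <- 1
    cz <- coords_full[[1]][lo[1]:hi[1]]
    cy <- coords_full[[2]][lo[2]:hi[2]]
    cx <- coords_full[[3]][lo[3]:hi[3]]
    nb <- dim(b)
    PZ <- array(cz, dim = nb)
    PY <- aperm(array(cy, dim = nb[c(2, 1, 3)]), c(2, 1, 3))
    PX <- aperm(array(cx, dim = nb[c(3, 2, 1)]), c(3, 2, 1))

    conv <- conv3_same(list(b,
                            PZ * b, PY * b, PX * b,
                            PZ * PZ * b, PY * PY * b, PX * PX * b,
                            PZ * PY * b, PZ * PX * b, PY * PX * b),
                       window$kernel)
    sel <- b == 1                      # voxels of this label
    s <- conv[[1]][sel]
    mz <- conv[[2]][sel] / s; my <- conv[[3]][sel] / s
    mx <- conv[[4]][sel] / s
    czz <- conv[[5]][sel] / s - mz * mz
    cyy <- conv[[6]][sel] / s - my * my
    cxx <- conv[[7]][sel] / s - mx * mx
    czy <- conv[[8]][sel] / s - mz * my
    czx <- conv[[9]][sel] / s - mz * mx
    cyx <- conv[[10]][sel] / s - my * mx

    vsel <- which(sel, arr.ind = TRUE)
    pz <- cz[vsel[, 1]]; py <- cy[vsel[, 2]]; px <- cx[vsel[, 3]]
    stats <- list(moff = cbind(mz - pz, my - py, mx - px),
                  cdiag = cbind(pmax(czz, 0), pmax(cyy, 0), pmax(cxx, 0)),
                  coff = cbind(czy, czx, cyx),
                  size = s)
    ch <- .assemble_lsd_matrix(stats, spec, window)  # n x 10
    gidx <- sweep(vsel, 2L, lo - 1L, "+")            # back to full volume
    for (c_i in 1:10)
      out[cbind(c_i, gidx)] <- ch[, c_i]
  }
  annotated_volume(out, labels$voxel_size, labels$offset, kind = "lsds")
}

# matrix (n voxels x 10) variant of .assemble_lsd
.assemble_lsd_matrix <- function(stats, spec, window) {
  if (spec$normalize) {
    sg <- spec$sigma
    stats$size <- pmin(stats$size / window$mass, 1)
    stats$moff <- (pmin(pmax(sweep(stats$moff, 2L, sg, "/"), -1), 1) + 1) / 2
    stats$cdiag <- pmin(pmax(sweep(stats$cdiag, 2L, sg^2, "/"), 0), 1)
    den <- c(sg[1] * sg[2], sg[1] * sg[3], sg[2] * sg[3])
    stats$coff <- (pmin(pmax(sweep(stats$coff, 2L, den, "/"), -1), 1) + 1) / 2
  }
  m <- cbind(stats$moff, stats$cdiag, stats$coff, stats$size)
  if (spec$channel_order == "equation") m <- m[, c(10, 1:9), drop = FALSE]
  colnames(m) <- lsd_channel_names(spec)
  m
}

#' Reassemble the 3x3 covariance matrix from LSD channels
#'
#' @param lsd named length-10 descriptor (or any vector in the given spec's
#'   channel order).
#' @param spec the [lsd_spec()] the descriptor was computed with.
#' @return symmetric 3x3 matrix in `(z, y, x)` order.
#' @export
lsd_covariance <- function(lsd, spec) {
  nm <- lsd_channel_names(spec)
  v <- stats::setNames(as.numeric(lsd), nm)
  m <- matrix(c(v["cov_zz"], v["cov_zy"], v["cov_zx"],
                v["cov_zy"], v["cov_yy"], v["cov_yx"],
                v["cov_zx"], v["cov_yx"], v["cov_xx"]), 3, 3)
  dimnames(m) <- list(c("z", "y", "x"), c("z", "y", "x"))
  m
}
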