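test_that("window discretization matches direct enumeration of its support", {
  # isotropic unit ball -> the 7-voxel cross
  w <- make_window(lsd_spec(1, "ball"), c(1, 1, 1))
  expect_equal(nrow(w$offsets), 7L)
  expect_true(all(rowSums(abs(w$offsets)) <= 1))

  # anisotropic support: enumerate the ellipsoid predicate independently
  vs <- c(20, 9, 9)
  sigma <- 100
  g <- expand.grid(z = -10:10, y = -15:15, x = -15:15)
  inside <- (g$z * vs[1])^2 + (g$y * vs[2])^2 + (g$x * vs[3])^2 <= sigma^2
  w2 <- make_window(lsd_spec(sigma, "ball"), vs)
  expect_equal(nrow(w2$offsets), sum(inside))
  expect_equal(max(abs(w2$offsets[, 1])), 5)   # floor(100/20)
  expect_equal(max(abs(w2$offsets[, 2])), 11)  # floor(100/9)

  # gaussian mass equals the weight sum and bounds the size channel
  wg <- make_window(lsd_spec(sigma, "gaussian", truncate = 2), vs)
  expect_equal(wg$mass, sum(wg$weights))
  expect_true(all(wg$weights > 0))
  expect_equal(max(wg$weights), 1)  # unnormalized: center weight 1

  expect_warning(make_window(lsd_spec(5, "ball"), vs), "degenerate")
})

test_that("single-voxel descriptors follow the definition", {
  d <- c(7, 7, 7)
  lab <- array(1L, dim = d)
  lab[, , 5:7] <- 2L
  vol <- annotated_volume(lab, c(1, 1, 1), kind = "labels")
  spec <- lsd_spec(2, "ball")

  # background voxel -> zero vector
  lab0 <- lab
  lab0[4, 4, 4] <- 0L
  vol0 <- annotated_volume(lab0, c(1, 1, 1), kind = "labels")
  expect_equal(unname(lsd_at_voxel_bruteforce(vol0, c(4, 4, 4), spec)),
               rep(0, 10))

  # voxel adjacent to a planar boundary: offset points away from it, only
  # along the boundary normal (x); z, y cancel by symmetry
  v <- lsd_at_voxel_bruteforce(vol, c(4, 4, 4), spec)
  expect_lt(v[["moff_x"]], 0)
  expect_equal(v[["moff_z"]], 0)
  expect_equal(v[["moff_y"]], 0)
  expect_length(v, 10L)
})

test_that("ball and gaussian covariances reach their closed-form limits", {
  # single label filling a large volume; interior voxel sees the full window
  d <- c(17, 17, 17)
  vol <- annotated_volume(array(1L, dim = d), c(1, 1, 1), kind = "labels")
  ctr <- c(9L, 9L, 9L)

  spec_b <- lsd_spec(5, "ball")
  win_b <- make_window(spec_b, c(1, 1, 1))
  v_b <- lsd_at_voxel_bruteforce(vol, ctr, spec_b, win_b)
  expect_equal(unname(v_b[1:3]), c(0, 0, 0))  # symmetry
  # discrete oracle: second moment of the enumerated ball
  oracle <- apply(win_b$offsets, 2, function(z) mean(z^2))
  expect_equal(unname(v_b[4:6]), unname(oracle))
  expect_equal(unname(v_b[4:6]), rep(5^2 / 5, 3), tolerance = 0.05)
  expect_equal(v_b[["size"]], nrow(win_b$offsets))

  # larger volume so the truncated gaussian support (half-width 12) fits
  d_g <- c(27, 27, 27)
  vol_g <- annotated_volume(array(1L, dim = d_g), c(1, 1, 1),
                            kind = "labels")
  ctr_g <- c(14L, 14L, 14L)
  spec_g <- lsd_spec(4, "gaussian", truncate = 3)
  win_g <- make_window(spec_g, c(1, 1, 1))
  v_g <- lsd_at_voxel_bruteforce(vol_g, ctr_g, spec_g, win_g)
  expect_equal(unname(v_g[1:3]), c(0, 0, 0))
  oracle_g <- apply(win_g$offsets, 2, function(z)
    sum(win_g$weights * z^2) / sum(win_g$weights))
  expect_equal(unname(v_g[4:6]), unname(oracle_g))
  expect_equal(unname(v_g[4:6]), rep(4^2, 3), tolerance = 0.05)

  # dense route agrees at the same voxel
  for (sp in list(spec_b, spec_g)) {
    dense <- compute_lsds(vol, sp)
    expect_equal(unname(dense$data[, ctr[1], ctr[2], ctr[3]]),
                 unname(lsd_at_voxel_bruteforce(vol, ctr, sp)),
                 tolerance = 1e-8)
  }
})

test_that("convolutional LSDs equal brute force on random anisotropic data", {
  vol <- coherent_labels(c(18, 18, 18), k = 5, voxel_size = c(20, 9, 9),
                         seed = 11)
  set.seed(2)
  probes <- cbind(sample(18, 25, TRUE), sample(18, 25, TRUE),
                  sample(18, 25, TRUE))
  for (sp in list(lsd_spec(45, "ball"), lsd_spec(40, "gaussian", truncate = 2))) {
    dense <- compute_lsds(vol, sp)
    win <- make_window(sp, vol$voxel_size)
    for (i in seq_len(nrow(probes))) {
      v <- probes[i, ]
      expect_equal(unname(dense$data[, v[1], v[2], v[3]]),
                   unname(lsd_at_voxel_bruteforce(vol, v, sp, win)),
                   tolerance = 1e-6)
    }
  }
})

test_that("descriptors depend only on the partition, not the label ids", {
  vol <- coherent_labels(c(14, 14, 14), k = 4, seed = 3)
  spec <- lsd_spec(3, "gaussian", truncate = 2)
  a <- compute_lsds(vol, spec)
  perm <- c(4, 1, 3, 2)
  relab <- vol$data
  fg <- relab != 0
  relab[fg] <- perm[relab[fg]]
  b <- compute_lsds(annotated_volume(relab, vol$voxel_size, kind = "labels"),
                    spec)
  expect_equal(a$data, b$data, tolerance = 1e-10)
})

test_that("LSDs are translation-equivariant away from the border", {
  vol <- coherent_labels(c(16, 16, 16), k = 3, seed = 5)
  spec <- lsd_spec(2.5, "gaussian", truncate = 2)
  t_off <- c(2L, 1L, 3L)
  shifted <- annotated_volume(
    lsdkit:::shift_array(vol$data, t_off), vol$voxel_size, kind = "labels")
  a <- compute_lsds(vol, spec)
  b <- compute_lsds(shifted, spec)
  h <- make_window(spec, vol$voxel_size)$half_width
  lo <- 1L + h + pmax(-t_off, 0L)
  hi <- 16L - h - pmax(t_off, 0L)
  # b at v equals a at v + t within the safe interior
  expect_equal(
    b$data[, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
    a$data[, (lo[1] + t_off[1]):(hi[1] + t_off[1]),
           (lo[2] + t_off[2]):(hi[2] + t_off[2]),
           (lo[3] + t_off[3]):(hi[3] + t_off[3])],
    tolerance = 1e-8)
})

test_that("descriptor channels respect their analytic bounds", {
  vol <- coherent_labels(c(14, 14, 14), k = 4, voxel_size = c(2, 1, 1),
                         seed = 7)
  spec <- lsd_spec(3, "gaussian", truncate = 2)
  win <- make_window(spec, vol$voxel_size)
  dense <- compute_lsds(vol, spec)
  fg <- which(vol$data != 0, arr.ind = TRUE)
  moff <- sapply(1:3, function(k) dense$data[cbind(k, fg)])
  sz <- dense$data[cbind(10L, fg)]
  expect_true(all(abs(moff[, 1]) <= win$radius_nm[1] + 1e-9))
  expect_true(all(abs(moff[, 2]) <= win$radius_nm[2] + 1e-9))
  expect_true(all(sz > 0))
  expect_true(all(sz <= win$mass + 1e-9))
  # covariance PSD and symmetric at every foreground voxel
  for (i in sample(nrow(fg), 40)) {
    v <- fg[i, ]
    cm <- lsd_covariance(dense$data[, v[1], v[2], v[3]], spec)
    expect_equal(cm, t(cm))
    expect_true(all(eigen(cm, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-6))
  }
  # background voxels are all-zero
  bg <- which(vol$data == 0, arr.ind = TRUE)[1, ]
  expect_equal(unname(dense$data[, bg[1], bg[2], bg[3]]), rep(0, 10))
})

test_that("normalization maps every channel into [0, 1]", {
  vol <- coherent_labels(c(12, 12, 12), k = 3, seed = 9)
  spec <- lsd_spec(3, "gaussian", truncate = 2, normalize = TRUE)
  dense <- compute_lsds(vol, spec)
  expect_true(all(dense$data >= 0 & dense$data <= 1))
  # equation channel order puts size first
  spec_eq <- lsd_spec(3, "gaussian", truncate = 2, normalize = TRUE,
                      channel_order = "equation")
  expect_equal(lsd_channel_names(spec_eq)[1], "size")
  d2 <- compute_lsds(vol, spec_eq)
  expect_equal(d2$data[1, , , ], dense$data[10, , , ])
})

test_that("downsampled computation preserves shape and background", {
  vol <- coherent_labels(c(12, 12, 12), k = 3, seed = 13)
  spec <- lsd_spec(3, "gaussian", truncate = 2, downsample = 2L)
  dense <- compute_lsds(vol, spec)
  expect_identical(dim(dense$data), c(10L, 12L, 12L, 12L))
  # strided-grid voxels carry the coarse-grid statistics of their own label
  coarse_bg <- vol$data[seq(1, 12, 2), seq(1, 12, 2), seq(1, 12, 2)] == 0
  sz_coarse <- dense$data[10, seq(1, 12, 2), seq(1, 12, 2), seq(1, 12, 2)]
  expect_true(all((sz_coarse == 0) == coarse_bg))
})

test_that("label cap refuses pathological volumes with guidance", {
  lab <- array(seq_len(27), dim = c(3, 3, 3))
  vol <- annotated_volume(lab, c(1, 1, 1), kind = "labels")
  expect_error(compute_lsds(vol, lsd_spec(1.5, "ball"), max_labels = 10),
               "blocks")
})
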