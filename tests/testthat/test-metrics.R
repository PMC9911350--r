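test_that("contingency tables count and conserve foreground voxels", {
  gt <- array(c(1L, 1L, 2L, 2L, 0L, 3L), dim = c(1, 1, 6))
  seg <- array(c(1L, 1L, 2L, 2L, 9L, 3L), dim = c(1, 1, 6))
  ct <- contingency(gt, seg)
  expect_equal(ct$total, 5L)                      # gt foreground only
  expect_equal(nrow(ct$counts), 3L)               # diagonal table
  expect_equal(sum(ct$counts$n), sum(gt != 0))
  # one-column table when seg is a single segment
  ct2 <- contingency(gt, array(1L, dim = dim(gt)))
  expect_equal(length(unique(ct2$counts$seg)), 1L)
  expect_error(contingency(gt, array(1L, dim = c(2, 1, 3))), "shapes")
})

test_that("VOI closed forms and invariances hold", {
  # identical up to relabeling -> (0, 0)
  gt <- coherent_labels(c(8, 8, 8), k = 4, seed = 31)
  relab <- gt$data
  fg <- relab != 0
  relab[fg] <- c(7, 5, 11, 2)[relab[fg]]
  expect_equal(unname(voi(gt, relab)), c(0, 0))

  # two equal halves merged into one segment -> (0, log 2)
  halves <- array(rep(c(1L, 2L), each = 32), dim = c(4, 4, 4))
  one <- array(1L, dim = c(4, 4, 4))
  expect_equal(unname(voi(halves, one)), c(0, log(2)))
  expect_equal(unname(voi(halves, one, base = 2)), c(0, 1))
  # and the mirror image: splitting scores on the other component
  expect_equal(unname(voi(one, halves)), c(log(2), 0))

  # random toy agrees with entropies computed from the printed table
  set.seed(4)
  g3 <- array(sample(1:3, 64, TRUE), dim = c(4, 4, 4))
  s2 <- array(sample(1:2, 64, TRUE), dim = c(4, 4, 4))
  tab <- table(as.vector(g3), as.vector(s2))
  expect_equal(unname(voi(g3, s2)), unname(voi_from_counts(tab)))

  # symmetry: split(A,B) = merge(B,A) on fully-foreground volumes
  for (s in 1:3) {
    set.seed(s)
    a <- array(sample(1:4, 27, TRUE), dim = c(3, 3, 3))
    b <- array(sample(1:3, 27, TRUE), dim = c(3, 3, 3))
    vab <- voi(a, b, ignore_background = FALSE)
    vba <- voi(b, a, ignore_background = FALSE)
    expect_equal(vab[["voi_split"]], vba[["voi_merge"]])
    expect_equal(vab[["voi_merge"]], vba[["voi_split"]])
  }
  expect_error(voi(array(0L, dim = c(4, 4, 4)), one), "foreground")
})

# a segmentation volume whose x-extent is carved into segments at given
# world-x breakpoints (voxel size 10 nm; nodes placed at voxel centers)
carve_segments <- function(n_x, breaks_x, ids) {
  seg <- array(0L, dim = c(3, 3, n_x))
  lo <- c(0, breaks_x)
  hi <- c(breaks_x, n_x * 10)
  for (i in seq_along(ids)) {
    vox <- which((seq_len(n_x) - 0.5) * 10 >= lo[i] &
                   (seq_len(n_x) - 0.5) * 10 < hi[i])
    seg[, , vox] <- ids[i]
  }
  annotated_volume(seg, c(10, 10, 10), kind = "segmentation")
}

test_that("ERL matches its closed forms", {
  # two skeletons of lengths 1000 and 3000 nm, perfectly segmented:
  # erl = (1000^2 + 3000^2) / 4000 = 2500 = max_erl
  sk <- make_skeletons(
    chain_skeleton_nodes(1, 5, 11, 100, z = 15, y = 5),     # length 1000
    chain_skeleton_nodes(2, 5, 31, 100, z = 15, y = 25,
                         id_offset = 100))                  # length 3000
  seg <- array(0L, dim = c(3, 3, 320))
  seg[, 1, ] <- 1L
  seg[, 3, ] <- 2L
  vol <- annotated_volume(seg, c(10, 10, 10), kind = "segmentation")
  e <- erl(sk, vol)
  expect_equal(unname(e), c(2500, 2500))

  # a single split at the midpoint of an L-long skeleton -> L / 2 in the
  # dense-node limit (the edge crossing the cut only counts toward L_total)
  sk1 <- make_skeletons(chain_skeleton_nodes(1, 5, 501, 2, z = 15, y = 15))
  vol2 <- carve_segments(110, breaks_x = 500, ids = c(1, 2))
  e2 <- erl(sk1, vol2)
  expect_equal(e2[["erl"]], 1000 / 2, tolerance = 0.01)
  expect_equal(e2[["max_erl"]], 1000)

  # merging any other skeleton's node into a segment zeroes that skeleton
  seg_m <- vol
  seg_m$data[, 3, 1] <- 1L   # one node of skeleton 2 falls into segment 1
  e3 <- erl(sk, seg_m)
  expect_lt(e3[["erl"]], e["erl"])
  # both skeletons now touch segment 1 -> segment 1 is merged; skeleton 1
  # contributes nothing
  expect_equal(e3[["erl"]], 2900^2 / 4000)
})

test_that("adding short error-free skeletons still lowers ERL", {
  sk <- make_skeletons(
    chain_skeleton_nodes(1, 5, 11, 100, z = 15, y = 5),
    chain_skeleton_nodes(2, 5, 31, 100, z = 15, y = 25, id_offset = 100))
  seg <- array(0L, dim = c(3, 3, 320))
  seg[, 1, ] <- 1L
  seg[, 3, ] <- 2L
  seg[, 2, ] <- 3L
  vol <- annotated_volume(seg, c(10, 10, 10), kind = "segmentation")
  base <- erl(sk, vol)[["erl"]]
  # a short, perfectly segmented fragment skeleton in its own segment
  sk_plus <- make_skeletons(
    chain_skeleton_nodes(1, 5, 11, 100, z = 15, y = 5),
    chain_skeleton_nodes(2, 5, 31, 100, z = 15, y = 25, id_offset = 100),
    chain_skeleton_nodes(3, 5, 3, 100, z = 15, y = 15, id_offset = 200))
  with_frag <- erl(sk_plus, vol)
  expect_lt(with_frag[["erl"]], base)
  expect_lt(with_frag[["max_erl"]], base)  # even a perfect result drops
  expect_equal(with_frag[["erl"]], with_frag[["max_erl"]])  # no errors
})

test_that("uniform-mode ERL weights skeletons equally", {
  sk <- make_skeletons(
    chain_skeleton_nodes(1, 5, 11, 100, z = 15, y = 5),
    chain_skeleton_nodes(2, 5, 31, 100, z = 15, y = 25, id_offset = 100))
  seg <- array(0L, dim = c(3, 3, 320))
  seg[, 1, ] <- 1L
  seg[, 3, ] <- 2L
  vol <- annotated_volume(seg, c(10, 10, 10), kind = "segmentation")
  e <- erl(sk, vol, mode = "uniform")
  expect_equal(e[["erl"]], mean(c(1000, 3000)))
  expect_equal(e[["max_erl"]], 2000)
})

test_that("MCM counts splits and merges as defined", {
  # perfect segmentation -> (0, 0)
  frag <- array(0L, dim = c(3, 3, 40))
  frag[, 1, ] <- 1L
  frag[, 3, ] <- 2L
  vol <- annotated_volume(frag, c(10, 10, 10), kind = "fragments")
  sk <- make_skeletons(
    chain_skeleton_nodes(1, 5, 5, 80, z = 15, y = 5),
    chain_skeleton_nodes(2, 5, 5, 80, z = 15, y = 25, id_offset = 10))
  g <- toy_graph(1, 2, list(0.05))        # weak edge, never merged
  g <- agglomerate(g, "mean")
  expect_equal(unname(mcm(sk, vol, g, threshold = 0.5)), c(0, 0))

  # one skeleton spanning two segments, no merges -> (0, 1)
  frag2 <- array(0L, dim = c(3, 3, 40))
  frag2[, , 1:20] <- 1L
  frag2[, , 21:40] <- 2L
  vol2 <- annotated_volume(frag2, c(10, 10, 10), kind = "fragments")
  sk1 <- make_skeletons(chain_skeleton_nodes(1, 5, 10, 40, z = 15, y = 15))
  g2 <- agglomerate(toy_graph(1, 2, list(0.05)), "mean")
  expect_equal(unname(mcm(sk1, vol2, g2, threshold = 0.5)), c(0, 1))
})

test_that("MCM min-cut severs exactly the weak edge of a fragment chain", {
  # chain 1-2-3-4; skeleton A on fragments 1-2, skeleton B on 3-4;
  # interior edge 2-3 is weak; everything merged at the threshold
  frag <- array(0L, dim = c(3, 3, 40))
  frag[, , 1:10] <- 1L
  frag[, , 11:20] <- 2L
  frag[, , 21:30] <- 3L
  frag[, , 31:40] <- 4L
  vol <- annotated_volume(frag, c(10, 10, 10), kind = "fragments")
  sk <- make_skeletons(
    chain_skeleton_nodes(1, 5, 5, 40, z = 15, y = 15),               # x<200
    chain_skeleton_nodes(2, 205, 5, 40, z = 15, y = 15, id_offset = 10))
  g <- agglomerate(toy_graph(c(1, 2, 3), c(2, 3, 4),
                             list(0.9, 0.1, 0.9)), "mean")
  res <- mcm(sk, vol, g, threshold = 1)
  expect_equal(unname(res), c(1, 0))
  # oracle: the exhaustive min cut on this chain is the single 0.1 edge
  expect_equal(bf_min_cut_value(c(1, 2, 3), c(2, 3, 4), c(0.9, 0.1, 0.9),
                                srcs = c(1, 2), snks = c(3, 4)), 0.1)
})

test_that("the min-cut inside MCM matches exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:5) {
    nv <- sample(4:6, 1)
    full <- t(combn(nv, 2))
    keep <- sample(nrow(full), min(nrow(full), 10))
    u <- full[keep, 1]
    v <- full[keep, 2]
    cap <- round(runif(length(u), 0.05, 1), 2)
    # ensure 1 and nv are connected in the kept graph; if not, skip round
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(u), to = as.character(v)),
      directed = FALSE,
      vertices = data.frame(name = as.character(1:nv)))
    comp <- igraph::components(g)$membership
    if (comp[["1"]] != comp[[as.character(nv)]]) next
    got <- lsdkit:::.min_cut_split(u, v, cap, src_frags = 1,
                                   sink_frags = nv)
    expect_equal(got$value,
                 bf_min_cut_value(u, v, cap, srcs = 1, snks = nv),
                 tolerance = 1e-9)
    # reported cut edges really disconnect source from sink
    cut_keys <- paste(got$cut_u, got$cut_v)
    keep_e <- !(paste(u, v) %in% cut_keys)
    g2 <- igraph::graph_from_data_frame(
      data.frame(from = as.character(u[keep_e]),
                 to = as.character(v[keep_e])),
      directed = FALSE, vertices = data.frame(name = as.character(1:nv)))
    comp2 <- igraph::components(g2)$membership
    expect_false(comp2[["1"]] == comp2[[as.character(nv)]])
  }
})

test_that("threshold sweeps report consistent optima and monotone VOI", {
  spec <- fixture_spec(style = "tubes", count = 3, shape = c(48, 48, 48),
                       seed = 42)
  labs <- make_toy_labels(spec)
  affs <- compute_affinities(labs)
  frags <- watershed_fragments(affs, 0.5, seed_min_distance = 40)
  rag <- agglomerate(build_rag(frags, affs))
  ths <- c(0, 0.25, 0.5, 0.75, 1)
  sw <- threshold_sweep(frags, rag, ths, gt = labs,
                        voi_restrict_to_seg = TRUE)
  expect_equal(nrow(sw$reports), 5L)
  expect_equal(sw$best_threshold,
               ths[which.min(sw$reports$voi_sum)])
  # along the hierarchy merging only proceeds: merge VOI non-decreasing,
  # split VOI non-increasing
  expect_true(all(diff(sw$reports$voi_merge) >= -1e-12))
  expect_true(all(diff(sw$reports$voi_split) <= 1e-12))
  expect_error(threshold_sweep(frags, rag, numeric(0), gt = labs), "empty")
})

test_that("ERL- and VOI-optimal thresholds can disagree on early merges", {
  # object A (long, 4 fragments) + tiny object B; the A-B bridge merges
  # before A reassembles, so VOI prefers full agglomeration while ERL
  # prefers no agglomeration
  frag <- array(0L, dim = c(3, 3, 50))
  frag[, , 1:10] <- 1L
  frag[, , 11:20] <- 2L
  frag[, , 21:30] <- 3L
  frag[, , 31:40] <- 4L
  frag[, , 45:50] <- 5L
  vol <- annotated_volume(frag, c(10, 10, 10), kind = "fragments")
  gt <- frag
  gt[gt %in% 1:4] <- 1L
  gt[gt == 5L] <- 2L
  sk <- make_skeletons(
    chain_skeleton_nodes(1, 5, 20, 20, z = 15, y = 15),           # inside A
    chain_skeleton_nodes(2, 445, 3, 20, z = 15, y = 15,
                         id_offset = 100))                        # inside B
  hist <- data.frame(a = c(1, 1, 2, 3), b = c(5, 2, 3, 4),
                     score = c(0.1, 0.3, 0.35, 0.4))
  ths <- c(0.05, 0.5)
  sw_voi <- threshold_sweep(vol, hist, ths, gt = gt, criterion = "voi")
  sw_erl <- threshold_sweep(vol, hist, ths, skeletons = sk,
                            criterion = "erl")
  expect_equal(sw_voi$best_threshold, 0.5)
  expect_equal(sw_erl$best_threshold, 0.05)
})
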