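# shared fixture builders and independent oracles

# a small random label volume with spatially coherent blobs: k seed points
# grown by nearest-seed assignment, a random subset relabeled background
coherent_labels <- function(shape, k = 5, voxel_size = c(1, 1, 1),
                            background_frac = 0.2, seed = 1) {
  set.seed(seed)
  d <- shape
  seeds <- cbind(sample(d[1], k, TRUE), sample(d[2], k, TRUE),
                 sample(d[3], k, TRUE))
  idx <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  pos <- sweep(idx, 2L, voxel_size, "*")
  spos <- sweep(seeds, 2L, voxel_size, "*")
  d2 <- sapply(seq_len(k), function(i) colSums((t(pos) - spos[i, ])^2))
  lab <- max.col(-d2)
  if (background_frac > 0) {
    drop <- sample(k, max(1, round(k * background_frac)))
    lab[lab %in% drop] <- 0
  }
  a <- array(lab, dim = d)
  annotated_volume(a, voxel_size, kind = "labels")
}

# independent s-t min-cut by exhaustive edge-subset enumeration (<= 12 edges):
# cheapest edge subset whose removal disconnects every src from every snk
bf_min_cut_value <- function(u, v, cap, srcs, snks) {
  ne <- length(u)
  stopifnot(ne <= 12)
  verts <- unique(c(u, v, srcs, snks))
  best <- Inf
  for (m in 0:(2^ne - 1)) {
    keep <- !as.logical(bitwAnd(m, 2^(seq_len(ne) - 1)))
    cost <- sum(cap[!keep])
    if (cost >= best) next
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(u[keep]), to = as.character(v[keep])),
      directed = FALSE, vertices = data.frame(name = as.character(verts)))
    comp <- igraph::components(g)$membership
    if (!any(outer(comp[as.character(srcs)], comp[as.character(snks)],
                   "==")))
      best <- cost
  }
  best
}

# entropy-based VOI computed directly from a printed contingency table
voi_from_counts <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  pg <- rowSums(p)
  ps <- colSums(p)
  split <- -sum(p[p > 0] * log((p / pg[row(p)])[p > 0]))  # H(Seg | GT)
  merge <- -sum(p[p > 0] * log((p / ps[col(p)])[p > 0]))  # H(GT | Seg)
  c(voi_split = split, voi_merge = merge)
}

# hand-built fragment graph (for metric toys)
toy_graph <- function(edges_u, edges_v, boundary_affs, node_ids = NULL) {
  ids <- if (is.null(node_ids)) sort(unique(c(edges_u, edges_v))) else node_ids
  structure(list(
    nodes = data.frame(id = ids, z = 0, y = 0, x = seq_along(ids),
                       count = 1L),
    edges = data.frame(u = pmin(edges_u, edges_v),
                       v = pmax(edges_u, edges_v)),
    boundary = boundary_affs,
    merge_history = data.frame(a = numeric(0), b = numeric(0),
                               score = numeric(0))),
    class = "fragment_graph")
}

# chain skeleton along +x at fixed (z, y), node spacing `step` nm
chain_skeleton_nodes <- function(skeleton_id, x0, n, step, z, y,
                                 id_offset = 0) {
  ids <- id_offset + seq_len(n)
  list(nodes = data.frame(node_id = ids, skeleton_id = skeleton_id,
                          z = z, y = y, x = x0 + (seq_len(n) - 1) * step),
       edges = data.frame(from = ids[-n], to = ids[-1]))
}

make_skeletons <- function(...) {
  parts <- list(...)
  skeleton_set(do.call(rbind, lapply(parts, `[[`, "nodes")),
               do.call(rbind, lapply(parts, `[[`, "edges")))
}
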