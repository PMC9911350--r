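#' Contingency table between two label volumes
#'
#' Sparse joint counts `n(i, j)` of voxels carrying ground-truth label `i`
#' and segmentation label `j`, the sufficient statistic for VOI. By default
#' only ground-truth foreground voxels (`gt != 0`) are counted.
#'
#' @param gt,seg aligned [annotated_volume()]s (or plain integer arrays of
#'   equal shape).
#' @param ignore_background drop voxels with `gt == 0` (default `TRUE`).
#' @return object of class `contingency_table`: list with `counts`
#'   (data.frame `gt, seg, n`), `gt_marginal`, `seg_marginal` (named
#'   vectors) and `total`.
#' @export
contingency <- function(gt, seg, ignore_background = TRUE) {
  g <- if (inherits(gt, "annotated_volume")) gt$data else gt
  s <- if (inherits(seg, "annotated_volume")) seg$data else seg
  if (!identical(dim(g), dim(s))) stop("gt and seg shapes differ")
  if (ignore_background) {
    keep <- g != 0
    g <- g[keep]
    s <- s[keep]
  }
  dt <- data.table::data.table(gt = as.vector(g), seg = as.vector(s))
  counts <- as.data.frame(dt[, .N, keyby = .(gt, seg)])
  names(counts)[3] <- "n"
  gt_marg <- tapply(counts$n, counts$gt, sum)
  seg_marg <- tapply(counts$n, counts$seg, sum)
  structure(list(counts = counts,
                 gt_marginal = gt_marg,
                 seg_marginal = seg_marg,
                 total = sum(counts$n)),
            class = "contingency_table")
}

#' Variation of information, split into its two conditional entropies
#'
#' `voi_split = H(Seg | GT)` measures over-segmentation (how uncertain the
#' segment id is given the true object) and `voi_merge = H(GT | Seg)`
#' measures under-segmentation. Both are 0 exactly when the partitions agree
#' up to a relabeling. Computed over ground-truth foreground voxels.
#'
#' @param gt,seg aligned label volumes.
#' @param base logarithm base; default `exp(1)` (nats).
#' @param ignore_background see [contingency()].
#' @param restrict_to_seg additionally drop voxels the segmentation leaves
#'   unclaimed (`seg == 0`). Watershed only labels voxels inside the
#'   boundary-map mask, so thin ground-truth boundary voxels can remain
#'   unclaimed even under perfect affinities; with `restrict_to_seg = TRUE`
#'   the comparison is over the jointly claimed foreground.
#' @return named numeric `c(voi_split, voi_merge)`.
#' @export
voi <- function(gt, seg, base = exp(1), ignore_background = TRUE,
                restrict_to_seg = FALSE) {
  if (restrict_to_seg) {
    g <- if (inherits(gt, "annotated_volume")) gt$data else gt
    s <- if (inherits(seg, "annotated_volume")) seg$data else seg
    keep <- s != 0
    gt <- array(g * keep, dim = dim(g))
    seg <- array(s * keep, dim = dim(s))
  }
  ct <- contingency(gt, seg, ignore_background = ignore_background)
  if (ct$total == 0) stop("no foreground voxels to evaluate")
  n <- ct$counts$n
  p <- n / ct$total
  pg <- ct$gt_marginal[as.character(ct$counts$gt)] / ct$total
  ps <- ct$seg_marginal[as.character(ct$counts$seg)] / ct$total
  voi_split <- -sum(p * log(p / pg)) / log(base)
  voi_merge <- -sum(p * log(p / ps)) / log(base)
  c(voi_split = max(voi_split, 0), voi_merge = max(voi_merge, 0))
}

#' Expected run length of skeletons under a segmentation
#'
#' Maps every skeleton node to the segment under it and scores the maximal
#' skeleton sub-paths ("runs") whose nodes share one nonzero, non-merged
#' segment. A segment containing nodes of two or more skeletons is merged,
#' and every run inside it scores zero — a whole neuron counts as wrong if
#' even a small fragment of another neuron is attached to it. Nodes on
#' background break runs. The default (length-weighted) ERL is the expected
#' run length at a uniformly random point on the skeletons,
#' `sum(len_run^2) / L_total`; a perfect segmentation attains
#' `max_erl = sum(L_k^2) / L_total`, so ERL can only reach the
#' skeleton-length scale of the ground truth, and adding short error-free
#' skeletons lowers both.
#'
#' @param skeletons a [skeleton_set()] in world coordinates (nm).
#' @param seg a segmentation [annotated_volume()].
#' @param mode `"length_weighted"` (default) or `"uniform"` (each skeleton
#'   contributes its expected run length with equal weight).
#' @param outside one of `"warn"` (skip nodes outside the volume with a
#'   warning) or `"error"`.
#' @return named numeric `c(erl, max_erl)` in nm.
#' @export
erl <- function(skeletons, seg,
                mode = c("length_weighted", "uniform"),
                outside = c("warn", "error")) {
  mode <- match.arg(mode)
  outside <- match.arg(outside)
  nodes <- skeletons$nodes
  d <- vol_shape(seg)
  idx <- world_to_voxel(as.matrix(nodes[, c("z", "y", "x")]), seg)
  inb <- idx[, 1] >= 1L & idx[, 1] <= d[1] &
    idx[, 2] >= 1L & idx[, 2] <= d[2] &
    idx[, 3] >= 1L & idx[, 3] <= d[3]
  if (any(!inb)) {
    if (outside == "error") stop(sum(!inb), " skeleton nodes outside the ROI")
    warning(sum(!inb), " skeleton nodes outside the ROI; treated as ",
            "unmapped (run breakpoints)")
  }
  seg_id <- rep(0, nrow(nodes))                # 0 = unmapped/background
  seg_id[inb] <- seg$data[idx[inb, , drop = FALSE]]
  names(seg_id) <- as.character(nodes$node_id)

  # merged segments: nonzero segments hosting >= 2 skeletons
  host <- unique(data.frame(seg = seg_id, sk = nodes$skeleton_id))
  host <- host[host$seg != 0, , drop = FALSE]
  merged <- as.numeric(names(which(table(host$seg) >= 2)))

  elen <- skeleton_edge_lengths(skeletons)
  sk_of <- stats::setNames(nodes$skeleton_id, as.character(nodes$node_id))
  e_from <- as.character(skeletons$edges$from)
  e_to <- as.character(skeletons$edges$to)
  L_total <- sum(elen)
  if (L_total == 0) stop("skeletons have no edges")

  # run edges: endpoints share one nonzero, non-merged segment
  ok <- seg_id[e_from] == seg_id[e_to] & seg_id[e_from] != 0 &
    !(seg_id[e_from] %in% merged)

  run_sq <- 0
  per_skel_sq <- stats::setNames(
    numeric(length(unique(nodes$skeleton_id))),
    sort(unique(nodes$skeleton_id)))
  if (any(ok)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = e_from[ok], to = e_to[ok]),
      directed = FALSE,
      vertices = data.frame(name = as.character(nodes$node_id)))
    comp <- igraph::components(g)$membership
    run_id <- comp[e_from[ok]]
    run_len <- tapply(elen[ok], run_id, sum)
    run_sq <- sum(run_len^2)
    run_sk <- tapply(sk_of[e_from[ok]], run_id, function(v) v[1])
    sq_by_skel <- tapply(as.numeric(run_len)^2, as.numeric(run_sk), sum)
    per_skel_sq[names(sq_by_skel)] <- sq_by_skel
  }

  L_k <- skeleton_lengths(skeletons)
  if (mode == "length_weighted") {
    c(erl = run_sq / L_total, max_erl = sum(L_k^2) / L_total)
  } else {
    lk <- L_k[names(per_skel_sq)]
    c(erl = mean(ifelse(lk > 0, per_skel_sq / lk, 0)),
      max_erl = mean(lk))
  }
}

# exact min s-t cut on a small fragment subgraph via igraph; capacities are
# boundary affinities (1 - merge score). Virtual source/sink tie together
# the fragments hosting each skeleton's nodes.
.min_cut_split <- function(edges_u, edges_v, cap, src_frags, sink_frags) {
  verts <- unique(c(edges_u, edges_v, src_frags, sink_frags))
  vn <- as.character(verts)
  big <- sum(cap) + 1
  ed <- data.frame(
    from = c(as.character(edges_u), rep("SRC", length(src_frags)),
             as.character(sink_frags)),
    to = c(as.character(edges_v), as.character(src_frags),
           rep("SNK", length(sink_frags))))
  caps <- c(cap, rep(big, length(src_frags)), rep(big, length(sink_frags)))
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = c(vn, "SRC", "SNK")))
  cut <- igraph::max_flow(g, source = "SRC", target = "SNK",
                          capacity = caps)
  eidx <- as.integer(cut$cut)
  keep <- eidx <= length(edges_u)          # virtual edges never cut (big cap)
  list(value = cut$value,
       cut_u = edges_u[eidx[keep]],
       cut_v = edges_v[eidx[keep]])
}

#' Min-cut metric: simulated proofreading effort
#'
#' Counts the edit operations an annotator with a min-cut split tool and a
#' merge tool would need to make the segmentation consistent with the
#' ground-truth skeletons. For every segment whose fragments host two or
#' more skeletons, the two skeletons with the most nodes in the conflicted
#' component (ties: lowest skeleton ids) are separated by an s-t min-cut on
#' the component's fragment subgraph — capacities are the aggregated
#' boundary affinities (`1 -` merge score), sources/sinks the fragments
#' hosting each skeleton's nodes — the cut edges are removed and one split
#' is counted, until every component hosts at most one skeleton. Merges are
#' then the number of components each skeleton is spread over, minus one,
#' summed over skeletons.
#'
#' @param skeletons a [skeleton_set()].
#' @param fragments the fragments [annotated_volume()].
#' @param graph an agglomerated `fragment_graph` (for the edge capacities).
#' @param threshold agglomeration threshold defining the segments.
#' @param on_unmapped `"skip"` (default: ignore skeleton nodes on background
#'   fragments) or `"error"`.
#' @return named numeric `c(splits, merges)`.
#' @export
mcm <- function(skeletons, fragments, graph, threshold,
                on_unmapped = c("skip", "error")) {
  on_unmapped <- match.arg(on_unmapped)
  nodes <- skeletons$nodes
  d <- vol_shape(fragments)
  idx <- world_to_voxel(as.matrix(nodes[, c("z", "y", "x")]), fragments)
  inb <- idx[, 1] >= 1L & idx[, 1] <= d[1] &
    idx[, 2] >= 1L & idx[, 2] <= d[2] &
    idx[, 3] >= 1L & idx[, 3] <= d[3]
  frag_id <- rep(0, nrow(nodes))
  frag_id[inb] <- fragments$data[idx[inb, , drop = FALSE]]
  if (any(frag_id == 0)) {
    if (on_unmapped == "error") stop("skeleton nodes on background fragments")
  }
  sk <- nodes$skeleton_id[frag_id != 0]
  fr <- frag_id[frag_id != 0]

  seg <- extract_segmentation(fragments, graph, threshold)
  # fragment -> segment lookup from the two volumes
  fgsel <- fragments$data != 0L
  lut_dt <- data.table::data.table(frag = fragments$data[fgsel],
                                   seg = seg$data[fgsel])
  lut <- as.data.frame(unique(lut_dt))
  seg_of <- stats::setNames(lut$seg, as.character(lut$frag))

  # capacities of RAG edges (aggregated affinity)
  mf <- graph$merge_function %||% "mean"
  qq <- graph$q %||% 0.75
  cap_all <- vapply(graph$boundary, .aggregate_boundary, numeric(1),
                    merge_function = mf, q = qq)
  eu <- graph$edges$u
  ev <- graph$edges$v

  # active adjacency per segment; cut edges are deleted as we go
  splits <- 0L
  host_by_frag <- split(sk, fr)           # skeletons seen on each fragment
  frag_seg <- seg_of[as.character(unique(fr))]
  edge_alive <- rep(TRUE, length(eu))
  eseg <- seg_of[as.character(eu)]        # both endpoints share a segment
  for (s in unique(frag_seg)) {
    repeat {
      # components of the segment's fragment subgraph under alive edges
      in_seg <- !is.na(eseg) & eseg == s & edge_alive &
        seg_of[as.character(ev)] == s
      frs <- unique(c(eu[in_seg], ev[in_seg],
                      as.numeric(names(frag_seg))[frag_seg == s]))
      if (!length(frs)) break
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(eu[in_seg]),
                   to = as.character(ev[in_seg])),
        directed = FALSE, vertices = data.frame(name = as.character(frs)))
      comp <- igraph::components(g)$membership
      # find a component hosting >= 2 skeletons
      conflict <- NULL
      for (ci in sort(unique(comp))) {
        cf <- names(comp)[comp == ci]
        sks <- unlist(host_by_frag[cf], use.names = FALSE)
        if (length(unique(sks)) >= 2) { conflict <- list(ci = ci, cf = cf,
                                                         sks = sks); break }
      }
      if (is.null(conflict)) break
      tab <- sort(table(conflict$sks), decreasing = TRUE)
      top2 <- as.numeric(names(tab))
      o <- order(-as.numeric(tab), as.numeric(names(tab)))
      top2 <- as.numeric(names(tab))[o][1:2]
      cf_num <- as.numeric(conflict$cf)
      src <- cf_num[vapply(host_by_frag[conflict$cf], function(v)
        top2[1] %in% v, logical(1))]
      snk <- cf_num[vapply(host_by_frag[conflict$cf], function(v)
        top2[2] %in% v, logical(1))]
      both <- intersect(src, snk)
      src <- setdiff(src, both)
      snk <- setdiff(snk, both)
      if (!length(src) || !length(snk)) break   # inseparable; skip per config
      sub_idx <- which(in_seg &
                         as.character(eu) %in% conflict$cf &
                         as.character(ev) %in% conflict$cf)
      cut <- .min_cut_split(eu[sub_idx], ev[sub_idx], cap_all[sub_idx],
                            src, snk)
      hit <- sub_idx[paste(eu[sub_idx], ev[sub_idx]) %in%
                       paste(cut$cut_u, cut$cut_v)]
      edge_alive[hit] <- FALSE
      splits <- splits + 1L
    }
  }

  # final components across all segments -> merge count
  all_in <- edge_alive & !is.na(eseg) &
    eseg == seg_of[as.character(ev)]
  frs <- unique(c(eu[all_in], ev[all_in], fr))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(eu[all_in]),
               to = as.character(ev[all_in])),
    directed = FALSE, vertices = data.frame(name = as.character(frs)))
  # components must also respect segment membership (fragments of different
  # segments are never implicitly connected)
  comp <- igraph::components(g)$membership
  comp_key <- paste(comp[as.character(fr)], seg_of[as.character(fr)])
  merges <- sum(tapply(comp_key, sk, function(k) length(unique(k)) - 1L))
  c(splits = as.numeric(splits), merges = as.numeric(merges))
}

#' Metric sweep over agglomeration thresholds
#'
#' Extracts a segmentation at every threshold and scores it, returning the
#' per-threshold reports and the optimum — the "line search on validation
#' data" by which the operating threshold is chosen. The optimum minimizes
#' the VOI sum (`criterion = "voi"`) or maximizes ERL
#' (`criterion = "erl"`).
#'
#' @param fragments fragments volume.
#' @param history agglomerated `fragment_graph` (or merge-history
#'   data.frame).
#' @param thresholds numeric vector in `[0, 1]`.
#' @param gt ground-truth label volume (needed for `criterion = "voi"`).
#' @param skeletons a [skeleton_set()] (needed for `criterion = "erl"`).
#' @param criterion `"voi"` or `"erl"`.
#' @param voi_restrict_to_seg passed to [voi()] (`restrict_to_seg`).
#' @return list with `reports` (data.frame: threshold, voi_split, voi_merge,
#'   voi_sum, erl, max_erl as available) and `best_threshold`.
#' @export
threshold_sweep <- function(fragments, history, thresholds,
                            gt = NULL, skeletons = NULL,
                            criterion = c("voi", "erl"),
                            voi_restrict_to_seg = FALSE) {
  criterion <- match.arg(criterion)
  if (!length(thresholds)) stop("empty threshold list")
  if (criterion == "voi" && is.null(gt)) stop("criterion 'voi' needs `gt`")
  if (criterion == "erl" && is.null(skeletons))
    stop("criterion 'erl' needs `skeletons`")
  rows <- lapply(thresholds, function(th) {
    seg <- extract_segmentation(fragments, history, th)
    row <- list(threshold = th)
    if (!is.null(gt)) {
      v <- voi(gt, seg, restrict_to_seg = voi_restrict_to_seg)
      row$voi_split <- v[["voi_split"]]
      row$voi_merge <- v[["voi_merge"]]
      row$voi_sum <- sum(v)
    }
    if (!is.null(skeletons)) {
      e <- suppressWarnings(erl(skeletons, seg))
      row$erl <- e[["erl"]]
      row$max_erl <- e[["max_erl"]]
    }
    as.data.frame(row)
  })
  reports <- do.call(rbind, rows)
  best <- if (criterion == "voi") which.min(reports$voi_sum)
          else which.max(reports$erl)
  list(reports = reports, best_threshold = thresholds[best])
}
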