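#' Region adjacency graph over watershed fragments
#'
#' Nodes are fragments (center of mass in nm, voxel count); one edge per pair
#' of face-adjacent fragments under the direct neighborhood. Each edge keeps
#' the multiset of affinity values across its boundary voxel pairs, from
#' which the merge score is computed as `1 - aggregate(boundary affinities)`
#' (so 0 merges first and "decreasing affinity" becomes increasing score).
#' The aggregate is chosen at agglomeration time (mean or a quantile).
#'
#' @param fragments an [annotated_volume()] of kind `"fragments"`.
#' @param affs the direct-neighbor affinities the fragments came from.
#' @return an object of class `fragment_graph`: list with `nodes`
#'   (data.frame `id, z, y, x, count`), `edges` (data.frame `u, v` with
#'   `u < v`), `boundary` (list of numeric affinity vectors, one per edge
#'   row) and empty `merge_history`.
#' @export
build_rag <- function(fragments, affs) {
  stopifnot(inherits(fragments, "annotated_volume"),
            fragments$kind == "fragments",
            identical(vol_shape(fragments), vol_shape(affs)))
  frag <- fragments$data
  d <- dim(frag)
  vs <- fragments$voxel_size

  fg <- which(frag != 0L, arr.ind = TRUE)
  ids <- frag[frag != 0L]
  if (length(ids)) {
    dt_nodes <- data.table::data.table(
      id = ids,
      z = (fg[, 1] - 0.5) * vs[1] + fragments$offset[1],
      y = (fg[, 2] - 0.5) * vs[2] + fragments$offset[2],
      x = (fg[, 3] - 0.5) * vs[3] + fragments$offset[3])
    nodes <- as.data.frame(dt_nodes[, .(z = mean(z), y = mean(y),
                                        x = mean(x), count = .N),
                                    keyby = id])
  } else {
    nodes <- data.frame(id = numeric(0), z = numeric(0), y = numeric(0),
                        x = numeric(0), count = integer(0))
  }

  direct <- rbind(c(-1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 0L, -1L))
  pieces <- list()
  for (j in 1:3) {
    partner <- shift_array(frag, direct[j, ], fill = 0L)
    sel <- frag != 0L & partner != 0L & frag != partner
    if (!any(sel)) next
    a <- array(affs$data[j, , , ], dim = d)
    pieces[[length(pieces) + 1L]] <- data.table::data.table(
      u = pmin(frag[sel], partner[sel]),
      v = pmax(frag[sel], partner[sel]),
      aff = a[sel])
  }
  if (length(pieces)) {
    all_pairs <- data.table::rbindlist(pieces)
    agg <- all_pairs[, .(affs = list(aff)), keyby = .(u, v)]
    edges <- as.data.frame(agg[, .(u, v)])
    boundary <- agg$affs
  } else {
    edges <- data.frame(u = numeric(0), v = numeric(0))
    boundary <- list()
  }
  structure(list(nodes = nodes, edges = edges, boundary = boundary,
                 merge_history = data.frame(a = numeric(0), b = numeric(0),
                                            score = numeric(0))),
            class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("<fragment_graph> %d fragments, %d edges, %d recorded merges\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$merge_history)))
  invisible(x)
}

# aggregate a boundary multiset into one affinity value
.aggregate_boundary <- function(vals, merge_function, q) {
  if (merge_function == "mean") mean(vals)
  else as.numeric(stats::quantile(vals, probs = q, type = 7))  # linear interp
}

#' Hierarchical agglomeration of a fragment graph
#'
#' Greedy merging of RAG edges in order of increasing merge score
#' (equivalently decreasing boundary affinity): repeatedly merge the
#' lowest-scoring edge, pool the boundary multisets of any parallel edges of
#' the merged pair and recompute their aggregate, until no edges remain. The
#' full merge history is recorded so a segmentation at any threshold can be
#' extracted afterwards. Ties are broken by the smallest fragment-id pair;
#' recorded scores are clamped to be non-decreasing (a pooled aggregate can
#' drop below the current merge level).
#'
#' @param rag a [build_rag()] result.
#' @param merge_function `"mean"` or `"quantile"` — the aggregate applied to
#'   an edge's boundary affinities (the "two merge functions" choice).
#' @param q quantile probability when `merge_function = "quantile"`
#'   (default 0.75, linear interpolation).
#' @return the `fragment_graph` with `merge_history` filled: data.frame
#'   `(a, b, score)` where `a`, `b` are the cluster representatives (smallest
#'   member id) at merge time and `score` is non-decreasing.
#' @export
agglomerate <- function(rag, merge_function = c("mean", "quantile"),
                        q = 0.75) {
  merge_function <- match.arg(merge_function)
  stopifnot(inherits(rag, "fragment_graph"))
  ne <- nrow(rag$edges)
  if (!ne) {
    rag$merge_history <- data.frame(a = numeric(0), b = numeric(0),
                                    score = numeric(0))
    rag$merge_function <- merge_function
    rag$q <- q
    return(rag)
  }

  # cluster bookkeeping: representative = smallest member id
  parent <- new.env(parent = emptyenv())
  find <- function(i) {
    key <- as.character(i)
    p <- get0(key, envir = parent, ifnotfound = NULL)
    if (is.null(p) || p == i) return(i)
    r <- find(p)
    assign(key, r, envir = parent)
    r
  }
  link <- function(a, b) assign(as.character(max(a, b)), min(a, b),
                                envir = parent)

  eu <- rag$edges$u
  ev <- rag$edges$v
  bnd <- rag$boundary
  score <- vapply(bnd, .aggregate_boundary, numeric(1),
                  merge_function = merge_function, q = q)
  score <- 1 - score
  alive <- rep(TRUE, ne)
  hist_a <- numeric(0); hist_b <- numeric(0); hist_s <- numeric(0)
  last <- 0

  while (any(alive)) {
    cand <- which(alive)
    s <- score[cand]
    best <- cand[order(s, eu[cand], ev[cand])][1]
    sc <- max(score[best], last)
    last <- sc
    a <- eu[best]; b <- ev[best]
    hist_a <- c(hist_a, a); hist_b <- c(hist_b, b); hist_s <- c(hist_s, sc)
    link(a, b)
    rep_new <- min(a, b)
    alive[best] <- FALSE
    # rewire remaining edges to cluster representatives; pool parallel edges
    if (any(alive)) {
      act <- which(alive)
      ru <- vapply(eu[act], find, numeric(1))
      rv <- vapply(ev[act], find, numeric(1))
      eu[act] <- pmin(ru, rv)
      ev[act] <- pmax(ru, rv)
      self <- act[eu[act] == ev[act]]
      alive[self] <- FALSE
      act <- which(alive)
      touched <- act[eu[act] == rep_new | ev[act] == rep_new]
      if (length(touched)) {
        key <- paste(eu[touched], ev[touched])
        for (grp in split(touched, key)) {
          if (length(grp) > 1L) {
            pooled <- unlist(bnd[grp])
            bnd[[grp[1]]] <- pooled
            alive[grp[-1]] <- FALSE
          }
          grp1 <- grp[1]
          score[grp1] <- 1 - .aggregate_boundary(bnd[[grp1]],
                                                 merge_function, q)
        }
      }
    }
  }
  rag$merge_history <- data.frame(a = hist_a, b = hist_b, score = hist_s)
  rag$merge_function <- merge_function
  rag$q <- q
  rag
}

#' Segmentation at an agglomeration threshold
#'
#' Applies all merges with score strictly below `threshold` (union-find over
#' the merge history) and relabels the fragment volume to the component
#' representatives. Threshold 0 returns the fragments unchanged; increasing
#' thresholds coarsen the partition monotonically.
#'
#' @param fragments the fragments volume the history was built from.
#' @param history a `fragment_graph` with `merge_history`, or the
#'   `merge_history` data.frame itself.
#' @param threshold merge-score threshold in `[0, 1]`.
#' @return an [annotated_volume()] of kind `"segmentation"`.
#' @export
extract_segmentation <- function(fragments, history, threshold) {
  if (inherits(history, "fragment_graph")) history <- history$merge_history
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ids <- sort(unique(as.vector(fragments$data)))
  ids <- ids[ids != 0]
  map <- stats::setNames(ids, as.character(ids))
  find <- function(i) {
    r <- i
    while (map[[as.character(r)]] != r) r <- map[[as.character(r)]]
    r
  }
  use <- history[history$score < threshold, , drop = FALSE]
  for (k in seq_len(nrow(use))) {
    ra <- find(use$a[k]); rb <- find(use$b[k])
    if (ra != rb) map[[as.character(max(ra, rb))]] <- min(ra, rb)
  }
  final <- vapply(ids, find, numeric(1))
  lut <- stats::setNames(final, as.character(ids))
  seg <- fragments$data
  fgsel <- seg != 0L
  seg[fgsel] <- lut[as.character(seg[fgsel])]
  storage.mode(seg) <- "integer"
  annotated_volume(seg, fragments$voxel_size, fragments$offset,
                   kind = "segmentation")
}

#' Block-wise watershed + agglomeration
#'
#' Processes the volume in blocks: watershed runs per block on a context-
#' padded region and is cropped back to the block core, fragment ids are
#' offset per block so they are globally unique, and a single global RAG is
#' built over the assembled fragments (cross-block edges arise on the shared
#' faces automatically). Agglomeration and threshold extraction then operate
#' on the stitched graph exactly as in the monolithic path.
#'
#' @param affs an [annotated_volume()] of kind `"affinities"`.
#' @param block_shape block core size in voxels `(z, y, x)`.
#' @param context halo in voxels added on every side for the per-block
#'   watershed; should cover at least `seed_min_distance`.
#' @param threshold agglomeration threshold for the returned segmentation.
#' @param mask_threshold,seed_min_distance passed to [watershed_fragments()].
#' @param merge_function,q passed to [agglomerate()].
#' @return the segmentation [annotated_volume()], with the stitched
#'   fragments volume and agglomerated graph attached as attributes
#'   `"fragments"` and `"graph"`.
#' @export
blockwise_segment <- function(affs, block_shape, context, threshold,
                              mask_threshold = 0.5, seed_min_distance = 10,
                              merge_function = "mean", q = 0.75) {
  d <- vol_shape(affs)
  block_shape <- as.integer(rep(block_shape, length.out = 3L))
  context <- as.integer(rep(context, length.out = 3L))
  if (any(context * affs$voxel_size < seed_min_distance))
    warning("context smaller than seed_min_distance; block seeds near faces ",
            "may differ from the monolithic result")
  grid <- ceiling(d / block_shape)
  frag <- array(0L, dim = d)
  next_offset <- 0L
  for (bi in seq_len(prod(grid))) {
    gidx <- arrayInd(bi, grid)
    lo <- (gidx - 1L) * block_shape + 1L
    hi <- pmin(lo + block_shape - 1L, d)
    elo <- pmax(lo - context, 1L)
    ehi <- pmin(hi + context, d)
    sub <- annotated_volume(
      affs$data[, elo[1]:ehi[1], elo[2]:ehi[2], elo[3]:ehi[3], drop = FALSE],
      affs$voxel_size,
      affs$offset + (elo - 1L) * affs$voxel_size,
      kind = "affinities",
      mask = if (!is.null(affs$mask))
        affs$mask[, elo[1]:ehi[1], elo[2]:ehi[2], elo[3]:ehi[3],
                  drop = FALSE])
    bf <- suppressWarnings(
      watershed_fragments(sub, mask_threshold, seed_min_distance))
    core <- bf$data[(lo[1] - elo[1] + 1L):(hi[1] - elo[1] + 1L),
                    (lo[2] - elo[2] + 1L):(hi[2] - elo[2] + 1L),
                    (lo[3] - elo[3] + 1L):(hi[3] - elo[3] + 1L),
                    drop = FALSE]
    nz <- core != 0L
    if (any(nz)) {
      core[nz] <- core[nz] + next_offset
      next_offset <- next_offset + max(bf$data)
      dst <- frag[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      dst[nz] <- core[nz]
      frag[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dst
    }
  }
  fragments <- annotated_volume(frag, affs$voxel_size, affs$offset,
                                kind = "fragments")
  rag <- build_rag(fragments, affs)
  rag <- agglomerate(rag, merge_function = merge_function, q = q)
  seg <- extract_segmentation(fragments, rag, threshold)
  attr(seg, "fragments") <- fragments
  attr(seg, "graph") <- rag
  seg
}

#' Persist / load a fragment graph as CSV tables
#'
#' Writes `<prefix>_nodes.csv` (`id, z, y, x, count`; positions nm),
#' `<prefix>_edges.csv` (`u, v, n_boundary, mean_affinity`) and, when merge
#' history is present, `<prefix>_merges.csv` (`a, b, score`). The boundary
#' multisets themselves are not persisted; a reloaded graph supports
#' threshold extraction but not re-agglomeration.
#'
#' @param rag a `fragment_graph`.
#' @param prefix file path prefix.
#' @return `invisible(NULL)`.
#' @export
write_fragment_graph <- function(rag, prefix) {
  utils::write.csv(rag$nodes, paste0(prefix, "_nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  ed <- rag$edges
  ed$n_boundary <- vapply(rag$boundary, length, integer(1))
  ed$mean_affinity <- vapply(rag$boundary, mean, numeric(1))
  utils::write.csv(ed, paste0(prefix, "_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  if (nrow(rag$merge_history))
    utils::write.csv(rag$merge_history, paste0(prefix, "_merges.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_fragment_graph
#' @export
read_fragment_graph <- function(prefix) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  ed <- utils::read.csv(paste0(prefix, "_edges.csv"))
  mh_path <- paste0(prefix, "_merges.csv")
  mh <- if (file.exists(mh_path)) utils::read.csv(mh_path)
        else data.frame(a = numeric(0), b = numeric(0), score = numeric(0))
  structure(list(nodes = nodes, edges = ed[, c("u", "v")],
                 boundary = lapply(seq_len(nrow(ed)), function(i)
                   rep(ed$mean_affinity[i], ed$n_boundary[i])),
                 merge_history = mh),
            class = "fragment_graph")
}
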