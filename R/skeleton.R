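#' Skeletonize a 3D mask
#'
#' Topology-preserving curve thinning: foreground voxels are peeled from the
#' six faces in turn, deleting only (26,6) simple points that are not curve
#' endpoints, until no voxel can be removed.  Solid blobs collapse to their
#' medial curves: a straight 1-voxel-wide line is already minimal and is
#' returned unchanged; a solid ellipsoid collapses to a short line along its
#' long axis.  The skeleton is always a subset of the mask and has the same
#' number of 26-connected components.
#'
#' @param mask binary 3D array (one structure, hole-filled, or a whole
#'   stack's worth of structures).
#' @return logical array of the same shape.
#' @export
skeletonize_3d <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  if (!any(m)) return(array(FALSE, d))
  out <- cpp_skeletonize(as.vector(m), d)
  dim(out) <- d
  out
}

#' Chebyshev distance-to-background map
#'
#' Number of radius-1 box erosions a voxel survives: 1 on the surface,
#' increasing towards the medial axis.  The maximum over a structure is its
#' inscribed (Chebyshev) ball radius.
#'
#' @param mask binary 3D array.
#' @return integer array of the same shape (0 on background).
#' @export
chebyshev_depth <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  depth <- array(0L, d)
  v <- as.numeric(m)
  k <- 0L
  while (any(v > 0.5)) {
    k <- k + 1L
    ve <- cpp_rank_filter(v, d, rep(1L, 3L), 0L)
    depth[v > 0.5 & ve <= 0.5] <- k
    v <- ve
  }
  depth
}

#' Geodesic centreline tree of a structure
#'
#' Extracts a curve skeleton as a tree of geodesic paths between the
#' structure's significant extremities, in the spirit of path-based
#' centreline algorithms.  The voxel farthest from the centroid is the
#' first tip and the voxel farthest from that tip the second; their
#' geodesic path (26-connected, Euclidean step weights, inside the mask)
#' forms the initial centreline.  Further tips are accepted greedily while the
#' candidate — the voxel farthest from the current tree — protrudes from
#' the tree by more than twice the structure's inscribed-ball radius.  The
#' threshold is scale-free and separates bodies from appendages: for any
#' solid ellipsoid the largest possible protrusion of the rim from the
#' long-axis centreline is the middle semi-axis, which never exceeds the
#' inscribed diameter, whereas a duct-like arm sticking out of a body does.
#' Unlike iterative thinning — which routinely absorbs one arm of a thick
#' T junction into a smooth elbow before it can thin to a curve — every
#' significant arm ends in a tip and is therefore guaranteed a branch.
#'
#' @param mask binary 3D array, one 26-connected structure, hole-filled.
#' @param protrusion_factor significance multiple of the inscribed radius.
#' @param max_tips maximum number of extremities.
#' @return logical array marking the centreline tree (a subset of the
#'   mask), or an all-`FALSE` array for an empty mask.
#' @export
centerline_tree <- function(mask, protrusion_factor = 2, max_tips = 8L) {
  m <- as_mask(mask)
  d <- dim(m)
  out <- array(FALSE, d)
  if (!any(m)) return(out)
  mv <- as.vector(m)
  dep <- chebyshev_depth(m)
  # Euclidean inscribed radius: exact distance from the deepest voxels to
  # the nearest outside voxel
  outside <- which(!m & (cpp_rank_filter(as.numeric(m), d, rep(1L, 3L),
                                         1L) > 0.5))
  if (!length(outside)) outside <- which(!m)
  oc <- arrayInd(outside, d)
  deepest <- order(dep[m], decreasing = TRUE)
  mask_idx <- which(mv)
  top <- mask_idx[deepest[seq_len(min(20, length(deepest)))]]
  r_eu <- if (length(outside)) {
    max(vapply(top, function(i) {
      p <- arrayInd(i, d)
      sqrt(min(rowSums(sweep(oc, 2, as.vector(p))^2)))
    }, 0))
  } else max(dep)

  backtrack <- function(v, parent) {
    path <- v
    while (parent[v] > 0) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  }
  # tips by Euclidean extremity: farthest voxel from the centroid, then
  # farthest from the first tip (geodesic-farthest is biased off-axis by
  # the few-percent length inflation of digital paths)
  cc <- arrayInd(mask_idx, d)
  cen <- colMeans(cc)
  e1 <- mask_idx[which.max(rowSums(sweep(cc, 2, cen)^2))]
  e2 <- mask_idx[which.max(rowSums(sweep(cc, 2,
                                         as.vector(arrayInd(e1, d)))^2))]
  b2 <- cpp_geodesic_dijkstra(mv, d, e1)
  tree <- backtrack(e2, b2$parent)
  tips <- list(as.vector(arrayInd(e1, d)), as.vector(arrayInd(e2, d)))
  point_segment_dist <- function(p, a, b) {
    ab <- b - a
    L2 <- sum(ab^2)
    t <- if (L2 < 1e-12) 0 else min(1, max(0, sum((p - a) * ab) / L2))
    sqrt(sum((p - (a + t * ab))^2))
  }
  while (length(tips) < max_tips) {
    bt <- cpp_geodesic_dijkstra(mv, d, as.integer(tree))
    cand <- which.max(replace(bt$dist, bt$dist < 0, -1))
    if (bt$dist[cand] <= 0) break
    # significance: the candidate must protrude from every straight chord
    # between accepted tips by more than `protrusion_factor` inscribed
    # radii.  Chords, not the geodesic tree, are the reference: a body that
    # bends (a T junction) moves its third tip far from the chord, whereas
    # the rim of a plain ellipsoid never leaves the long-axis chord by more
    # than the middle semi-axis
    pc <- as.vector(arrayInd(cand, d))
    prs <- combn(length(tips), 2)
    prot <- min(vapply(seq_len(ncol(prs)), function(s) {
      point_segment_dist(pc, tips[[prs[1, s]]], tips[[prs[2, s]]])
    }, 0))
    if (prot <= protrusion_factor * r_eu) break
    tree <- union(tree, backtrack(cand, bt$parent))
    tips <- c(tips, list(pc))
  }
  out[tree] <- TRUE
  # a final thinning pass removes the occasional redundant voxel where a
  # digital path changes direction, so the tree is a clean 1-voxel curve
  out <- skeletonize_3d(out)
  attr(out, "inscribed_radius") <- r_eu
  out
}

# 26-adjacency edges among skeleton voxels; coords is an n x 3 matrix
skeleton_edges <- function(coords, spacing) {
  n <- nrow(coords)
  if (n < 2L) {
    return(data.frame(from = integer(), to = integer(), weight = numeric()))
  }
  key <- coords[, 1] + 2^21 * coords[, 2] + 2^42 * coords[, 3]
  ord <- order(key)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  # keep one orientation of each offset pair so every edge appears once
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    o <- as.numeric(offs[i, ])
    nk <- (coords[, 1] + o[1]) + 2^21 * (coords[, 2] + o[2]) +
      2^42 * (coords[, 3] + o[3])
    pos <- findInterval(nk, key[ord])
    j <- rep(NA_integer_, n)
    j[pos >= 1] <- ord[pos[pos >= 1]]
    hit <- !is.na(j) & key[j] == nk
    if (any(hit)) {
      from <- c(from, which(hit))
      to <- c(to, j[hit])
      w <- c(w, rep(sqrt(sum((o * spacing)^2)), sum(hit)))
    }
  }
  data.frame(from = from, to = to, weight = w)
}

#' Build the branch graph of a skeleton
#'
#' Skeleton voxels are classified by their 26-neighbour count (1 neighbour:
#' endpoint, 2: path, 3 or more: junction); branches are the maximal paths
#' between endpoint/junction nodes, with physical length the sum of
#' Euclidean steps between consecutive voxels (diagonal steps weigh
#' `sqrt(2)`/`sqrt(3)` times the spacing, so lengths are physical, not step
#' counts).  An isolated voxel yields one zero-length branch; a pure cycle
#' contributes one branch of its perimeter length.  Spur branches shorter
#' than `prune_length` that run from a junction to an endpoint are removed
#' (thinning artifacts on bumpy surfaces inflate branch counts; the default
#' of 2 is chosen so a rasterized ellipsoid reports a single branch).
#'
#' @param skeleton logical array from [skeletonize_3d()] (one structure).
#' @param spacing voxel spacing `(dz, dy, dx)`.
#' @param prune_length minimum physical length of a junction-to-endpoint
#'   spur; 0 disables pruning.
#' @return a `skeleton_graph`: list with `nodes` (tibble of endpoint and
#'   junction voxels), `branches` (tibble: branch id, terminal voxel ids,
#'   voxel count, physical length), `branch_voxels` (list of voxel-index
#'   vectors per branch), `coords`, `n_branches`, `total_length`,
#'   `has_multiple_branches`.
#' @export
skeleton_graph <- function(skeleton, spacing = c(1, 1, 1), prune_length = 2) {
  m <- as_mask(skeleton)
  spacing <- as.numeric(spacing)
  coords <- which(m, arr.ind = TRUE)
  colnames(coords) <- c("z", "y", "x")
  g <- build_branches(coords, spacing)
  if (prune_length > 0 && nrow(g$branches) > 1L) {
    for (pass in 1:10) {
      spur <- with(g$branches, (from_type == "endpoint") !=
                     (to_type == "endpoint") & length < prune_length)
      # never prune a whole component: spurs must end at a junction
      spur <- spur & (g$branches$from_type == "junction" |
                        g$branches$to_type == "junction")
      if (!any(spur)) break
      drop_vox <- unlist(lapply(which(spur), function(b) {
        bb <- g$branches[b, ]
        vox <- g$branch_voxels[[b]]
        keep_end <- if (bb$from_type == "junction") bb$from else bb$to
        setdiff(vox, keep_end)
      }))
      coords <- coords[-drop_vox, , drop = FALSE]
      g <- build_branches(coords, spacing)
      if (nrow(g$branches) <= 1L) break
    }
  }
  structure(
    list(
      nodes = g$nodes,
      branches = g$branches,
      branch_voxels = g$branch_voxels,
      coords = coords,
      n_branches = nrow(g$branches),
      total_length = sum(g$branches$length),
      has_multiple_branches = nrow(g$branches) > 1L
    ),
    class = "skeleton_graph"
  )
}

# decompose the voxel adjacency graph into maximal branches
build_branches <- function(coords, spacing) {
  n <- nrow(coords)
  empty <- list(
    nodes = tibble::tibble(voxel = integer(), z = integer(), y = integer(),
                           x = integer(), type = character()),
    branches = tibble::tibble(branch = integer(), from = integer(),
                              to = integer(), from_type = character(),
                              to_type = character(), n_voxels = integer(),
                              length = numeric()),
    branch_voxels = list()
  )
  if (n == 0L) return(empty)
  ed <- skeleton_edges(coords, spacing)
  deg <- tabulate(c(ed$from, ed$to), nbins = n)
  vtype <- ifelse(deg <= 1L, "endpoint", ifelse(deg == 2L, "path", "junction"))
  adj <- vector("list", n)
  for (i in seq_len(nrow(ed))) {
    adj[[ed$from[i]]] <- rbind(adj[[ed$from[i]]], c(ed$to[i], i))
    adj[[ed$to[i]]] <- rbind(adj[[ed$to[i]]], c(ed$from[i], i))
  }
  used <- logical(nrow(ed))
  branches <- list()
  branch_voxels <- list()
  nb <- 0L
  walk <- function(start, first_edge_row) {
    # follow the path from `start` through degree-2 voxels
    path <- start
    len <- 0
    cur <- start
    erow <- first_edge_row
    repeat {
      used[erow[2]] <<- TRUE
      len <- len + ed$weight[erow[2]]
      nxt <- erow[1]
      path <- c(path, nxt)
      if (vtype[nxt] != "path" || nxt == start) break
      cand <- adj[[nxt]]
      cand <- cand[!used[cand[, 2]], , drop = FALSE]
      if (nrow(cand) == 0L) break
      erow <- cand[1, ]
      cur <- nxt
    }
    list(path = path, length = len)
  }
  terminals <- which(vtype != "path")
  for (v in terminals) {
    if (is.null(adj[[v]])) next
    for (r in seq_len(nrow(adj[[v]]))) {
      erow <- adj[[v]][r, ]
      if (used[erow[2]]) next
      res <- walk(v, erow)
      nb <- nb + 1L
      branches[[nb]] <- data.frame(
        branch = nb, from = v, to = res$path[length(res$path)],
        from_type = vtype[v], to_type = vtype[res$path[length(res$path)]],
        n_voxels = length(res$path), length = res$length
      )
      branch_voxels[[nb]] <- res$path
    }
  }
  # pure cycles (all remaining unused edges lie on degree-2 loops)
  remaining <- which(!used)
  while (length(remaining)) {
    erow <- remaining[1]
    start <- ed$from[erow]
    res <- walk(start, c(ed$to[erow], erow))
    nb <- nb + 1L
    branches[[nb]] <- data.frame(
      branch = nb, from = start, to = start,
      from_type = "cycle", to_type = "cycle",
      n_voxels = length(unique(res$path)), length = res$length
    )
    branch_voxels[[nb]] <- unique(res$path)
    remaining <- which(!used)
  }
  # isolated voxels: one zero-length branch each
  for (v in which(deg == 0L)) {
    nb <- nb + 1L
    branches[[nb]] <- data.frame(
      branch = nb, from = v, to = v, from_type = "endpoint",
      to_type = "endpoint", n_voxels = 1L, length = 0
    )
    branch_voxels[[nb]] <- v
  }
  node_idx <- sort(unique(c(terminals, which(deg == 0L))))
  list(
    nodes = tibble::tibble(
      voxel = node_idx,
      z = coords[node_idx, 1], y = coords[node_idx, 2],
      x = coords[node_idx, 3],
      type = vtype[node_idx]
    ),
    branches = dplyr::bind_rows(branches) |> tibble::as_tibble(),
    branch_voxels = branch_voxels
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d voxel(s), %d branch(es), total length %.3g\n",
    nrow(x$coords), x$n_branches, x$total_length
  ))
  invisible(x)
}

#' Complexity measures of a skeleton graph
#'
#' The three complexity quantities of a structure's skeleton: whether it has
#' more than one branch, the number of branches, and the cumulated physical
#' length of all branches (`C`).  The higher the cumulated length, the more
#' convoluted or branched the structure.
#'
#' @param graph a [skeleton_graph()].
#' @return list with `has_multiple_branches`, `n_branches`, `complexity`.
#' @export
complexity_metrics <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  list(
    has_multiple_branches = graph$has_multiple_branches,
    n_branches = graph$n_branches,
    complexity = graph$total_length
  )
}

#' Skeletonize and measure every labeled structure
#'
#' Builds each structure's skeleton (cropped to its bounding box), derives
#' the branch graph with [skeleton_graph()] and collects the complexity
#' measures.  Skeletons are computed on the hole-filled masks, so lumena
#' never create spurious cycles.
#'
#' Two skeletonization methods are available.  `"geodesic"` (the default)
#' uses the extremity-based centreline tree of [centerline_tree()], which
#' guarantees that every significant duct-like arm terminates in a tip and
#' is counted as a branch, and that surface bumps are not; it is the
#' stable choice for branch statistics on voxelised, smoothed bodies.
#' `"thinning"` uses the iterative thinning of [skeletonize_3d()], whose
#' branch counts on compact bodies are sensitive to surface detail: a bump
#' can grow a fork while a genuinely crossing duct can be absorbed into a
#' smooth elbow.
#'
#' @param labels a [label_components()] result (filled masks).
#' @param spacing voxel spacing.
#' @param prune_length spur-pruning threshold, see [skeleton_graph()].
#' @param method `"geodesic"` or `"thinning"`.
#' @return tibble: `label`, `n_branches`, `total_length`,
#'   `has_multiple_branches`.
#' @export
measure_complexity <- function(labels, spacing = attr(labels, "spacing"),
                               prune_length = 2,
                               method = c("geodesic", "thinning")) {
  method <- match.arg(method)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  k <- attr(labels, "n_labels") %||% max(labels)
  if (k == 0L) {
    return(tibble::tibble(label = integer(), n_branches = integer(),
                          total_length = numeric(),
                          has_multiple_branches = logical()))
  }
  idx <- which(labels > 0L)
  coords <- arrayInd(idx, dim(labels))
  ids <- labels[idx]
  rows <- lapply(seq_len(k), function(i) {
    cc <- coords[ids == i, , drop = FALSE]
    lo <- apply(cc, 2, min) - 2L
    d <- apply(cc, 2, max) - lo + 3L
    m <- array(FALSE, d)
    m[(cc[, 1] - lo[1]) + d[1] * ((cc[, 2] - lo[2] - 1L) +
                                    d[2] * (cc[, 3] - lo[3] - 1L))] <- TRUE
    sk <- if (method == "geodesic") centerline_tree(m) else skeletonize_3d(m)
    g <- skeleton_graph(sk, spacing, prune_length)
    cm <- complexity_metrics(g)
    tibble::tibble(
      label = i, n_branches = cm$n_branches, total_length = cm$complexity,
      has_multiple_branches = cm$has_multiple_branches
    )
  })
  dplyr::bind_rows(rows)
}
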