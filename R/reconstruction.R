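#' Estimate oriented surface normals for a point cloud
#'
#' Fits a plane to the `k_neighbors` nearest neighbours of each point
#' (PCA; the normal is the smallest-variance direction), then makes the
#' orientation globally consistent by propagating along a minimum
#' spanning tree of the neighbourhood graph (edges weighted by normal
#' disagreement), and finally flips the whole field so that normals point
#' away from the centroid on average.  `k_neighbors = 0` is a sentinel
#' that returns a cloud already carrying normals unchanged.
#'
#' @param cloud a [point_cloud()].
#' @param k_neighbors neighbourhood size (>= 3), or 0 to pass through.
#' @return a [point_cloud()] with unit normals.
#' @export
estimate_normals <- function(cloud, k_neighbors = 16) {
  if (k_neighbors == 0) {
    if (is.null(cloud$normals)) stop("cloud carries no normals to pass through")
    return(cloud)
  }
  if (k_neighbors < 3) stop("k_neighbors must be at least 3 (or 0)")
  P <- cloud$points
  n <- nrow(P)
  if (n < k_neighbors + 1) stop("fewer points than k_neighbors")
  nn <- cpp_knn(P, as.integer(k_neighbors), knn_cell_size(P))
  N <- cpp_pca_normals(P, nn)
  N <- N / sqrt(rowSums(N^2))

  # orientation: MST over the kNN graph, weight = normal disagreement
  src <- rep(seq_len(n), ncol(nn))
  dst <- as.vector(nn) + 1L
  keep <- dst >= 1L
  src <- src[keep]
  dst <- dst[keep]
  w <- 1 - abs(rowSums(N[src, , drop = FALSE] * N[dst, , drop = FALSE])) + 1e-9
  g <- igraph::graph_from_edgelist(cbind(src, dst), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  g <- igraph::simplify(g, edge.attr.comb = "min")
  mst <- igraph::mst(g)
  root <- which.max(P[, 3])
  bf <- igraph::bfs(mst, root = root, father = TRUE, order = TRUE,
                    unreachable = TRUE)
  ord <- as.integer(bf$order)
  father <- as.integer(bf$father)
  if ((P[root, 3] - mean(P[, 3])) >= 0 && N[root, 3] < 0) N[root, ] <- -N[root, ]
  for (v in ord) {
    f <- father[v]
    if (is.na(f)) next
    if (sum(N[f, ] * N[v, ]) < 0) N[v, ] <- -N[v, ]
  }
  ctr <- colMeans(P)
  if (mean(rowSums((P - rep(ctr, each = n)) * N)) < 0) N <- -N
  point_cloud(P, N)
}

# spatial-hash cell size heuristic for surface-sampled clouds
knn_cell_size <- function(P) {
  rng <- apply(P, 2, range)
  d <- rng[2, ] - rng[1, ]
  area <- max(2 * (d[1] * d[2] + d[1] * d[3] + d[2] * d[3]), 1e-12)
  2 * sqrt(area / nrow(P))
}

# median nearest-neighbour spacing
cloud_spacing <- function(P) {
  nn <- cpp_knn(P, 1L, knn_cell_size(P))
  ok <- nn[, 1] >= 0
  median(sqrt(rowSums((P[ok, , drop = FALSE] -
                       P[nn[ok, 1] + 1, , drop = FALSE])^2)))
}

#' Reconstruct a watertight surface from an oriented point cloud
#'
#' Implicit-function reconstruction: a signed field is interpolated from
#' the tangent planes of the `k` nearest points (distance-weighted), and
#' its zero level set is extracted by marching tetrahedra on a grid of
#' pitch `spacing`.  Components contributing less than `min_component`
#' of the total area (spurious blobs) are removed, and the result is
#' oriented outward.
#'
#' @param cloud a [point_cloud()] with normals (see [estimate_normals()]).
#' @param method reconstruction method; `"implicit"` is implemented.
#' @param spacing grid pitch in m; default 2.5 times the median point
#'   spacing.
#' @param k number of neighbour tangent planes blended per field sample.
#' @param min_component area fraction below which components are dropped.
#' @return a watertight, outward-oriented [mesh3t()].
#' @export
reconstruct_surface <- function(cloud, method = c("implicit"), spacing = NULL,
                                k = 10, min_component = 0.01) {
  method <- match.arg(method)
  if (is.null(cloud$normals))
    stop("reconstruction requires normals; run estimate_normals() first")
  P <- cloud$points
  if (is.null(spacing)) spacing <- 2.5 * cloud_spacing(P)
  raw <- cpp_mesh_from_points(P, cloud$normals, spacing, as.integer(k),
                              knn_cell_size(P))
  mesh <- mesh3t(raw$vertices, raw$faces + 1L, validate = FALSE)
  if (!nrow(mesh$faces)) stop("reconstruction produced no surface")
  mesh <- clean_components(mesh, min_component)
  if (!is_watertight(mesh)) {
    k2 <- edge_key(mesh_edges(mesh), nrow(mesh$vertices))
    tab <- tabulate(match(k2, unique(k2)))
    stop(sprintf("reconstruction yielded no closed surface (%d boundary edges)",
                 sum(tab == 1L)))
  }
  orient_outward(mesh)
}

#' Close small holes in a mesh
#'
#' Triangulates each boundary loop as a fan around the loop centroid.
#' Intended for meshes that are nearly closed (on the order of 10%
#' boundary edges); a boundary loop longer than 30% of the total edge
#' count is refused, as fan filling such a hole would fabricate a large
#' share of the surface.
#'
#' @param mesh a [mesh3t()] object.
#' @return a watertight, outward-oriented [mesh3t()]; an already
#'   watertight input is returned unchanged.
#' @export
make_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  k <- edge_key(e, nv)
  uk <- unique(k)
  cnt <- tabulate(match(k, uk))
  nb <- sum(cnt == 1L)
  if (nb == 0L) return(mesh)
  # boundary edges, directed as they appear in their single face
  f <- mesh$faces
  de <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  bnd <- de[cnt[match(k, uk)] == 1L, , drop = FALSE]
  # chain boundary loops by consuming reversed directed edges (fill
  # triangles must oppose the face winding); consuming edges rather than
  # following a vertex-successor map keeps traversal finite even when
  # several holes share a vertex
  from <- bnd[, 2]
  to <- bnd[, 1]
  m <- length(from)
  out <- vector("list", nv)
  for (e in seq_len(m)) out[[from[e]]] <- c(out[[from[e]]], e)
  used_e <- logical(m)
  V <- mesh$vertices
  newF <- list()
  for (e0 in seq_len(m)) {
    if (used_e[e0]) next
    loop <- integer(0)
    e <- e0
    repeat {
      used_e[e] <- TRUE
      loop <- c(loop, from[e])
      cand <- out[[to[e]]]
      cand <- cand[!used_e[cand]]
      if (!length(cand)) break
      e <- cand[1]
    }
    closed <- to[e] == from[e0]
    if (length(loop) > 0.30 * length(uk))
      stop("boundary loop longer than 30% of edges; refusing to fill")
    if (!closed || length(loop) < 3) next # unfixable chain; caught below
    # a walk may traverse several holes that share a vertex (a pinched,
    # figure-8 boundary); fan-filling that directly would duplicate the
    # edges at the pinch, so split into simple cycles first
    stack <- integer(0)
    pos <- integer(nv)
    cycles <- list()
    for (v in loop) {
      if (pos[v] > 0) {
        p <- pos[v]
        cyc <- stack[p:length(stack)]
        if (length(cyc) >= 3) cycles[[length(cycles) + 1]] <- cyc
        for (u in cyc) pos[u] <- 0
        stack <- c(stack[seq_len(p - 1)], v)
        pos[v] <- length(stack)
      } else {
        stack <- c(stack, v)
        pos[v] <- length(stack)
      }
    }
    if (length(stack) >= 3) cycles[[length(cycles) + 1]] <- stack
    for (cyc in cycles) {
      ctr <- colMeans(V[cyc, , drop = FALSE])
      V <- rbind(V, ctr)
      ci <- nrow(V)
      newF[[length(newF) + 1]] <- cbind(cyc, c(cyc[-1], cyc[1]), ci)
    }
  }
  out <- mesh3t(V, rbind(f, do.call(rbind, newF)), validate = FALSE)
  if (!is_watertight(out)) stop("hole filling failed to close the surface")
  orient_outward(out)
}
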