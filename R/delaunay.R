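# Bowyer-Watson Delaunay triangulation and its dual, used to
# re-triangulate the seam of merged misoriented domains.  Pure R; point
# sets here are a few hundred pore centres, for which incremental
# insertion is plenty fast.

#' Delaunay triangulation of a 2D point set
#'
#' Incremental Bowyer-Watson construction.  Points are rescaled to unit
#' size for conditioning; ties (near-cocircular quadruples) resolve by
#' insertion order, which is made deterministic upstream.
#'
#' @param pts Numeric matrix (n x 2) or data frame with `x`, `y`.
#' @return Integer matrix (m x 3) of triangle vertex indices, rows
#'   counter-clockwise.
#' @export
delaunay <- function(pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  n <- nrow(pts)
  stopifnot(n >= 3L)
  ctr <- colMeans(pts)
  sc <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)
  p <- sweep(pts, 2, ctr) / sc
  M <- 20
  p <- rbind(p, c(-M, -M), c(M, -M), c(0, M))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)

  for (i in seq_len(n)) {
    qx <- p[i, 1]; qy <- p[i, 2]
    ax <- p[tris[, 1], 1] - qx; ay <- p[tris[, 1], 2] - qy
    bx <- p[tris[, 2], 1] - qx; by <- p[tris[, 2], 2] - qy
    cx <- p[tris[, 3], 1] - qx; cy <- p[tris[, 3], 2] - qy
    d <- ax * (by * (cx^2 + cy^2) - cy * (bx^2 + by^2)) -
      ay * (bx * (cx^2 + cy^2) - cx * (bx^2 + by^2)) +
      (ax^2 + ay^2) * (bx * cy - by * cx)
    orient <- (p[tris[, 2], 1] - p[tris[, 1], 1]) *
      (p[tris[, 3], 2] - p[tris[, 1], 2]) -
      (p[tris[, 2], 2] - p[tris[, 1], 2]) *
      (p[tris[, 3], 1] - p[tris[, 1], 1])
    bad <- (d * sign(orient)) > 0
    if (!any(bad)) next  # degenerate; point on hull of current mesh
    cavity <- tris[bad, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    edges <- rbind(cavity[, c(1, 2)], cavity[, c(2, 3)], cavity[, c(3, 1)])
    k <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[k %in% names(which(table(k) == 1L)), , drop = FALSE]
    tris <- rbind(tris, cbind(boundary, i))
  }
  tris <- tris[tris[, 1] <= n & tris[, 2] <= n & tris[, 3] <= n, , drop = FALSE]
  # normalise to counter-clockwise
  o <- (p[tris[, 2], 1] - p[tris[, 1], 1]) * (p[tris[, 3], 2] - p[tris[, 1], 2]) -
    (p[tris[, 2], 2] - p[tris[, 1], 2]) * (p[tris[, 3], 1] - p[tris[, 1], 1])
  flip <- o < 0
  tmp <- tris[flip, 2]; tris[flip, 2] <- tris[flip, 3]; tris[flip, 3] <- tmp
  tris
}

circumcenters <- function(pts, tris) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  a <- pts[tris[, 1], , drop = FALSE]
  b <- pts[tris[, 2], , drop = FALSE]
  c <- pts[tris[, 3], , drop = FALSE]
  d <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
              c[, 1] * (a[, 2] - b[, 2]))
  ux <- ((a[, 1]^2 + a[, 2]^2) * (b[, 2] - c[, 2]) +
           (b[, 1]^2 + b[, 2]^2) * (c[, 2] - a[, 2]) +
           (c[, 1]^2 + c[, 2]^2) * (a[, 2] - b[, 2])) / d
  uy <- ((a[, 1]^2 + a[, 2]^2) * (c[, 1] - b[, 1]) +
           (b[, 1]^2 + b[, 2]^2) * (a[, 1] - c[, 1]) +
           (c[, 1]^2 + c[, 2]^2) * (b[, 1] - a[, 1])) / d
  cbind(ux, uy)
}

# Dual (Voronoi-skeleton) graph of a triangulation: one vertex per
# triangle circumcenter, edges between triangles sharing an edge.  If
# `keep` marks a subset of triangles, only those contribute; interior
# faces of the dual are the closed cells of interior points.
dual_pore_graph <- function(pts, tris, keep = NULL) {
  if (!is.null(keep)) tris <- tris[keep, , drop = FALSE]
  cc <- circumcenters(pts, tris)
  m <- nrow(tris)
  ekey <- character(0); owner <- list()
  for (t in seq_len(m)) {
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tris[t, pr[1]]; j <- tris[t, pr[2]]
      k <- paste(min(i, j), max(i, j))
      pos <- match(k, ekey)
      if (is.na(pos)) {
        ekey <- c(ekey, k); owner[[length(ekey)]] <- t
      } else {
        owner[[pos]] <- c(owner[[pos]], t)
      }
    }
  }
  pairs <- owner[lengths(owner) == 2L]
  e <- if (length(pairs))
    tibble::tibble(v1 = vapply(pairs, `[`, integer(1), 1L),
                   v2 = vapply(pairs, `[`, integer(1), 2L))
  else tibble::tibble(v1 = integer(), v2 = integer())
  pore_graph(tibble::tibble(x = cc[, 1], y = cc[, 2]), e)
}
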