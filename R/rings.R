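#' Planar pore graphs and ring statistics
#'
#' A `pore_graph` is a straight-line planar embedding of the network's
#' vertex graph: vertex coordinates plus an undirected edge list.  The
#' planar embedding (rotation system) is taken from the coordinates by
#' sorting each vertex's neighbours by azimuth, which is exact for
#' straight-line embeddings.
#'
#' @param vertices Tibble/data frame with columns `x`, `y` (and optionally
#'   `id`).
#' @param edges Tibble/data frame with integer columns `v1`, `v2` indexing
#'   rows of `vertices`.
#' @return A `pore_graph`.
#' @export
pore_graph <- function(vertices, edges) {
  v <- tibble::as_tibble(vertices)
  if (!"id" %in% names(v)) v$id <- seq_len(nrow(v))
  e <- tibble::as_tibble(edges)[, c("v1", "v2")]
  if (any(e$v1 == e$v2)) stop("self-loops are not allowed", call. = FALSE)
  k <- paste(pmin(e$v1, e$v2), pmax(e$v1, e$v2))
  if (anyDuplicated(k)) stop("duplicate edges", call. = FALSE)
  structure(list(vertices = v, edges = e), class = "pore_graph")
}

#' @export
print.pore_graph <- function(x, ...) {
  cat(sprintf("<pore_graph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' @rdname pore_graph
#' @param net A `honeycomb_network`.
#' @export
as_pore_graph <- function(net) {
  stopifnot(inherits(net, "honeycomb_network"))
  pore_graph(net$vertices, net$edges)
}

# all faces of the straight-line embedding as vertex cycles
trace_faces <- function(g) {
  v <- g$vertices; e <- g$edges
  n <- nrow(v)
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e$v1[i]]] <- c(adj[[e$v1[i]]], e$v2[i])
    adj[[e$v2[i]]] <- c(adj[[e$v2[i]]], e$v1[i])
  }
  for (u in seq_len(n)) {
    nb <- adj[[u]]
    if (length(nb))
      adj[[u]] <- nb[order(atan2(v$y[nb] - v$y[u], v$x[nb] - v$x[u]))]
  }
  # directed half-edges; next half-edge of (u -> w) is (w -> previous
  # neighbour of u in w's counter-clockwise order), tracing each face once
  he <- rbind(cbind(e$v1, e$v2), cbind(e$v2, e$v1))
  hk <- paste(he[, 1], he[, 2])
  used <- logical(nrow(he))
  faces <- list()
  for (s in seq_len(nrow(he))) {
    if (used[s]) next
    cyc <- integer()
    u <- he[s, 1]; w <- he[s, 2]
    repeat {
      idx <- match(paste(u, w), hk)
      if (used[idx]) break
      used[idx] <- TRUE
      cyc <- c(cyc, u)
      nb <- adj[[w]]
      pos <- match(u, nb)
      nxt <- nb[(pos - 2L) %% length(nb) + 1L]
      u <- w; w <- nxt
      if (u == he[s, 1] && w == he[s, 2]) break
    }
    if (length(cyc) >= 3L) faces[[length(faces) + 1L]] <- cyc
  }
  faces
}

#' Ring statistics of a planar pore graph
#'
#' Traverses the faces of the straight-line embedding and histograms the
#' face sizes; the outer (unbounded) face is excluded by its orientation.
#' A pristine honeycomb fragment is all six-membered rings; a large-angle
#' grain boundary shows paired five- and seven-membered rings.
#'
#' @param g A [pore_graph()] (or a `honeycomb_network`, converted via
#'   [as_pore_graph()]).
#' @param max_ring Faces larger than this are not rings but holes of the
#'   sampled region (for example where an incomplete feature was excised)
#'   and are dropped along with the outer face.
#' @return Named integer vector: ring size -> count.
#' @examples
#' ring_statistics(as_pore_graph(build_honeycomb(cells = c(3, 3))))
#' @export
ring_statistics <- function(g, max_ring = 12L) {
  if (inherits(g, "honeycomb_network")) g <- as_pore_graph(g)
  stopifnot(inherits(g, "pore_graph"))
  faces <- trace_faces(g)
  if (!length(faces)) return(stats::setNames(integer(), character()))
  area <- vapply(faces, function(cyc)
    polygon_area(g$vertices$x[cyc], g$vertices$y[cyc]), numeric(1))
  sizes <- lengths(faces)[area > 0]  # interior faces are counter-clockwise
  tab <- table(sizes[sizes <= max_ring])
  stats::setNames(as.integer(tab), names(tab))
}

#' Insert a single 5-7 ring pair into a pristine graph
#'
#' Local edge surgery at an interior degree-3 vertex: one of its edges is
#' removed and re-attached between two of its neighbours, converting two
#' adjacent hexagons into a pentagon and a heptagon.  The ring histogram
#' changes by exactly \{5:+1, 7:+1, 6:-2\}, the signature of one
#' dislocation.
#'
#' @param g A [pore_graph()].
#' @param vertex Interior vertex id; default picks the one nearest the
#'   graph centroid whose three faces are all interior.
#' @return The modified `pore_graph`.
#' @export
insert_ring_pair <- function(g, vertex = NULL) {
  stopifnot(inherits(g, "pore_graph"))
  deg <- table(c(g$edges$v1, g$edges$v2))
  candidates <- as.integer(names(deg)[deg == 3L])
  if (!length(candidates)) stop("no degree-3 vertex available", call. = FALSE)
  if (is.null(vertex)) {
    ctr <- c(mean(g$vertices$x), mean(g$vertices$y))
    vertex <- candidates[which.min((g$vertices$x[candidates] - ctr[1])^2 +
                                     (g$vertices$y[candidates] - ctr[2])^2)]
  }
  if (!vertex %in% candidates) stop("vertex must have degree 3", call. = FALSE)
  nb <- c(g$edges$v2[g$edges$v1 == vertex], g$edges$v1[g$edges$v2 == vertex])
  nb <- nb[order(atan2(g$vertices$y[nb] - g$vertices$y[vertex],
                       g$vertices$x[nb] - g$vertices$x[vertex]))]
  v <- nb[1]; t <- nb[2]
  drop <- which((g$edges$v1 == vertex & g$edges$v2 == t) |
                  (g$edges$v2 == vertex & g$edges$v1 == t))
  g$edges <- g$edges[-drop, ]
  g$edges <- dplyr::bind_rows(g$edges, tibble::tibble(v1 = v, v2 = t))
  g
}
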