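# Junction topology from cell polygons.
#
# Cells are polygons that share boundary segments vertex-for-vertex (as
# produced by the synthetic generators and by typical vertex-model /
# skeletonised segmentations). Vertices within the merging tolerance are
# clustered; an edge between two cells carries the total shared boundary
# length and the (sign-aligned) mean direction of its segments.

#' Build a junction graph from cell polygons
#'
#' @param frame a [tissue_frame()] whose `polygons` list covers all cells.
#' @param tol vertex-merging tolerance (µm); below the cell scale so that
#'   numerical jitter does not create spurious high-order vertices.
#' @param check_overlap if TRUE, raise a geometry error when two polygons
#'   overlap by more than 1% of the smaller cell's area (convex clipping
#'   test on bounding-box-overlapping pairs).
#' @return object of class `junction_graph`: `vertices` (data.frame x,y),
#'   `vertex_cells` (list of incident cell-id vectors, parallel to
#'   `vertices`), and `edges` (data.frame cell_a, cell_b, length, ux, uy).
#' @export
build_junction_graph <- function(frame, tol = 0.25, check_overlap = TRUE) {
  stopifnot(inherits(frame, "tissue_frame"))
  polys <- frame$polygons
  if (is.null(polys) || !all(as.character(frame$cells$cell_id) %in%
                             names(polys))) {
    stop("all cells must carry polygons; attach them before building the ",
         "junction graph", call. = FALSE)
  }
  ids <- frame$cells$cell_id
  polys <- polys[as.character(ids)]

  if (check_overlap) .check_polygon_overlaps(polys, ids)

  pts <- do.call(rbind, polys)
  owner <- rep(seq_along(polys), vapply(polys, nrow, integer(1)))
  cl <- .cluster_points(pts, tol)
  vpos <- cl$centers
  vid_of_point <- cl$assignment

  # boundary of each cell as a cyclic sequence of vertex ids
  offsets <- c(0L, cumsum(vapply(polys, nrow, integer(1))))
  segs_key <- character(0); segs_cell <- integer(0)
  segs_v1 <- integer(0); segs_v2 <- integer(0)
  for (i in seq_along(polys)) {
    vids <- vid_of_point[(offsets[i] + 1L):offsets[i + 1L]]
    vids <- vids[c(TRUE, diff(vids) != 0L)]           # drop merged repeats
    if (length(vids) > 1L && vids[1L] == vids[length(vids)]) {
      vids <- vids[-length(vids)]
    }
    if (length(vids) < 2L) next
    v1 <- vids; v2 <- c(vids[-1L], vids[1L])
    a <- pmin(v1, v2); b <- pmax(v1, v2)
    segs_key <- c(segs_key, paste(a, b, sep = "-"))
    segs_cell <- c(segs_cell, rep(i, length(a)))
    segs_v1 <- c(segs_v1, a); segs_v2 <- c(segs_v2, b)
  }

  # segments shared by exactly two cells become junction pieces
  edge_env <- new.env(parent = emptyenv())
  seg_split <- split(seq_along(segs_key), segs_key)
  for (k in names(seg_split)) {
    rows <- seg_split[[k]]
    cells_here <- unique(segs_cell[rows])
    if (length(cells_here) != 2L) next
    v1 <- segs_v1[rows[1L]]; v2 <- segs_v2[rows[1L]]
    dvec <- vpos[v2, ] - vpos[v1, ]
    len <- sqrt(sum(dvec^2))
    u <- if (len > 0) dvec / len else c(0, 0)
    ca <- min(ids[cells_here]); cb <- max(ids[cells_here])
    key <- paste(ca, cb, sep = "-")
    cur <- edge_env[[key]]
    if (is.null(cur)) {
      edge_env[[key]] <- list(a = ca, b = cb, length = len, dir = u * len)
    } else {
      # align segment direction with the accumulated one before averaging
      if (sum(cur$dir * u) < 0) u <- -u
      cur$length <- cur$length + len
      cur$dir <- cur$dir + u * len
      edge_env[[key]] <- cur
    }
  }
  keys <- ls(edge_env)
  edges <- if (length(keys) > 0L) {
    rows <- lapply(keys, function(k) {
      e <- edge_env[[k]]
      nd <- sqrt(sum(e$dir^2))
      u <- if (nd > 0) e$dir / nd else c(NA_real_, NA_real_)
      data.frame(cell_a = e$a, cell_b = e$b, length = e$length,
                 ux = u[1], uy = u[2])
    })
    do.call(rbind, rows)
  } else {
    data.frame(cell_a = numeric(), cell_b = numeric(), length = numeric(),
               ux = numeric(), uy = numeric())
  }

  # vertex incidence: cells whose boundary uses the vertex
  vcells <- vector("list", nrow(vpos))
  for (i in seq_along(polys)) {
    vids <- unique(vid_of_point[(offsets[i] + 1L):offsets[i + 1L]])
    for (v in vids) vcells[[v]] <- c(vcells[[v]], ids[i])
  }
  vcells <- lapply(vcells, function(z) sort(unique(z)))
  keep <- vapply(vcells, length, integer(1)) >= 3L
  structure(list(
    vertices = data.frame(x = vpos[keep, 1], y = vpos[keep, 2]),
    vertex_cells = vcells[keep],
    edges = edges), class = "junction_graph")
}

#' @export
print.junction_graph <- function(x, ...) {
  cat("<junction_graph>", nrow(x$vertices), "vertices (>=3-fold),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# single-linkage clustering of points within tolerance; returns cluster
# centers and per-point assignment
.cluster_points <- function(pts, tol) {
  n <- nrow(pts)
  # coarse hash on a tol-grid, then exact merge of neighbouring occupied bins
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  ord <- order(pts[, 1], pts[, 2])
  # sweep by x: only compare points within tol in x
  xs <- pts[ord, 1]
  lo <- 1L
  for (k in seq_len(n)) {
    while (xs[k] - xs[lo] > tol) lo <- lo + 1L
    if (lo < k) {
      for (m in lo:(k - 1L)) {
        if (abs(pts[ord[m], 2] - pts[ord[k], 2]) <= tol &&
            sum((pts[ord[m], ] - pts[ord[k], ])^2) <= tol^2) {
          unite(ord[m], ord[k])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  uroots <- unique(roots)
  assignment <- match(roots, uroots)
  centers <- t(vapply(seq_along(uroots), function(i) {
    colMeans(pts[assignment == i, , drop = FALSE])
  }, numeric(2)))
  list(centers = centers, assignment = assignment)
}

.check_polygon_overlaps <- function(polys, ids) {
  n <- length(polys)
  bb <- t(vapply(polys, function(p) c(min(p[, 1]), max(p[, 1]),
                                      min(p[, 2]), max(p[, 2])), numeric(4)))
  areas <- vapply(polys, polygon_area, numeric(1))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
          bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
      inter <- .convex_clip_area(polys[[i]], polys[[j]])
      if (inter > 0.01 * min(areas[i], areas[j])) {
        stop("polygons of cells ", ids[i], " and ", ids[j],
             " overlap by more than 1% of the smaller cell", call. = FALSE)
      }
    }
  }
  invisible(NULL)
}

# Sutherland-Hodgman clip (clip polygon assumed convex); area of result.
.convex_clip_area <- function(subject, clip) {
  # ensure counter-clockwise clip polygon
  if (.signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) return(0)
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    inp <- out; out <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (k in seq_len(np)) {
      kn <- if (k == np) 1L else k + 1L
      cur_in <- side[k] >= -1e-12; nxt_in <- side[kn] >= -1e-12
      if (cur_in) out <- rbind(out, inp[k, ])
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[kn])
        out <- rbind(out, inp[k, ] + t * (inp[kn, ] - inp[k, ]))
      }
    }
  }
  if (nrow(out) < 3L) 0 else polygon_area(out)
}

.signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}
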