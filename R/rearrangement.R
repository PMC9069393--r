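# Cell-rearrangement analysis from junction-graph time series: T1
# neighbour exchanges, rosettes, new-junction orientation, and the
# directional tissue elongation rate from tracked centroids.

.edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

# translate a frame's cell ids to track ids (identity when no track given)
.to_track_ids <- function(frame_index, ids, track) {
  if (is.null(track)) return(ids)
  sel <- track[track$frame == frame_index, ]
  out <- sel$track_id[match(ids, sel$cell_id)]
  if (any(is.na(out))) {
    stop("cell id(s) in frame ", frame_index, " missing from the track table",
         call. = FALSE)
  }
  out
}

#' Detect T1 transitions in a junction-graph time series
#'
#' A T1 candidate arises when the junction between a cell pair (a, b)
#' shrinks below `L_min` at frame t. The event is confirmed if, within
#' `persistence` frames, a junction appears between the two remaining
#' members (c, d) of the adjacency quad (the common neighbours of a and b
#' at frame t). Each quad emits at most one event per series
#' (deduplicated to the earliest confirmation).
#'
#' @param series list of [tissue_frame()]s, each with a junction graph.
#' @param track optional [track_table()] linking cell ids across frames;
#'   omit when cell ids are already persistent.
#' @param L_min junction-length threshold (µm).
#' @param persistence confirmation window (frames).
#' @return list of `t1_event` objects with fields `frame_start`,
#'   `frame_end`, `losing` (a, b), `gaining` (c, d), `new_direction`
#'   (unit vector of the new junction) and `pre_areas` (areas of the four
#'   participants at `frame_start`). Ids are track ids when a track table
#'   is supplied.
#' @export
detect_t1 <- function(series, track = NULL, L_min = 1.0, persistence = 3L) {
  if (length(series) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (any(vapply(series, function(f) is.null(f$junction_graph), logical(1)))) {
    stop("every frame needs a junction graph; run build_junction_graph first",
         call. = FALSE)
  }
  nfr <- length(series)
  # per-frame edge tables and adjacency in track-id space
  edges <- vector("list", nfr); areas <- vector("list", nfr)
  for (t in seq_len(nfr)) {
    fr <- series[[t]]
    e <- fr$junction_graph$edges
    ta <- .to_track_ids(fr$frame_index, e$cell_a, track)
    tb <- .to_track_ids(fr$frame_index, e$cell_b, track)
    edges[[t]] <- data.frame(a = pmin(ta, tb), b = pmax(ta, tb),
                             length = e$length, ux = e$ux, uy = e$uy)
    cid <- .to_track_ids(fr$frame_index, fr$cells$cell_id, track)
    areas[[t]] <- stats::setNames(fr$cells$area, cid)
  }
  events <- list()
  seen_quads <- character(0)
  for (t in seq_len(nfr)) {
    et <- edges[[t]]
    cand <- which(et$length < L_min)
    for (i in cand) {
      a <- et$a[i]; b <- et$b[i]
      nb_a <- unique(c(et$b[et$a == a], et$a[et$b == a]))
      nb_b <- unique(c(et$b[et$a == b], et$a[et$b == b]))
      common <- setdiff(intersect(nb_a, nb_b), c(a, b))
      if (length(common) != 2L) next
      cd <- sort(common)
      quad <- paste(sort(c(a, b, cd)), collapse = "-")
      if (quad %in% seen_quads) next
      key_cd <- .edge_key(cd[1], cd[2])
      for (t2 in (t + 1L):min(nfr, t + persistence)) {
        if (t2 > nfr) break
        e2 <- edges[[t2]]
        j <- which(.edge_key(e2$a, e2$b) == key_cd)
        if (length(j) > 0L) {
          pa <- areas[[t]][as.character(c(a, b, cd))]
          events[[length(events) + 1L]] <- structure(list(
            frame_start = t, frame_end = t2,
            losing = c(a, b), gaining = cd,
            new_direction = c(e2$ux[j[1]], e2$uy[j[1]]),
            pre_areas = unname(pa)), class = "t1_event")
          seen_quads <- c(seen_quads, quad)
          break
        }
      }
    }
  }
  events
}

#' Detect rosettes in a frame
#'
#' A rosette is a junction vertex where at least `m_min` cells meet
#' (4-fold vertices are transient T1 midpoints and excluded by default).
#'
#' @param frame a [tissue_frame()] with a junction graph.
#' @param m_min minimum vertex multiplicity (>= 4).
#' @return list of `rosette_event` objects with `frame_index`, `vertex`
#'   (x, y) and `cells`.
#' @export
detect_rosettes <- function(frame, m_min = 5L) {
  stopifnot(inherits(frame, "tissue_frame"))
  if (m_min < 4L) stop("m_min must be >= 4", call. = FALSE)
  jg <- frame$junction_graph
  if (is.null(jg)) stop("frame has no junction graph", call. = FALSE)
  hits <- which(vapply(jg$vertex_cells, length, integer(1)) >= m_min)
  lapply(hits, function(i) {
    structure(list(frame_index = frame$frame_index,
                   vertex = c(jg$vertices$x[i], jg$vertices$y[i]),
                   cells = jg$vertex_cells[[i]]), class = "rosette_event")
  })
}

#' Angle between a new junction and the protrusion direction
#'
#' Acute angle (degrees) between the T1 event's new-junction direction and
#' the local tissue protrusion direction.
#'
#' @param event a `t1_event` from [detect_t1()].
#' @param protrusion_direction length-2 vector (need not be unit).
#' @return angle in `[0, 90]` degrees.
#' @export
junction_angle_to_protrusion <- function(event, protrusion_direction) {
  u <- event$new_direction
  p <- protrusion_direction
  nu <- sqrt(sum(u^2)); np <- sqrt(sum(p^2))
  if (nu == 0 || np == 0) stop("zero direction vector", call. = FALSE)
  acos(min(1, abs(sum(u * p)) / (nu * np))) * 180 / pi
}

#' Directional tissue elongation rate from tracked cells
#'
#' Fits the affine map between tracked centroid configurations `window`
#' frames apart, removes the rigid rotation by polar decomposition of the
#' deformation gradient (F = R U), and takes the stretch-rate tensor
#' `log(U) / elapsed`; the result is `d . log(U) . d / elapsed`, the
#' elongation rate along `d` (1/h). Exact for affine motions, exactly
#' zero for rigid ones, and insensitive to superposed rotations.
#'
#' @param series list of [tissue_frame()]s (used for frame indexing only).
#' @param track a [track_table()] with positions in µm.
#' @param direction length-2 direction (normalised internally).
#' @param window frame separation over which to measure.
#' @param dt frame interval (h).
#' @return elongation rate (1/h).
#' @export
elongation_rate <- function(series, track, direction, window = 1L, dt = 1) {
  stopifnot(inherits(track, "track_table"), length(direction) == 2L)
  frames <- sort(unique(track$frame))
  if (length(frames) < window + 1L) {
    stop("need at least window + 1 tracked frames", call. = FALSE)
  }
  f0 <- frames[1]; f1 <- frames[1 + window]
  a <- track[track$frame == f0, ]; b <- track[track$frame == f1, ]
  common <- intersect(a$track_id, b$track_id)
  if (length(common) < 4L) stop("need >= 4 tracked cells", call. = FALSE)
  ia <- match(common, a$track_id); ib <- match(common, b$track_id)
  X0 <- cbind(a$x[ia], a$y[ia]); X1 <- cbind(b$x[ib], b$y[ib])
  M <- cbind(1, X0)
  if (qr(M)$rank < 3L) {
    stop("degenerate (collinear) centroid configuration", call. = FALSE)
  }
  beta <- qr.solve(M, X1)                 # rows: intercept, x, y
  Fm <- t(beta[2:3, , drop = FALSE])      # deformation gradient
  elapsed <- (f1 - f0) * dt
  sv <- svd(Fm)                           # F = W S V' -> U = V S V'
  logU <- sv$v %*% diag(log(sv$d)) %*% t(sv$v)
  d <- direction / sqrt(sum(direction^2))
  as.numeric(t(d) %*% logU %*% d) / elapsed
}

#' Estimate the local tissue-protrusion direction
#'
#' When no protrusion direction is measured, the outward radial direction
#' at a point -- the direction in which the local colony boundary
#' advances as the sheet spreads -- is the natural estimate.
#'
#' @param frame a [tissue_frame()].
#' @param point length-2 position (µm), e.g. a T1 event's quad centre.
#' @return unit vector pointing outward from the colony centroid.
#' @export
protrusion_direction <- function(frame, point) {
  stopifnot(inherits(frame, "tissue_frame"), length(point) == 2L)
  v <- as.numeric(point) - frame$colony_centroid
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("point coincides with the colony centroid",
                    call. = FALSE)
  v / nv
}

#' Areas of rearrangement participants before the event
#'
#' Retrieves the areas of each event's participating cells in the last
#' pre-event frame and summarises the fraction below a size cutoff
#' (intercalation concentrates in small cells).
#'
#' @param events list of `t1_event` and/or `rosette_event` objects.
#' @param series list of [tissue_frame()]s.
#' @param track optional [track_table()] (same usage as [detect_t1()]).
#' @param cutoff area cutoff (µm², default 300).
#' @return list with `areas` (per-event list), `all_areas`,
#'   `fraction_below_cutoff` and `cutoff`.
#' @export
pre_event_areas <- function(events, series, track = NULL, cutoff = 300) {
  if (length(events) == 0L) {
    return(list(areas = list(), all_areas = numeric(0),
                fraction_below_cutoff = NA_real_, cutoff = cutoff))
  }
  area_of <- function(t, ids) {
    fr <- series[[t]]
    cid <- .to_track_ids(fr$frame_index, fr$cells$cell_id, track)
    m <- match(ids, cid)
    if (any(is.na(m))) {
      stop("event references a cell absent from frame ", t, call. = FALSE)
    }
    fr$cells$area[m]
  }
  per_event <- lapply(events, function(e) {
    if (inherits(e, "t1_event")) {
      area_of(e$frame_start, c(e$losing, e$gaining))
    } else {
      t <- which(vapply(series, function(f) f$frame_index,
                        numeric(1)) == e$frame_index)[1]
      area_of(t, e$cells)
    }
  })
  all_areas <- unlist(per_event)
  list(areas = per_event, all_areas = all_areas,
       fraction_below_cutoff = mean(all_areas < cutoff), cutoff = cutoff)
}
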