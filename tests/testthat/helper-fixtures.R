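# Shared geometric fixtures, built in code.

# regular hexagon polygon (circumradius s), pointy-top orientation
hex_poly <- function(cx, cy, s) {
  a <- pi / 6 + (0:5) * pi / 3
  cbind(cx + s * cos(a), cy + s * sin(a))
}

# 7-cell honeycomb patch (central cell id 1) as a tissue_frame with
# polygons attached
honeycomb_frame <- function(s = 5) {
  centers <- rbind(c(0, 0),
                   t(sapply(0:5, function(k) {
                     sqrt(3) * s * c(cos(k * pi / 3), sin(k * pi / 3))
                   })))
  polys <- lapply(seq_len(7), function(i) {
    hex_poly(centers[i, 1], centers[i, 2], s)
  })
  names(polys) <- as.character(1:7)
  cells <- data.frame(frame = 0L, cell_id = 1:7,
                      x = centers[, 1], y = centers[, 2],
                      area = vapply(polys, polygon_area, numeric(1)),
                      perimeter = vapply(polys, polygon_perimeter,
                                         numeric(1)))
  fr <- tissue_frame(0L, cells, polygons = polys)
  fr$junction_graph <- build_junction_graph(fr, check_overlap = FALSE)
  fr
}

# reverse a T1 series in time, renumbering frame indices and rebuilding
# the identity track
reverse_series <- function(fix) {
  series <- rev(fix$series)
  for (i in seq_along(series)) series[[i]]$frame_index <- i - 1L
  rows <- do.call(rbind, lapply(seq_along(series), function(t) {
    data.frame(track_id = series[[t]]$cells$cell_id, frame = t - 1L,
               cell_id = series[[t]]$cells$cell_id,
               x = series[[t]]$cells$x, y = series[[t]]$cells$y)
  }))
  list(series = series, track = track_table(rows))
}

# simple affine-motion track table: positions p(t) = F(t) p0 + b(t)
affine_track <- function(p0, n_frames, transform) {
  n <- nrow(p0)
  rows <- lapply(seq_len(n_frames), function(t) {
    q <- transform(p0, t - 1L)
    data.frame(track_id = seq_len(n), frame = t - 1L, cell_id = seq_len(n),
               x = q[, 1], y = q[, 2])
  })
  track_table(do.call(rbind, rows))
}
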