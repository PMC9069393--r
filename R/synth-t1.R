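# Scripted junction-topology sequences: T1 quad swaps and rosettes with
# exact ground truth for detector validation.

# Four-cell T1 patch in a 6x6 box centred at (ox, oy). `half` is the
# half-length of the inner junction; positive state "v" = vertical inner
# edge between the left/right pair, "h" = horizontal edge between the
# top/bottom pair. Cell ids: base + (1 top, 2 bottom, 3 left, 4 right).
.t1_patch <- function(ox, oy, half, state, base) {
  s <- function(p) cbind(p[, 1] + ox, p[, 2] + oy)
  if (state == "v") {
    d <- half
    top    <- rbind(c(-3, 3), c(3, 3), c(2, 1), c(0, d), c(-2, 1))
    bottom <- rbind(c(-3, -3), c(3, -3), c(2, -1), c(0, -d), c(-2, -1))
    left   <- rbind(c(-3, 3), c(-2, 1), c(0, d), c(0, -d), c(-2, -1),
                    c(-3, -3))
    right  <- rbind(c(3, 3), c(2, 1), c(0, d), c(0, -d), c(2, -1),
                    c(3, -3))
  } else {
    d <- half
    top    <- rbind(c(-3, 3), c(3, 3), c(2, 1), c(d, 0), c(-d, 0),
                    c(-2, 1))
    bottom <- rbind(c(-3, -3), c(3, -3), c(2, -1), c(d, 0), c(-d, 0),
                    c(-2, -1))
    left   <- rbind(c(-3, 3), c(-2, 1), c(-d, 0), c(-2, -1), c(-3, -3))
    right  <- rbind(c(3, 3), c(2, 1), c(d, 0), c(2, -1), c(3, -3))
  }
  polys <- list(s(top), s(bottom), s(left), s(right))
  names(polys) <- as.character(base + 1:4)
  polys
}

# rosette patch: m pie slices of radius 3 about (ox, oy); the centre
# vertex is m-fold. Cell ids base + 1..m.
.rosette_patch <- function(ox, oy, m, base) {
  ang <- seq(0, 2 * pi, length.out = m + 1L)
  polys <- lapply(seq_len(m), function(i) {
    rbind(c(ox, oy),
          c(ox + 3 * cos(ang[i]), oy + 3 * sin(ang[i])),
          c(ox + 3 * cos(ang[i + 1L]), oy + 3 * sin(ang[i + 1L])))
  })
  names(polys) <- as.character(base + seq_len(m))
  polys
}

#' Generate a scripted T1/rosette frame sequence
#'
#' Builds a six-frame polygon sequence containing exactly `n_t1`
#' quad-swap events (an inner junction shrinks 2.4 -> 1.6 -> 0.8 µm, then
#' the orthogonal junction grows 0.8 -> 1.6 -> 2.4 µm) and `n_rosette`
#' static five-fold (configurable) vertices, all in disjoint patches.
#' With `n_t1 = 0` the T1 patches are frozen (static lattice). Junction
#' graphs are attached to every frame; cell ids persist across frames.
#'
#' @param n_t1 number of T1 events (>= 0).
#' @param n_rosette number of rosette vertices (>= 0).
#' @param seed integer seed (stamps the truth record; the sequence itself
#'   is deterministic geometry).
#' @param rosette_m rosette multiplicity (>= 5).
#' @param n_static number of static patches when `n_t1 = 0` (so the
#'   sequence is never empty).
#' @return list with `series` (six [tissue_frame()]s with junction
#'   graphs), `track` (identity [track_table()]) and `truth` (event
#'   frames, losing/gaining pairs, rosette participants).
#' @export
make_t1_sequence <- function(n_t1, n_rosette = 0L, seed = 1L,
                             rosette_m = 5L, n_static = 1L) {
  if (n_t1 < 0L || n_rosette < 0L) stop("counts must be >= 0", call. = FALSE)
  if (rosette_m < 5L) stop("rosette_m must be >= 5", call. = FALSE)
  n_frames <- 6L
  halves <- c(1.2, 0.8, 0.4, 0.4, 0.8, 1.2)
  states <- c("v", "v", "v", "h", "h", "h")
  n_patch <- max(n_t1, n_static)
  series <- vector("list", n_frames)
  t1_truth <- list()
  ros_truth <- list()
  for (t in seq_len(n_frames)) {
    polys <- list()
    for (p in seq_len(n_patch)) {
      frozen <- p > n_t1            # static patch: never swaps
      st <- if (frozen) "v" else states[t]
      hf <- if (frozen) 1.2 else halves[t]
      polys <- c(polys, .t1_patch((p - 1) * 20, 0, hf, st, (p - 1L) * 10L))
    }
    for (q in seq_len(n_rosette)) {
      polys <- c(polys, .rosette_patch((q - 1) * 20, 20, rosette_m,
                                       1000L + (q - 1L) * 100L))
    }
    ids <- as.numeric(names(polys))
    cells <- data.frame(
      frame = t - 1L, cell_id = ids,
      x = vapply(polys, function(p) mean(p[, 1]), numeric(1)),
      y = vapply(polys, function(p) mean(p[, 2]), numeric(1)),
      area = vapply(polys, polygon_area, numeric(1)),
      perimeter = vapply(polys, polygon_perimeter, numeric(1)))
    fr <- tissue_frame(t - 1L, cells, polygons = polys)
    fr$junction_graph <- build_junction_graph(fr, check_overlap = FALSE)
    series[[t]] <- fr
  }
  for (p in seq_len(n_t1)) {
    base <- (p - 1L) * 10L
    t1_truth[[p]] <- list(frame_start = 3L, frame_end = 4L,
                          losing = base + c(3, 4),    # left-right pair
                          gaining = base + c(1, 2))   # top-bottom pair
  }
  for (q in seq_len(n_rosette)) {
    ros_truth[[q]] <- list(vertex = c((q - 1) * 20, 20),
                           cells = 1000L + (q - 1L) * 100L +
                             seq_len(rosette_m))
  }
  ids <- series[[1]]$cells$cell_id
  rows <- lapply(seq_len(n_frames), function(t) {
    data.frame(track_id = ids, frame = t - 1L, cell_id = ids,
               x = series[[t]]$cells$x, y = series[[t]]$cells$y)
  })
  truth <- structure(list(generator = "make_t1_sequence", seed = seed,
                          n_t1 = n_t1, n_rosette = n_rosette,
                          rosette_m = rosette_m, t1_events = t1_truth,
                          rosettes = ros_truth), class = "ground_truth")
  list(series = series, track = track_table(do.call(rbind, rows)),
       truth = truth)
}
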