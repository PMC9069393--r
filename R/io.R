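# CSV dialect: comma-separated, header required, UTF-8, '.' decimal.

#' Read a per-cell segmentation table
#'
#' Expects columns `frame,cell_id,x,y,area,perimeter` with optional
#' `thickness,width`. Lengths are multiplied by `pixel_size`, areas by
#' `pixel_size^2`; pass `pixel_size = 1` when the table is already in
#' micrometres.
#'
#' @param path CSV file path.
#' @param pixel_size µm per pixel used to convert pixel-unit tables.
#' @return list of [tissue_frame()] objects, one per distinct frame index,
#'   sorted by frame.
#' @export
read_cells_csv <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "cell_id", "x", "y", "area", "perimeter")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("cells CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$area) | df$area <= 0)
  if (length(bad) > 0L) {
    stop("non-positive area in cells CSV at data row ", bad[1L], call. = FALSE)
  }
  ps <- pixel_size
  df$x <- df$x * ps; df$y <- df$y * ps
  df$area <- df$area * ps^2; df$perimeter <- df$perimeter * ps
  if ("thickness" %in% names(df)) df$thickness <- df$thickness * ps
  if ("width" %in% names(df)) df$width <- df$width * ps
  frames <- sort(unique(df$frame))
  lapply(frames, function(fr) {
    tissue_frame(fr, df[df$frame == fr, , drop = FALSE])
  })
}

#' Write tissue frames back to a cells CSV
#'
#' Inverse of [read_cells_csv()] (with `pixel_size = 1`): round-tripping is
#' lossless on all tabulated fields.
#'
#' @param frames list of `tissue_frame` objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(frames, path) {
  if (inherits(frames, "tissue_frame")) frames <- list(frames)
  tabs <- lapply(frames, function(f) f$cells)
  cols <- Reduce(union, lapply(tabs, names))
  tabs <- lapply(tabs, function(t) {
    for (cl in setdiff(cols, names(t))) t[[cl]] <- NA_real_
    t[, cols, drop = FALSE]
  })
  out <- do.call(rbind, tabs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track table from CSV
#'
#' Columns `track_id,frame,cell_id,x,y`; coordinates multiplied by
#' `pixel_size`.
#' @inheritParams read_cells_csv
#' @return a [track_table()].
#' @export
read_tracks_csv <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$x <- df$x * pixel_size; df$y <- df$y * pixel_size
  track_table(df)
}

#' Write a track table to CSV
#' @param track a [track_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Convert a label image to a tissue frame
#'
#' Automated analogue of manual boundary labelling: per label, area is the
#' pixel count times `pixel_size^2`, the perimeter is the boundary
#' pixel-edge count times `pixel_size` (outer edge-count convention, exact
#' on rectilinear shapes), and the centroid is the mean pixel centre
#' (0-based indexing). A junction graph is built from label adjacency:
#' edge lengths count shared 4-neighbour pixel edges; diagonal-only
#' contacts yield zero-length edges.
#'
#' @param label_image integer matrix; 0 is background.
#' @param pixel_size µm per pixel.
#' @param frame_index frame index to stamp on the result.
#' @return a [tissue_frame()]; an all-zero image gives a frame with an
#'   empty cell table.
#' @export
label_image_to_cells <- function(label_image, pixel_size = 1,
                                 frame_index = 0L) {
  if (!is.matrix(label_image)) stop("label_image must be a matrix",
                                    call. = FALSE)
  if (any(label_image != round(label_image)) || any(label_image < 0)) {
    stop("label_image must contain non-negative integers", call. = FALSE)
  }
  lab <- matrix(as.integer(label_image), nrow(label_image))
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids) == 0L) {
    empty <- data.frame(frame = integer(), cell_id = integer(),
                        x = numeric(), y = numeric(), area = numeric(),
                        perimeter = numeric())
    return(structure(list(frame_index = as.integer(frame_index),
                          cells = empty, polygons = NULL,
                          junction_graph = NULL,
                          colony_centroid = c(0, 0), colony_radius = 0),
                     class = "tissue_frame"))
  }
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  lv <- lab[idx]
  row0 <- (idx - 1L) %% nr          # 0-based row (y)
  col0 <- (idx - 1L) %/% nr         # 0-based col (x)
  area_px <- tabulate(match(lv, ids), nbins = length(ids))
  cx <- tapply(col0, factor(lv, levels = ids), mean)
  cy <- tapply(row0, factor(lv, levels = ids), mean)

  # pad with background, count pixel edges whose two sides differ
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  shifts <- list(up    = pad[1:nr, 2:(nc + 1L)],
                 down  = pad[3:(nr + 2L), 2:(nc + 1L)],
                 left  = pad[2:(nr + 1L), 1:nc],
                 right = pad[2:(nr + 1L), 3:(nc + 2L)])
  per_px <- numeric(length(ids))
  adj_len <- new.env(parent = emptyenv())   # 4-neighbour shared edge counts
  for (s in shifts) {
    diffm <- ctr > 0L & s != ctr
    per_px <- per_px + tabulate(match(ctr[diffm], ids), length(ids))
    both <- diffm & s > 0L
    if (any(both)) {
      a <- pmin(ctr[both], s[both]); b <- pmax(ctr[both], s[both])
      keys <- paste(a, b, sep = "-")
      tb <- table(keys)
      for (k in names(tb)) {
        adj_len[[k]] <- (if (is.null(adj_len[[k]])) 0 else adj_len[[k]]) +
          as.numeric(tb[[k]])
      }
    }
  }
  # diagonal adjacency (8-neighbour) adds zero-length edges
  diags <- list(pad[1:nr, 1:nc], pad[1:nr, 3:(nc + 2L)],
                pad[3:(nr + 2L), 1:nc], pad[3:(nr + 2L), 3:(nc + 2L)])
  for (s in diags) {
    both <- ctr > 0L & s > 0L & s != ctr
    if (any(both)) {
      a <- pmin(ctr[both], s[both]); b <- pmax(ctr[both], s[both])
      for (k in unique(paste(a, b, sep = "-"))) {
        if (is.null(adj_len[[k]])) adj_len[[k]] <- 0
      }
    }
  }
  keys <- ls(adj_len)
  edges <- if (length(keys) > 0L) {
    ab <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
    lens <- vapply(keys, function(k) adj_len[[k]] / 2, numeric(1))
    data.frame(cell_a = as.integer(ab[, 1]), cell_b = as.integer(ab[, 2]),
               length = lens * pixel_size, ux = NA_real_, uy = NA_real_,
               row.names = NULL)
  } else {
    data.frame(cell_a = integer(), cell_b = integer(), length = numeric(),
               ux = numeric(), uy = numeric())
  }
  # vertices: 2x2 pixel corners where >= 3 distinct labels meet
  vx <- numeric(0); vy <- numeric(0); vcells <- list()
  if (nr >= 2L && nc >= 2L) {
    q1 <- pad[1:(nr + 1L), 1:(nc + 1L)]
    q2 <- pad[1:(nr + 1L), 2:(nc + 2L)]
    q3 <- pad[2:(nr + 2L), 1:(nc + 1L)]
    q4 <- pad[2:(nr + 2L), 2:(nc + 2L)]
    nz <- (q1 > 0L) + (q2 > 0L) + (q3 > 0L) + (q4 > 0L)
    cand <- which(nz >= 3L)
    for (k in cand) {
      labs4 <- unique(c(q1[k], q2[k], q3[k], q4[k]))
      labs4 <- labs4[labs4 > 0L]
      if (length(labs4) >= 3L) {
        r0 <- (k - 1L) %% (nr + 1L); c0 <- (k - 1L) %/% (nr + 1L)
        vx <- c(vx, (c0 - 0.5) * pixel_size)
        vy <- c(vy, (r0 - 0.5) * pixel_size)
        vcells <- c(vcells, list(sort(labs4)))
      }
    }
  }
  jg <- structure(list(
    vertices = data.frame(x = vx, y = vy),
    vertex_cells = vcells,
    edges = edges), class = "junction_graph")
  cells <- data.frame(frame = as.integer(frame_index), cell_id = ids,
                      x = as.numeric(cx) * pixel_size,
                      y = as.numeric(cy) * pixel_size,
                      area = area_px * pixel_size^2,
                      perimeter = per_px * pixel_size)
  tissue_frame(frame_index, cells, junction_graph = jg)
}

#' Read a (possibly multi-page) integer label TIFF
#'
#' @param path TIFF file.
#' @param pixel_size µm per pixel.
#' @return list of [tissue_frame()]s, one per page.
#' @export
read_label_tiff <- function(path, pixel_size = 1) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF label images",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    label_image_to_cells(round(pages[[i]]), pixel_size, frame_index = i - 1L)
  })
}
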