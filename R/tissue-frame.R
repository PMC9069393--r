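#' @keywords internal
"_PACKAGE"

# Coordinate conventions used throughout the package:
# Cartesian micrometres, origin at the image top-left, x to the right and
# y downward, 0-based pixel indexing; all angles in degrees.

ISOPERIMETRIC_FLOOR <- 2 * sqrt(pi)   # smallest possible perimeter/sqrt(area)

#' Validate a table of per-cell records
#'
#' Checks the invariants every downstream analysis assumes: positive areas
#' and perimeters, the isoperimetric bound `perimeter >= 2*sqrt(pi*area)`
#' (within relative tolerance), unique cell ids within a frame, and --
#' when polygons are attached -- agreement between the polygon's shoelace
#' area and the tabulated area.
#'
#' @param cells data.frame with columns `frame`, `cell_id`, `x`, `y`,
#'   `area`, `perimeter` and optionally `thickness`, `width` (micrometres).
#' @param polygons optional named list of n-by-2 vertex matrices keyed by
#'   `cell_id`.
#' @param iso_tol relative tolerance on the isoperimetric bound.
#' @return the validated `cells` data.frame, invisibly unchanged.
#' @export
validate_cells <- function(cells, polygons = NULL, iso_tol = 1e-9) {
  required <- c("frame", "cell_id", "x", "y", "area", "perimeter")
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0L) {
    stop("cells table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_area <- which(!is.finite(cells$area) | cells$area <= 0)
  if (length(bad_area) > 0L) {
    stop("non-positive or non-finite area at row ", bad_area[1L], call. = FALSE)
  }
  bad_per <- which(!is.finite(cells$perimeter) | cells$perimeter <= 0)
  if (length(bad_per) > 0L) {
    stop("non-positive or non-finite perimeter at row ", bad_per[1L],
         call. = FALSE)
  }
  floor_p <- 2 * sqrt(pi * cells$area)
  viol <- which(cells$perimeter < floor_p * (1 - iso_tol))
  if (length(viol) > 0L) {
    stop("perimeter below the isoperimetric bound at row ", viol[1L],
         " (perimeter ", signif(cells$perimeter[viol[1L]], 6),
         " < ", signif(floor_p[viol[1L]], 6), ")", call. = FALSE)
  }
  dup <- duplicated(cells[, c("frame", "cell_id")])
  if (any(dup)) {
    stop("duplicate cell_id within a frame at row ", which(dup)[1L],
         call. = FALSE)
  }
  if (!is.null(polygons)) {
    for (id in names(polygons)) {
      i <- match(as.numeric(id), cells$cell_id)
      if (is.na(i)) next
      a_poly <- polygon_area(polygons[[id]])
      if (abs(a_poly - cells$area[i]) > 0.01 * cells$area[i]) {
        stop("polygon area of cell ", id, " (", signif(a_poly, 6),
             ") disagrees with tabulated area (", signif(cells$area[i], 6),
             ") by more than 1%", call. = FALSE)
      }
    }
  }
  invisible(cells)
}

#' Construct a single-time-point tissue frame
#'
#' A `tissue_frame` bundles one frame's cell records with the colony
#' geometry (centroid and outer radius) and, optionally, per-cell polygons
#' and a junction graph. It is the universal substrate of the
#' quantification pipeline.
#'
#' The colony centroid defaults to the area-weighted centroid of all cells
#' (robust to edge protrusions); the outer radius defaults to the largest
#' centroid distance plus one mean cell radius, standing in for the outer
#' boundary the segmentation does not carry explicitly.
#'
#' @param frame_index integer frame index (>= 0).
#' @param cells per-cell table, see [validate_cells()].
#' @param polygons optional named list of n-by-2 vertex matrices (µm).
#' @param junction_graph optional [build_junction_graph()] result.
#' @param colony_centroid length-2 numeric (µm) or NULL to estimate.
#' @param colony_radius outer colony radius R (µm) or NULL to estimate.
#' @return object of class `tissue_frame`.
#' @export
tissue_frame <- function(frame_index, cells, polygons = NULL,
                         junction_graph = NULL, colony_centroid = NULL,
                         colony_radius = NULL) {
  validate_cells(cells, polygons)
  if (is.null(colony_centroid)) {
    w <- cells$area / sum(cells$area)
    colony_centroid <- c(sum(cells$x * w), sum(cells$y * w))
  }
  d <- sqrt((cells$x - colony_centroid[1])^2 +
            (cells$y - colony_centroid[2])^2)
  mean_cell_radius <- mean(sqrt(cells$area / pi))
  if (is.null(colony_radius)) {
    colony_radius <- max(d) + mean_cell_radius
  }
  if (colony_radius < 0) stop("colony_radius must be >= 0", call. = FALSE)
  if (any(d > colony_radius + 2 * mean_cell_radius)) {
    stop("cell centroid lies outside colony_radius + one mean cell diameter",
         call. = FALSE)
  }
  structure(
    list(frame_index = as.integer(frame_index),
         cells = cells,
         polygons = polygons,
         junction_graph = junction_graph,
         colony_centroid = as.numeric(colony_centroid),
         colony_radius = as.numeric(colony_radius)),
    class = "tissue_frame")
}

#' @export
print.tissue_frame <- function(x, ...) {
  cat("<tissue_frame> frame", x$frame_index, "|", nrow(x$cells), "cells | R =",
      signif(x$colony_radius, 4), "um | centroid (",
      signif(x$colony_centroid[1], 4), ",", signif(x$colony_centroid[2], 4),
      ")\n")
  invisible(x)
}

#' Radial coordinate of every cell in a frame
#'
#' @param frame a `tissue_frame`.
#' @return numeric vector of distances (µm) from the colony centroid.
#' @export
cell_radii <- function(frame) {
  stopifnot(inherits(frame, "tissue_frame"))
  sqrt((frame$cells$x - frame$colony_centroid[1])^2 +
       (frame$cells$y - frame$colony_centroid[2])^2)
}

#' Construct a validated track table
#'
#' Long-format cell tracks: one row per (track, frame) observation.
#' Within a track the frame index must be strictly increasing and a
#' (frame, cell_id) pair may belong to at most one track.
#'
#' @param df data.frame with columns `track_id`, `frame`, `cell_id`, `x`, `y`.
#' @return object of class `track_table` (a data.frame).
#' @export
track_table <- function(df) {
  required <- c("track_id", "frame", "cell_id", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("track table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  by_track <- split(df$frame, df$track_id)
  if (any(vapply(by_track, function(f) any(diff(f) <= 0), logical(1)))) {
    stop("frame index must be strictly increasing within a track",
         call. = FALSE)
  }
  if (anyDuplicated(df[, c("frame", "cell_id")])) {
    stop("a (frame, cell_id) pair appears in more than one track",
         call. = FALSE)
  }
  class(df) <- c("track_table", "data.frame")
  df
}

#' Shoelace area of a polygon
#'
#' @param poly n-by-2 matrix of vertices (closed implicitly).
#' @return absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Perimeter of a polygon
#' @param poly n-by-2 matrix of vertices.
#' @return total edge length.
#' @export
polygon_perimeter <- function(poly) {
  d <- diff(rbind(poly, poly[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Default analysis configuration
#'
#' One place for the thresholds and conventions the pipeline uses, so a
#' fixed (config, seed, input) triple always reproduces identical outputs.
#'
#' @param seed integer RNG seed.
#' @param pixel_size µm per pixel.
#' @param strain_convention only `"linear"` is implemented:
#'   strain = 1 - sqrt(A/A0).
#' @param piv_window,piv_overlap PIV interrogation window (px) and overlap
#'   fraction.
#' @param angle_bins division-angle class boundaries (degrees).
#' @param t1_lmin junction-length threshold for T1 candidate edges (µm).
#' @param rosette_min minimum vertex multiplicity for a rosette.
#' @param junction_tol vertex-merging tolerance (µm).
#' @param p0_threshold shape-index jamming threshold.
#' @return named list of class `mm_config`.
#' @export
mm_config <- function(seed = 1L, pixel_size = 1, strain_convention = "linear",
                      piv_window = 32L, piv_overlap = 0.5,
                      angle_bins = c(30, 60), t1_lmin = 1.0,
                      rosette_min = 5L, junction_tol = 0.25,
                      p0_threshold = 3.81) {
  strain_convention <- match.arg(strain_convention, "linear")
  stopifnot(pixel_size > 0, piv_window > 0, piv_overlap >= 0, piv_overlap < 1,
            all(angle_bins > 0), t1_lmin > 0, rosette_min >= 4,
            junction_tol > 0, p0_threshold > 0)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 strain_convention = strain_convention,
                 piv_window = as.integer(piv_window),
                 piv_overlap = piv_overlap, angle_bins = angle_bins,
                 t1_lmin = t1_lmin, rosette_min = as.integer(rosette_min),
                 junction_tol = junction_tol, p0_threshold = p0_threshold),
            class = "mm_config")
}
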