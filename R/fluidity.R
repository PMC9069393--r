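# Tissue-fluidity metrics: cell shape index and the vertex-model jamming
# threshold, and drift-subtracted rms velocity from PIV fields.

#' Cell shape index
#'
#' `p0 = perimeter / sqrt(area)`, dimensionless and invariant under rigid
#' motion and uniform scaling. The isoperimetric floor is 2*sqrt(pi)
#' (a disc, ~3.5449); values below it beyond tolerance indicate a
#' segmentation problem and raise a warning, but the value is still
#' returned.
#'
#' @param perimeter cell perimeter (µm), vectorised.
#' @param area cell area (µm²).
#' @param iso_tol relative tolerance on the isoperimetric floor.
#' @return shape index values.
#' @export
shape_index <- function(perimeter, area, iso_tol = 1e-9) {
  stopifnot(all(perimeter > 0), all(area > 0))
  p0 <- perimeter / sqrt(area)
  floor0 <- 2 * sqrt(pi)
  if (any(p0 < floor0 * (1 - iso_tol))) {
    warning("shape index below the isoperimetric floor 2*sqrt(pi); ",
            "check the segmentation", call. = FALSE)
  }
  p0
}

#' Jamming classification from the median shape index
#'
#' Vertex-model rigidity transition: a tissue whose median shape index
#' reaches p0* ~ 3.81 is unjammed (fluid-like); below it, jammed
#' (solid-like). The boundary value itself classifies as fluid-like.
#'
#' @param p0_med median shape index of the tissue.
#' @param threshold transition threshold (default 3.81).
#' @return `"fluid_like"` or `"solid_like"`.
#' @export
classify_jamming <- function(p0_med, threshold = 3.81) {
  stopifnot(is.finite(p0_med), p0_med >= 2 * sqrt(pi) * (1 - 1e-9))
  if (p0_med >= threshold) "fluid_like" else "solid_like"
}

#' Shape-index report for a frame
#'
#' @param frame a [tissue_frame()].
#' @param threshold jamming threshold passed to [classify_jamming()].
#' @return list of class `shape_index_report` with per-cell `p0`, the
#'   tissue median `p0_med`, the `classification` and the `threshold`.
#' @export
shape_index_report <- function(frame, threshold = 3.81) {
  stopifnot(inherits(frame, "tissue_frame"))
  p0 <- shape_index(frame$cells$perimeter, frame$cells$area)
  p0_med <- stats::median(p0)
  structure(list(p0 = p0, p0_med = p0_med,
                 classification = classify_jamming(p0_med, threshold),
                 threshold = threshold),
            class = "shape_index_report")
}

#' @export
print.shape_index_report <- function(x, ...) {
  cat("<shape_index_report> median p0 =", signif(x$p0_med, 5), "->",
      x$classification, "(threshold", x$threshold, ")\n")
  invisible(x)
}

#' Centre-versus-periphery shape-index contrast
#'
#' Median shape index of cells inside `r < center_fraction * R` versus
#' the remaining (peripheral) cells. In a compressed solid-like colony the
#' central cells are rounder, so the centre value is lower.
#'
#' @param frame a [tissue_frame()].
#' @param center_fraction radius fraction delimiting the central region.
#' @return named numeric `c(p0_center, p0_periphery)`.
#' @export
shape_index_region_contrast <- function(frame, center_fraction = 0.5) {
  stopifnot(inherits(frame, "tissue_frame"),
            center_fraction > 0, center_fraction <= 1)
  r <- cell_radii(frame)
  central <- r < center_fraction * frame$colony_radius
  if (!any(central) || all(central)) {
    stop("one of the regions is empty at center_fraction = ",
         center_fraction, call. = FALSE)
  }
  p0 <- shape_index(frame$cells$perimeter, frame$cells$area)
  c(p0_center = stats::median(p0[central]),
    p0_periphery = stats::median(p0[!central]))
}

#' Construct a velocity field
#'
#' @param x,y grid positions (µm).
#' @param u,v velocity components (µm/h), parallel to `x`/`y`.
#' @param valid logical validity flags (e.g. PIV peak-ratio test).
#' @param window,overlap,dt PIV metadata (px, fraction, h).
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(x, y, u, v, valid = rep(TRUE, length(x)),
                           window = NA_integer_, overlap = NA_real_,
                           dt = NA_real_) {
  stopifnot(length(x) == length(y), length(u) == length(x),
            length(v) == length(x), length(valid) == length(x))
  if (any(!is.finite(u[valid])) || any(!is.finite(v[valid]))) {
    stop("valid velocity vectors must be finite", call. = FALSE)
  }
  structure(list(x = x, y = y, u = u, v = v, valid = valid,
                 window = window, overlap = overlap, dt = dt),
            class = "velocity_field")
}

#' Drift-subtracted rms velocity
#'
#' For each field the mean vector (collective drift) is subtracted, then
#' `v_rms = sqrt(mean(|v|^2))`; the mean over fields is returned. A pure
#' drift field therefore yields zero.
#'
#' @param fields a `velocity_field` or list of them.
#' @param subtract_drift subtract each field's mean vector first
#'   (default TRUE, the standard procedure; FALSE is available when the
#'   net drift is known to be negligible).
#' @return rms velocity (µm/h).
#' @export
rms_velocity <- function(fields, subtract_drift = TRUE) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  if (length(fields) == 0L) stop("no velocity fields given", call. = FALSE)
  per_field <- vapply(fields, function(f) {
    u <- f$u[f$valid]; v <- f$v[f$valid]
    if (length(u) == 0L) stop("velocity field has no valid vectors",
                              call. = FALSE)
    if (subtract_drift) { u <- u - mean(u); v <- v - mean(v) }
    sqrt(mean(u^2 + v^2))
  }, numeric(1))
  mean(per_field)
}

#' Render track velocities into per-interval velocity fields
#'
#' Finite-difference velocities of tracked cells, one field per frame
#' interval, evaluated at the cells' positions.
#'
#' @param track a [track_table()].
#' @param dt frame interval (h).
#' @return list of [velocity_field()]s.
#' @export
tracks_to_velocity_fields <- function(track, dt) {
  stopifnot(inherits(track, "track_table"), dt > 0)
  frames <- sort(unique(track$frame))
  out <- list()
  for (i in seq_len(length(frames) - 1L)) {
    a <- track[track$frame == frames[i], ]
    b <- track[track$frame == frames[i + 1L], ]
    common <- intersect(a$track_id, b$track_id)
    if (length(common) == 0L) next
    ia <- match(common, a$track_id); ib <- match(common, b$track_id)
    out[[length(out) + 1L]] <- velocity_field(
      x = a$x[ia], y = a$y[ia],
      u = (b$x[ib] - a$x[ia]) / dt, v = (b$y[ib] - a$y[ia]) / dt,
      dt = dt)
  }
  out
}
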