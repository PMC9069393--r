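# Mitotic spindle orientation analysis: the angle between the spindle
# axis (pole-to-pole) and the substrate plane decides whether a division
# is symmetric (planar, daughter stays in the layer) or asymmetric
# (oblique/perpendicular, daughter seeds a new layer).

#' Construct a division event
#'
#' @param pole1,pole2 numeric length-3 spindle-pole (or daughter-nucleus
#'   centroid) coordinates (µm).
#' @param thickness,width cell thickness and width (µm), optional.
#' @param substrate_normal unit normal of the substrate plane (default +z;
#'   configurable for tilted cryosections).
#' @param frame_index frame of the event.
#' @return object of class `division_event`.
#' @export
division_event <- function(pole1, pole2, thickness = NA_real_,
                           width = NA_real_, substrate_normal = c(0, 0, 1),
                           frame_index = NA_integer_) {
  stopifnot(length(pole1) == 3L, length(pole2) == 3L,
            length(substrate_normal) == 3L)
  if (all(pole1 == pole2)) stop("spindle poles must differ", call. = FALSE)
  nn <- sqrt(sum(substrate_normal^2))
  if (abs(nn - 1) > 1e-9) stop("substrate_normal must be unit length",
                               call. = FALSE)
  structure(list(pole1 = as.numeric(pole1), pole2 = as.numeric(pole2),
                 thickness = thickness, width = width,
                 substrate_normal = as.numeric(substrate_normal),
                 frame_index = frame_index),
            class = "division_event")
}

#' Spindle-axis angle to the substrate plane
#'
#' `asin(|axis . normal| / |axis|)` in degrees: 0 for an in-plane spindle,
#' 90 for one perpendicular to the substrate. Invariant under swapping the
#' poles and under in-plane rotation.
#'
#' @param event a [division_event()].
#' @return angle in degrees, `[0, 90]`.
#' @export
spindle_angle <- function(event) {
  stopifnot(inherits(event, "division_event"))
  axis <- event$pole2 - event$pole1
  len <- sqrt(sum(axis^2))
  if (len == 0) stop("zero-length spindle axis", call. = FALSE)
  s <- abs(sum(axis * event$substrate_normal)) / len
  asin(min(1, s)) * 180 / pi
}

#' Classify a division by its spindle angle
#'
#' Symmetric (parallel) up to and including 30 degrees; asymmetric above,
#' subdivided into oblique (30-60] and perpendicular (60-90]. The 30- and
#' 60-degree boundaries belong to the lower class.
#'
#' @param angle spindle angle in degrees, `[0, 90]`; vectorised.
#' @param bins class boundaries (degrees), default `c(30, 60)`.
#' @return data.frame with `class` (symmetric/asymmetric) and `subclass`
#'   (parallel/oblique/perpendicular).
#' @export
classify_division <- function(angle, bins = c(30, 60)) {
  if (any(angle < 0 | angle > 90)) {
    stop("spindle angle must lie in [0, 90] degrees", call. = FALSE)
  }
  subclass <- ifelse(angle <= bins[1], "parallel",
                     ifelse(angle <= bins[2], "oblique", "perpendicular"))
  data.frame(class = ifelse(subclass == "parallel", "symmetric",
                            "asymmetric"),
             subclass = subclass)
}

#' Cell deformation ratio
#'
#' Thickness over width: tall compressed cells exceed 1, flat spread
#' cells stay below it.
#'
#' @param thickness,width positive lengths (µm), vectorised.
#' @return thickness / width.
#' @export
deformation_ratio <- function(thickness, width) {
  if (any(thickness <= 0) || any(width <= 0)) {
    stop("thickness and width must be positive", call. = FALSE)
  }
  thickness / width
}

#' Association between cell deformation and spindle angle
#'
#' Spearman rank correlation (mid-ranks for ties) between the deformation
#' ratio and the spindle angle across events.
#'
#' @param events list of [division_event()]s with thickness and width set.
#' @return list with `rho` and `n`.
#' @export
angle_deformation_association <- function(events) {
  if (length(events) < 5L) stop("need at least 5 events", call. = FALSE)
  defo <- vapply(events, function(e) {
    if (!is.finite(e$thickness) || !is.finite(e$width)) {
      stop("all events must carry thickness and width", call. = FALSE)
    }
    deformation_ratio(e$thickness, e$width)
  }, numeric(1))
  ang <- vapply(events, spindle_angle, numeric(1))
  if (stats::sd(defo) == 0 || stats::sd(ang) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  list(rho = stats::cor(defo, ang, method = "spearman"), n = length(events))
}

#' Construct a metaphase-plate oscillation trace
#'
#' @param time_min strictly increasing time points (minutes).
#' @param angle_deg metaphase-plate angle series (degrees).
#' @return object of class `oscillation_trace`.
#' @export
oscillation_trace <- function(time_min, angle_deg) {
  stopifnot(length(time_min) == length(angle_deg))
  if (any(diff(time_min) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(angle_deg))) stop("angles must be finite", call. = FALSE)
  structure(list(time_min = time_min, angle_deg = angle_deg),
            class = "oscillation_trace")
}

#' Extent of metaphase-plate oscillation
#'
#' Mean absolute angular speed: the total absolute angular path length
#' divided by the elapsed time (degrees/min). The raw path length is also
#' reported, since "extent" statistics in the literature vary (amplitude,
#' SD, path length); the choice here is recorded in the output.
#'
#' @param trace an [oscillation_trace()] with >= 3 samples.
#' @return list with `rate_deg_per_min`, `path_deg` and `definition`.
#' @export
oscillation_extent <- function(trace) {
  stopifnot(inherits(trace, "oscillation_trace"))
  if (length(trace$time_min) < 3L) stop("need at least 3 samples",
                                        call. = FALSE)
  path <- sum(abs(diff(trace$angle_deg)))
  elapsed <- trace$time_min[length(trace$time_min)] - trace$time_min[1]
  list(rate_deg_per_min = path / elapsed, path_deg = path,
       definition = "total absolute angular path length / elapsed time")
}

#' Read division events from CSV
#'
#' Columns `frame,x1,y1,z1,x2,y2,z2,thickness,width`.
#' @param path CSV path.
#' @return list of [division_event()]s.
#' @export
read_divisions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    division_event(c(df$x1[i], df$y1[i], df$z1[i]),
                   c(df$x2[i], df$y2[i], df$z2[i]),
                   thickness = df$thickness[i], width = df$width[i],
                   frame_index = df$frame[i])
  })
}
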