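# Per-cell compressive strain from segmented areas. Sign convention:
# strain > 0 is compression, strain < 0 is tension. The linear convention
# eps = 1 - sqrt(A / A0) is used so that the strain of a cell whose area
# follows the shear-lag prediction A0 (1 - k (R - r))^2 is exactly
# k (R - r) = sigma / E_eff — the two modules' conventions compose.

#' Reference (uncompressed) cell area of a growth series
#'
#' The normal area of a full-grown cell without compression, taken as the
#' mean cell area of an early frame of the series (default the first).
#'
#' @param series list of [tissue_frame()]s.
#' @param frame_index which frame of the series to average (1-based
#'   position, default 1).
#' @return mean cell area (µm²).
#' @export
reference_area <- function(series, frame_index = 1L) {
  if (inherits(series, "tissue_frame")) series <- list(series)
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  fr <- series[[frame_index]]
  if (nrow(fr$cells) == 0L) stop("reference frame has no cells", call. = FALSE)
  mean(fr$cells$area)
}

#' Compressive strain of a cell from its area
#'
#' `eps = 1 - sqrt(area / A0)`: zero at the reference area, positive under
#' compression, negative under tension, always below 1.
#'
#' @param area cell area (µm²), vectorised.
#' @param A0 reference area (µm²).
#' @return dimensionless strain.
#' @export
cell_strain <- function(area, A0) {
  if (any(!is.finite(area) | area <= 0) || !is.finite(A0) || A0 <= 0) {
    stop("area and A0 must be positive", call. = FALSE)
  }
  1 - sqrt(area / A0)
}

#' Per-cell strain records and a gridded strain map
#'
#' Computes the strain of every cell in a frame and renders it on a
#' regular grid by nearest-cell assignment inside the colony disc; grid
#' points outside the colony are NA.
#'
#' @param frame a [tissue_frame()].
#' @param A0 reference area (µm²), e.g. from [reference_area()].
#' @param grid_step grid spacing (µm); NULL skips the rendering.
#' @return list with `records` (data.frame cell_id, r, strain) and `grid`
#'   (list x, y, strain matrix) or NULL.
#' @export
strain_map <- function(frame, A0, grid_step = NULL) {
  stopifnot(inherits(frame, "tissue_frame"))
  r <- cell_radii(frame)
  records <- data.frame(cell_id = frame$cells$cell_id, r = r,
                        strain = cell_strain(frame$cells$area, A0))
  grid <- NULL
  if (!is.null(grid_step)) {
    if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
    cc <- frame$colony_centroid; R <- frame$colony_radius
    gx <- seq(cc[1] - R, cc[1] + R, by = grid_step)
    gy <- seq(cc[2] - R, cc[2] + R, by = grid_step)
    gxm <- matrix(gx, length(gx), length(gy))
    gym <- matrix(gy, length(gx), length(gy), byrow = TRUE)
    inside <- (gxm - cc[1])^2 + (gym - cc[2])^2 <= R^2
    vals <- matrix(NA_real_, length(gx), length(gy))
    if (any(inside) && nrow(records) > 0L) {
      qx <- gxm[inside]; qy <- gym[inside]
      # nearest cell centroid, chunked to bound memory
      n <- length(qx); assign_idx <- integer(n)
      cx <- frame$cells$x; cy <- frame$cells$y
      chunk <- max(1L, floor(2e6 / length(cx)))
      for (s in seq(1L, n, by = chunk)) {
        e <- min(n, s + chunk - 1L)
        d2 <- outer(qx[s:e], cx, "-")^2 + outer(qy[s:e], cy, "-")^2
        assign_idx[s:e] <- max.col(-d2, ties.method = "first")
      }
      vals[inside] <- records$strain[assign_idx]
    }
    grid <- list(x = gx, y = gy, strain = vals)
  }
  list(records = records, grid = grid)
}

#' Radial strain profile
#'
#' Mean per-cell strain in equal-width radial bins on `[0, R]`.
#'
#' @inheritParams strain_map
#' @param n_bins number of bins (>= 2).
#' @return data.frame with `r_mid`, `mean_strain` (NA for empty bins),
#'   `n` and `empty` flag.
#' @export
radial_strain_profile <- function(frame, A0, n_bins = 10L) {
  stopifnot(inherits(frame, "tissue_frame"), n_bins >= 2L)
  rec <- strain_map(frame, A0)$records
  R <- frame$colony_radius
  breaks <- seq(0, R, length.out = n_bins + 1L)
  bin <- cut(pmin(rec$r, R), breaks, include.lowest = TRUE, labels = FALSE)
  mean_strain <- tapply(rec$strain, factor(bin, levels = seq_len(n_bins)),
                        mean)
  n <- tabulate(bin, nbins = n_bins)
  data.frame(r_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean_strain = as.numeric(mean_strain), n = n, empty = n == 0L)
}

#' Strain-gradient slope of a frame
#'
#' Least-squares slope of per-cell strain against the distance from the
#' free edge, `eps ~ k (R - r)` (regression through the origin, since the
#' edge is strain-free by construction). Under the shear-lag model the
#' slope estimates k = f / (h E_eff).
#'
#' @inheritParams strain_map
#' @return list with `k_hat` (1/µm) and `se` (standard error).
#' @export
fit_strain_gradient <- function(frame, A0) {
  rec <- strain_map(frame, A0)$records
  dr <- frame$colony_radius - rec$r
  fit <- stats::lm(strain ~ dr - 1, data = data.frame(strain = rec$strain,
                                                      dr = dr))
  n <- length(dr)
  s2 <- sum(stats::resid(fit)^2) / max(n - 1L, 1L)
  list(k_hat = unname(stats::coef(fit)[1]),
       se = sqrt(s2 / sum(dr^2)))
}
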