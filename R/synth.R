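# Synthetic tissue generators. Every generator is a pure function of its
# spec and seed, restores the caller's RNG state, and returns the full
# ground truth needed to predict every downstream measurement.

#' Specification for synthetic colonies
#'
#' Defaults encode the study conditions the generators emulate: a
#' monoclonal colony of ~20 µm cells (A0 = 400 µm²) of outer radius
#' 300 µm whose imposed linear strain gradient k reaches 1e-3 /µm (centre
#' strain 0.3), with 10% multiplicative area noise; fluid-like colonies
#' carry no persistent gradient but temporally fluctuating areas.
#'
#' @param seed integer seed.
#' @param n_cells number of cells (>= 4).
#' @param A0_true uncompressed cell area (µm²).
#' @param gradient_k_true imposed strain slope k (1/µm); must satisfy
#'   `k * R < 1`.
#' @param R_true colony radius (µm).
#' @param regime `"solid_like"` or `"fluid_like"`.
#' @param noise_cv multiplicative area-noise coefficient of variation.
#' @param v_rms_true target rms speed for motion generators (µm/h).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_cells = 500L, A0_true = 400,
                       gradient_k_true = 1e-3, R_true = 300,
                       regime = c("solid_like", "fluid_like"),
                       noise_cv = 0.1, v_rms_true = 10) {
  regime <- match.arg(regime)
  stopifnot(n_cells >= 4L, A0_true > 0, gradient_k_true >= 0, R_true > 0,
            noise_cv >= 0, v_rms_true >= 0)
  if (gradient_k_true * R_true >= 1) {
    stop("gradient_k_true * R_true must stay below 1 (strain < 1)",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 A0_true = A0_true, gradient_k_true = gradient_k_true,
                 R_true = R_true, regime = regime, noise_cv = noise_cv,
                 v_rms_true = v_rms_true), class = "synth_spec")
}

# imposed area profile A(r) = A0 (1 - k (R - r))^2
.area_profile <- function(r, A0, k, R) A0 * (1 - k * (R - r))^2

# sample radii from the cell-number intensity ~ r / A(r) by inverse CDF
.sample_radii <- function(n, A0, k, R) {
  grid <- seq(0, R, length.out = 2048L)
  dens <- grid / pmax(.area_profile(grid, A0, k, R), 1e-12)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(c(0, cdf), c(0, grid), xout = u, ties = "ordered")$y
}

# regime-dependent shape-index profile: compressed central cells are
# rounder (lower p0); fluid tissue sits above the jamming threshold
.p0_profile <- function(r_frac, regime, n) {
  if (regime == "solid_like") {
    pmax(3.66 + 0.22 * r_frac + stats::rnorm(n, 0, 0.02), 3.60)
  } else {
    pmax(3.90 + stats::rnorm(n, 0, 0.03), 3.60)
  }
}

# regular hexagon of given area, centred and rotated
.hexagon <- function(cx, cy, area, rot = 0) {
  s <- sqrt(2 * area / (3 * sqrt(3)))
  a <- rot + seq(0, by = pi / 3, length.out = 6L)
  cbind(cx + s * cos(a), cy + s * sin(a))
}

#' Generate a radially graded synthetic colony
#'
#' Cell positions are drawn from the number density 1/A(r) implied by the
#' imposed area profile `A(r) = A0 (1 - k (R - r))^2`; each cell is then
#' assigned its on-profile area times multiplicative lognormal noise with
#' the spec's CV, so a noiseless spec lies exactly on the profile.
#' Perimeters follow a regime-dependent shape-index profile (compressed
#' central cells are rounder).
#'
#' @param spec a [synth_spec()].
#' @param polygons attach area-matched hexagonal polygons.
#' @return list with `frame` (a [tissue_frame()]) and `truth`
#'   (`ground_truth` record of every generating parameter).
#' @export
make_radial_tessellation <- function(spec, polygons = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  A0 <- spec$A0_true; k <- spec$gradient_k_true; R <- spec$R_true
  # feasibility: the colony must be able to hold n_cells at the target
  # area profile
  grid <- seq(0, R, length.out = 2048L)
  capacity <- sum(2 * pi * grid / .area_profile(grid, A0, k, R)) *
    (grid[2] - grid[1])
  if (spec$n_cells > capacity) {
    stop("infeasible spec: ", spec$n_cells, " cells exceed the colony's ",
         "capacity (", floor(capacity), ") at the target area profile",
         call. = FALSE)
  }
  out <- .with_seed(spec$seed, {
    n <- spec$n_cells
    r <- .sample_radii(n, A0, k, R)
    th <- stats::runif(n, 0, 2 * pi)
    area <- .area_profile(r, A0, k, R) * .lognoise(n, spec$noise_cv)
    p0 <- .p0_profile(r / R, spec$regime, n)
    rot <- stats::runif(n, 0, 2 * pi)
    list(r = r, th = th, area = area, p0 = p0, rot = rot)
  })
  cells <- data.frame(frame = 0L, cell_id = seq_len(spec$n_cells),
                      x = out$r * cos(out$th), y = out$r * sin(out$th),
                      area = out$area,
                      perimeter = out$p0 * sqrt(out$area))
  polys <- NULL
  if (polygons) {
    polys <- lapply(seq_len(spec$n_cells), function(i) {
      .hexagon(cells$x[i], cells$y[i], cells$area[i], out$rot[i])
    })
    names(polys) <- as.character(cells$cell_id)
  }
  frame <- tissue_frame(0L, cells, polygons = polys,
                        colony_centroid = c(0, 0), colony_radius = R)
  truth <- structure(list(generator = "make_radial_tessellation",
                          seed = spec$seed, n_cells = spec$n_cells,
                          A0_true = A0, k_true = k, R_true = R,
                          regime = spec$regime, noise_cv = spec$noise_cv),
                     class = "ground_truth")
  list(frame = frame, truth = truth)
}

#' Generate a growth series
#'
#' Solid-like regime: the colony radius grows by `growth_factor` while
#' the strain gradient strengthens linearly from `k_true/4` to `k_true`;
#' each cell keeps its identity, its relative radial position and its
#' (fixed) area-noise multiplier, so per-cell areas are persistent and
#' the central strain deepens frame by frame. Fluid-like regime: the
#' radius grows 1.3x faster, the gradient stays at zero, and per-cell
#' areas fluctuate frame-to-frame as lognormal noise with temporal
#' correlation 0.5 at the spec's CV.
#'
#' @param spec a [synth_spec()].
#' @param n_frames number of frames (>= 2).
#' @param growth_factor ratio of final to initial colony radius
#'   (solid-like regime).
#' @return list with `series` (list of [tissue_frame()]s), `track`
#'   (a [track_table()]) and `truth` (per-frame R and k).
#' @export
make_growth_series <- function(spec, n_frames = 5L, growth_factor = 1.5) {
  stopifnot(inherits(spec, "synth_spec"), n_frames >= 2L, growth_factor > 1)
  n <- spec$n_cells
  solid <- spec$regime == "solid_like"
  gf <- if (solid) growth_factor else 1 + 1.3 * (growth_factor - 1)
  R_t <- spec$R_true * seq(1, gf, length.out = n_frames)
  k_t <- if (solid) {
    spec$gradient_k_true * seq(0.25, 1, length.out = n_frames)
  } else rep(0, n_frames)
  if (max(k_t * R_t) >= 1) {
    stop("growth would push the centre strain to 1; reduce k or growth",
         call. = FALSE)
  }
  dat <- .with_seed(spec$seed, {
    rho <- .sample_radii(n, spec$A0_true, k_t[n_frames], R_t[n_frames]) /
      R_t[n_frames]
    th <- stats::runif(n, 0, 2 * pi)
    noise_fix <- .lognoise(n, spec$noise_cv)
    # AR(1) log-noise for the fluid regime, stationary CV = noise_cv
    s2 <- log(1 + spec$noise_cv^2)
    phi <- 0.5
    eps <- matrix(stats::rnorm(n * n_frames, 0, sqrt(s2 * (1 - phi^2))),
                  n, n_frames)
    logm <- matrix(0, n, n_frames)
    logm[, 1] <- stats::rnorm(n, 0, sqrt(s2))
    for (t in 2:n_frames) logm[, t] <- phi * logm[, t - 1] + eps[, t]
    list(rho = rho, th = th, noise_fix = noise_fix,
         noise_t = exp(logm - s2 / 2))
  })
  series <- vector("list", n_frames)
  rows <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    r <- dat$rho * R_t[t]
    base_area <- .area_profile(r, spec$A0_true, k_t[t], R_t[t])
    area <- if (solid) base_area * dat$noise_fix
            else spec$A0_true * dat$noise_t[, t]
    p0 <- .with_seed(spec$seed + 1000L + t,
                     .p0_profile(r / R_t[t], spec$regime, n))
    cells <- data.frame(frame = t - 1L, cell_id = seq_len(n),
                        x = r * cos(dat$th), y = r * sin(dat$th),
                        area = area, perimeter = p0 * sqrt(area))
    series[[t]] <- tissue_frame(t - 1L, cells, colony_centroid = c(0, 0),
                                colony_radius = R_t[t])
    rows[[t]] <- data.frame(track_id = seq_len(n), frame = t - 1L,
                            cell_id = seq_len(n), x = cells$x, y = cells$y)
  }
  track <- track_table(do.call(rbind, rows))
  truth <- structure(list(generator = "make_growth_series", seed = spec$seed,
                          regime = spec$regime, n_frames = n_frames,
                          A0_true = spec$A0_true, R_t = R_t, k_t = k_t,
                          noise_cv = spec$noise_cv,
                          temporal_correlation = 0.5),
                     class = "ground_truth")
  list(series = series, track = track, truth = truth)
}

#' Generate motion tracks in a jammed or unjammed regime
#'
#' Unjammed: persistent (AR(1), persistence 0.8) correlated random-walk
#' velocities with rms speed `v_rms_true`. Jammed: caged jitter about
#' fixed anchors with rms speed `v_rms_true / 5` and plateauing mean
#' squared displacement.
#'
#' @param regime `"jammed"` or `"unjammed"`.
#' @param v_rms_true target rms speed (µm/h).
#' @param n_cells,n_frames ensemble size.
#' @param dt frame interval (h).
#' @param seed integer seed.
#' @param box side of the square seeding region (µm).
#' @return list with `track` (a [track_table()]) and `truth`.
#' @export
make_motion_tracks <- function(regime = c("unjammed", "jammed"),
                               v_rms_true = 10, n_cells = 100L,
                               n_frames = 100L, dt = 1 / 6, seed = 1L,
                               box = 500) {
  regime <- match.arg(regime)
  stopifnot(v_rms_true >= 0, n_cells >= 1L, n_frames >= 2L, dt > 0)
  rms_target <- if (regime == "jammed") v_rms_true / 5 else v_rms_true
  dat <- .with_seed(seed, {
    x0 <- stats::runif(n_cells, 0, box)
    y0 <- stats::runif(n_cells, 0, box)
    if (regime == "unjammed") {
      phi <- 0.8
      sd_v <- rms_target / sqrt(2)            # per component
      vx <- matrix(0, n_cells, n_frames - 1L)
      vy <- matrix(0, n_cells, n_frames - 1L)
      vx[, 1] <- stats::rnorm(n_cells, 0, sd_v)
      vy[, 1] <- stats::rnorm(n_cells, 0, sd_v)
      if (n_frames > 2L) {
        for (t in 2:(n_frames - 1L)) {
          vx[, t] <- phi * vx[, t - 1] +
            stats::rnorm(n_cells, 0, sd_v * sqrt(1 - phi^2))
          vy[, t] <- phi * vy[, t - 1] +
            stats::rnorm(n_cells, 0, sd_v * sqrt(1 - phi^2))
        }
      }
      rowcum <- function(m) if (ncol(m) == 1L) m else t(apply(m, 1, cumsum))
      x <- cbind(x0, x0 + rowcum(vx * dt))
      y <- cbind(y0, y0 + rowcum(vy * dt))
    } else {
      s <- rms_target * dt / 2                # per-component jitter SD
      ex <- matrix(stats::rnorm(n_cells * n_frames, 0, s), n_cells)
      ey <- matrix(stats::rnorm(n_cells * n_frames, 0, s), n_cells)
      x <- x0 + ex; y <- y0 + ey
    }
    list(x = x, y = y)
  })
  rows <- lapply(seq_len(n_frames), function(t) {
    data.frame(track_id = seq_len(n_cells), frame = t - 1L,
               cell_id = seq_len(n_cells),
               x = dat$x[, t], y = dat$y[, t])
  })
  track <- track_table(do.call(rbind, rows))
  truth <- structure(list(generator = "make_motion_tracks", seed = seed,
                          regime = regime, v_rms_true = rms_target,
                          dt = dt, n_cells = n_cells, n_frames = n_frames),
                     class = "ground_truth")
  list(track = track, truth = truth)
}
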