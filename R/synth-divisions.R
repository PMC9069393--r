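# Synthetic division events with a prescribed deformation -> spindle-angle
# coupling.

#' Step coupling between deformation and spindle angle
#'
#' Flat cells (thickness/width < 1) divide in plane (5 degrees); tall
#' compressed cells (ratio >= 1) divide out of plane (75 degrees).
#'
#' @param ratio deformation ratio (thickness/width).
#' @return spindle angle (degrees).
#' @export
coupling_step <- function(ratio) ifelse(ratio < 1, 5, 75)

#' Linear monotone coupling between deformation and spindle angle
#'
#' Maps the generated ratio range [0.4, 2] linearly onto [0, 90] degrees.
#'
#' @inheritParams coupling_step
#' @export
coupling_linear <- function(ratio) {
  pmin(90, pmax(0, (ratio - 0.4) / 1.6 * 90))
}

#' Generate synthetic division events
#'
#' Each event draws a deformation ratio uniformly from [0.4, 2], maps it
#' through the coupling to a spindle angle (plus optional truncated
#' Gaussian noise), and places the spindle poles at exactly that angle
#' with a uniform in-plane azimuth.
#'
#' @param n number of events (>= 1).
#' @param coupling monotone function ratio -> angle (degrees); default
#'   [coupling_step()].
#' @param seed integer seed.
#' @param angle_noise_sd SD of additive angle noise (degrees), clipped to
#'   [0, 90].
#' @param spindle_length pole-to-pole distance (µm).
#' @return list with `events` (list of [division_event()]s) and `truth`
#'   (per-event ratio, noise-free angle, realised angle and class).
#' @export
make_division_events <- function(n, coupling = coupling_step, seed = 1L,
                                 angle_noise_sd = 0, spindle_length = 8) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  dat <- .with_seed(seed, {
    ratio <- stats::runif(n, 0.4, 2.0)
    angle0 <- coupling(ratio)
    angle <- pmin(90, pmax(0, angle0 + stats::rnorm(n, 0, angle_noise_sd)))
    azim <- stats::runif(n, 0, 2 * pi)
    width <- stats::runif(n, 8, 15)
    cx <- stats::runif(n, 0, 200); cy <- stats::runif(n, 0, 200)
    list(ratio = ratio, angle0 = angle0, angle = angle, azim = azim,
         width = width, cx = cx, cy = cy)
  })
  events <- lapply(seq_len(n), function(i) {
    th <- dat$angle[i] * pi / 180
    axis <- c(cos(th) * cos(dat$azim[i]), cos(th) * sin(dat$azim[i]),
              sin(th)) * spindle_length / 2
    ctr <- c(dat$cx[i], dat$cy[i], 5)
    division_event(ctr - axis, ctr + axis,
                   thickness = dat$ratio[i] * dat$width[i],
                   width = dat$width[i], frame_index = i)
  })
  truth <- structure(list(generator = "make_division_events", seed = seed,
                          n = n, ratio = dat$ratio,
                          angle_noise_free = dat$angle0,
                          angle_true = dat$angle,
                          class_true = ifelse(dat$angle <= 30, "symmetric",
                                              "asymmetric")),
                     class = "ground_truth")
  list(events = events, truth = truth)
}
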