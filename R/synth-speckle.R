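# Synthetic speckle image pairs advected by a known displacement field --
# the PIV validation input.

#' Displacement field descriptors
#'
#' `field_uniform(u, v)`: constant shift (px). `field_rotation(angle_deg,
#' center)`: rigid in-plane rotation about `center` (px, defaults to the
#' image centre at generation time).
#'
#' @param u,v constant displacement components (px).
#' @return descriptor list understood by [make_speckle_pair()] and
#'   [field_displacement()].
#' @export
field_uniform <- function(u, v) {
  structure(list(type = "uniform", u = u, v = v), class = "disp_field")
}

#' @rdname field_uniform
#' @param angle_deg rotation angle (degrees, counter-clockwise in image
#'   coordinates).
#' @param center rotation centre (px, 0-based), NULL = image centre.
#' @export
field_rotation <- function(angle_deg, center = NULL) {
  structure(list(type = "rotation", angle_deg = angle_deg, center = center),
            class = "disp_field")
}

#' Evaluate a displacement field
#'
#' Displacement u(x) such that the pattern at position x in the first
#' image appears at x + u(x) in the second.
#'
#' @param field a `disp_field` descriptor.
#' @param x,y query positions (px, 0-based).
#' @return list with components `u`, `v` (px).
#' @export
field_displacement <- function(field, x, y) {
  switch(field$type,
    uniform = list(u = rep(field$u, length(x)), v = rep(field$v, length(x))),
    rotation = {
      th <- field$angle_deg * pi / 180
      cx <- field$center[1]; cy <- field$center[2]
      dx <- x - cx; dy <- y - cy
      list(u = dx * (cos(th) - 1) - dy * sin(th),
           v = dx * sin(th) + dy * (cos(th) - 1))
    },
    stop("unknown field type: ", field$type, call. = FALSE))
}

# bilinear sample of matrix img at 0-based (x, y); outside -> 0
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  get <- function(r0, c0) {
    ok <- r0 >= 0 & r0 <= nr - 1 & c0 >= 0 & c0 <= nc - 1
    out <- numeric(length(r0))
    out[ok] <- img[cbind(r0[ok] + 1L, c0[ok] + 1L)]
    out
  }
  val <- get(y0, x0) * (1 - fx) * (1 - fy) +
         get(y0, x0 + 1) * fx * (1 - fy) +
         get(y0 + 1, x0) * (1 - fx) * fy +
         get(y0 + 1, x0 + 1) * fx * fy
  val
}

#' Generate a speckle image pair advected by a known field
#'
#' The first image is Gaussian-filtered white noise (speckle of ~2 px
#' grain); the second is the first warped by the displacement field
#' (bilinear inverse mapping) plus optional additive Gaussian noise. The
#' exact field is returned as ground truth.
#'
#' @param field a `disp_field` descriptor.
#' @param size image side (px).
#' @param seed integer seed.
#' @param noise_sd additive Gaussian noise SD (image intensity units; the
#'   speckle itself has SD ~ 1).
#' @param window PIV window size the pair is destined for; displacements
#'   at or beyond `window/2` are rejected as a spec error.
#' @return list with `imageA`, `imageB` (matrices) and `truth` (field
#'   descriptor with centre resolved, plus the generation record).
#' @export
make_speckle_pair <- function(field, size = 256L, seed = 1L, noise_sd = 0,
                              window = 32L) {
  stopifnot(inherits(field, "disp_field"), size >= 32L, noise_sd >= 0)
  if (field$type == "rotation" && is.null(field$center)) {
    field$center <- c((size - 1) / 2, (size - 1) / 2)
  }
  # precondition: the field must stay resolvable by the PIV window
  xs <- seq(0, size - 1, length.out = 17L)
  gr <- expand.grid(x = xs, y = xs)
  d <- field_displacement(field, gr$x, gr$y)
  if (max(abs(c(d$u, d$v))) >= window / 2) {
    stop("displacement too large for a ", window, " px PIV window",
         call. = FALSE)
  }
  imgs <- .with_seed(seed, {
    white <- matrix(stats::rnorm(size * size), size, size)
    # Gaussian smoothing by FFT, sigma ~ 1.5 px
    fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
    kx <- exp(-2 * pi^2 * 1.5^2 * fx^2)
    K <- outer(kx, kx)
    A <- Re(stats::fft(stats::fft(white) * K, inverse = TRUE)) / size^2
    A <- A / stats::sd(A)
    # inverse mapping: B(x) = A(x - u(x)) evaluated with u at the target
    # position (exact for uniform shifts and rigid rotations)
    idx <- expand.grid(y = 0:(size - 1), x = 0:(size - 1))
    dd <- field_displacement(field, idx$x, idx$y)
    src_x <- if (field$type == "rotation") {
      th <- -field$angle_deg * pi / 180
      cx <- field$center[1]; cy <- field$center[2]
      (idx$x - cx) * cos(th) - (idx$y - cy) * sin(th) + cx
    } else idx$x - dd$u
    src_y <- if (field$type == "rotation") {
      th <- -field$angle_deg * pi / 180
      cx <- field$center[1]; cy <- field$center[2]
      (idx$x - cx) * sin(th) + (idx$y - cy) * cos(th) + cy
    } else idx$y - dd$v
    B <- matrix(.bilinear(A, src_x, src_y), size, size)
    if (noise_sd > 0) B <- B + matrix(stats::rnorm(size * size, 0, noise_sd),
                                      size, size)
    list(A = A, B = B)
  })
  truth <- structure(list(generator = "make_speckle_pair", seed = seed,
                          field = unclass(field), size = size,
                          noise_sd = noise_sd), class = "ground_truth")
  list(imageA = imgs$A, imageB = imgs$B, truth = truth)
}
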