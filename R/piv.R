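# Window-based cross-correlation particle image velocimetry.
#
# One-pass interrogation (no window deformation): each window pair is
# mean-subtracted, cross-correlated via FFT on a zero-padded grid, and the
# correlation peak is refined to sub-pixel accuracy with a three-point
# Gaussian fit in each axis. Windows whose peak-to-second-peak ratio falls
# below a detectability threshold are flagged invalid and replaced by the
# 3x3 local median (single pass).

#' Particle image velocimetry between two images
#'
#' @param imageA,imageB numeric matrices of identical size (frame t and
#'   t + dt). Matrix rows are y (downward), columns x.
#' @param window interrogation window size (px, >= 16).
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param dt frame interval (h); with `dt = 1` and `pixel_size = 1`
#'   vectors are displacements in pixels.
#' @param pixel_size µm per pixel.
#' @param peak_ratio_min minimum first-to-second correlation peak ratio
#'   for a vector to be accepted.
#' @param max_disp largest trusted displacement (px); defaults to
#'   window/4. Peaks beyond it are invalid.
#' @return a [velocity_field()] with grid positions at window centres
#'   (µm) and velocities in µm/h.
#' @export
piv <- function(imageA, imageB, window = 32L, overlap = 0.5, dt = 1,
                pixel_size = 1, peak_ratio_min = 1.2, max_disp = NULL) {
  stopifnot(is.matrix(imageA), is.matrix(imageB),
            all(dim(imageA) == dim(imageB)))
  window <- as.integer(window)
  if (window < 16L) stop("window must be >= 16 px", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)",
                                        call. = FALSE)
  if (nrow(imageA) < window || ncol(imageA) < window) {
    stop("image smaller than one interrogation window", call. = FALSE)
  }
  if (is.null(max_disp)) max_disp <- window / 4
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  ys <- seq(1L, nrow(imageA) - window + 1L, by = step)
  xs <- seq(1L, ncol(imageA) - window + 1L, by = step)
  m <- 2L * window                      # padded correlation size
  nyq <- window                          # index offset of zero displacement
  # overlap-area normalisation removes the triangular bias of the
  # zero-padded linear correlation (peak pulled toward zero shift)
  dvals <- (-nyq):(nyq - 1L)
  ow <- pmax(window - abs(dvals), 1L) / window
  overlap_w <- outer(ow, ow)
  ny <- length(ys); nx <- length(xs)
  u <- matrix(NA_real_, ny, nx); v <- matrix(NA_real_, ny, nx)
  ok <- matrix(FALSE, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      ra <- ys[iy]:(ys[iy] + window - 1L)
      ca <- xs[ix]:(xs[ix] + window - 1L)
      a <- imageA[ra, ca]; b <- imageB[ra, ca]
      a <- a - mean(a); b <- b - mean(b)
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) next
      pa <- matrix(0, m, m); pb <- matrix(0, m, m)
      pa[1:window, 1:window] <- a
      pb[1:window, 1:window] <- b
      cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb),
                          inverse = TRUE)) / (m * m * na * nb)
      # displacement s: circular index shift; reorder so zero lies at
      # (nyq+1, nyq+1) with range -window..window-1
      cc <- cc[c((nyq + 1L):m, 1L:nyq), c((nyq + 1L):m, 1L:nyq)] / overlap_w
      # restrict the search to trusted displacements
      lo <- nyq + 1L - floor(max_disp); hi <- nyq + 1L + floor(max_disp)
      sub <- cc[lo:hi, lo:hi]
      pk <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      py <- pk[1L] + lo - 1L; px <- pk[2L] + lo - 1L
      peak1 <- cc[py, px]
      if (peak1 <= 0) next
      # second peak outside the 3x3 neighbourhood of the first
      sub2 <- sub
      r0 <- max(1L, pk[1L] - 1L):min(nrow(sub), pk[1L] + 1L)
      c0 <- max(1L, pk[2L] - 1L):min(ncol(sub), pk[2L] + 1L)
      sub2[r0, c0] <- -Inf
      peak2 <- max(sub2)
      dy <- py - (nyq + 1L); dx <- px - (nyq + 1L)
      # three-point Gaussian sub-pixel refinement per axis
      gx <- .gauss3(cc[py, px - 1L], peak1, cc[py, px + 1L])
      gy <- .gauss3(cc[py - 1L, px], peak1, cc[py + 1L, px])
      u[iy, ix] <- (dx + gx) * pixel_size / dt
      v[iy, ix] <- (dy + gy) * pixel_size / dt
      ok[iy, ix] <- peak2 <= 0 || (peak1 / max(peak2, 1e-300)) >= peak_ratio_min
    }
  }
  # single-pass 3x3 local median replacement of invalid vectors
  bad <- which(!ok | !is.finite(u), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    u_f <- u; v_f <- v
    for (k in seq_len(nrow(bad))) {
      ri <- max(1L, bad[k, 1L] - 1L):min(ny, bad[k, 1L] + 1L)
      ci <- max(1L, bad[k, 2L] - 1L):min(nx, bad[k, 2L] + 1L)
      nb_u <- u[ri, ci][ok[ri, ci]]; nb_v <- v[ri, ci][ok[ri, ci]]
      if (length(nb_u) > 0L) {
        u_f[bad[k, 1L], bad[k, 2L]] <- stats::median(nb_u)
        v_f[bad[k, 1L], bad[k, 2L]] <- stats::median(nb_v)
      }
    }
    u <- u_f; v <- v_f
  }
  centre <- (window - 1) / 2
  gx <- (rep(xs, each = ny) - 1 + centre) * pixel_size
  gy <- (rep(ys, times = nx) - 1 + centre) * pixel_size
  keep <- is.finite(as.vector(u)) & is.finite(as.vector(v))
  velocity_field(x = gx[keep], y = gy[keep],
                 u = as.vector(u)[keep], v = as.vector(v)[keep],
                 valid = as.vector(ok)[keep],
                 window = window, overlap = overlap, dt = dt)
}

# 3-point Gaussian peak interpolation; parabolic fallback when a
# neighbour is non-positive.
.gauss3 <- function(cm, c0, cp) {
  if (cm > 0 && cp > 0 && c0 > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
    if (den < 0) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm + cp - 2 * c0)
  if (den < 0) (cm - cp) / den else 0
}
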