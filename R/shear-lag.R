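# Shear-lag model of the radial compression gradient in a growing cell
# sheet. A constant interfacial shear traction f, directed against the
# sheet's expansion, accumulates compressive stress from the free edge
# toward the colony centre:
#
#   sigma(r) = f * (R - r) / h         (compression positive)
#
# with h the sheet thickness and R the outer radius. Linear strain is
# eps = sigma / E_eff and the cell-area readout is A = A0 * (1 - eps)^2.
# Delamination (the onset of stratification) is predicted where the
# stored elastic energy per unit interface area, U = sigma^2 h / (2 E_eff),
# reaches the interfacial adhesion energy Gamma.
#
# Units: Pa and micrometres at the interface; energy conversions to J/m^2
# are centralised in .energy_si().

.energy_si <- function(sigma_pa, h_um, E_pa) {
  sigma_pa^2 * (h_um * 1e-6) / (2 * E_pa)   # J/m^2
}

#' Shear-lag model parameters
#'
#' @param f interfacial shear stress (Pa, >= 0).
#' @param h sheet thickness (µm).
#' @param E_eff effective sheet modulus (Pa); any Poisson factor is
#'   absorbed into it, keeping the model identifiable from area data.
#' @param R outer colony radius (µm).
#' @param Gamma interfacial normal-adhesion energy (J/m²); `Inf` means
#'   delamination can never occur.
#' @param A0 uncompressed reference cell area (µm²).
#' @return object of class `shear_lag_params`. The model is valid only
#'   while the centre strain f·R/(h·E_eff) stays below 1.
#' @export
shear_lag_params <- function(f, h, E_eff, R, Gamma = Inf, A0 = 400) {
  stopifnot(f >= 0, h > 0, E_eff > 0, R >= 0, Gamma >= 0, A0 > 0)
  p <- structure(list(f = f, h = h, E_eff = E_eff, R = R, Gamma = Gamma,
                      A0 = A0), class = "shear_lag_params")
  p$k <- f / (h * E_eff)           # strain gradient, 1/µm
  p$valid <- p$k * R < 1
  p
}

.check_r <- function(params, r) {
  if (any(r < 0 | r > params$R)) {
    stop("radial coordinates must lie in [0, R]", call. = FALSE)
  }
  if (!params$valid) {
    stop("invalid shear-lag parameters: f*R/(h*E_eff) >= 1 ",
         "(strain would reach 1)", call. = FALSE)
  }
}

#' Radial stress/strain/area profile of the shear-lag model
#'
#' @param params a [shear_lag_params()].
#' @param r radii (µm), all in `[0, R]`.
#' @return object of class `stress_profile`: data.frame-like list with
#'   `r`, `sigma` (Pa, compression positive, zero at the free edge),
#'   `strain` (= sigma / E_eff) and `area_pred` (= A0 (1 - strain)^2).
#' @export
stress_profile <- function(params, r) {
  stopifnot(inherits(params, "shear_lag_params"))
  .check_r(params, r)
  sigma <- params$f * (params$R - r) / params$h
  strain <- sigma / params$E_eff
  structure(list(r = r, sigma = sigma, strain = strain,
                 area_pred = params$A0 * (1 - strain)^2),
            class = "stress_profile")
}

#' Predicted cell-area profile
#'
#' `A(r) = A0 (1 - k (R - r))^2` with `k = f / (h E_eff)`; increasing in r,
#' equal to A0 at the free edge.
#'
#' @inheritParams stress_profile
#' @return numeric vector of areas (µm²).
#' @export
predicted_area_profile <- function(params, r) {
  stress_profile(params, r)$area_pred
}

#' Fit the shear-lag area profile to a segmented frame
#'
#' Nonlinear least squares of `A(r) = A0 (1 - k (R - r))^2` to the per-cell
#' areas of a frame, with R fixed to the frame's colony radius and
#' (A0, k) free (Levenberg-Marquardt, analytic model, iteration cap 200,
#' relative tolerance 1e-10). When the unconstrained optimum has k < 0 the
#' estimate is clipped to the boundary k = 0 and flagged.
#'
#' @param frame a [tissue_frame()] with at least 10 cells.
#' @param n_boot number of bootstrap resamples over cells for confidence
#'   intervals (0 = none).
#' @param boot_seed seed for the bootstrap resampling.
#' @return list with `A0_hat` (µm²), `k_hat` (1/µm), `R_hat` (µm, the fixed
#'   colony radius), `residual` (root-mean-square residual, µm²),
#'   `k_at_boundary` flag and, when `n_boot > 0`, `ci` (2.5/97.5%
#'   bootstrap percentile intervals for A0 and k).
#' @export
fit_area_profile <- function(frame, n_boot = 0L, boot_seed = 1L) {
  stopifnot(inherits(frame, "tissue_frame"))
  if (nrow(frame$cells) < 10L) {
    stop("need at least 10 cells to fit the area profile", call. = FALSE)
  }
  r <- cell_radii(frame)
  A <- frame$cells$area
  R <- frame$colony_radius
  A0_start <- mean(A[r > stats::quantile(r, 0.9)])
  if (!is.finite(A0_start) || A0_start <= 0) A0_start <- mean(A)
  k_start <- max((1 - sqrt(min(A) / A0_start)) / R, 1e-6)
  df <- data.frame(A = A, dr = R - r)
  fit <- try(minpack.lm::nlsLM(
    A ~ A0 * (1 - k * dr)^2, data = df,
    start = list(A0 = A0_start, k = k_start),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                         ptol = 1e-10)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("area-profile fit did not converge: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  est <- stats::coef(fit)
  k_at_boundary <- FALSE
  if (est[["k"]] < 0) {
    k_at_boundary <- TRUE
    est[["k"]] <- 0
    est[["A0"]] <- mean(A)
  }
  resid <- A - est[["A0"]] * (1 - est[["k"]] * (R - r))^2
  out <- list(A0_hat = unname(est[["A0"]]), k_hat = unname(est[["k"]]),
              R_hat = R, residual = sqrt(mean(resid^2)),
              k_at_boundary = k_at_boundary)
  if (n_boot > 0L) {
    boots <- .with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(frame$cells), replace = TRUE)
        fb <- frame
        fb$cells <- frame$cells[idx, , drop = FALSE]
        fb$cells$cell_id <- seq_len(nrow(fb$cells))
        ft <- try(fit_area_profile(fb), silent = TRUE)
        if (inherits(ft, "try-error")) c(NA_real_, NA_real_)
        else c(ft$A0_hat, ft$k_hat)
      }, numeric(2))
    })
    out$ci <- list(
      A0 = unname(stats::quantile(boots[1, ], c(0.025, 0.975),
                                  na.rm = TRUE)),
      k = unname(stats::quantile(boots[2, ], c(0.025, 0.975),
                                 na.rm = TRUE)),
      n_boot = n_boot)
  }
  out
}

#' Stored elastic strain energy per unit interface area
#'
#' `U = sigma^2 h / (2 E_eff)`, converted to J/m².
#'
#' @param sigma compressive stress (Pa, >= 0); vectorised.
#' @param params a [shear_lag_params()].
#' @return energy density (J/m²).
#' @export
strain_energy_per_area <- function(sigma, params) {
  stopifnot(inherits(params, "shear_lag_params"), all(sigma >= 0))
  .energy_si(sigma, params$h, params$E_eff)
}

#' Critical colony radius for delamination
#'
#' The radius at which the centre stress sigma(0) = f R / h first stores
#' enough elastic energy to pay the interfacial adhesion energy:
#' `R* = sqrt(2 E_eff h Gamma) / f` (µm). Delamination is predicted at the
#' colony centre first. With f = 0 the sheet never delaminates and `Inf`
#' is returned.
#'
#' @param params a [shear_lag_params()] with Gamma > 0.
#' @return critical radius (µm); `Inf` when f = 0 or Gamma = Inf.
#' @export
critical_radius <- function(params) {
  stopifnot(inherits(params, "shear_lag_params"))
  if (params$Gamma <= 0) stop("Gamma must be > 0", call. = FALSE)
  if (params$f == 0 || is.infinite(params$Gamma)) return(Inf)
  sqrt(2 * params$E_eff * (params$h * 1e-6) * params$Gamma) / params$f * 1e6
}

#' Delamination mask over a stress profile
#'
#' TRUE where the stored energy U(sigma(r)) reaches Gamma; when any point
#' delaminates the mask is a contiguous central disc (stress decreases
#' outward).
#'
#' @param profile a [stress_profile()].
#' @param params the generating [shear_lag_params()].
#' @return logical vector parallel to `profile$r`.
#' @export
delamination_mask <- function(profile, params) {
  stopifnot(inherits(profile, "stress_profile"),
            inherits(params, "shear_lag_params"))
  if (is.infinite(params$Gamma)) return(rep(FALSE, length(profile$r)))
  strain_energy_per_area(profile$sigma, params) >= params$Gamma
}
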