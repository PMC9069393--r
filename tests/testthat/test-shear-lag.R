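test_that("stress profile follows the shear-lag closed form", {
  p <- shear_lag_params(f = 100, h = 10, E_eff = 10000, R = 500)
  sp <- stress_profile(p, c(0, 250, 500))
  expect_equal(sp$sigma, c(5000, 2500, 0))
  expect_equal(sp$strain, sp$sigma / p$E_eff)
  # free edge exactly zero; f = 0 kills the profile
  p0 <- shear_lag_params(f = 0, h = 10, E_eff = 1000, R = 500)
  expect_true(all(stress_profile(p0, seq(0, 500, 50))$sigma == 0))
  # strictly decreasing when f > 0
  r <- seq(0, 500, length.out = 21)
  expect_true(all(diff(stress_profile(p, r)$sigma) < 0))
  # domain and validity errors
  expect_error(stress_profile(p, c(-1, 10)), "\\[0, R\\]")
  pbad <- shear_lag_params(f = 100, h = 10, E_eff = 1000, R = 500)
  expect_error(stress_profile(pbad, 0), "strain")
})

test_that("predicted area profile maps strain to (1 - eps)^2", {
  p <- shear_lag_params(f = 10, h = 10, E_eff = 1000, R = 300, A0 = 400)
  expect_equal(predicted_area_profile(p, 300), 400)
  # k (R - r) = 0.1 -> 0.81 A0
  k <- p$k
  r01 <- 300 - 0.1 / k
  expect_equal(predicted_area_profile(p, r01), 0.81 * 400)
  # monotone interpolation: A(0) <= A(r) <= A(R) over random params
  set.seed(0)
  for (i in 1:20) {
    pp <- shear_lag_params(f = runif(1, 0, 5), h = runif(1, 5, 20),
                           E_eff = runif(1, 500, 5000),
                           R = runif(1, 100, 600), A0 = runif(1, 100, 900))
    if (!pp$valid) next
    rr <- sort(runif(10, 0, pp$R))
    A <- predicted_area_profile(pp, rr)
    expect_true(all(A >= predicted_area_profile(pp, 0) - 1e-9))
    expect_true(all(A <= pp$A0 + 1e-9))
    expect_true(all(diff(A) >= -1e-12))
  }
})

test_that("area-profile fit recovers the generating parameters", {
  # noiseless: sub-0.1% identifiability
  s <- synth_spec(seed = 2L, n_cells = 500, gradient_k_true = 1e-3,
                  noise_cv = 0)
  fr <- make_radial_tessellation(s)$frame
  fit <- fit_area_profile(fr)
  expect_lt(abs(fit$k_hat - 1e-3) / 1e-3, 1e-3)
  expect_lt(abs(fit$A0_hat - s$A0_true) / s$A0_true, 1e-3)
  expect_false(fit$k_at_boundary)

  # gradient-free data lands on the k = 0 boundary (flagged) or within
  # noise of zero
  s0 <- synth_spec(seed = 6L, n_cells = 300, gradient_k_true = 0,
                   noise_cv = 0.05)
  fit0 <- fit_area_profile(make_radial_tessellation(s0)$frame)
  expect_true(fit0$k_at_boundary || abs(fit0$k_hat) < 5e-5)

  expect_error(fit_area_profile(
    make_radial_tessellation(synth_spec(seed = 1, n_cells = 8))$frame),
    "at least 10")

  # bootstrap interval brackets the generating gradient
  sn <- synth_spec(seed = 3L, n_cells = 200, gradient_k_true = 1e-3,
                   noise_cv = 0.1)
  frn <- make_radial_tessellation(sn)$frame
  fb <- fit_area_profile(frn, n_boot = 40)
  # interval brackets the point estimate and sits near the truth
  expect_lte(fb$ci$k[1], fb$k_hat)
  expect_gte(fb$ci$k[2], fb$k_hat)
  expect_lte(fb$ci$k[1], 1e-3 * 1.05)
  expect_gte(fb$ci$k[2], 1e-3 * 0.95)
})

test_that("strain energy and critical radius follow the energy balance", {
  p <- shear_lag_params(f = 100, h = 10, E_eff = 1000, R = 40,
                        Gamma = 1e-4)
  expect_equal(strain_energy_per_area(0, p), 0)
  expect_equal(strain_energy_per_area(2 * 300, p),
               4 * strain_energy_per_area(300, p))
  expect_equal(strain_energy_per_area(5000, p), 0.125)
  expect_equal(critical_radius(p), sqrt(2) * 10, tolerance = 1e-9)
  # root-finding cross-check: U(sigma(0; R*)) = Gamma
  Rs <- critical_radius(p)
  u_at <- function(R) {
    pp <- shear_lag_params(f = p$f, h = p$h, E_eff = p$E_eff, R = R,
                           Gamma = p$Gamma)
    strain_energy_per_area(stress_profile(pp, 0)$sigma, pp)
  }
  root <- uniroot(function(R) u_at(R) - p$Gamma, c(1, 30),
                  tol = 1e-10)$root
  expect_equal(Rs, root, tolerance = 1e-6)
  # scalings: Gamma x4 doubles R*, f x2 halves it
  p4 <- shear_lag_params(f = 100, h = 10, E_eff = 1000, R = 40,
                         Gamma = 4e-4)
  expect_equal(critical_radius(p4), 2 * Rs, tolerance = 1e-12)
  p2f <- shear_lag_params(f = 200, h = 10, E_eff = 1000, R = 40,
                          Gamma = 1e-4)
  expect_equal(critical_radius(p2f), Rs / 2, tolerance = 1e-12)
  # monotonicity in all parameters
  expect_gt(critical_radius(shear_lag_params(100, 20, 1000, 40, 1e-4)), Rs)
  expect_gt(critical_radius(shear_lag_params(100, 10, 2000, 40, 1e-4)), Rs)
  # f = 0 never delaminates
  expect_identical(critical_radius(shear_lag_params(0, 10, 1000, 40,
                                                    1e-4)), Inf)
})

test_that("delamination mask is a central disc matching the pointwise rule", {
  p <- shear_lag_params(f = 100, h = 10, E_eff = 1000, R = 2 * sqrt(2) * 10,
                        Gamma = 1e-4)
  Rs <- critical_radius(p)
  r <- seq(0, p$R, length.out = 201)
  mask <- delamination_mask(stress_profile(p, r), p)
  # brute-force pointwise oracle
  manual <- strain_energy_per_area(stress_profile(p, r)$sigma, p) >= p$Gamma
  expect_identical(mask, manual)
  away <- abs(r - (p$R - Rs)) > 1e-6      # grid points off the boundary
  expect_identical(mask[away], (r < p$R - Rs)[away])
  expect_true(all(diff(as.integer(mask)) <= 0))   # contiguous central disc
  # below critical size: nothing delaminates; Gamma = Inf sentinel
  psmall <- shear_lag_params(f = 100, h = 10, E_eff = 1000, R = 10,
                             Gamma = 1e-4)
  expect_false(any(delamination_mask(stress_profile(psmall, r / p$R * 10),
                                     psmall)))
  pinf <- shear_lag_params(f = 100, h = 10, E_eff = 1000, R = 40)
  expect_false(any(delamination_mask(stress_profile(pinf, c(0, 40)), pinf)))
})
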