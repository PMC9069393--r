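test_that("degenerate limits behave: no friction, no growth", {
  p0 <- sim_params(n_elements = 50, growth_rate = 0.05, f = 0,
                   Gamma = 1e-6, t_end = 2, R0 = 100)
  out <- run_growth(p0, stop_at_onset = FALSE)
  expect_true(all(abs(out$state$sigma) < 1e-8))
  expect_false(any(out$state$delaminated))
  expect_equal(max(out$state$r), 100 * exp(0.05 * out$state$time),
               tolerance = 1e-9)

  pg <- sim_params(n_elements = 50, growth_rate = 0, f = 1, t_end = 1,
                   R0 = 100, dt = 0.1)
  st <- sheet_init(pg)
  st2 <- sim_step(st, pg)
  expect_equal(st2$r, st$r, tolerance = 1e-12)
  expect_equal(st2$sigma, st$sigma, tolerance = 1e-12)
})

test_that("solid-limit stress profile matches the shear-lag oracle", {
  pr <- sim_params(n_elements = 200, growth_rate = 0.05, E_eff = 1000,
                   h = 10, f = 0.5, Gamma = Inf, tau = Inf, t_end = 8,
                   R0 = 100)
  out <- run_growth(pr, stop_at_onset = FALSE)
  sn <- stress_snapshot(out$state)
  R <- max(out$state$r)
  analytic <- pr$f * (R - sn$r) / pr$h
  l2 <- sqrt(sum((sn$sigma - analytic)^2) / sum(analytic^2))
  expect_lt(l2, 0.02)
  # free edge: outermost element stress at the half-tributary level
  expect_lt(sn$sigma[200], pr$f * diff(out$state$r)[200] / pr$h + 1e-8)
  # node radii strictly increasing; delamination flags monotone (none)
  expect_true(all(diff(out$state$r) > 0))
})

test_that("delamination onset tracks the analytic critical radius", {
  E <- 1000; h <- 10; f <- 1; Gam <- 2e-6
  Rstar <- critical_radius(shear_lag_params(f, h, E, R = 100, Gamma = Gam))
  pr <- sim_params(n_elements = 200, growth_rate = 0.05, E_eff = E, h = h,
                   f = f, Gamma = Gam, tau = Inf, t_end = 40, R0 = 100)
  out <- run_growth(pr)
  expect_false(is.null(out$onset))
  expect_lt(abs(out$onset$R - Rstar) / Rstar, 0.1)
  # delaminated region is a contiguous central disc
  flags <- out$state$delaminated
  expect_true(any(flags))
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("fluid limit saturates the centre stress and never delaminates", {
  E <- 1000; h <- 10; f <- 1; Gam <- 2e-6; g <- 0.05; tau <- 0.1
  sigma_star <- sqrt(2 * E * Gam / (h * 1e-6))
  expect_lt(E * g * tau, sigma_star)        # growth-relaxation balance
  pr <- sim_params(n_elements = 100, growth_rate = g, E_eff = E, h = h,
                   f = f, Gamma = Gam, tau = tau,
                   t_end = log(2.2) / g, R0 = 100)
  out <- run_growth(pr)
  expect_null(out$onset)
  expect_lt(max(out$trajectory$sigma_max), sigma_star)
  # steady centre stress: bounded by the Maxwell balance E g tau
  expect_lt(max(out$trajectory$sigma_max), E * g * tau * 1.05)
  n2 <- nrow(out$trajectory)
  late <- out$trajectory$sigma_max[(n2 - 20):n2]
  expect_lt(diff(range(late)) / mean(late), 0.05)   # steady
})

test_that("discretisation: step halving and heterogeneous friction", {
  base <- sim_params(n_elements = 80, growth_rate = 0.05, E_eff = 1000,
                     h = 10, f = 1, tau = 0.5, t_end = 1, R0 = 100,
                     dt = 0.05)
  half <- sim_params(n_elements = 80, growth_rate = 0.05, E_eff = 1000,
                     h = 10, f = 1, tau = 0.5, t_end = 1, R0 = 100,
                     dt = 0.025)
  s1 <- run_growth(base, stop_at_onset = FALSE)$state
  s2 <- run_growth(half, stop_at_onset = FALSE)$state
  # O(dt) step error: halving dt changes the profile by O(dt^2) per step
  # x number of steps = O(dt)
  expect_lt(max(abs(s1$sigma - s2$sigma)) / max(s2$sigma), 0.05)

  het <- sim_params(n_elements = 200, growth_rate = 0.05, E_eff = 1000,
                    h = 10, f = 0.5, t_end = 8, R0 = 100,
                    friction_ratio_map = function(rf) ifelse(rf < 0.5, 5, 1))
  st <- run_growth(het, stop_at_onset = FALSE)$state
  sn <- stress_snapshot(st)
  R <- max(st$r)
  inner <- sn$r < 0.4 * R; outer <- sn$r > 0.6 * R & sn$r < 0.95 * R
  slope <- function(sel) {
    stats::coef(stats::lm(sn$sigma[sel] ~ sn$r[sel]))[2]
  }
  expect_equal(unname(slope(inner) / slope(outer)), 5, tolerance = 0.05)
})

test_that("phase diagram reproduces the solid/fluid dichotomy", {
  base <- sim_params(n_elements = 60, growth_rate = 0.05, E_eff = 1000,
                     h = 10, f = 1, Gamma = 2e-6, tau = Inf,
                     t_end = log(2.2) / 0.05, R0 = 100)
  grid <- expand.grid(f = c(0, 1, 2), tau = c(Inf, 0.2))
  pd <- phase_diagram(grid, base)
  expect_false(any(pd$stratifies[pd$f == 0]))
  solid <- pd[is.infinite(pd$tau) & pd$f > 0, ]
  expect_true(all(solid$stratifies))
  # onset radius decreases with f at fixed Gamma, tau
  expect_true(all(diff(solid$onset_R[order(solid$f)]) < 0))
  fluid <- pd[pd$tau == 0.2 & pd$f > 0, ]
  expect_false(any(fluid$stratifies))
})
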