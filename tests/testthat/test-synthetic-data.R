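test_that("radial tessellation enforces the imposed area profile", {
  # no gradient: mean area within 3 SE of A0
  s0 <- synth_spec(seed = 3L, n_cells = 300, gradient_k_true = 0,
                   noise_cv = 0.1)
  fr0 <- make_radial_tessellation(s0)$frame
  se <- stats::sd(fr0$cells$area) / sqrt(nrow(fr0$cells))
  expect_lt(abs(mean(fr0$cells$area) - s0$A0_true), 3 * se)

  # gradient, noiseless: binned mean area strictly increasing with r
  s1 <- synth_spec(seed = 3L, n_cells = 400, gradient_k_true = 1e-3,
                   noise_cv = 0)
  fr1 <- make_radial_tessellation(s1)$frame
  r <- cell_radii(fr1)
  bins <- cut(r, seq(0, fr1$colony_radius, length.out = 6),
              include.lowest = TRUE)
  means <- tapply(fr1$cells$area, bins, mean)
  expect_true(all(diff(means) > 0))

  # determinism
  fr1b <- make_radial_tessellation(s1)$frame
  expect_identical(fr1$cells, fr1b$cells)

  # infeasible density rejected
  expect_error(make_radial_tessellation(
    synth_spec(seed = 1L, n_cells = 5000, A0_true = 400, R_true = 100)),
    "infeasible")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(make_radial_tessellation(synth_spec(seed = 7L, n_cells = 50)))
  invisible(make_motion_tracks(n_cells = 5, n_frames = 5, seed = 7L))
  expect_identical(.Random.seed, before)
})

test_that("growth series contrasts solid and fluid regimes", {
  sol <- make_growth_series(synth_spec(seed = 5L, n_cells = 250,
                                       regime = "solid_like",
                                       noise_cv = 0.05), n_frames = 4)
  # central strain deepens over frames
  strain_center <- vapply(seq_along(sol$series), function(t) {
    rec <- strain_map(sol$series[[t]], sol$truth$A0_true)$records
    mean(rec$strain[rec$r < 0.2 * sol$series[[t]]$colony_radius])
  }, numeric(1))
  expect_gt(strain_center[4], strain_center[1])

  flu <- make_growth_series(synth_spec(seed = 5L, n_cells = 250,
                                       regime = "fluid_like",
                                       noise_cv = 0.1), n_frames = 4)
  k_solid <- sol$truth$k_t[4]
  for (t in seq_along(flu$series)) {
    k_hat <- fit_strain_gradient(flu$series[[t]], flu$truth$A0_true)$k_hat
    expect_lt(abs(k_hat), 0.1 * k_solid)
  }

  # track table consistent with the frames
  expect_equal(sort(unique(sol$track$frame)),
               vapply(sol$series, function(f) f$frame_index, numeric(1)))
  expect_equal(nrow(sol$track), 250 * 4)

  # fluid areas fluctuate frame-to-frame; solid per-cell multipliers are
  # fixed once the imposed profile is divided out
  noise_at <- function(out, t) {
    fr <- out$series[[t]]; tr <- out$truth
    r <- cell_radii(fr)
    fr$cells$area / (tr$A0_true * (1 - tr$k_t[t] * (tr$R_t[t] - r))^2)
  }
  expect_equal(noise_at(sol, 1), noise_at(sol, 4), tolerance = 1e-10)
  a_flu <- sapply(flu$series, function(f) f$cells$area)
  cv_t_flu <- mean(apply(a_flu, 1, sd) / rowMeans(a_flu))
  expect_gt(cv_t_flu, 0.05)
})

test_that("speckle pairs realise the requested displacement field", {
  z <- make_speckle_pair(field_uniform(0, 0), size = 64, seed = 2)
  expect_equal(z$imageA, z$imageB, tolerance = 1e-12)
  z2 <- make_speckle_pair(field_uniform(3, 0), size = 64, seed = 2)
  expect_equal(z2$imageB[10:60, 10:60], z2$imageA[10:60, 7:57],
               tolerance = 1e-12)
  tr <- field_displacement(field_rotation(0.5, center = c(10, 10)),
                           c(10, 20), c(10, 10))
  expect_equal(tr$u[1], 0); expect_equal(tr$v[1], 0)
  expect_equal(tr$v[2], 10 * sin(0.5 * pi / 180), tolerance = 1e-12)
  expect_error(make_speckle_pair(field_uniform(40, 0), size = 64, seed = 1),
               "too large")
})

test_that("division-event generator places poles at the scripted angles", {
  de <- make_division_events(50, coupling_step, seed = 11)
  ang <- vapply(de$events, spindle_angle, numeric(1))
  expect_equal(ang, de$truth$angle_true, tolerance = 1e-9)
  cls <- classify_division(ang)$class
  expect_identical(cls, de$truth$class_true)
  expect_error(make_division_events(0), ">= 1")
  de2 <- make_division_events(50, coupling_step, seed = 11)
  expect_equal(vapply(de2$events, spindle_angle, numeric(1)), ang)
})

test_that("motion tracks hit the target rms speed and caging", {
  mt <- make_motion_tracks("unjammed", v_rms_true = 10, n_cells = 120,
                           n_frames = 100, seed = 2)
  v <- rms_velocity(tracks_to_velocity_fields(mt$track, dt = 1 / 6))
  expect_lt(abs(v - 10) / 10, 0.05)
  mtj <- make_motion_tracks("jammed", v_rms_true = 10, n_cells = 120,
                            n_frames = 100, seed = 2)
  vj <- rms_velocity(tracks_to_velocity_fields(mtj$track, dt = 1 / 6))
  expect_lt(abs(vj - 2) / 2, 0.05)

  # jammed MSD is sub-linear (plateaus); unjammed grows
  msd <- function(track, lag) {
    w <- reshape(as.data.frame(track)[, c("track_id", "frame", "x", "y")],
                 direction = "wide", idvar = "track_id", timevar = "frame")
    xs <- as.matrix(w[, grep("^x", names(w))])
    ys <- as.matrix(w[, grep("^y", names(w))])
    mean((xs[, 1 + lag] - xs[, 1])^2 + (ys[, 1 + lag] - ys[, 1])^2)
  }
  expect_lt(msd(mtj$track, 50) / msd(mtj$track, 5), 2)
  expect_gt(msd(mt$track, 50) / msd(mt$track, 5), 10)
})

test_that("ground truth round-trips through YAML", {
  fx <- make_t1_sequence(1, 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(fx$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$n_t1, 1)
  expect_equal(back$t1_events[[1]]$losing, fx$truth$t1_events[[1]]$losing)
})
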