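test_that("T1 detection matches scripted ground truth", {
  fx <- make_t1_sequence(n_t1 = 2, n_rosette = 0, seed = 1)
  ev <- detect_t1(fx$series, fx$track, L_min = 1.0)
  expect_length(ev, 2L)
  got <- lapply(ev, function(e) list(losing = sort(e$losing),
                                     gaining = sort(e$gaining)))
  want <- lapply(fx$truth$t1_events, function(e) list(
    losing = sort(e$losing), gaining = sort(e$gaining)))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
  # static lattice: no events
  fx0 <- make_t1_sequence(n_t1 = 0, n_rosette = 0, seed = 1)
  expect_length(detect_t1(fx0$series, fx0$track, L_min = 1.0), 0L)
  # time reversal swaps losing and gaining pairs
  rv <- reverse_series(make_t1_sequence(n_t1 = 1, seed = 2))
  ev_r <- detect_t1(rv$series, rv$track, L_min = 1.0)
  expect_length(ev_r, 1L)
  expect_equal(sort(ev_r[[1]]$losing), c(1, 2))
  expect_equal(sort(ev_r[[1]]$gaining), c(3, 4))
  # missing junction graphs are reported
  bare <- fx$series
  bare[[1]]$junction_graph <- NULL
  expect_error(detect_t1(bare, fx$track), "junction graph")
})

test_that("rosette detection keys on vertex multiplicity", {
  expect_length(detect_rosettes(honeycomb_frame(), m_min = 5), 0L)
  fx <- make_t1_sequence(n_t1 = 0, n_rosette = 1, seed = 1, rosette_m = 5)
  ros <- detect_rosettes(fx$series[[1]], m_min = 5)
  expect_length(ros, 1L)
  expect_equal(sort(ros[[1]]$cells), sort(fx$truth$rosettes[[1]]$cells))
  expect_length(detect_rosettes(fx$series[[1]], m_min = 6), 0L)
  expect_error(detect_rosettes(fx$series[[1]], m_min = 3), ">= 4")
})

test_that("new-junction angles to the protrusion direction are acute", {
  fx <- make_t1_sequence(n_t1 = 1, seed = 3)
  ev <- detect_t1(fx$series, fx$track, L_min = 1.0)[[1]]
  # new junction is horizontal in the fixture
  expect_equal(junction_angle_to_protrusion(ev, c(1, 0)), 0,
               tolerance = 1e-9)
  expect_equal(junction_angle_to_protrusion(ev, c(0, 1)), 90,
               tolerance = 1e-9)
  expect_equal(junction_angle_to_protrusion(ev, c(1, 1) / sqrt(2)), 45,
               tolerance = 1e-9)
  expect_error(junction_angle_to_protrusion(ev, c(0, 0)), "zero")
  # estimated protrusion direction is the outward radial unit vector
  fr <- fx$series[[1]]
  d <- protrusion_direction(fr, fr$colony_centroid + c(3, 4))
  expect_equal(d, c(0.6, 0.8), tolerance = 1e-12)
})

test_that("elongation rate recovers affine stretches and ignores rigid motion", {
  set.seed(4)
  p0 <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  stretch <- affine_track(p0, 3, function(p, t) {
    cbind(p[, 1] * exp(0.1 * t), p[, 2])
  })
  expect_equal(elongation_rate(NULL, stretch, c(1, 0), window = 2, dt = 1),
               0.1, tolerance = 1e-6)
  expect_equal(elongation_rate(NULL, stretch, c(0, 1), window = 2, dt = 1),
               0, tolerance = 1e-9)
  # linear in the imposed rate
  stretch2 <- affine_track(p0, 2, function(p, t) {
    cbind(p[, 1] * exp(0.05 * t), p[, 2])
  })
  expect_equal(elongation_rate(NULL, stretch2, c(1, 0), window = 1, dt = 1),
               0.05, tolerance = 1e-6)
  # rigid rotation + translation
  rigid <- affine_track(p0, 2, function(p, t) {
    th <- 0.2 * t
    cbind(cos(th) * p[, 1] - sin(th) * p[, 2] + 3 * t,
          sin(th) * p[, 1] + cos(th) * p[, 2] - t)
  })
  expect_lt(abs(elongation_rate(NULL, rigid, c(1, 0), window = 1, dt = 1)),
            1e-9)
  # rotation superposed on stretch leaves the rate intact
  mix <- affine_track(p0, 2, function(p, t) {
    th <- 0.2 * t
    q <- cbind(p[, 1] * exp(0.1 * t), p[, 2])
    cbind(cos(th) * q[, 1] - sin(th) * q[, 2],
          sin(th) * q[, 1] + cos(th) * q[, 2])
  })
  expect_equal(elongation_rate(NULL, mix, c(1, 0), window = 1, dt = 1),
               0.1, tolerance = 1e-6)
  # collinear configurations are rejected
  line <- affine_track(cbind(1:5, 2 * (1:5)), 2, function(p, t) p)
  expect_error(elongation_rate(NULL, line, c(1, 0), window = 1),
               "degenerate|collinear")
})

test_that("pre-event areas retrieve participants and the size fraction", {
  fx <- make_t1_sequence(n_t1 = 1, n_rosette = 1, seed = 5)
  ev <- c(detect_t1(fx$series, fx$track, L_min = 1.0),
          detect_rosettes(fx$series[[1]], m_min = 5))
  pa <- pre_event_areas(ev, fx$series)
  expect_length(pa$areas, 2L)
  expect_length(pa$areas[[1]], 4L)       # T1 quad
  expect_length(pa$areas[[2]], 5L)       # rosette participants
  # exact retrieval against the frame tables
  fr3 <- fx$series[[3]]
  ids <- c(ev[[1]]$losing, ev[[1]]$gaining)
  expect_equal(pa$areas[[1]],
               fr3$cells$area[match(ids, fr3$cells$cell_id)])
  expect_true(pa$fraction_below_cutoff >= 0 &&
              pa$fraction_below_cutoff <= 1)
  empty <- pre_event_areas(list(), fx$series)
  expect_length(empty$all_areas, 0L)
})
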