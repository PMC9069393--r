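test_that("spindle angles are exact on axis-aligned constructions", {
  ev <- function(p2) division_event(c(0, 0, 0), p2)
  expect_equal(spindle_angle(ev(c(1, 0, 0))), 0)
  expect_equal(spindle_angle(ev(c(0, 0, 1))), 90)
  expect_equal(spindle_angle(ev(c(1, 0, 1))), 45)
  # invariant under pole swap and in-plane rotation
  e1 <- division_event(c(1, 2, 0), c(3, 5, 2))
  e2 <- division_event(c(3, 5, 2), c(1, 2, 0))
  expect_equal(spindle_angle(e1), spindle_angle(e2))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                           0, 0, 1), 3)
  e3 <- division_event(as.numeric(R %*% c(1, 2, 0)),
                       as.numeric(R %*% c(3, 5, 2)))
  expect_equal(spindle_angle(e3), spindle_angle(e1), tolerance = 1e-9)
  expect_error(division_event(c(0, 0, 0), c(0, 0, 0)), "differ")
  expect_error(division_event(c(0, 0, 0), c(1, 0, 0),
                              substrate_normal = c(0, 0, 2)), "unit")
})

test_that("division classes use the 30/60 degree bins, boundary inclusive", {
  cl <- classify_division(c(5, 30, 45, 60, 75))
  expect_identical(cl$class,
                   c("symmetric", "symmetric", "asymmetric", "asymmetric",
                     "asymmetric"))
  expect_identical(cl$subclass,
                   c("parallel", "parallel", "oblique", "oblique",
                     "perpendicular"))
  expect_error(classify_division(91), "\\[0, 90\\]")
})

test_that("deformation ratio and its association with angle behave", {
  expect_equal(deformation_ratio(10, 10), 1)
  expect_equal(deformation_ratio(20, 10), 2)
  set.seed(3)
  tk <- runif(20, 5, 30); wd <- runif(20, 5, 30)
  expect_equal(deformation_ratio(tk, wd), tk / wd)
  expect_error(deformation_ratio(0, 10), "positive")

  # perfectly monotone coupling: rho = +1; reversed: -1
  de <- make_division_events(40, coupling_linear, seed = 2)
  expect_equal(angle_deformation_association(de$events)$rho, 1)
  rev_events <- lapply(de$events, function(e) {
    division_event(e$pole1, e$pole2, thickness = 1 / e$thickness * 100,
                   width = 1 / e$width * 100)
  })
  # inverted deformation ordering flips the sign
  expect_equal(angle_deformation_association(rev_events)$rho, -1)

  # noisy monotone coupling still strongly associated
  den <- make_division_events(200, coupling_linear, seed = 7,
                              angle_noise_sd = 10)
  expect_gt(angle_deformation_association(den$events)$rho, 0.6)

  const <- lapply(1:6, function(i) {
    division_event(c(0, 0, 0), c(1, 0, 0), thickness = 10, width = 10)
  })
  expect_error(angle_deformation_association(const), "constant")
})

test_that("oscillation extent is the mean absolute angular speed", {
  tr <- oscillation_trace(seq(0, 27, by = 3), rep(c(10, -10),
                                                  length.out = 10))
  out <- oscillation_extent(tr)
  expect_equal(out$rate_deg_per_min, 180 / 27)
  expect_equal(out$path_deg, 180)
  # offset invariance; constant trace is zero
  tr2 <- oscillation_trace(seq(0, 27, by = 3),
                           rep(c(10, -10), length.out = 10) + 33)
  expect_equal(oscillation_extent(tr2)$rate_deg_per_min, 180 / 27)
  expect_equal(oscillation_extent(oscillation_trace(0:5,
                                                    rep(4, 6)))$rate_deg_per_min,
               0)
  expect_error(oscillation_trace(c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("divisions CSV reader reconstructs events", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x1,y1,z1,x2,y2,z2,thickness,width",
               "0,0,0,0,1,0,1,12,10"), path)
  ev <- read_divisions_csv(path)
  expect_length(ev, 1L)
  expect_equal(spindle_angle(ev[[1]]), 45)
  expect_equal(deformation_ratio(ev[[1]]$thickness, ev[[1]]$width), 1.2)
})
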