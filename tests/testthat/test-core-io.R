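test_that("cells CSV round trip is lossless and validated", {
  spec <- synth_spec(seed = 0L, n_cells = 40)
  frame <- make_radial_tessellation(spec)$frame
  path <- withr::local_tempfile(fileext = ".csv")
  write_cells_csv(frame, path)
  back <- read_cells_csv(path)
  expect_length(back, 1L)
  for (col in c("frame", "cell_id", "x", "y", "area", "perimeter")) {
    expect_equal(back[[1]]$cells[[col]], frame$cells[[col]],
                 tolerance = 1e-12)
  }

  # two rows, one frame
  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,cell_id,x,y,area,perimeter",
               "0,1,0,0,100,40", "0,2,5,5,100,40"), tiny)
  frames <- read_cells_csv(tiny)
  expect_length(frames, 1L)
  expect_equal(nrow(frames[[1]]$cells), 2L)

  # schema and row-level validation errors
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,cell_id,x,y,area", "0,1,0,0,100"), bad)
  expect_error(read_cells_csv(bad), "perimeter")
  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,cell_id,x,y,area,perimeter",
               "0,1,0,0,100,40", "0,2,5,5,-1,40"), neg)
  expect_error(read_cells_csv(neg), "row 2")
})

test_that("cell-record invariants are enforced", {
  cells <- data.frame(frame = 0L, cell_id = 1:2, x = c(0, 10), y = c(0, 0),
                      area = c(100, 100), perimeter = c(40, 40))
  expect_silent(validate_cells(cells))
  # isoperimetric bound: perimeter < 2 sqrt(pi A)
  cells$perimeter[2] <- 30
  expect_error(validate_cells(cells), "isoperimetric")
  cells$perimeter[2] <- 40
  cells$cell_id[2] <- 1L
  expect_error(validate_cells(cells), "duplicate")
})

test_that("track tables reject inconsistent rows", {
  df <- data.frame(track_id = c(1, 1), frame = c(0, 1), cell_id = c(1, 1),
                   x = 0, y = 0)
  expect_s3_class(track_table(df), "track_table")
  df2 <- df; df2$frame <- c(0, 0); df2$cell_id <- c(1, 2)
  expect_error(track_table(df2), "strictly increasing")
  df3 <- data.frame(track_id = c(1, 2), frame = c(0, 0), cell_id = c(1, 1),
                    x = 0, y = 0)
  expect_error(track_table(df3), "more than one track")
})

test_that("label images convert with the edge-count convention", {
  img <- matrix(0L, 8, 8); img[3:6, 3:6] <- 1L
  fr <- label_image_to_cells(img, pixel_size = 1)
  expect_equal(fr$cells$area, 16)
  expect_equal(fr$cells$perimeter, 16)

  img2 <- matrix(0L, 6, 8); img2[3:4, 2:3] <- 1L; img2[3:4, 4:5] <- 2L
  fr2 <- label_image_to_cells(img2)
  expect_equal(nrow(fr2$junction_graph$edges), 1L)
  expect_equal(fr2$junction_graph$edges$length, 2)

  # pixel-count oracle on a discrete Voronoi labelling
  set.seed(1)
  pts <- cbind(runif(15, 1, 30), runif(15, 1, 30))
  lab <- outer(1:30, 1:30, Vectorize(function(r, cc) {
    which.min((pts[, 2] - r)^2 + (pts[, 1] - cc)^2)
  }))
  fr3 <- label_image_to_cells(lab, pixel_size = 2)
  expect_equal(sum(fr3$cells$area), sum(lab > 0) * 4)

  expect_equal(nrow(label_image_to_cells(matrix(0L, 4, 4))$cells), 0L)
  expect_error(label_image_to_cells(matrix(0.5, 4, 4)), "integer")
})

test_that("junction graphs from polygons have honeycomb topology", {
  fr <- honeycomb_frame()
  jg <- build_junction_graph(fr)
  central <- sum(jg$edges$cell_a == 1 | jg$edges$cell_b == 1)
  expect_equal(central, 6L)
  expect_true(all(vapply(jg$vertex_cells, length, integer(1)) == 3L))
  # halving the merge tolerance on exact geometry changes nothing
  jg2 <- build_junction_graph(fr, tol = 0.125)
  expect_equal(nrow(jg2$edges), nrow(jg$edges))
  expect_equal(sort(jg2$edges$length), sort(jg$edges$length),
               tolerance = 1e-9)
  # disjoint cells share no junctions
  polys <- list(`1` = hex_poly(0, 0, 3), `2` = hex_poly(100, 0, 3))
  cells <- data.frame(frame = 0L, cell_id = 1:2, x = c(0, 100), y = 0,
                      area = sapply(polys, polygon_area),
                      perimeter = sapply(polys, polygon_perimeter))
  fr2 <- tissue_frame(0L, cells, polygons = polys)
  expect_equal(nrow(build_junction_graph(fr2)$edges), 0L)
})

test_that("overlapping polygons raise a geometry error", {
  polys <- list(`1` = hex_poly(0, 0, 3), `2` = hex_poly(1, 0, 3))
  cells <- data.frame(frame = 0L, cell_id = 1:2, x = c(0, 1), y = 0,
                      area = sapply(polys, polygon_area),
                      perimeter = sapply(polys, polygon_perimeter))
  fr <- tissue_frame(0L, cells, polygons = polys)
  expect_error(build_junction_graph(fr), "overlap")
})
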