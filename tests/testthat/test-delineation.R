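test_that("the diagnosis store is append-only with contiguous 1-based indices", {
  st <- diagnosis_store()
  st <- add_diagnosis(st, make_pose(10, 10), make_diag(positive = TRUE))
  expect_equal(nrow(st$records), 1)
  expect_equal(st$records$index, 1L)

  for (i in 2:10) {
    st <- add_diagnosis(st, make_pose(10 * i, 15),
                        make_diag(positive = i %% 2 == 0))
  }
  expect_equal(st$records$index, 1:10)

  expect_warning(st2 <- add_diagnosis(st, make_pose(1, 1, valid = FALSE),
                                      make_diag()),
                 "invalid")
  expect_equal(nrow(st2$records), 10)
})

test_that("a serialized store reproduces the identical delineation", {
  st <- diagnosis_store()
  set.seed(6)
  for (i in 1:8) {
    st <- add_diagnosis(st, make_pose(40 + 30 * runif(1), 40 + 30 * runif(1)),
                        make_diag(positive = i <= 5))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_store_csv(st, path)
  st2 <- read_store_csv(path)
  pos <- function(s) as.matrix(s$records[s$records$positive, c("tipx", "tipy")])
  r1 <- build_boundary(pos(st), 2, 0.5, c(120, 120))
  r2 <- build_boundary(pos(st2), 2, 0.5, c(120, 120))
  expect_identical(r1$mask, r2$mask)
})

test_that("boundary geometry: hull, disk, capsule and nesting", {
  # right triangle with legs 30 and 40: polygon area exactly 600
  tri <- cbind(c(0, 30, 0), c(0, 0, 40))
  res <- build_boundary(tri, margin_mm = 0, mm_per_px = 1,
                        frame_shape = c(60, 60))
  b <- res$boundary
  shoelace <- abs(sum(b[, 1] * c(b[-1, 2], b[1, 2]) -
                      c(b[-1, 1], b[1, 1]) * b[, 2])) / 2
  expect_equal(shoelace, 600, tolerance = 1e-6)

  # single positive at margin 3 mm and 0.5 mm/px: disk of radius 6 px
  disk <- build_boundary(cbind(30, 30), 3, 0.5, c(60, 60))
  expect_equal(sum(disk$mask), pi * 36, tolerance = 0.05 * pi * 36)

  # two positives: a capsule (segment buffered by r)
  cap <- build_boundary(cbind(c(20, 40), c(30, 30)), 3, 0.5, c(60, 60))
  expect_equal(sum(cap$mask), pi * 36 + 20 * 12,
               tolerance = 0.05 * (pi * 36 + 240))

  # no positives: empty result
  none <- build_boundary(cbind(numeric(0), numeric(0)), 3, 0.5, c(60, 60))
  expect_false(any(none$mask))
  expect_null(none$boundary)

  # increasing margins strictly nest
  m0 <- build_boundary(tri + 10, 0, 1, c(60, 60))$mask
  m1 <- build_boundary(tri + 10, 1.5, 1, c(60, 60))$mask
  m2 <- build_boundary(tri + 10, 3, 1, c(60, 60))$mask
  expect_true(all(m1[m0]))
  expect_true(all(m2[m1]))
  expect_gt(sum(m1), sum(m0))
  expect_gt(sum(m2), sum(m1))

  # the tip radius widens the sensed disk
  tip <- build_boundary(cbind(30, 30), 0, 0.5, c(60, 60),
                        tip_diameter_mm = 2.1)
  expect_equal(sum(tip$mask), pi * (2.1 / 2 / 0.5)^2, tolerance = 2)
})

test_that("the boundary depends on the set of positives, not their order", {
  set.seed(3)
  pts <- cbind(runif(12, 20, 80), runif(12, 20, 80))
  a <- build_boundary(pts, 2, 0.5, c(100, 100))
  b <- build_boundary(pts[sample(12), ], 2, 0.5, c(100, 100))
  expect_identical(a$mask, b$mask)
})

test_that("adding a positive point never shrinks the mask", {
  set.seed(13)
  pts <- cbind(runif(6, 30, 60), runif(6, 30, 60))
  base <- build_boundary(pts, 2, 0.5, c(100, 100))$mask
  grown <- build_boundary(rbind(pts, c(80, 80)), 2, 0.5, c(100, 100))$mask
  expect_true(all(grown[base]))
})

test_that("suggested measurement sites ring the boundary at the given spacing", {
  st <- diagnosis_store()
  st <- add_diagnosis(st, make_pose(60, 60, mm_per_px = 0.5), make_diag())
  cand <- suggest_points(st, spacing_mm = 3)
  spacing_px <- 3 / 0.5
  r <- sqrt((cand[, 1] - 60)^2 + (cand[, 2] - 60)^2)
  expect_true(all(abs(r - spacing_px) < 0.1))
  # arc gaps between consecutive candidates approximately equal the spacing
  ang <- sort(atan2(cand[, 2] - 60, cand[, 1] - 60))
  gaps <- diff(c(ang, ang[1] + 2 * pi)) * spacing_px
  expect_true(all(abs(gaps - spacing_px) < 0.35 * spacing_px))
  # every candidate is at least one spacing away from every measurement
  expect_true(all(r >= spacing_px - 1e-6))

  expect_error(suggest_points(st, spacing_mm = 0), "positive")
  empty <- diagnosis_store()
  empty <- add_diagnosis(empty, make_pose(10, 10), make_diag(positive = FALSE))
  expect_equal(nrow(suggest_points(empty, 3)), 0)
})

test_that("overlay rendering draws one square per acquisition, deterministically", {
  frame <- array(0.5, c(100, 140, 3))
  st <- diagnosis_store()
  locs <- cbind(c(20, 60, 100, 120, 40), c(20, 30, 70, 20, 80))
  for (i in 1:5) {
    st <- add_diagnosis(st, make_pose(locs[i, 1], locs[i, 2]),
                        make_diag(positive = i > 2))
  }
  out <- render_overlay(frame, st)
  changed <- apply(abs(out - frame), c(1, 2), max) > 0
  comp <- EBImage::bwlabel(changed * 1)
  expect_equal(max(comp), 5)

  # empty store: passthrough copy
  expect_identical(render_overlay(frame, diagnosis_store()), frame)

  # bit-identical on repeat, boundary included
  res <- build_boundary(locs[3:5, ], 2, 0.5, c(100, 140))
  o1 <- render_overlay(frame, st, res)
  o2 <- render_overlay(frame, st, res)
  expect_identical(o1, o2)
})

test_that("fluorescence thresholding separates signal from noise floor", {
  set.seed(5)
  img <- matrix(abs(rnorm(40 * 60, 0, 0.05)), 40, 60)
  expect_false(any(fluorescence_delineation(img, "fixed", 1)))
  expect_true(all(fluorescence_delineation(img, "fixed", 0)))

  # a bright region is fully recovered by the automatic bimodal threshold
  img2 <- img
  img2[10:30, 20:40] <- img2[10:30, 20:40] + 4
  auto <- fluorescence_delineation(img2, "auto")
  expect_gte(mean(auto[10:30, 20:40]), 0.95)
  expect_lt(mean(auto[-(10:30), ]), 0.05)

  flat <- matrix(1, 10, 10)
  expect_error(fluorescence_delineation(flat, "auto"), "flat")
  expect_error(fluorescence_delineation(img, "fixed"), "threshold_value")
})
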