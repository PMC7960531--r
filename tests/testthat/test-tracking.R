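test_that("calibration from seed pixels recovers marker centroids", {
  setup <- small_tracking_setup(n_frames = 2)
  vid <- generate_probe_video(setup$scene, setup$video)
  tr <- vid$truth[1, ]
  frame <- vid$frames[[1]]
  specs <- calibrate_hsv(frame, list(proximal = c(tr$mx1, tr$my1),
                                     distal = c(tr$mx2, tr$my2)))
  expect_named(specs, c("proximal", "distal"))
  seg <- segment_markers(frame, specs)
  expect_true(all(seg$found))
  expect_lt(abs(seg$cx[seg$name == "proximal"] - tr$mx1), 1)
  expect_lt(abs(seg$cy[seg$name == "proximal"] - tr$my1), 1)
  expect_lt(abs(seg$cx[seg$name == "distal"] - tr$mx2), 1)
  expect_lt(abs(seg$cy[seg$name == "distal"] - tr$my2), 1)

  # calibration is deterministic
  specs2 <- calibrate_hsv(frame, list(proximal = c(tr$mx1, tr$my1),
                                      distal = c(tr$mx2, tr$my2)))
  expect_identical(specs, specs2)

  # a seed on the gray background has no usable saturation
  expect_error(calibrate_hsv(frame, list(proximal = c(5, 5),
                                         distal = c(tr$mx2, tr$my2))),
               "low-saturation")

  # two seeds in the same marker give indistinguishable hue windows
  expect_error(calibrate_hsv(frame, list(proximal = c(tr$mx1, tr$my1),
                                         distal = c(tr$mx1, tr$my1))),
               "overlap")
})

test_that("segmentation handles hue wrap-around across 0 degrees", {
  frame <- array(0.5, c(60, 80, 3))
  frame[, , 2:3] <- 0.5
  # disk with hue 2 degrees, nearly pure red
  col <- as.numeric(grDevices::col2rgb(grDevices::hsv(2 / 360, 1, 1))) / 255
  for (ch in 1:3) {
    xs <- matrix(1:80, 60, 80, byrow = TRUE)
    ys <- matrix(1:60, 60, 80)
    inside <- sqrt((xs - 40)^2 + (ys - 30)^2) <= 6
    patch <- frame[, , ch]
    patch[inside] <- col[ch]
    frame[, , ch] <- patch
  }
  spec <- marker_spec("red", hue_center = 359, hue_tol = 10, min_area_px = 10)
  seg <- segment_markers(frame, list(spec))
  expect_true(seg$found)
  expect_lt(abs(seg$cx - 40), 0.5)
  expect_lt(abs(seg$cy - 30), 0.5)
})

test_that("occluded frames miss both markers", {
  setup <- small_tracking_setup(n_frames = 3, occluded_frames = 2L)
  vid <- generate_probe_video(setup$scene, setup$video)
  specs <- calibrated_specs(vid)
  seg <- segment_markers(vid$frames[[2]], specs)
  expect_false(any(seg$found))
})

test_that("the ratiometric tip formula and its equivariances hold", {
  geom <- probe_geometry(marker_separation_mm = 20, tip_offset_mm = 30)
  pose <- estimate_tip(c(100, 100), c(140, 100), geom)
  expect_true(pose$valid)
  expect_equal(pose$tip_px, c(200, 100))
  expect_equal(pose$mm_per_px, 0.5)
  expect_equal(pose$angle_rad, 0)

  # zero offset puts the tip on the distal marker
  geom0 <- probe_geometry(20, 0)
  expect_equal(estimate_tip(c(100, 100), c(140, 100), geom0)$tip_px,
               c(140, 100))

  # rotation equivariance: rotate the marker pair, the tip rotates with it
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ctr <- c(100, 100)
  rot <- function(p) as.numeric(R %*% (p - ctr) + ctr)
  pose_r <- estimate_tip(rot(c(100, 100)), rot(c(140, 100)), geom)
  expect_equal(pose_r$tip_px, rot(c(200, 100)), tolerance = 1e-9)
  expect_equal(pose_r$mm_per_px, 0.5, tolerance = 1e-12)

  # translation + uniform scaling: tip follows, mm_per_px rescales inversely
  sc <- 2; shift <- c(13, -7)
  pose_s <- estimate_tip(c(100, 100) * sc + shift, c(140, 100) * sc + shift, geom)
  expect_equal(pose_s$tip_px, c(200, 100) * sc + shift, tolerance = 1e-9)
  expect_equal(pose_s$mm_per_px, 0.5 / sc, tolerance = 1e-12)

  expect_false(estimate_tip(c(5, 5), c(5, 5), geom)$valid)
  expect_false(estimate_tip(c(NA, NA), c(140, 100), geom)$valid)
})

test_that("video tracking is per-frame independent with misses as invalid rows", {
  setup <- small_tracking_setup(n_frames = 6, occluded_frames = 3L)
  vid <- generate_probe_video(setup$scene, setup$video)
  specs <- calibrated_specs(vid)
  poses <- track_video(vid$frames, specs, setup$geom)
  expect_equal(nrow(poses), 6)
  expect_false(poses$valid[3])
  expect_true(all(poses$valid[-3]))

  # reversing the frame order reverses the pose table exactly
  rev_poses <- track_video(rev(vid$frames), specs, setup$geom)
  expect_equal(rev_poses[, -1], poses[rev(seq_len(6)), -1],
               ignore_attr = TRUE)

  expect_error(track_video(list(), specs, setup$geom), "no frames")
})
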