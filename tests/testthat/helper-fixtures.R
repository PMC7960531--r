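# Shared fixtures built in code: small scenes/videos keep unit tests fast;
# the full-size study conditions live in the acceptance tests.

# a compact scene + video whose marker chain stays well inside the frame
small_tracking_setup <- function(n_frames = 8L, occluded_frames = integer(0)) {
  scene <- elliptical_lesion_scene(320, 240, mm_per_px = 1,
                                   semi_axes = c(60, 45))
  t <- seq(0, 2 * pi, length.out = n_frames)
  trajectory <- data.frame(
    x = 200 + 40 * sin(t),
    y = 130 + 30 * sin(2 * t),
    angle = pi / 5 + 0.4 * sin(t)
  )
  video <- video_gen_spec(n_frames = n_frames,
                          marker_separation_mm = 30,
                          tip_offset_mm = 40,
                          trajectory = trajectory,
                          occluded_frames = occluded_frames)
  geom <- probe_geometry(marker_separation_mm = 30, tip_offset_mm = 40)
  list(scene = scene, video = video, geom = geom)
}

calibrated_specs <- function(vid) {
  tr <- vid$truth[which(!vid$truth$occluded)[1], ]
  frame <- vid$frames[[tr$frame]]
  calibrate_hsv(frame, list(proximal = c(tr$mx1, tr$my1),
                            distal = c(tr$mx2, tr$my2)))
}

# dense reference solve of the asymmetric penalized least-squares system,
# mirroring the banded implementation step for step
dense_whittaker_oracle <- function(y, lambda, p, iters, diff_order) {
  n <- length(y)
  D <- diag(n)
  for (d in seq_len(diff_order)) D <- diff(D)
  P <- lambda * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  as.numeric(z)
}

# first PLS latent variables by brute-force eigen-decomposition with
# deflation: weight = leading eigenvector of X'YY'X
eigen_pls_oracle <- function(X, Y, ncomp) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  scores <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    M <- t(X) %*% Y %*% t(Y) %*% X
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t_h <- X %*% w
    p_h <- t(X) %*% t_h / sum(t_h^2)
    q_h <- t(Y) %*% t_h / sum(t_h^2)
    X <- X - t_h %*% t(p_h)
    Y <- Y - t_h %*% t(q_h)
    scores[, h] <- t_h
  }
  scores
}

make_pose <- function(x, y, mm_per_px = 0.5, valid = TRUE) {
  structure(list(proximal_px = c(NA, NA), distal_px = c(NA, NA),
                 tip_px = c(x, y), angle_rad = 0, mm_per_px = mm_per_px,
                 valid = valid),
            class = "probe_pose")
}

make_diag <- function(label = "phantom", positive = TRUE, score = 0.9) {
  structure(list(label = label,
                 scores = stats::setNames(score, label),
                 positive = positive),
            class = "diagnosis")
}
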