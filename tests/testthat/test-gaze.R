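# gaze: head calibration, pose recovery, horizon correction, marker-label
# repair, ray projection, dome density

test_that("head calibration: keypoints, beak direction, equivariance", {
  fx <- head_fixture()
  cal <- calibrate_head(fx$markers, fx$eye_l, fx$eye_r, fx$beak)
  # eye midpoint is the origin; in head coordinates the beak lies on +y
  expect_lt(max(abs(cal$keypoints["eye_left", ] - c(-0.01, 0, 0))), 1e-12)
  beak_dir <- cal$keypoints["beak_tip", ] /
    sqrt(sum(cal$keypoints["beak_tip", ]^2))
  expect_equal(as.numeric(beak_dir), c(0, 1, 0), tolerance = 1e-9)
  # the head y axis expressed in the calibration frame is the normalized
  # beak vector before horizon correction: (0, 2, -1)/sqrt(5)
  obs0 <- array(fx$markers, c(1, 4, 3))
  obs0[1, , ] <- fx$markers
  hp0 <- head_poses(obs0, cal)
  R0 <- arenatrack:::quat_to_rotmat(c(hp0$qw[1], hp0$qx[1], hp0$qy[1],
                                      hp0$qz[1]))
  expect_equal(as.numeric(R0[, 2]), c(0, 2, -1) / sqrt(5),
               tolerance = 1e-9)
  # a rigid motion of every calibration input leaves the calibration fixed
  set.seed(6)
  R <- arenatrack:::random_rotation(); t <- stats::rnorm(3)
  mv <- function(p) as.numeric(R %*% p + t)
  cal2 <- calibrate_head(moved_markers(fx$markers, R, t),
                         mv(fx$eye_l), mv(fx$eye_r), mv(fx$beak))
  expect_lt(max(abs(cal$marker_template - cal2$marker_template)), 1e-9)
  expect_error(calibrate_head(cbind(1:4, 2 * (1:4), 3 * (1:4)),
                              fx$eye_l, fx$eye_r, fx$beak), "collinear")
  expect_error(calibrate_head(fx$markers, c(-0.01, 0, 0), c(0.01, 0, 0),
                              c(0.05, 0, 0)), "eye axis")
})

test_that("pose recovery reproduces a known rigid motion", {
  fx <- head_fixture()
  cal <- calibrate_head(fx$markers, fx$eye_l, fx$eye_r, fx$beak)
  yaw <- 0.3; pitch <- -0.5; roll <- 0.1
  R <- arenatrack:::rotmat_from_ypr(yaw, pitch, roll)
  t <- c(1, 2, 0.5)
  obs <- array(NA_real_, c(3, nrow(cal$marker_template), 3))
  for (f in 1:3) obs[f, , ] <- moved_markers(cal$marker_template, R, t)
  hp <- head_poses(obs, cal, time_s = c(0, 0.01, 0.02))
  expect_equal(hp$yaw[1], yaw, tolerance = 1e-9)
  expect_equal(hp$pitch[1], pitch, tolerance = 1e-9)
  expect_equal(hp$roll[1], roll, tolerance = 1e-9)
  expect_equal(c(hp$x[1], hp$y[1], hp$z[1]), t, tolerance = 1e-9)
  # self-consistency: applying the pose to the template reproduces markers
  Rq <- arenatrack:::quat_to_rotmat(c(hp$qw[1], hp$qx[1], hp$qy[1],
                                      hp$qz[1]))
  rec <- cal$marker_template %*% t(Rq) +
    rep(c(hp$x[1], hp$y[1], hp$z[1]), each = 4)
  expect_lt(max(abs(rec - obs[1, , ])), 1e-9)
  # orthonormal right-handed frame at every pose
  expect_lt(max(abs(crossprod(Rq) - diag(3))), 1e-9)
  expect_equal(det(Rq), 1, tolerance = 1e-9)
})

test_that("horizon correction zeroes median roll/pitch and keeps yaw", {
  fx <- head_fixture()
  cal <- calibrate_head(fx$markers, fx$eye_l, fx$eye_r, fx$beak)
  yaws <- seq(-1, 1, length.out = 11)
  obs <- array(NA_real_, c(11, 4, 3))
  for (f in 1:11) {
    R <- arenatrack:::rotmat_from_ypr(yaws[f], arenatrack:::deg2rad(-30),
                                      arenatrack:::deg2rad(5))
    obs[f, , ] <- moved_markers(cal$marker_template, R, c(0, 0, 0.3))
  }
  hp <- head_poses(obs, cal)
  cor <- horizon_correction(hp)
  expect_lt(max(abs(cor$roll)), 1e-9)       # constant roll 5 deg -> 0
  expect_lt(max(abs(cor$pitch)), 1e-9)      # constant pitch -30 deg -> 0
  expect_equal(cor$yaw, hp$yaw)
  expect_equal(stats::median(cor$roll), 0)
  expect_equal(stats::median(cor$pitch), 0)
  expect_equal(attr(cor, "median_pitch"), arenatrack:::deg2rad(-30),
               tolerance = 1e-9)
})

test_that("marker-label repair inverts injected swaps and is idempotent", {
  mk <- swap_markers()
  set.seed(13)
  nf <- 300
  truth <- array(NA_real_, c(nf, 4, 3))
  for (f in seq_len(nf)) {
    truth[f, , ] <- mk + 1e-4 * matrix(stats::rnorm(12), 4, 3)
  }
  swapped <- truth
  swapped[100:200, c(1, 2), ] <- swapped[100:200, c(2, 1), ]
  rep1 <- repair_marker_labels(swapped)
  expect_identical(max(abs(rep1 - truth)), 0)
  expect_identical(attr(rep1, "unrepairable"), integer(0))
  # clean track: identity permutation everywhere, no boundaries
  clean <- repair_marker_labels(truth)
  expect_identical(max(abs(clean - truth)), 0)
  expect_identical(attr(clean, "boundaries"), integer(0))
  # idempotence
  rep2 <- repair_marker_labels(structure(as.array(rep1)))
  expect_identical(max(abs(rep2 - truth)), 0)
  # genuinely deforming body is flagged unrepairable
  grow <- truth
  for (f in 150:nf) grow[f, 1, ] <- grow[f, 1, ] * (1 + 0.5 * (f - 149))
  bad <- repair_marker_labels(grow)
  expect_gt(length(attr(bad, "unrepairable")), 0)
  expect_error(repair_marker_labels(array(0, c(10, 7, 3))), "at most 6")
})

test_that("gaze rays: identity pose, yaw equivariance, mirror symmetry", {
  idp <- list(x = 0, y = 0, z = 0, qw = 1, qx = 0, qy = 0, qz = 0)
  g <- project_gaze(idp, include_red_area = FALSE)
  right <- as.numeric(g[g$specialization == "right_fovea",
                        c("dx", "dy", "dz")])
  expect_equal(right, c(sin(arenatrack:::deg2rad(75)),
                        cos(arenatrack:::deg2rad(75)), 0),
               tolerance = 1e-12)
  left <- as.numeric(g[g$specialization == "left_fovea",
                       c("dx", "dy", "dz")])
  # left/right foveas mirror in the sagittal (y-z) plane
  expect_equal(left, right * c(-1, 1, 1), tolerance = 1e-12)
  # yawing the head 90 deg right rotates rays exactly 90 deg about z
  Ry90 <- arenatrack:::rotmat_from_ypr(-pi / 2, 0, 0)
  q <- arenatrack:::rotmat_to_quat(Ry90)
  g2 <- project_gaze(list(x = 0, y = 0, z = 0, qw = q[1], qx = q[2],
                          qy = q[3], qz = q[4]), include_red_area = FALSE)
  right2 <- as.numeric(g2[g2$specialization == "right_fovea",
                          c("dx", "dy", "dz")])
  expect_equal(right2, as.numeric(Ry90 %*% right), tolerance = 1e-12)
  # red area stays in the frontal-lower sector of the head frame
  g3 <- project_gaze(idp)
  red <- g3[g3$specialization == "red_area", ]
  expect_true(all(red$dz <= 1e-12))
})

test_that("dome density: binning, exclusions and mass conservation", {
  ray <- function(o, d) data.frame(specialization = "right_fovea",
                                   x = o[1], y = o[2], z = o[3],
                                   dx = d[1], dy = d[2], dz = d[3])
  # single ray from the centroid at elevation 47, azimuth 85 -> one bin
  el47 <- arenatrack:::deg2rad(47); az85 <- arenatrack:::deg2rad(85)
  d47 <- c(sin(az85) * cos(el47), cos(az85) * cos(el47), sin(el47))
  H <- dome_density(ray(c(0, 0, 0), d47), c(0, 0, 0))
  expect_identical(sum(H), 1L)
  hit <- which(H == 1L, arr.ind = TRUE)
  expect_identical(attr(H, "az_breaks_deg")[hit[1]], 80)
  expect_identical(attr(H, "el_breaks_deg")[hit[2]], 45)
  # horizontal ray from the centroid is below the 15 deg band
  H2 <- dome_density(ray(c(0, 0, 0), c(0, 1, 0)), c(0, 0, 0))
  expect_identical(sum(H2), 0L)
  expect_identical(attr(H2, "excluded_below"), 1L)
  # off-center origin: sphere-intersection oracle gives ~60 deg elevation
  H3 <- dome_density(ray(c(5, 0, 0), c(0, 0, 1)), c(0, 0, 0))
  hit3 <- which(H3 == 1L, arr.ind = TRUE)
  el_lo <- attr(H3, "el_breaks_deg")[hit3[2]]
  expect_true(el_lo <= 60 && 60 <= el_lo + 5)
  # origin outside the dome is excluded but counted
  H4 <- dome_density(ray(c(30, 0, 0), c(0, 0, 1)), c(0, 0, 0))
  expect_identical(attr(H4, "excluded_outside"), 1L)
  # mass conservation over a random bundle
  set.seed(3)
  rays <- do.call(rbind, lapply(1:200, function(i) {
    ray(stats::rnorm(3, 0, 3), stats::rnorm(3))
  }))
  H5 <- dome_density(rays, c(0, 0, 0))
  expect_identical(sum(H5) + attr(H5, "excluded_below") +
                     attr(H5, "excluded_outside"), 200L)
})

test_that("whole-scene rotation shifts the dome histogram azimuthally", {
  set.seed(8)
  origins <- matrix(stats::rnorm(60, 0, 2), 20, 3)
  dirs <- matrix(stats::rnorm(60), 20, 3)
  dirs[, 3] <- abs(dirs[, 3]) + 1          # aim upward
  mk_rays <- function(o, d) data.frame(specialization = "right_fovea",
                                       x = o[, 1], y = o[, 2], z = o[, 3],
                                       dx = d[, 1], dy = d[, 2],
                                       dz = d[, 3])
  H <- dome_density(mk_rays(origins, dirs), c(0, 0, 0),
                    az_breaks_deg = seq(0, 360, by = 30))
  Rz <- arenatrack:::rot_z(-arenatrack:::deg2rad(30))  # +30 deg azimuth
  H2 <- dome_density(mk_rays(origins %*% t(Rz), dirs %*% t(Rz)), c(0, 0, 0),
                     az_breaks_deg = seq(0, 360, by = 30))
  shifted <- H[c(12, 1:11), ]
  expect_equal(H2, shifted, ignore_attr = TRUE)
})
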