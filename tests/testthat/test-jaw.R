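test_that("strand kinematics: length, line of action, via points", {
  s <- list(origin = c(0, 0, 0), insertion = c(0, 0, 10), f_max = 10)
  k <- strand_kinematics(s, jaw_pose())
  expect_equal(k$length, 10)
  expect_equal(k$u_origin, c(0, 0, 1))
  expect_equal(k$u_insertion, c(0, 0, -1))
  # a via point off-axis strictly lengthens the path (triangle inequality)
  s2 <- list(origin = c(0, 0, 0), insertion = c(0, 0, 10),
             via = rbind(c(3, 0, 5)), f_max = 10)
  expect_gt(strand_kinematics(s2, jaw_pose())$length, 10)
  # coincident consecutive points error
  s3 <- list(origin = c(1, 1, 1), insertion = c(1, 1, 1), f_max = 1)
  expect_error(strand_kinematics(s3, jaw_pose()), "degenerate")
})

test_that("strand length is invariant under rigid transform of the model", {
  rot <- function(p, R, d) as.numeric(R %*% p + d)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d <- c(5, -3, 2)
  s <- list(origin = c(1, 2, 3), insertion = c(4, -1, 7),
            via = rbind(c(2, 2, 5)), f_max = 1)
  pose <- jaw_pose(gape_deg = 9, side = "R", centre = c(0, 10, 2))
  L1 <- strand_kinematics(s, pose)$length
  # transform every defining point and the pose centre/rotation
  s2 <- list(origin = rot(s$origin, R, d),
             insertion = rot(apply_pose(pose, s$insertion), R, d),
             via = matrix(rot(s$via[1, ], R, d), 1), f_max = 1)
  L2 <- strand_kinematics(s2, jaw_pose())$length
  expect_equal(L1, L2, tolerance = 1e-12)
})

test_that("passive tension is zero at slack, monotone, and capped at 0.1%", {
  s <- list(f_max = 100, L0 = 20, p_cap = 0.001, k = 3, s_max = 0.05)
  expect_identical(passive_tension(s, 20), 0)
  expect_identical(passive_tension(s, 15), 0) # below slack
  # at (and beyond) the cap strain the force is exactly p_cap * F_max
  expect_equal(passive_tension(s, 20 * 1.05), 0.1)
  expect_equal(passive_tension(s, 20 * 1.2), 0.1)
  # monotone non-decreasing in between
  L <- seq(20, 21.2, by = 0.01)
  tp <- passive_tension(s, L)
  expect_true(all(diff(tp) >= -1e-15))
  expect_true(all(tp >= 0 & tp <= 0.1 + 1e-15))
  # mid-range values are strictly between 0 and the cap and increase
  expect_gt(passive_tension(s, 20.4), 0)
  expect_lt(passive_tension(s, 20.4), passive_tension(s, 20.8))
})

test_that("required load vanishes for a static closed jaw and matches lever
           statics under a bolus", {
  jaw <- small_jaw()
  spec <- bite_cycle_spec("incisor", tooth = "incisor", side = "R")
  expect_equal(inverse_required_load(jaw, spec, 0), rep(0, 6))
  # full compression: vertical bolus resistance R_v acting at the bite
  # point => required sagittal muscle moment = R_v * anteroposterior arm
  t_end <- spec$t_open + spec$t_fast + spec$t_slow
  req <- inverse_required_load(jaw, spec, t_end)
  tip <- jaw$teeth[jaw$teeth$tooth == "incisor" & jaw$teeth$side == "R", ]
  arm <- abs(tip$y - jaw$centre[2])
  expect_equal(abs(req[4]), spec$R_v * arm, tolerance = 1e-9)
  expect_equal(req[3], spec$R_v, tolerance = 1e-12) # vertical force
})

test_that("quasi-static and dynamic required loads agree on slow cycles", {
  jaw <- small_jaw()
  slow <- bite_cycle_spec("molar", tooth = "cheek1", side = "R",
                          t_open = 2.4, t_fast = 1.6, t_slow = 3, dt = 0.1)
  for (t in c(1.2, 3.2, 5.5)) {
    qs <- inverse_required_load(jaw, slow, t, dynamic = FALSE)
    dy <- inverse_required_load(jaw, slow, t, dynamic = TRUE)
    scale <- max(1, max(abs(qs)))
    expect_lt(max(abs(dy - qs)) / scale, 0.01)
  }
})
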