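test_that("molar cycle reaches the prescribed gape and excursion", {
  traj <- fixture("molar_traj_default", function()
    simulate_bite_cycle(small_jaw(),
                        bite_cycle_spec("molar", tooth = "cheek1",
                                        side = "R")))
  expect_equal(max(traj$gape_deg[traj$phase == "opening"]), 12,
               tolerance = 0.1 / 12)
  expect_equal(max(traj$excursion_deg[traj$phase == "fast_close"]), 5.5,
               tolerance = 0.1 / 5.5)
  # back to the midline at the end of the slow closing phase
  expect_equal(traj$excursion_deg[length(traj$time)], 0, tolerance = 1e-12)
  # bite force rises during slow close and overcomes the 30 N bolus
  expect_gte(max(traj$bite_force), 30)
})

test_that("incisor cycle stays mirror-symmetric throughout", {
  jaw <- small_jaw()
  traj <- simulate_bite_cycle(jaw, bite_cycle_spec("incisor",
                                                   tooth = "incisor",
                                                   side = "R", dt = 0.01))
  expect_true(all(traj$excursion_deg == 0))
  # mirrored strand pairs carry equal activations at every step
  iL <- grep("_L_", jaw$strands$id)
  iR <- match(gsub("_L_", "_R_", jaw$strands$id[iL]), jaw$strands$id)
  expect_lt(max(abs(traj$activation[, iL] - traj$activation[, iR])), 1e-7)
})

test_that("mandible force balance closes at the snapshot", {
  jaw <- small_jaw()
  traj <- fixture("molar_traj_default", function()
    simulate_bite_cycle(jaw, bite_cycle_spec("molar", tooth = "cheek1",
                                             side = "R")))
  it <- which.max(traj$bite_force)
  pose <- traj$poses[[it]]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  Fm <- c(0, 0, 0); Mm <- c(0, 0, 0)
  for (i in seq_len(nrow(jaw$strands))) {
    kin <- strand_kinematics(as.list(jaw$strands[i, ]), pose)
    f <- traj$strand_force[it, i] * kin$u_insertion
    Fm <- Fm + f
    Mm <- Mm + cross3(kin$path[nrow(kin$path), ] - jaw$centre, f)
  }
  tip <- jaw$teeth[jaw$teeth$tooth == "cheek1" & jaw$teeth$side == "R", ]
  Fb <- -traj$bite_force_vec[it, ]
  Mb <- cross3(c(tip$x, tip$y, tip$z) - jaw$centre, Fb)
  rw <- jaw$tmj_right - jaw$centre; rb <- jaw$tmj_left - jaw$centre
  Mt <- cross3(rw, traj$tmj_working[it, ]) +
    cross3(rb, traj$tmj_balancing[it, ])
  resid <- c(Fm + Fb + traj$tmj_working[it, ] + traj$tmj_balancing[it, ],
             Mm + Mb + Mt)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("load regime snapshot is taken at maximum bite force", {
  jaw <- small_jaw()
  traj <- simulate_bite_cycle(jaw, bite_cycle_spec("incisor",
                                                   tooth = "incisor",
                                                   side = "R", dt = 0.01))
  reg <- extract_load_regime(traj)
  # monotone-rising incisor bite force: snapshot at the final instant
  expect_equal(reg$snapshot_time, traj$time[length(traj$time)])
  expect_equal(reg$bite_force, 30)
  # every strand force at least its passive tension, at most F_max + cap
  it <- which.max(traj$bite_force)
  expect_true(all(reg$force_mag >= traj$passive[it, ] - 1e-12))
  expect_true(all(reg$force_mag <=
                    jaw$strands$f_max * (1 + jaw$strands$p_cap) + 1e-9))
})

test_that("regime reflection is an involution preserving magnitudes", {
  regs <- small_regimes()
  back <- reflect_load_regime(regs$L)
  expect_identical(back, regs$R)
  expect_identical(regs$L$bite_force, regs$R$bite_force)
  expect_identical(sqrt(rowSums(regs$L$force^2)),
                   sqrt(rowSums(regs$R$force^2)))
  expect_identical(regs$L$side, "L")
  # strand ids remap left/right consistently with the phantom landmarks
  ph <- small_phantom()
  expect_true(all(paste0("origin_", gsub("_R_", "_L_", regs$R$strand_id))
                  %in% names(ph$node_sets)))
})

test_that("simulating a left bite equals reflecting the right-side result", {
  jaw <- small_jaw()
  trajL <- simulate_bite_cycle(jaw, bite_cycle_spec("molar",
                                                    tooth = "cheek1",
                                                    side = "L", dt = 0.01))
  regL <- extract_load_regime(trajL)
  refl <- reflect_load_regime(small_regimes()$R)
  i1 <- order(refl$strand_id); i2 <- order(regL$strand_id)
  expect_lt(max(abs(refl$force[i1, ] - regL$force[i2, ])), 1e-6)
  expect_equal(refl$bite_force, regL$bite_force, tolerance = 1e-9)
})

test_that("regime enumeration yields two regimes per bite point", {
  jaw <- small_jaw() # 1 incisor + 1 cheek tooth per side
  regs <- fixture("enum_regs", function()
    enumerate_bite_regimes(jaw, list(dt = 0.01)))
  expect_length(regs, 4L)
  expect_false(anyDuplicated(names(regs)) > 0)
  modes <- vapply(regs, `[[`, "", "mode")
  expect_identical(sum(modes == "incisor"), 2L)
  expect_identical(sum(modes == "molar"), 2L)
  # stable ids across runs with the same configuration
  regs2 <- enumerate_bite_regimes(jaw, list(dt = 0.01))
  expect_identical(names(regs2), names(regs))
})

test_that("bite cycle specification validates its invariants", {
  expect_error(bite_cycle_spec("incisor", excursion_deg = 3), "symmetric")
  expect_error(bite_cycle_spec("molar", excursion_deg = 0), "positive")
  expect_error(bite_cycle_spec("molar", t_open = 0), "positive")
  s <- bite_cycle_spec("incisor", tooth = "incisor")
  expect_identical(s$excursion_deg, 0)
  expect_identical(s$R_ml, 0)
  m <- bite_cycle_spec("molar")
  expect_identical(m$gape_deg, 12)
  expect_identical(m$excursion_deg, 5.5)
  expect_identical(m$R_v, 30)
  expect_identical(m$R_ml, 30)
})
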