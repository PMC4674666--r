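test_that("blunt pole metrics reproduce closed-form cases", {
  expect_equal(blunt_pole_distance(c(3, 4), c(0, 0)), 5)
  expect_equal(blunt_pole_distance(c(7, 2), c(7, 2)), 0)

  # image coordinates, y down; angles counter-clockwise in the y-up frame
  expect_equal(blunt_pole_angle(c(1, 0), c(0, 0)), 0)
  expect_equal(blunt_pole_angle(c(0, 0), c(0, 1)), 90)   # above center on screen
  expect_equal(blunt_pole_angle(c(0, 1), c(0, 0)), 270)  # below center on screen
  expect_error(blunt_pole_angle(c(5, 5), c(5, 5)), "coincides")

  expect_equal(blunt_pole_orientation(c(0, 5), c(0, 0)), 90)
  expect_equal(blunt_pole_orientation(c(1, 0), c(0, 1)), 45)
  # axial symmetry: swapping the poles changes nothing
  expect_equal(blunt_pole_orientation(c(3, 9), c(11, 2)),
               blunt_pole_orientation(c(11, 2), c(3, 9)))
  expect_error(blunt_pole_orientation(c(2, 2), c(2, 2)), "zero-length")
  expect_error(blunt_pole_distance(c(NA, 1), c(0, 0)), "finite")
})

test_that("metrics agree with an independent complex-arithmetic oracle", {
  set.seed(101)
  for (rep in 1:100) {
    obs <- random_clutch(n_eggs = sample(2:5, 1))
    e <- obs$eggs
    for (i in seq_len(nrow(e))) {
      b <- c(e$blunt_x[i], e$blunt_y[i]); s <- c(e$sharp_x[i], e$sharp_y[i])
      expect_equal(blunt_pole_distance(b, obs$center), o_dist(b, obs$center),
                   tolerance = 1e-9)
      expect_equal(blunt_pole_angle(b, obs$center), o_angle(b, obs$center),
                   tolerance = 1e-9)
      expect_equal(blunt_pole_orientation(b, s), o_orient(b, s),
                   tolerance = 1e-9)
    }
    expect_equal(adjacent_angles(obs), o_adjacent(obs), tolerance = 1e-9)
  }
})

test_that("adjacent angles close the ring and handle degenerate clutches", {
  # two parallel eggs -> both adjacent angles zero
  par2 <- clutch_observation(
    "p", "before", c(50, 50),
    data.frame(egg_id = c("a", "b"), blunt_x = c(30, 70), blunt_y = c(50, 50),
               sharp_x = c(30, 70), sharp_y = c(60, 60), is_model_egg = FALSE))
  expect_equal(unname(adjacent_angles(par2)), c(0, 0))

  # two perpendicular eggs -> both 90
  perp2 <- clutch_observation(
    "q", "before", c(50, 50),
    data.frame(egg_id = c("a", "b"), blunt_x = c(30, 70), blunt_y = c(50, 50),
               sharp_x = c(30, 80), sharp_y = c(60, 50), is_model_egg = FALSE))
  expect_equal(unname(adjacent_angles(perp2)), c(90, 90))

  set.seed(7)
  for (rep in 1:25) {
    obs <- random_clutch(n_eggs = sample(3:5, 1))
    adj <- adjacent_angles(obs)
    expect_length(adj, nrow(obs$eggs))
    expect_true(all(adj >= 0 & adj < 180))
    # signed cyclic axial differences telescope to 0 mod 180
    resid <- sum(adj) %% 180
    expect_lt(min(resid, 180 - resid), 1e-8)
  }

  one <- random_clutch(n_eggs = 1)
  expect_error(adjacent_angles(one), "at least 2")
})

test_that("change scores are zero on identity and |delta|/sqrt(2) on shifts", {
  set.seed(11)
  obs <- random_clutch(n_eggs = 5)
  after <- obs; after$phase <- "after"
  ch <- arrangement_change(obs, after)
  expect_equal(ch$sd_blunt_pole_distance, 0)
  expect_equal(ch$sd_blunt_pole_angle, 0)
  expect_equal(ch$sd_blunt_pole_orientation, 0)
  expect_equal(ch$sd_adjacent_angle, 0)

  # single egg whose blunt pole distance goes 10 -> 20 px along the same ray
  mk <- function(d) clutch_observation(
    "n1", "before", c(50, 50),
    data.frame(egg_id = "e1", blunt_x = 50 + d, blunt_y = 50,
               sharp_x = 50 + d + 15, sharp_y = 50, is_model_egg = FALSE))
  b <- mk(10); a <- mk(20); a$phase <- "after"
  ch <- arrangement_change(b, a)
  expect_equal(ch$sd_blunt_pole_distance, 10 / sqrt(2), tolerance = 1e-12)
  expect_equal(ch$sd_blunt_pole_angle, 0)

  # two-point circular SDs agree with the unit-vector oracle
  set.seed(12)
  for (rep in 1:50) {
    b <- random_clutch(n_eggs = 3)
    a <- random_clutch(n_eggs = 3); a$phase <- "after"
    ch <- arrangement_change(b, a)
    ang_b <- sapply(1:3, function(i)
      o_angle(c(b$eggs$blunt_x[i], b$eggs$blunt_y[i]), b$center))
    ang_a <- sapply(1:3, function(i)
      o_angle(c(a$eggs$blunt_x[i], a$eggs$blunt_y[i]), a$center))
    expect_equal(ch$sd_blunt_pole_angle,
                 mean(mapply(o_circ_sd2, ang_b, ang_a, period = 360)),
                 tolerance = 1e-9)
  }
})

test_that("change scores respect translation, scaling and reference invariance", {
  set.seed(21)
  b <- random_clutch(n_eggs = 4)
  a <- random_clutch(n_eggs = 4); a$phase <- "after"
  base <- arrangement_change(b, a)

  # common translation of both observations changes nothing
  sh <- arrangement_change(transform_obs(b, shift = c(13, -7)),
                           transform_obs(a, shift = c(13, -7)))
  expect_equal(sh[-1], base[-1], tolerance = 1e-9, ignore_attr = TRUE)

  # uniform scaling scales the distance score linearly, leaves angles alone
  sc <- arrangement_change(transform_obs(b, scale = 2.5),
                           transform_obs(a, scale = 2.5))
  expect_equal(sc$sd_blunt_pole_distance, 2.5 * base$sd_blunt_pole_distance,
               tolerance = 1e-9)
  expect_equal(sc$sd_blunt_pole_angle, base$sd_blunt_pole_angle, tolerance = 1e-9)
  expect_equal(sc$sd_blunt_pole_orientation, base$sd_blunt_pole_orientation,
               tolerance = 1e-9)

  # relabeling the 0-degree reference (common rotation about the center)
  rt <- arrangement_change(transform_obs(b, rotate_deg = 33),
                           transform_obs(a, rotate_deg = 33))
  expect_equal(rt[-1], base[-1], tolerance = 1e-6, ignore_attr = TRUE)

  # rotating only the after clutch leaves the distance score untouched
  a_id <- b; a_id$phase <- "after"
  rot_after <- arrangement_change(b, transform_obs(a_id, rotate_deg = 40))
  expect_equal(rot_after$sd_blunt_pole_distance, 0, tolerance = 1e-9)
  expect_gt(rot_after$sd_blunt_pole_angle, 0)
})

test_that("pairing excludes the model egg and survives relabelled ids", {
  set.seed(31)
  g <- generator_config()
  b <- generate_clutch(g, 4, seed = 500)
  a <- apply_treatment(b, "constant", g, seed = 501)
  expect_identical(sum(a$eggs$is_model_egg), 1L)
  ch <- arrangement_change(b, a)
  expect_true(all(unlist(ch[-1]) >= 0))

  # nearest-centroid pairing: scramble after ids, scores unchanged
  a2 <- a
  a2$eggs$egg_id <- paste0("x", seq_len(nrow(a2$eggs)))
  ch2 <- arrangement_change(b, a2)
  expect_equal(ch2[-1], ch[-1], tolerance = 1e-9, ignore_attr = TRUE)

  # count mismatch after model-egg exclusion is a pairing error
  a3 <- a
  a3$eggs <- a3$eggs[-1, ]
  expect_error(arrangement_change(b, a3), "cannot pair")
})
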