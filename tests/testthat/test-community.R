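test_that("shading attenuates light linearly by taller cover", {
  # no taller plants: floor light unchanged
  expect_equal(shaded_light(c(1.0, 0.5), c(0.5, 0.5), 0.4)[1], 0.4)
  # fully covered by taller plants at s = 0.75: 0.4 * 0.25 = 0.1
  expect_equal(shaded_light(c(0.1, 1.0), c(0, 1), 0.4, s = 0.75)[1], 0.1)
  # equal heights do not shade each other
  expect_equal(shaded_light(c(0.5, 0.5), c(0.7, 0.3), 0.4), c(0.4, 0.4))
  # result clipped to [floor_light * (1 - s), floor_light]
  li <- shaded_light(c(0.1, 0.5, 1.8), c(0.4, 0.4, 0.2), 0.3, s = 0.9)
  expect_true(all(li >= 0.3 * 0.1 - 1e-12 & li <= 0.3 + 1e-12))
})

test_that("light_at_height resolves a species within the community", {
  tbl <- recovery_true_table()
  covers <- stats::setNames(rep(1 / 6, 6), tbl$name)
  li <- light_at_height("sp_sub1", covers, tbl, floor_light = 0.2)
  taller <- sum(covers[tbl$shading_height_m > tbl$shading_height_m[tbl$name == "sp_sub1"]])
  expect_equal(li, 0.2 * (1 - 0.75 * taller))
  expect_error(light_at_height("nope", covers, tbl, 0.2), "not in table")
})

test_that("strength is suitability, optionally sharpened", {
  expect_equal(plant_strength(0), 0)
  expect_equal(plant_strength(1), 1)
  expect_equal(plant_strength(c(0.2, 0.4)), c(0.2, 0.4))
  expect_equal(plant_strength(0.5, gamma = 2), 0.25)
})

test_that("cover assignment is proportional normalization", {
  expect_equal(as.numeric(assign_relative_cover(rep(2, 4))), rep(0.25, 4))
  expect_equal(as.numeric(assign_relative_cover(c(2, 1, 1))), c(0.5, 0.25, 0.25))
  # a zero-strength species receives zero cover
  z <- assign_relative_cover(c(0, 1))
  expect_equal(as.numeric(z), c(0, 1))
  allzero <- assign_relative_cover(c(0, 0))
  expect_false(attr(allzero, "viable"))
  expect_equal(as.numeric(allzero), c(0, 0))
  expect_error(assign_relative_cover(c(-1, 1)), "finite")
})

test_that("step_community interpolates between state and target", {
  tbl <- recovery_true_table()[1:2, ]
  tbl <- species_table(as.data.frame(tbl))
  series <- constant_drivers(2001)
  covers <- stats::setNames(c(1, 0), tbl$name)
  half <- step_community(covers, tbl, series, 2001, 6, lambda = 0.5)
  full <- step_community(covers, tbl, series, 2001, 6, lambda = 1)
  expect_equal(sum(half), 1)
  expect_equal(half, 0.5 * covers + 0.5 * full, tolerance = 1e-12)
})

test_that("single species holds full cover; identical species split evenly", {
  one <- species_table(data.frame(
    name = "only", ph_opt = 4.3, ph_var = 1, n_opt = 1, n_var = 6,
    moisture_opt = 0.6, moisture_var = 0.08, light_opt = 0.15, light_var = 0.08,
    tmin = 0, tmax = 30, rooting_depth_m = 0.2, shading_height_m = 0.3))
  series <- constant_drivers(2001:2002)
  traj <- simulate_community(one, series)
  expect_true(all(traj$cover == 1))

  twin <- species_table(data.frame(
    name = c("a", "b"), ph_opt = 4.3, ph_var = 1, n_opt = 1, n_var = 6,
    moisture_opt = 0.6, moisture_var = 0.08, light_opt = 0.15, light_var = 0.08,
    tmin = 0, tmax = 30, rooting_depth_m = 0.2, shading_height_m = 0.3))
  expect_equal(as.numeric(covers_at(simulate_community(twin, series))),
               c(0.5, 0.5), tolerance = 1e-9)
})

test_that("with s = 0 and identical niches, covers equalize despite heights", {
  tbl <- species_table(data.frame(
    name = c("short", "mid", "tall"), ph_opt = 4.3, ph_var = 1, n_opt = 1,
    n_var = 6, moisture_opt = 0.6, moisture_var = 0.08, light_opt = 0.15,
    light_var = 0.08, tmin = 0, tmax = 30, rooting_depth_m = 0.2,
    shading_height_m = c(0.05, 0.5, 1.8)))
  series <- constant_drivers(2001)
  expect_equal(as.numeric(covers_at(simulate_community(tbl, series, s = 0))),
               rep(1 / 3, 3), tolerance = 1e-9)
  # with shading on, the taller identical species gains
  cv <- covers_at(simulate_community(tbl, series, s = 0.75))
  expect_gt(cv["tall"], cv["short"])
})

test_that("stationarity under constant drivers", {
  tbl <- recovery_true_table()
  series <- constant_drivers(2001:2003)
  traj <- simulate_community(tbl, series)
  y1 <- covers_at(traj, 2001)
  y3 <- covers_at(traj, 2003)
  expect_equal(y1, y3, tolerance = 1e-4)
})

test_that("non-viable communities are flagged rather than erroring", {
  tbl <- recovery_true_table()
  tbl$tmin <- 25; tbl$tmax <- 30   # window excludes all soil temperatures
  series <- constant_drivers(2001, temperature = 10)
  traj <- simulate_community(tbl, series)
  expect_true(all(traj$cover == 0))
})

test_that("model property suite holds over 100 random tables and drivers", {
  # covers normalized every year, covers within [0,1], fixed point
  # converges, and the trajectory is deterministic in the seed
  for (seed in 1:100) {
    tbl <- random_species_table(seed, n = 4)
    series <- generate_synthetic_drivers(synthetic_driver_config(
      years = 2001:2002, seed = seed))
    traj <- simulate_community(tbl, series)
    conv <- attr(traj, "convergence")
    expect_true(all(conv$converged))
    sums <- tapply(traj$cover, traj$year, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(traj$cover >= 0 & traj$cover <= 1))
  }
})

test_that("removing a species releases its competitors (light-limited regime)", {
  # Sampled light optima all exceed the forest-floor light level, so
  # every species is light-limited (more light always helps). Release
  # is checked where it is an exact consequence of the model: removing
  # any species under pure resource competition (s = 0), and removing
  # the top of the shading hierarchy with shading on. (Removing a
  # short species with shading on can marginally increase the shade on
  # mid-height species through the growth of taller survivors.)
  for (seed in 1:30) {
    tbl <- random_species_table(seed, n = 5, light_min_class = 2)
    series <- constant_drivers(2001)

    full0 <- covers_at(simulate_community(tbl, series, s = 0))
    drop0 <- (seed %% 5) + 1
    reduced0 <- species_table(as.data.frame(tbl)[-drop0, ])
    part0 <- covers_at(simulate_community(reduced0, series, s = 0))
    expect_true(all(part0 >= full0[names(part0)] - 1e-9))

    full <- covers_at(simulate_community(tbl, series))
    drop <- which.max(tbl$shading_height_m)
    reduced <- species_table(as.data.frame(tbl)[-drop, ])
    part <- covers_at(simulate_community(reduced, series))
    expect_true(all(part >= full[names(part)] - 1e-9))
  }
})
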