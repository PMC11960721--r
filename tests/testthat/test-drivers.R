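test_that("driver CSV round-trips losslessly", {
  series <- generate_synthetic_drivers(synthetic_driver_config(
    years = 2001:2002, seed = 3))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_drivers(series, tmp)
  back <- read_drivers(tmp, attr(series, "profile"))
  expect_equal(as.data.frame(back), as.data.frame(series), tolerance = 1e-12)
})

test_that("driver schema violations are reported with field and row", {
  series <- generate_synthetic_drivers(synthetic_driver_config(
    years = 2001, seed = 3))
  prof <- attr(series, "profile")
  df <- as.data.frame(series)

  bad <- df
  bad$moisture_frac[5] <- 1.2
  expect_error(driver_series(bad, prof), "moisture_frac.*row 5")

  bad <- df
  bad$N_mgL[2] <- -1
  expect_error(driver_series(bad, prof), "N_mgL")

  expect_error(driver_series(df[0, ], prof), "no records")
  expect_error(driver_series(df[, -4], prof), "missing columns")

  gap <- df[!(df$month == 6), ]
  expect_error(driver_series(gap, prof), "consecutive")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("year,month,layer,pH,N_mgL,moisture_frac,soil_temp_C,floor_light_frac",
             tmp)
  expect_error(read_drivers(tmp, prof), "no records")
})

test_that("root-zone aggregation is a thickness-weighted mean", {
  prof <- soil_profile(c("O", "B"), c(0, 0.2), c(0.2, 0.4))
  df <- expand.grid(month = 1:12, year = 2001, layer = c("O", "B"))
  df$pH <- ifelse(df$layer == "O", 4, 5)
  df$N_mgL <- ifelse(df$layer == "O", 4, 6)
  df$moisture_frac <- 0.5
  df$soil_temp_C <- 10
  df$floor_light_frac <- 0.2
  series <- driver_series(df, prof)

  # two equally thick layers, rooting depth spanning both
  env <- aggregate_root_zone(series, 0.4, 2001, 6)
  expect_equal(env[["N"]], 5)
  # rooting depth inside the first layer returns that layer's values
  env1 <- aggregate_root_zone(series, 0.1, 2001, 6)
  expect_equal(env1[["pH"]], 4)
  expect_equal(env1[["N"]], 4)
  # deepest-layer mode
  envd <- aggregate_root_zone(series, 0.4, 2001, 6, method = "deepest")
  expect_equal(envd[["pH"]], 5)
  # depth beyond the profile bottom clamps with a warning
  expect_warning(envc <- aggregate_root_zone(series, 2, 2001, 6), "clamped")
  expect_equal(envc[["pH"]], (4 * 0.2 + 5 * 0.2) / 0.4)

  # 0.1 m at pH 4 over 0.3 m at pH 5, rooted to 0.4 m -> 4.75
  prof2 <- soil_profile(c("O", "B"), c(0, 0.1), c(0.1, 0.4))
  df$layer <- rep(c("O", "B"), each = 12)
  df$pH <- ifelse(df$layer == "O", 4, 5)
  series2 <- driver_series(df, prof2)
  expect_equal(aggregate_root_zone(series2, 0.4, 2001, 6)[["pH"]], 4.75)
})

test_that("aggregation stays within the layer value range", {
  series <- generate_synthetic_drivers(synthetic_driver_config(
    years = 2001, seed = 11))
  withr::with_seed(5, {
    for (rep in 1:25) {
      m <- sample(12, 1)
      rd <- runif(1, 0.01, 0.8)
      env <- aggregate_root_zone(series, rd, 2001, m)
      sub <- series[series$year == 2001 & series$month == m, ]
      expect_gte(env[["pH"]] + 1e-12, min(sub$pH))
      expect_lte(env[["pH"]] - 1e-12, max(sub$pH))
      expect_gte(env[["N"]] + 1e-12, min(sub$N_mgL))
      expect_lte(env[["N"]] - 1e-12, max(sub$N_mgL))
    }
  })
})

test_that("synthetic generator is deterministic and respects ranges", {
  cfg <- synthetic_driver_config(years = 1991:2000, seed = 99)
  a <- generate_synthetic_drivers(cfg)
  b <- generate_synthetic_drivers(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # the caller's RNG stream is not consumed
  withr::with_seed(1, x1 <- runif(1))
  withr::with_seed(1, {
    invisible(generate_synthetic_drivers(cfg))
    x2 <- runif(1)
  })
  expect_identical(x1, x2)

  withr::with_seed(8, {
    for (rep in 1:20) {
      cfg2 <- synthetic_driver_config(
        years = 2001:2004,
        pH = list(baseline = runif(1, 3.5, 6), amplitude = runif(1, 0, 0.3),
                  trend_decade = runif(1, -0.2, 0.2), noise = runif(1, 0, 0.3),
                  depth_gradient = runif(1, 0, 1)),
        N = list(baseline = runif(1, 0.2, 5), amplitude = runif(1, 0, 1),
                 trend_decade = runif(1, -0.5, 0.5), noise = runif(1, 0, 0.5),
                 depth_gradient = runif(1, -1, 1)),
        moisture = list(baseline = runif(1, 0.2, 0.8), amplitude = runif(1, -0.3, 0.3),
                        trend_decade = 0, noise = runif(1, 0, 0.2),
                        depth_gradient = runif(1, -0.2, 0.2)),
        temperature = list(baseline = runif(1, 2, 10), amplitude = runif(1, 0, 10),
                           trend_decade = runif(1, 0, 0.5), noise = runif(1, 0, 2),
                           depth_gradient = 0),
        light = list(baseline = runif(1, 0.05, 0.9), amplitude = runif(1, -0.2, 0.2),
                     trend_decade = 0, noise = runif(1, 0, 0.3),
                     depth_gradient = 0),
        seed = sample.int(1e6, 1))
      s <- generate_synthetic_drivers(cfg2)
      expect_true(all(s$moisture_frac >= 0 & s$moisture_frac <= 1))
      expect_true(all(s$floor_light_frac >= 0 & s$floor_light_frac <= 1))
      expect_true(all(s$N_mgL >= 0))
    }
  })
})

test_that("degenerate configuration yields a constant series", {
  s <- constant_drivers(years = 2001, pH = 4.5)
  expect_true(all(s$pH == 4.5))
  expect_true(all(s$floor_light_frac == 0.15))
})

test_that("linear trend shifts the span mean by trend * decades / 2", {
  dec <- 3
  cfg <- synthetic_driver_config(
    years = 2001:(2001 + dec * 10 - 1),
    pH = list(baseline = 5, amplitude = 0, trend_decade = 0.2, noise = 0,
              depth_gradient = 0),
    N = list(baseline = 1, amplitude = 0, trend_decade = 0, noise = 0,
             depth_gradient = 0),
    moisture = list(baseline = 0.5, amplitude = 0, trend_decade = 0, noise = 0,
                    depth_gradient = 0),
    temperature = list(baseline = 8, amplitude = 0, trend_decade = 0, noise = 0,
                       depth_gradient = 0),
    light = list(baseline = 0.2, amplitude = 0, trend_decade = 0, noise = 0,
                 depth_gradient = 0),
    seed = 1)
  s <- generate_synthetic_drivers(cfg)
  expect_equal(mean(s$pH), 5 + 0.2 * dec / 2, tolerance = 0.01)
})
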