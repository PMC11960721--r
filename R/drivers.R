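#' Define a soil profile
#'
#' Ordered, contiguous, non-overlapping soil layers. The number of
#' layers and their depths are user data (a podzol might use O, A, E,
#' Bhs, Bs1, Bs2, Bs3, Cd; the synthetic default uses three layers).
#'
#' @param layer character vector of layer labels, top to bottom.
#' @param top_m,bottom_m numeric vectors of layer boundary depths in m
#'   below the surface; `top_m[1]` must be 0 and each layer must start
#'   where the previous one ends.
#' @return a `soil_profile` data.frame.
#' @export
soil_profile <- function(layer, top_m, bottom_m) {
  if (length(layer) < 1L) stop("need at least one layer", call. = FALSE)
  if (anyDuplicated(layer)) stop("duplicate layer labels", call. = FALSE)
  if (length(top_m) != length(layer) || length(bottom_m) != length(layer)) {
    stop("layer, top_m and bottom_m must have equal length", call. = FALSE)
  }
  if (top_m[1] != 0) stop("first layer must start at depth 0", call. = FALSE)
  if (any(bottom_m <= top_m)) stop("each layer needs bottom_m > top_m", call. = FALSE)
  if (length(layer) > 1L && any(abs(top_m[-1] - bottom_m[-length(bottom_m)]) > 1e-9)) {
    stop("layers must be contiguous (each top equals previous bottom)", call. = FALSE)
  }
  structure(data.frame(layer = as.character(layer), top_m = top_m,
                       bottom_m = bottom_m, stringsAsFactors = FALSE),
            class = c("soil_profile", "data.frame"))
}

driver_cols <- c("year", "month", "layer", "pH", "N_mgL", "moisture_frac",
                 "soil_temp_C", "floor_light_frac")

#' Assemble and validate a monthly driver series
#'
#' A driver series is a long-format `data.frame` with one row per
#' (year, month, soil layer) holding soil-solution pH, N concentration
#' (mg/L), moisture saturation fraction, soil temperature (degrees C)
#' and the fraction of above-canopy light reaching the forest floor
#' (`floor_light_frac`, repeated across the layer rows of a month).
#' Months must be strictly increasing with no gaps and identical across
#' layers.
#'
#' @param df a `data.frame` with columns `year`, `month`, `layer`,
#'   `pH`, `N_mgL`, `moisture_frac`, `soil_temp_C`, `floor_light_frac`.
#' @param profile the [soil_profile()] the layer labels refer to.
#' @return a `driver_series` (the validated data.frame with the profile
#'   attached as an attribute).
#' @export
driver_series <- function(df, profile) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(driver_cols, names(df))
  if (length(missing)) {
    stop("driver table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no records", call. = FALSE)
  bad <- which(df$moisture_frac < 0 | df$moisture_frac > 1)
  if (length(bad)) {
    stop(sprintf("moisture_frac out of [0, 1] at row %d (value %g)",
                 bad[1], df$moisture_frac[bad[1]]), call. = FALSE)
  }
  bad <- which(df$floor_light_frac < 0 | df$floor_light_frac > 1)
  if (length(bad)) {
    stop(sprintf("floor_light_frac out of [0, 1] at row %d (value %g)",
                 bad[1], df$floor_light_frac[bad[1]]), call. = FALSE)
  }
  bad <- which(df$N_mgL < 0)
  if (length(bad)) {
    stop(sprintf("N_mgL negative at row %d (value %g)", bad[1], df$N_mgL[bad[1]]),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$layer), profile$layer)
  if (length(unknown)) {
    stop("driver layers not in profile: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- df$year * 12 + df$month
  for (lay in unique(df$layer)) {
    li <- sort(idx[df$layer == lay])
    if (length(li) > 1L && any(diff(li) != 1L)) {
      stop(sprintf("time stamps for layer '%s' must be consecutive months", lay),
           call. = FALSE)
    }
  }
  df <- df[order(idx, match(df$layer, profile$layer)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("driver_series", "data.frame"), profile = profile)
}

#' Read a monthly driver series from CSV
#'
#' The CSV must carry a header with the columns documented in
#' [driver_series()]; layer depths are supplied through `profile` (they
#' are a property of the site, not of each record).
#'
#' @param path path to the CSV file.
#' @param profile a [soil_profile()].
#' @return a `driver_series`.
#' @export
read_drivers <- function(path, profile) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  driver_series(df, profile)
}

#' Write a driver series to CSV
#'
#' `write_drivers()` then [read_drivers()] reproduces the series
#' exactly (values are written in full precision).
#'
#' @param series a `driver_series`.
#' @param path output path.
#' @export
write_drivers <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate drivers over a species' root zone
#'
#' A species' rooting depth gives it access to the soil layers between
#' the surface and that depth. The default aggregation is the
#' thickness-weighted mean of each driver over the intersected layers
#' (a partially reached layer contributes its intersected thickness);
#' `method = "deepest"` instead returns the values of the deepest
#' reached layer. Rooting depths below the profile bottom are clamped
#' to the bottom with a warning.
#'
#' @param series a `driver_series`.
#' @param rooting_depth_m rooting depth in m, `> 0`.
#' @param year,month the month to aggregate.
#' @param method `"weighted"` (default) or `"deepest"`.
#' @param profile soil profile; defaults to the one attached to
#'   `series`.
#' @return named numeric vector with elements `pH`, `N`, `moisture`,
#'   `temperature`, `light`.
#' @export
aggregate_root_zone <- function(series, rooting_depth_m, year, month,
                                method = c("weighted", "deepest"),
                                profile = attr(series, "profile")) {
  method <- match.arg(method)
  if (!is.numeric(rooting_depth_m) || rooting_depth_m <= 0) {
    stop("'rooting_depth_m' must be > 0", call. = FALSE)
  }
  sub <- series[series$year == year & series$month == month, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no driver records for year %d month %d", year, month),
         call. = FALSE)
  }
  bottom <- max(profile$bottom_m)
  if (rooting_depth_m > bottom + 1e-9) {
    warning(sprintf("rooting depth %.2f m exceeds profile bottom %.2f m; clamped",
                    rooting_depth_m, bottom))
    rooting_depth_m <- bottom
  }
  sub <- sub[match(profile$layer, sub$layer), , drop = FALSE]
  w <- pmax(0, pmin(profile$bottom_m, rooting_depth_m) - profile$top_m)
  if (method == "deepest") {
    w <- as.numeric(seq_along(w) == max(which(w > 0)))
  }
  w <- w / sum(w)
  c(pH = sum(w * sub$pH),
    N = sum(w * sub$N_mgL),
    moisture = sum(w * sub$moisture_frac),
    temperature = sum(w * sub$soil_temp_C),
    light = sub$floor_light_frac[1])
}

#' Configuration for the synthetic driver generator
#'
#' Each driver gets a baseline, a seasonal (sinusoidal) amplitude, a
#' linear trend per decade and a noise scale; see
#' [generate_synthetic_drivers()] for how they combine. Defaults
#' emulate a multi-decadal monthly record for an acidified northern
#' hardwood forest soil: acid soil solution slowly recovering (pH
#' trending up, N trending down), a marked soil-temperature seasonal
#' cycle damped with depth, wetter conditions in spring/fall, and a
#' closed-canopy forest floor receiving about 15 % of above-canopy
#' light.
#'
#' @param years integer vector of simulation years (calendar years).
#' @param profile a [soil_profile()]; the default has three layers
#'   (organic, upper B, lower B) to 0.8 m.
#' @param pH,N,moisture,temperature,light per-driver parameter lists
#'   with elements `baseline`, `amplitude`, `trend_decade`, `noise`
#'   (noise is a standard deviation: additive for pH, temperature,
#'   moisture and light, multiplicative lognormal for the N
#'   concentration so it stays non-negative), and `depth_gradient`
#'   (units per m of layer-midpoint depth) for the three soil-solution
#'   drivers.
#' @param seed integer seed; the same configuration and seed always
#'   yield the identical series.
#' @return a `synthetic_driver_config` list.
#' @export
synthetic_driver_config <- function(
    years = 1981:2010,
    profile = soil_profile(c("O", "B1", "B2"), c(0, 0.1, 0.4), c(0.1, 0.4, 0.8)),
    pH = list(baseline = 4.2, amplitude = 0.1, trend_decade = 0.05,
              noise = 0.08, depth_gradient = 0.6),
    N = list(baseline = 1.2, amplitude = 0.5, trend_decade = -0.1,
             noise = 0.25, depth_gradient = -0.8),
    moisture = list(baseline = 0.6, amplitude = -0.15, trend_decade = 0,
                    noise = 0.04, depth_gradient = 0.15),
    temperature = list(baseline = 6, amplitude = 8, trend_decade = 0.2,
                       noise = 0.8, depth_gradient = 0),
    light = list(baseline = 0.15, amplitude = 0.05, trend_decade = 0,
                 noise = 0.015, depth_gradient = 0),
    seed = 1L) {
  cfg <- list(years = years, profile = profile, pH = pH, N = N,
              moisture = moisture, temperature = temperature, light = light,
              seed = as.integer(seed))
  for (d in c("pH", "N", "moisture", "temperature", "light")) {
    if (cfg[[d]]$noise < 0) stop("noise scale must be >= 0", call. = FALSE)
  }
  if (length(years) < 1L) stop("span must cover at least one year", call. = FALSE)
  structure(cfg, class = "synthetic_driver_config")
}

#' Generate a synthetic monthly driver series
#'
#' Stands in for the monthly output of a biogeochemical forest soil
#' simulator. For every driver the monthly value is
#' `baseline + amplitude * sin(2 pi (month - 4) / 12) + trend_decade *
#' elapsed_decades + noise`, evaluated per soil layer with a
#' depth-gradient offset on the soil-solution drivers and the seasonal
#' temperature amplitude damped exponentially with layer-midpoint
#' depth (e-folding 0.5 m). The sine phase peaks in July; a negative
#' amplitude (the moisture default) yields a late-summer minimum. Noise
#' is additive Gaussian except for the N concentration, which gets
#' multiplicative lognormal noise so concentrations stay non-negative
#' and right-skewed. Fractions are clipped to [0, 1] and N to `>= 0`
#' after summing the terms. Identical configuration and seed give a
#' bit-identical series; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_driver_config()].
#' @return a `driver_series`.
#' @export
generate_synthetic_drivers <- function(config = synthetic_driver_config()) {
  stopifnot(inherits(config, "synthetic_driver_config"))
  prof <- config$profile
  months <- expand.grid(month = 1:12, year = config$years)
  nm <- nrow(months)
  elapsed_dec <- ((months$year - config$years[1]) * 12 + months$month - 1) / 120
  season <- sin(2 * pi * (months$month - 4) / 12)
  mid <- (prof$top_m + prof$bottom_m) / 2

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  base_term <- function(p, damp_season = 1) {
    p$baseline + p$amplitude * damp_season * season +
      p$trend_decade * elapsed_dec
  }

  light_cfg <- config$light
  light <- base_term(light_cfg) + stats::rnorm(nm, 0, light_cfg$noise)
  light <- pmin(1, pmax(0, light))

  rows <- lapply(seq_len(nrow(prof)), function(i) {
    ph_cfg <- config$pH; n_cfg <- config$N
    mo_cfg <- config$moisture; te_cfg <- config$temperature
    ph <- base_term(ph_cfg) + ph_cfg$depth_gradient * mid[i] +
      stats::rnorm(nm, 0, ph_cfg$noise)
    n_det <- pmax(0, base_term(n_cfg) + n_cfg$depth_gradient * mid[i])
    n <- if (n_cfg$noise > 0) {
      n_det * stats::rlnorm(nm, -n_cfg$noise^2 / 2, n_cfg$noise)
    } else n_det
    moist <- base_term(mo_cfg) + mo_cfg$depth_gradient * mid[i] +
      stats::rnorm(nm, 0, mo_cfg$noise)
    temp <- base_term(te_cfg, damp_season = exp(-mid[i] / 0.5)) +
      stats::rnorm(nm, 0, te_cfg$noise)
    data.frame(year = months$year, month = months$month, layer = prof$layer[i],
               pH = ph, N_mgL = pmax(0, n),
               moisture_frac = pmin(1, pmax(0, moist)),
               soil_temp_C = temp, floor_light_frac = light,
               stringsAsFactors = FALSE)
  })
  driver_series(do.call(rbind, rows), prof)
}
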