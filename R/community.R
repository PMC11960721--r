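#' Light available to each species after shading
#'
#' Taller plants shade shorter ones: the light available to a species
#' is the forest-floor light attenuated linearly by the summed cover of
#' all strictly taller plants, `floor_light * (1 - s * C_taller)`, with
#' shading efficiency `s` in \[0, 1\] (default 0.75). Species of equal
#' shading height do not shade each other, so the attenuation is
#' symmetric and order-independent, and the result is clipped to
#' `[floor_light * (1 - s), floor_light]`.
#'
#' @param heights numeric vector of shading heights (m), one per
#'   species.
#' @param covers numeric vector of relative covers (same order,
#'   summing to at most 1).
#' @param floor_light fraction of above-canopy light reaching the
#'   forest floor, in \[0, 1\].
#' @param s shading efficiency in \[0, 1\].
#' @return numeric vector of per-species available light fractions.
#' @export
shaded_light <- function(heights, covers, floor_light, s = 0.75) {
  if (floor_light < 0 || floor_light > 1) {
    stop("'floor_light' must lie in [0, 1]", call. = FALSE)
  }
  if (s < 0 || s > 1) stop("'s' must lie in [0, 1]", call. = FALSE)
  taller <- vapply(heights, function(h) sum(covers[heights > h]), numeric(1))
  pmin(floor_light, pmax(floor_light * (1 - s), floor_light * (1 - s * taller)))
}

#' Light available to one species within a community state
#'
#' Convenience wrapper around [shaded_light()] for a single species.
#'
#' @param species species name (must be present in `table`).
#' @param covers named numeric vector of current relative covers.
#' @param table a `veg_table`.
#' @inheritParams shaded_light
#' @return available light fraction for `species`.
#' @export
light_at_height <- function(species, covers, table, floor_light, s = 0.75) {
  i <- match(species, table$name)
  if (is.na(i)) stop(sprintf("species '%s' not in table", species), call. = FALSE)
  shaded_light(table$shading_height_m, covers[table$name], floor_light, s)[i]
}

#' Competitive strength from suitability
#'
#' The strength with which a plant competes for cover is its site
#' suitability (computed with the shaded light as the light driver, so
#' the shading-height advantage is already inside), optionally
#' sharpened by an exponent `gamma` (`strength = suitability^gamma`,
#' default 1, the identity).
#'
#' @param suitability suitability values in \[0, 1\].
#' @param gamma dominance exponent, `> 0`.
#' @return non-negative strengths.
#' @export
plant_strength <- function(suitability, gamma = 1) {
  if (gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  if (any(suitability < 0)) stop("suitability must be >= 0", call. = FALSE)
  suitability^gamma
}

#' Assign relative covers proportional to strength
#'
#' Each species receives `strength_i / sum(strength)` of the surface,
#' so covers are normalized over the modeled species (no explicit bare
#' ground). When every strength is zero no species is viable: the
#' all-zero cover vector is returned with attribute `viable = FALSE`
#' rather than raising a division error.
#'
#' @param strengths non-negative numeric vector (named by species if
#'   available).
#' @return cover fractions summing to 1 (or to 0 in the non-viable
#'   case).
#' @export
assign_relative_cover <- function(strengths) {
  if (any(strengths < 0) || any(!is.finite(strengths))) {
    stop("strengths must be finite and >= 0", call. = FALSE)
  }
  tot <- sum(strengths)
  if (tot == 0) {
    return(structure(strengths, viable = FALSE))
  }
  structure(strengths / tot, viable = TRUE)
}

# Strengths of all species for one month, given current covers.
month_strengths <- function(table, series, year, month, covers,
                            s = 0.75, gamma = 1, method = "weighted") {
  envs <- lapply(table$rooting_depth_m, function(rd)
    aggregate_root_zone(series, rd, year, month, method = method))
  floor_light <- envs[[1]][["light"]]
  avail <- shaded_light(table$shading_height_m, covers, floor_light, s)
  suit <- vapply(seq_len(nrow(table)), function(i) {
    site_suitability(table[i, ], envs[[i]], envs[[i]][["temperature"]], avail[i])
  }, numeric(1))
  plant_strength(suit, gamma)
}

#' Advance a community by one month
#'
#' Computes target covers from the current month's strengths (light
#' attenuation evaluated against the current state) and moves the
#' community a fraction `lambda` of the way there:
#' `new = (1 - lambda) * old + lambda * target`, renormalized.
#' `lambda = 1` is instantaneous replacement.
#'
#' @param covers named numeric vector of current covers (summing to 1).
#' @param table a `veg_table`.
#' @param series a `driver_series`.
#' @param year,month the month to step through.
#' @param lambda inertia parameter in (0, 1].
#' @param s shading efficiency.
#' @param gamma dominance exponent.
#' @return updated named cover vector.
#' @export
step_community <- function(covers, table, series, year, month, lambda = 1,
                           s = 0.75, gamma = 1) {
  if (lambda <= 0 || lambda > 1) stop("'lambda' must lie in (0, 1]", call. = FALSE)
  st <- month_strengths(table, series, year, month, covers, s = s, gamma = gamma)
  target <- assign_relative_cover(st)
  new <- (1 - lambda) * covers + lambda * target
  tot <- sum(new)
  if (tot > 0) new <- new / tot
  stats::setNames(as.numeric(new), table$name)
}

#' Simulate annual community composition
#'
#' For every simulated year, per-species suitabilities are computed for
#' each month of the growing season (default May-September) and
#' averaged before the strength computation; single-date relevés are
#' compared against these annual covers, and sub-annual compositional
#' dynamics are deliberately not resolved. Because the light each
#' species receives depends on the covers being solved for, the
#' within-year state is found by damped fixed-point iteration (damping
#' 0.5, convergence when the largest cover change drops below `tol`,
#' at most `max_iter` sweeps); non-convergence is flagged, and the last
#' iterate kept, with a warning. Across years the community carries
#' inertia `lambda`: the new annual state is
#' `(1 - lambda) * previous + lambda * fixed point`.
#'
#' @param table a `veg_table`.
#' @param series a `driver_series` covering the requested years.
#' @param years integer vector of years to simulate; defaults to all
#'   years present in `series`.
#' @param season integer months of the growing season (default `5:9`).
#' @param lambda annual inertia in (0, 1] (default 1).
#' @param s shading efficiency in \[0, 1\].
#' @param gamma dominance exponent.
#' @param init optional named initial cover vector (default equal
#'   covers).
#' @param tol fixed-point tolerance on the maximum cover change.
#' @param max_iter maximum fixed-point sweeps per year.
#' @param method root-zone aggregation, `"weighted"` or `"deepest"`.
#' @return a `community_trajectory`: long data.frame with columns
#'   `year`, `species`, `cover`, and a `convergence` attribute
#'   (data.frame of per-year iterations and convergence flags).
#' @export
simulate_community <- function(table, series, years = NULL, season = 5:9,
                               lambda = 1, s = 0.75, gamma = 1, init = NULL,
                               tol = 1e-6, max_iter = 100,
                               method = "weighted") {
  if (lambda <= 0 || lambda > 1) stop("'lambda' must lie in (0, 1]", call. = FALSE)
  if (is.null(years)) years <- sort(unique(series$year))
  if (!all(years %in% series$year)) {
    stop("driver series does not cover all requested years", call. = FALSE)
  }
  n <- nrow(table)
  covers <- if (is.null(init)) rep(1 / n, n) else as.numeric(init[table$name])
  covers <- covers / sum(covers)

  # The non-light part of the monthly suitability (pH, N, moisture
  # responses and the temperature indicator) does not depend on covers,
  # so it is computed once per (year, month, species).
  base_suit <- function(year) {
    vapply(season, function(m) {
      vapply(seq_len(n), function(i) {
        env <- aggregate_root_zone(series, table$rooting_depth_m[i], year, m,
                                   method = method)
        response_gaussian(env[["pH"]], table$ph_opt[i], table$ph_var[i]) *
          response_gaussian(env[["N"]], table$n_opt[i], table$n_var[i]) *
          response_gaussian(env[["moisture"]], table$moisture_opt[i],
                            table$moisture_var[i]) *
          response_temperature(env[["temperature"]], table$tmin[i], table$tmax[i])
      }, numeric(1))
    }, numeric(n))
  }
  floor_lights <- function(year) {
    vapply(season, function(m) {
      series$floor_light_frac[series$year == year & series$month == m][1]
    }, numeric(1))
  }

  out <- vector("list", length(years))
  conv <- data.frame(year = years, iterations = NA_integer_, converged = NA)
  for (k in seq_along(years)) {
    yr <- years[k]
    bs <- matrix(base_suit(yr), nrow = n)   # n x length(season)
    fl <- floor_lights(yr)
    strengths_at <- function(cv) {
      sm <- matrix(vapply(seq_along(season), function(j) {
        avail <- shaded_light(table$shading_height_m, cv, fl[j], s)
        lr <- vapply(seq_len(n), function(i)
          response_gaussian(avail[i], table$light_opt[i], table$light_var[i]),
          numeric(1))
        bs[, j] * lr
      }, numeric(n)), nrow = n)
      plant_strength(rowMeans(sm), gamma)
    }
    cv <- covers
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      target <- assign_relative_cover(strengths_at(cv))
      if (!isTRUE(attr(target, "viable"))) {
        cv <- as.numeric(target)
        converged <- TRUE
        break
      }
      new <- 0.5 * cv + 0.5 * as.numeric(target)
      new <- new / sum(new)
      if (max(abs(new - cv)) < tol) {
        cv <- new
        converged <- TRUE
        break
      }
      cv <- new
    }
    if (!converged) {
      warning(sprintf("fixed-point iteration did not converge in year %d (%d sweeps)",
                      yr, max_iter))
    }
    conv$iterations[k] <- iter
    conv$converged[k] <- converged
    if (sum(cv) > 0) {
      covers <- (1 - lambda) * covers + lambda * cv
      covers <- covers / sum(covers)
    } else {
      covers <- cv
    }
    out[[k]] <- data.frame(year = yr, species = table$name, cover = covers,
                           stringsAsFactors = FALSE)
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  structure(traj, class = c("community_trajectory", "data.frame"),
            convergence = conv)
}

#' Extract the cover vector of one simulated year
#'
#' @param trajectory a `community_trajectory`.
#' @param year the year to extract; defaults to the last simulated
#'   year.
#' @return named numeric vector of covers.
#' @export
covers_at <- function(trajectory, year = max(trajectory$year)) {
  sub <- trajectory[trajectory$year == year, ]
  if (nrow(sub) == 0L) stop("year not in trajectory", call. = FALSE)
  stats::setNames(sub$cover, sub$species)
}

#' Read / write annual cover tables
#'
#' Long CSV with columns `year`, `species`, `cover_frac`; writing then
#' reading reproduces the values exactly.
#'
#' @param trajectory a `community_trajectory` (or any data.frame with
#'   columns `year`, `species`, `cover`).
#' @param path file path.
#' @return `read_covers()` returns a data.frame with columns `year`,
#'   `species`, `cover`.
#' @export
write_covers <- function(trajectory, path) {
  df <- data.frame(year = trajectory$year, species = trajectory$species,
                   cover_frac = trajectory$cover)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_covers
#' @export
read_covers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "species", "cover_frac")
  if (!all(need %in% names(df))) {
    stop("cover file must have columns year, species, cover_frac", call. = FALSE)
  }
  data.frame(year = df$year, species = df$species, cover = df$cover_frac,
             stringsAsFactors = FALSE)
}
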