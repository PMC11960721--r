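#' Gaussian niche response to an environmental driver
#'
#' Evaluates the normalized Gaussian fundamental-niche response
#' \deqn{Resp(driver, opt, var) = e^{-(driver - opt)^2 / var}}
#' where `opt` is the driver value at which the species' response is
#' maximal and `var` its tolerance, in squared driver units, to
#' deviations from the optimum. The response is 1 exactly at the optimum
#' and decreases strictly with `|driver - opt|`.
#'
#' Responses smaller than `1e-300` are clamped to 0: at that distance
#' from the optimum a species is excluded for any practical purpose and
#' the clamp avoids denormalized arithmetic downstream.
#'
#' @param driver numeric vector of driver values (pH, N in mg/L, moisture
#'   saturation fraction, or light fraction).
#' @param opt numeric scalar, niche optimum in driver units, or a
#'   [niche_axis()] object (in which case `var` is taken from it).
#' @param var numeric scalar, niche tolerance. By default interpreted
#'   literally as the denominator of the exponent (squared driver
#'   units); set `var_is_sd = TRUE` to supply a standard-deviation-like
#'   width that is squared internally.
#' @param var_is_sd logical; see `var`.
#' @return numeric vector of responses in \[0, 1\].
#' @examples
#' response_gaussian(5.0, opt = 4.0, var = 1.0)  # exp(-1)
#' @export
response_gaussian <- function(driver, opt, var = NULL,
                              var_is_sd = getOption("vegniche.var_is_sd", FALSE)) {
  if (inherits(opt, "niche_axis")) {
    var <- opt$var
    opt <- opt$opt
  }
  if (!is.numeric(driver) || anyNA(driver) || any(!is.finite(driver))) {
    stop("'driver' must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(opt) || length(opt) != 1L || !is.finite(opt)) {
    stop("'opt' must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(var) || length(var) != 1L || !is.finite(var) || var <= 0) {
    stop("'var' must be a single positive number", call. = FALSE)
  }
  if (isTRUE(var_is_sd)) var <- var^2
  r <- exp(-(driver - opt)^2 / var)
  r[r < 1e-300] <- 0
  r
}

#' Temperature window response
#'
#' A hard presence/absence indicator: the response is 1 when the
#' temperature lies inside the closed interval `[tmin, tmax]` and 0
#' otherwise. Unlike the four Gaussian niche axes, the temperature niche
#' is a window with no tolerance tails.
#'
#' @param t numeric vector of temperatures (degrees C).
#' @param tmin,tmax window bounds (degrees C), `tmin < tmax`. `tmin` may
#'   also be a [temperature_window()] object.
#' @return numeric vector of 0/1 responses.
#' @export
response_temperature <- function(t, tmin, tmax = NULL) {
  if (inherits(tmin, "temperature_window")) {
    tmax <- tmin$tmax
    tmin <- tmin$tmin
  }
  if (!is.numeric(t) || anyNA(t)) stop("'t' must be numeric", call. = FALSE)
  if (!is.numeric(tmin) || !is.numeric(tmax) || tmin >= tmax) {
    stop("invalid temperature window: need tmin < tmax", call. = FALSE)
  }
  as.numeric(t >= tmin & t <= tmax)
}

#' Construct a single niche axis
#'
#' @param axis one of `"pH"`, `"N"`, `"moisture"`, `"light"`.
#' @param opt niche optimum in driver units.
#' @param var niche tolerance (squared driver units), `> 0`.
#' @return an object of class `niche_axis`.
#' @export
niche_axis <- function(axis, opt, var) {
  axis <- match.arg(axis, c("pH", "N", "moisture", "light"))
  if (!is.finite(opt)) stop("'opt' must be finite", call. = FALSE)
  if (!is.finite(var) || var <= 0) stop("'var' must be > 0", call. = FALSE)
  if (axis %in% c("moisture", "light") && (opt < 0 || opt > 1)) {
    stop(sprintf("%s optimum must lie in [0, 1]", axis), call. = FALSE)
  }
  if (axis == "N" && opt < 0) stop("N optimum must be >= 0", call. = FALSE)
  structure(list(axis = axis, opt = opt, var = var), class = "niche_axis")
}

#' Construct a temperature window
#'
#' @param tmin,tmax window bounds in degrees C, `tmin < tmax`.
#' @return an object of class `temperature_window`.
#' @export
temperature_window <- function(tmin, tmax) {
  if (!is.finite(tmin) || !is.finite(tmax) || tmin >= tmax) {
    stop("invalid temperature window: need finite tmin < tmax", call. = FALSE)
  }
  structure(list(tmin = tmin, tmax = tmax), class = "temperature_window")
}

#' Site suitability of a species
#'
#' Multiplies the four Gaussian responses (pH, N, moisture, light) and
#' the temperature window indicator. The product is bounded above by
#' each individual factor; a temperature outside the window forces zero
#' suitability.
#'
#' @param species a single-row species record from a parameter table
#'   (see [read_species_table()]) or a list with elements `ph_opt`,
#'   `ph_var`, `n_opt`, `n_var`, `moisture_opt`, `moisture_var`,
#'   `light_opt`, `light_var`, `tmin`, `tmax`.
#' @param env named numeric vector with elements `pH`, `N`, `moisture`
#'   (root-zone aggregated driver values, see [aggregate_root_zone()]).
#' @param t soil temperature, degrees C.
#' @param light light fraction available to the plant in \[0, 1\]
#'   (after shading, see [shaded_light()]).
#' @return suitability in \[0, 1\].
#' @export
site_suitability <- function(species, env, t, light) {
  if (light < 0 || light > 1) stop("'light' must lie in [0, 1]", call. = FALSE)
  sp <- as.list(species)
  r <- response_gaussian(env[["pH"]], sp$ph_opt, sp$ph_var) *
    response_gaussian(env[["N"]], sp$n_opt, sp$n_var) *
    response_gaussian(env[["moisture"]], sp$moisture_opt, sp$moisture_var) *
    response_gaussian(light, sp$light_opt, sp$light_var) *
    response_temperature(t, sp$tmin, sp$tmax)
  unname(r)
}

# Per-axis Gaussian response factors of one species, as a named vector.
# Used by the calibration to find the most limiting / most permissive axis.
suitability_factors <- function(species, env, t, light) {
  sp <- as.list(species)
  c(
    light    = response_gaussian(light, sp$light_opt, sp$light_var),
    N        = response_gaussian(env[["N"]], sp$n_opt, sp$n_var),
    pH       = response_gaussian(env[["pH"]], sp$ph_opt, sp$ph_var),
    moisture = response_gaussian(env[["moisture"]], sp$moisture_opt, sp$moisture_var),
    temperature = response_temperature(t, sp$tmin, sp$tmax)
  )
}
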