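#' Default class-to-units key
#'
#' Niche parameters are assigned by experts as ordered integer classes
#' along each axis; a class key maps every rank to physical units. The
#' published key for the original parameterization is not reproducible
#' from the available material, so the package ships a replaceable
#' default with five evenly spaced optima spanning plausible field
#' ranges: pH 3-7, N 0-10 mg/L, moisture saturation 0.05-0.95, light
#' fraction 0.02-1.0. Tolerances (`var`, squared driver units) are
#' constant per axis and sized so that adjacent classes overlap but
#' remain clearly distinguishable. Shading-height classes span the
#' herbaceous layer (up to 1.8 m) and rooting-depth classes typical
#' forest-floor root zones.
#'
#' Any key with the same structure can be supplied instead, e.g. via
#' [read_class_key()].
#'
#' @return a `class_key`: a list with elements `pH`, `N`, `moisture`,
#'   `light` (each a rank-indexed list of `c(opt, var)`), `shading`
#'   (rank to height in m) and `rooting` (rank to depth in m).
#' @export
default_class_key <- function() {
  gaussian_axis <- function(opts, var) {
    stats::setNames(lapply(opts, function(o) c(opt = o, var = var)),
                    seq_along(opts))
  }
  structure(list(
    pH       = gaussian_axis(seq(3, 7, length.out = 5), var = 0.8),
    N        = gaussian_axis(seq(0, 10, length.out = 5), var = 6),
    moisture = gaussian_axis(seq(0.05, 0.95, length.out = 5), var = 0.08),
    light    = gaussian_axis(seq(0.02, 1.0, length.out = 5), var = 0.08),
    shading  = stats::setNames(as.list(c(0.05, 0.2, 0.5, 1.0, 1.8)), 1:5),
    rooting  = stats::setNames(as.list(c(0.05, 0.15, 0.3, 0.5, 0.8)), 1:5)
  ), class = "class_key")
}

axis_key_name <- function(axis) {
  switch(axis,
         pH = "pH", ph = "pH",
         # YAML 1.1 parses a bare N as boolean false; accept the mangled name
         N = "N", n = "N", "FALSE" = "N",
         moisture = "moisture",
         light = "light",
         shading = "shading", shading_height = "shading",
         rooting = "rooting", rooting_depth = "rooting",
         stop(sprintf("unknown axis '%s'", axis), call. = FALSE))
}

#' Convert a class rank to physical units
#'
#' Strict lookup: the rank must be defined in the key, there is no
#' interpolation between ranks.
#'
#' @param rank integer class rank.
#' @param axis axis name: `"pH"`, `"N"`, `"moisture"`, `"light"`,
#'   `"shading"` or `"rooting"`.
#' @param key a class key, by default [default_class_key()].
#' @return for the four Gaussian axes, `c(opt, var)` in physical units;
#'   for `shading`/`rooting`, a height/depth in m.
#' @export
class_to_units <- function(rank, axis, key = default_class_key()) {
  axis <- axis_key_name(axis)
  ax <- key[[axis]]
  if (is.null(ax)) stop(sprintf("axis '%s' not in key", axis), call. = FALSE)
  hit <- match(as.character(rank), names(ax))
  if (is.na(hit)) {
    stop(sprintf("rank %s not defined for axis '%s' (valid ranks: %s)",
                 format(rank), axis, paste(names(ax), collapse = ", ")),
         call. = FALSE)
  }
  ax[[hit]]
}

#' Convert physical units back to a class rank
#'
#' Inverse of [class_to_units()]: finds the rank whose optimum (or
#' height/depth) matches the supplied value. The match must be exact up
#' to a small numerical tolerance; values between ranks are an error.
#'
#' @param value a niche optimum (for the Gaussian axes) or a height /
#'   depth in m (for `shading` / `rooting`).
#' @inheritParams class_to_units
#' @return integer class rank.
#' @export
units_to_class <- function(value, axis, key = default_class_key()) {
  axis <- axis_key_name(axis)
  ax <- key[[axis]]
  if (is.null(ax)) stop(sprintf("axis '%s' not in key", axis), call. = FALSE)
  opts <- vapply(ax, function(v) v[[1]], numeric(1))
  hit <- which(abs(opts - value) < 1e-9)
  if (length(hit) != 1L) {
    stop(sprintf("value %s matches no rank on axis '%s' (rank optima: %s)",
                 format(value), axis, paste(format(opts), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(names(ax)[hit])
}

#' Read a class key from a YAML file
#'
#' The file maps each axis to `rank: [opt, var]` entries (Gaussian axes)
#' or `rank: value` entries (shading heights, rooting depths). Optima
#' must be strictly monotone in rank along each axis.
#'
#' @param path path to a YAML file.
#' @return a `class_key` (see [default_class_key()]).
#' @export
read_class_key <- function(path) {
  raw <- yaml::read_yaml(path)
  key <- list()
  for (axis in names(raw)) {
    nm <- axis_key_name(axis)
    entries <- raw[[axis]]
    ranks <- suppressWarnings(as.integer(names(entries)))
    if (anyNA(ranks)) stop("class key ranks must be integers", call. = FALSE)
    ord <- order(ranks)
    entries <- entries[ord]
    ranks <- ranks[ord]
    parsed <- lapply(entries, function(e) {
      if (length(e) == 2L) c(opt = e[[1]], var = e[[2]]) else e[[1]]
    })
    opts <- vapply(parsed, function(v) v[[1]], numeric(1))
    if (any(diff(opts) <= 0)) {
      stop(sprintf("class key optima must be strictly increasing in rank (axis '%s')",
                   nm), call. = FALSE)
    }
    key[[nm]] <- stats::setNames(parsed, ranks)
  }
  structure(key, class = "class_key")
}

#' Write a class key to a YAML file
#'
#' @param key a `class_key`.
#' @param path output path.
#' @export
write_class_key <- function(key, path) {
  out <- lapply(unclass(key), function(ax) lapply(ax, function(v) as.numeric(v)))
  yaml::write_yaml(out, path)
  invisible(path)
}
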