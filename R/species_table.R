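#' Build a species parameter table
#'
#' A species table is a `data.frame` (class `veg_table`) with one row
#' per species and the physical niche parameters in the columns
#' `ph_opt`, `ph_var`, `n_opt`, `n_var`, `moisture_opt`,
#' `moisture_var`, `light_opt`, `light_var`, `tmin`, `tmax`,
#' `rooting_depth_m`, `shading_height_m`, plus the species `name`.
#' Class-rank columns (`ph_class`, `n_class`, `moisture_class`,
#' `light_class`, `shading_class`, `rooting_class`) may be carried
#' alongside; when a rank column is present and the matching physical
#' columns are missing they are filled from the class `key`.
#'
#' Duplicate species names are collapsed to a single row, keeping the
#' first non-missing value of every column.
#'
#' @param df a `data.frame` of species parameters.
#' @param key class key used to resolve rank columns
#'   ([default_class_key()] by default).
#' @param provenance free-text provenance tag (e.g. "expert blind",
#'   "calibrated"), stored as an attribute.
#' @return a validated `veg_table`.
#' @export
species_table <- function(df, key = default_class_key(), provenance = "unspecified") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) stop("species table needs a 'name' column", call. = FALSE)

  rank_map <- list(ph = "pH", n = "N", moisture = "moisture", light = "light")
  for (pre in names(rank_map)) {
    cls <- paste0(pre, "_class")
    oc <- paste0(pre, "_opt"); vc <- paste0(pre, "_var")
    if (cls %in% names(df) && !(oc %in% names(df) && !anyNA(df[[oc]]))) {
      uv <- t(vapply(df[[cls]], class_to_units, numeric(2),
                     axis = rank_map[[pre]], key = key))
      df[[oc]] <- uv[, 1]
      df[[vc]] <- uv[, 2]
    }
  }
  if ("shading_class" %in% names(df) && !"shading_height_m" %in% names(df)) {
    df$shading_height_m <- vapply(df$shading_class, function(r)
      class_to_units(r, "shading", key), numeric(1))
  }
  if ("rooting_class" %in% names(df) && !"rooting_depth_m" %in% names(df)) {
    df$rooting_depth_m <- vapply(df$rooting_class, function(r)
      class_to_units(r, "rooting", key), numeric(1))
  }

  # collapse duplicated names, first non-missing value wins
  if (anyDuplicated(df$name)) {
    df <- do.call(rbind, lapply(split(df, factor(df$name, levels = unique(df$name))),
                                function(g) {
      out <- g[1, , drop = FALSE]
      for (col in names(g)) {
        v <- g[[col]][!is.na(g[[col]])]
        if (length(v)) out[[col]] <- v[1]
      }
      out
    }))
    rownames(df) <- NULL
  }

  validate_species_table(df)
  structure(df, class = c("veg_table", "data.frame"), provenance = provenance,
            key = key)
}

required_species_cols <- c(
  "name", "ph_opt", "ph_var", "n_opt", "n_var", "moisture_opt",
  "moisture_var", "light_opt", "light_var", "tmin", "tmax",
  "rooting_depth_m", "shading_height_m"
)

validate_species_table <- function(df) {
  missing <- setdiff(required_species_cols, names(df))
  if (length(missing)) {
    stop("species table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$name)) || anyNA(df$name)) {
    stop("species names must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(df$name)) stop("duplicate species names", call. = FALSE)
  for (vc in c("ph_var", "n_var", "moisture_var", "light_var")) {
    if (any(df[[vc]] <= 0)) stop(sprintf("'%s' must be > 0", vc), call. = FALSE)
  }
  for (oc in c("moisture_opt", "light_opt")) {
    if (any(df[[oc]] < 0 | df[[oc]] > 1)) {
      stop(sprintf("'%s' must lie in [0, 1]", oc), call. = FALSE)
    }
  }
  if (any(df$n_opt < 0)) stop("'n_opt' must be >= 0", call. = FALSE)
  if (any(df$tmin >= df$tmax)) stop("need tmin < tmax for every species", call. = FALSE)
  if (any(df$rooting_depth_m <= 0)) stop("'rooting_depth_m' must be > 0", call. = FALSE)
  if (any(df$shading_height_m <= 0 | df$shading_height_m > 1.8)) {
    stop("'shading_height_m' must lie in (0, 1.8]", call. = FALSE)
  }
  invisible(df)
}

#' Read a species parameter table from TSV
#'
#' Tab-separated, UTF-8, one row per species, `#` comment lines
#' allowed. Columns as in [species_table()]; class-rank columns are
#' resolved through `key`.
#'
#' @param path path to the TSV file.
#' @inheritParams species_table
#' @return a `veg_table`.
#' @export
read_species_table <- function(path, key = default_class_key(),
                               provenance = basename(path)) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  species_table(df, key = key, provenance = provenance)
}

#' Write a species parameter table to TSV
#'
#' @param table a `veg_table`.
#' @param path output path.
#' @export
write_species_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
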