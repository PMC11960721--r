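#' Load the packaged relevé cover fixture for a site
#'
#' The package ships, as plain CSV, the published relative-cover table
#' for three northern hardwood forest sites: HBEF (Hubbard Brook
#' Experimental Forest, relevé year 2013) and the East Bear (EB) and
#' West Bear (WB) watersheds (1997). Each file holds the observed
#' covers next to the blind (uncalibrated expert parameterization) and
#' calibrated simulated covers, rounded to two decimals as printed; a
#' species row duplicated in the original printed table is collapsed to
#' one entry. Empty cells mean the species was not reported at that
#' site (`NA`; treated as cover 0 by [cover_pair()]).
#'
#' @param site one of `"HBEF"`, `"EB"`, `"WB"` (case-insensitive).
#' @return data.frame with columns `species`, `observed`, `blind`,
#'   `calibrated`.
#' @export
load_cover_fixture <- function(site) {
  valid <- c("HBEF", "EB", "WB")
  site <- toupper(site)
  if (!site %in% valid) {
    stop(sprintf("unknown site '%s' (valid sites: %s)", site,
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", sprintf("cover_%s.csv", tolower(site)),
                      package = "vegniche", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cover columns of a site fixture as named vectors
#'
#' @param site see [load_cover_fixture()].
#' @param column one of `"observed"`, `"blind"`, `"calibrated"`.
#' @param drop_na drop species with no reported value (default keeps
#'   them as `NA`).
#' @return named numeric cover vector.
#' @export
fixture_covers <- function(site, column = c("observed", "blind", "calibrated"),
                           drop_na = FALSE) {
  column <- match.arg(column)
  df <- load_cover_fixture(site)
  v <- stats::setNames(df[[column]], df$species)
  if (drop_na) v <- v[!is.na(v)]
  v
}
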