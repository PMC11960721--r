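#' Paired predicted/observed series
#'
#' @param predicted,observed equal-length numeric vectors with no
#'   missing values.
#' @return a `paired_series` data.frame with columns `P` and `O`.
#' @export
paired_series <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(predicted) < 1L) stop("need at least one pair", call. = FALSE)
  if (anyNA(predicted) || anyNA(observed)) {
    stop("missing values are not allowed after pairing", call. = FALSE)
  }
  structure(data.frame(P = as.numeric(predicted), O = as.numeric(observed)),
            class = c("paired_series", "data.frame"))
}

as_pair <- function(series, observed = NULL) {
  if (inherits(series, "paired_series")) return(series)
  paired_series(series, observed)
}

#' Normalized average error (NAE)
#'
#' `NAE = (mean(P) - mean(O)) / mean(O)`: the relative bias of the
#' predicted mean against the observed mean. The sign gives the bias
#' direction (positive = overestimation). Suitable when only a handful
#' of pairs exist, since only the means enter.
#'
#' @param series a [paired_series()], or the predicted vector when
#'   `observed` is given.
#' @param observed optional observed vector.
#' @return dimensionless NAE.
#' @export
nae <- function(series, observed = NULL) {
  pr <- as_pair(series, observed)
  ob <- mean(pr$O)
  if (ob == 0) stop("NAE undefined: observed mean is zero", call. = FALSE)
  (mean(pr$P) - ob) / ob
}

#' Normalized root-mean-square error (NRMSE)
#'
#' `NRMSE = sqrt(mean((P - O)^2)) / mean(O)`: the total pairwise
#' error scaled by the observed mean. A strict difference metric, it
#' amplifies large individual discrepancies, unlike [nae()] which only
#' compares the two means.
#'
#' @inheritParams nae
#' @return dimensionless NRMSE, `>= 0`.
#' @export
nrmse <- function(series, observed = NULL) {
  pr <- as_pair(series, observed)
  ob <- mean(pr$O)
  if (ob == 0) stop("NRMSE undefined: observed mean is zero", call. = FALSE)
  sqrt(mean((pr$P - pr$O)^2)) / ob
}

#' Zero-intercept 1:1 regression of predicted on observed
#'
#' Fits `P = slope * O` by least squares through the origin
#' (`slope = sum(P*O) / sum(O^2)`), with the standard error of that
#' slope and the Pearson correlation of the pairs. A slope below 1
#' indicates underestimation by the model. Preferred over [nae()] when
#' enough pairs are available for the bias to vary along the value
#' range.
#'
#' @inheritParams nae
#' @return list with elements `slope`, `se`, `correlation`, `n`.
#' @export
one_to_one <- function(series, observed = NULL) {
  pr <- as_pair(series, observed)
  if (nrow(pr) < 2L) stop("need at least two pairs", call. = FALSE)
  so2 <- sum(pr$O^2)
  if (so2 == 0) stop("1:1 slope undefined: all observed values are zero",
                     call. = FALSE)
  slope <- sum(pr$P * pr$O) / so2
  resid <- pr$P - slope * pr$O
  se <- sqrt(sum(resid^2) / (nrow(pr) - 1L) / so2)
  r <- suppressWarnings(stats::cor(pr$P, pr$O))
  list(slope = slope, se = se, correlation = r, n = nrow(pr))
}

#' Align two cover vectors over the species union
#'
#' Species present in only one vector are kept with cover 0 in the
#' other; `NA` covers (species with no reported value) are treated as
#' absent, i.e. 0.
#'
#' @param predicted,observed named numeric cover vectors.
#' @return a `cover_pair` data.frame with columns `species`, `P`, `O`.
#' @export
cover_pair <- function(predicted, observed) {
  if (is.null(names(predicted)) || is.null(names(observed))) {
    stop("cover vectors must be named by species", call. = FALSE)
  }
  sp <- union(names(predicted), names(observed))
  p <- predicted[sp]; o <- observed[sp]
  p[is.na(p)] <- 0; o[is.na(o)] <- 0
  if (any(p < 0) || any(o < 0)) stop("covers must be >= 0", call. = FALSE)
  structure(data.frame(species = sp, P = as.numeric(p), O = as.numeric(o),
                       stringsAsFactors = FALSE),
            class = c("cover_pair", "data.frame"))
}

#' Czekanowski similarity index
#'
#' `CzI = 1 - sum(|P - O|) / sum(P + O)`, also known as the
#' quantitative Sörensen index or the reverse Bray-Curtis index. For
#' normalized cover vectors it integrates inter-community overlap
#' symmetrically without over- or under-weighting the non-dominant
#' species. `CzI = 1` is a perfect fit; smaller values mean less
#' similar communities.
#'
#' @param predicted a [cover_pair()], or a named cover vector when
#'   `observed` is given.
#' @param observed optional named cover vector.
#' @return CzI in \[0, 1\].
#' @export
czekanowski <- function(predicted, observed = NULL) {
  pair <- if (inherits(predicted, "cover_pair")) predicted
          else cover_pair(predicted, observed)
  denom <- sum(pair$P + pair$O)
  if (denom == 0) stop("CzI undefined: both cover vectors are all-zero",
                       call. = FALSE)
  1 - sum(abs(pair$P - pair$O)) / denom
}

#' Pair modeled monthly values with observations by yearly medians
#'
#' For every calendar year with at least one observation inside the
#' modeled span, the median of that year's observations is paired with
#' the median of the modeled monthly values of the same year.
#' Observation years outside the modeled span are dropped with a
#' message. A mean-based aggregation is available via `fun`.
#'
#' @param modeled data.frame with columns `year`, `month`, `value`
#'   (monthly model output).
#' @param observations data.frame with columns `year`, `value` (dated
#'   observations; multiple per year allowed).
#' @param fun aggregation function, default [stats::median()].
#' @return a [paired_series()] with one pair per overlapping year and a
#'   `years` attribute.
#' @export
annual_median_pairs <- function(modeled, observations, fun = stats::median) {
  if (!all(c("year", "value") %in% names(modeled)) ||
      !all(c("year", "value") %in% names(observations))) {
    stop("modeled and observations need 'year' and 'value' columns", call. = FALSE)
  }
  yrs <- sort(intersect(unique(observations$year), unique(modeled$year)))
  dropped <- setdiff(unique(observations$year), yrs)
  if (length(dropped)) {
    message("dropping observation years outside modeled span: ",
            paste(dropped, collapse = ", "))
  }
  if (length(yrs) == 0L) {
    stop("no overlapping years between model and observations", call. = FALSE)
  }
  p <- vapply(yrs, function(y) fun(modeled$value[modeled$year == y]), numeric(1))
  o <- vapply(yrs, function(y) fun(observations$value[observations$year == y]),
              numeric(1))
  out <- paired_series(p, o)
  attr(out, "years") <- yrs
  out
}

#' Evaluate modeled against observed covers
#'
#' Bundles the metric suite for one modeled/observed cover comparison.
#'
#' @param predicted,observed named cover vectors.
#' @return list with `czi`, `nae`, `nrmse`, `one_to_one` (the latter
#'   three computed on the aligned per-species pairs).
#' @export
evaluate_covers <- function(predicted, observed) {
  pair <- cover_pair(predicted, observed)
  ps <- paired_series(pair$P, pair$O)
  list(czi = czekanowski(pair), nae = nae(ps), nrmse = nrmse(ps),
       one_to_one = one_to_one(ps))
}
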