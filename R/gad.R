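# Piecewise component functions of the gene age-dynamic (GAD) score.
# All x arguments are percentages of positive cells on the 0-100 scale.

gad_old <- function(x) {
  ifelse(x <= 3, 1 / (1 + exp(-2 * x)),
    ifelse(x <= 20, 1, -x / 4 + 6)
  )
}

gad_gain <- function(x) {
  ifelse(x < 5, x / 5, ifelse(x > 15, -x / 5 + 4, 1))
}

gad_young <- function(x) {
  ifelse(x < 5, 1, -x / 2 + 3.5)
}

gad_ratio <- function(r) pmin(r, 2.5)

#' Mouse gene age-dynamic (GAD) score
#'
#' Scores how well a gene's positivity dynamics match the expected behaviour
#' of a senescence marker: rare in young cells, present in a minority of old
#' cells, with a large relative gain. The score is the sum of four piecewise
#' weighted metrics of the percent of positive cells:
#' \itemize{
#'   \item old(x): logistic `1/(1+exp(-2x))` for `x <= 3`, `1` for
#'     `3 < x <= 20`, `-x/4 + 6` above 20;
#'   \item gain(x): `x/5` below 5, `-x/5 + 4` above 15, `1` otherwise,
#'     with `x_gain = x_old - x_young`;
#'   \item young(x): `1` below 5, `-x/2 + 3.5` otherwise;
#'   \item ratio(r): the old/young positivity ratio capped at 2.5.
#' }
#'
#' @param x_young_pct,x_old_pct Percent of positive cells (0-100 scale) in
#'   the young and old baselines.
#' @param r Old/young positivity ratio, must be > 0 (impute the young
#'   proportion as 1/n first when no young cell is positive).
#' @return A tibble with one row per gene: the four components, `gad`
#'   (their sum) and the inputs.
#' @export
#' @examples
#' gad_mouse(x_young_pct = 2, x_old_pct = 10, r = 5) # components 1,1,1,2.5
gad_mouse <- function(x_young_pct, x_old_pct, r) {
  if (any(r <= 0)) {
    abort("ratio r must be > 0 (impute young zeros as 1/n first)",
      class = "senesig_data_error"
    )
  }
  x_gain <- x_old_pct - x_young_pct
  old <- gad_old(x_old_pct)
  gain <- gad_gain(x_gain)
  young <- gad_young(x_young_pct)
  ratio <- gad_ratio(r)
  tibble(
    x_young = x_young_pct, x_old = x_old_pct, x_gain = x_gain, r = r,
    old = old, gain = gain, young = young, ratio = ratio,
    gad = old + gain + young + ratio
  )
}

#' Human gene age-dynamic (GAD) score
#'
#' Extends the mouse score to binned human ages. In addition to the old, gain
#' and young terms of [gad_mouse()], the human score rewards genes whose
#' positivity peaks at (or near) the oldest sampled bin and whose positivity
#' trend over age bins is positive:
#' \itemize{
#'   \item dMax: `1` when the peak-positivity bin lies within 50 years of the
#'     oldest bin, else `-(dMax_years - 50)`;
#'   \item aMax: `1` when the oldest bin index is >= 38 years, else
#'     `age_max - 38`;
#'   \item slope: the per-year regression slope of positivity (percentage
#'     points per year), weighted by 5.
#' }
#' A gene is only a senescence candidate when the slope is positive; the
#' `candidate` column records this.
#'
#' @param x_young_pct,x_old_pct Percent positive (0-100) in the young and
#'   oldest bins.
#' @param slope_pct_per_year Regression slope of percent positive over bin age.
#' @param age_of_peak Bin index (years) with maximal positivity; ties are
#'   broken towards the oldest bin upstream.
#' @param age_max Oldest bin index (years) available for the population.
#' @param dmax_literal If `TRUE`, use the literal printed difference
#'   `age_of_peak - age_max` (whose penalty branch is unreachable); default
#'   uses the corrected direction `age_max - age_of_peak` so peaks far before
#'   the oldest bin are penalized.
#' @return A tibble with the six components, `gad` (their sum), `candidate`,
#'   and the inputs.
#' @export
#' @examples
#' gad_human(2, 10, slope_pct_per_year = 0.1, age_of_peak = 68, age_max = 68)
gad_human <- function(x_young_pct, x_old_pct, slope_pct_per_year,
                      age_of_peak, age_max, dmax_literal = FALSE) {
  x_gain <- x_old_pct - x_young_pct
  d_max <- if (dmax_literal) age_of_peak - age_max else age_max - age_of_peak
  dmax <- ifelse(d_max < 50, 1, -(d_max - 50))
  amax <- ifelse(age_max >= 38, 1, age_max - 38)
  old <- gad_old(x_old_pct)
  gain <- gad_gain(x_gain)
  young <- gad_young(x_young_pct)
  slope_term <- 5 * slope_pct_per_year
  tibble(
    x_young = x_young_pct, x_old = x_old_pct, x_gain = x_gain,
    slope = slope_pct_per_year, age_of_peak = age_of_peak, age_max = age_max,
    old = old, gain = gain, young = young, dMax = dmax, aMax = amax,
    slope_term = slope_term,
    gad = old + gain + young + dmax + amax + slope_term,
    candidate = slope_pct_per_year > 0
  )
}

#' Extrapolate the young-bin positivity for populations without young donors
#'
#' When no age bin at or below 28 years is available, the young (18-year)
#' positivity is extrapolated by ordinary least squares through the observed
#' (bin age, proportion) points, evaluated at 18 years. Non-positive
#' extrapolations are floored at `1/n` of the youngest available bin.
#'
#' @param ages Numeric bin indices (years), at least two distinct values.
#' @param ps Proportions positive per bin, same length as `ages`.
#' @param n_youngest Cell count of the youngest available bin (for the floor).
#' @return The extrapolated proportion at age 18.
#' @export
extrapolate_p18 <- function(ages, ps, n_youngest) {
  stopifnot(length(ages) == length(ps))
  if (length(unique(ages)) < 2) {
    abort("extrapolation needs at least two distinct age bins",
      class = "senesig_data_error"
    )
  }
  slope <- stats::cov(ages, ps) / stats::var(ages)
  p18 <- mean(ps) + slope * (18 - mean(ages))
  if (p18 <= 0) p18 <- 1 / n_youngest
  p18
}
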