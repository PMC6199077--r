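#' @include AllClasses.R
NULL

#' Bactericidal efficiency from paired plate counts
#'
#' Per replicate, the efficiency is (control - surface) CFU (after applying
#' any dilution factors) divided by the assayed area and incubation time,
#' i.e. cells inactivated per cm^2 per minute relative to the control. The
#' replicate mean and standard error of the mean are reported together with
#' a two-tailed paired t test of control vs surface counts. Negative
#' per-replicate efficiencies (surface count above control) are retained
#' rather than truncated - truncation would bias the mean - and flagged in
#' the notes.
#'
#' @param v a \linkS4class{ViabilityTable}.
#' @return an \linkS4class{EfficiencyResult}. The pooled dead fraction
#'   1 - mean(surface)/mean(control) is clipped to [0, 1].
#' @examples
#' v <- generateViability(7.02e6, killFraction = 1, incubationMin = 180,
#'                        countNoiseCv = 0, replicates = 3, seed = 1)
#' bactericidalEfficiency(v)   # 3.9e4 cells/min/cm^2
#' @export
bactericidalEfficiency <- function(v) {
  stopifnot(is(v, "ViabilityTable"))
  d <- v@counts
  dil <- if ("dilution" %in% names(d)) d$dilution else rep(1, nrow(d))
  ctrl <- d$control_cfu * dil
  surf <- d$surface_cfu * dil
  eff <- (ctrl - surf) / (v@areaCm2 * v@incubationMin)
  n <- length(eff)
  notes <- character(0)
  if (any(eff < 0))
    notes <- c(notes, sprintf(
      "%d replicate(s) with surface > control (negative efficiency) retained",
      sum(eff < 0)))
  sem <- if (n >= 2) stats::sd(eff) / sqrt(n) else NA_real_
  if (n < 2) notes <- c(notes, "single replicate: SEM and t test unavailable")
  tt <- if (n >= 2) pairedTTest(ctrl, surf) else
    list(t = NA_real_, p = NA_real_, error = NULL)
  if (!is.null(tt$error)) notes <- c(notes, tt$error)
  deadFrac <- if (mean(ctrl) > 0)
    min(max(1 - mean(surf) / mean(ctrl), 0), 1) else NA_real_
  res <- new("EfficiencyResult", perReplicate = eff, mean = mean(eff),
             sem = sem, deadFraction = deadFrac,
             tStatistic = tt$t, pValue = tt$p, notes = notes)
  if (any(eff < 0))
    warning("negative per-replicate efficiency retained (see notes)")
  res
}

#' Dead-cell fraction from live/dead counts
#'
#' @param live,dead non-negative cell counts (e.g. from live/dead staining);
#'   their sum must be positive.
#' @return dead / (live + dead), in [0, 1].
#' @examples
#' deadFraction(live = 7, dead = 93)   # 0.93
#' @export
deadFraction <- function(live, dead) {
  stopifnot(live >= 0, dead >= 0)
  if (live + dead == 0) stop("live + dead must be positive")
  dead / (live + dead)
}

#' Two-tailed paired Student t test
#'
#' Classic paired t test on the per-replicate differences, with the p value
#' taken from the t distribution on n - 1 degrees of freedom. When the
#' differences have zero variance the statistic is undefined; the one
#' exception is identical inputs (all differences zero), reported as t = 0,
#' p = 1 since there is no evidence of any difference.
#'
#' @param x,y paired replicate values of equal length >= 2.
#' @return list with \code{t}, \code{p}, \code{df} and \code{error}
#'   (NULL, or an explanation when the test is not computable).
#' @examples
#' pairedTTest(c(10, 12, 9, 14, 11), c(8, 9, 9, 10, 10))
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  dif <- x - y
  if (stats::sd(dif) == 0) {
    if (all(dif == 0))
      return(list(t = 0, p = 1, df = length(x) - 1L, error = NULL))
    return(list(t = NA_real_, p = NA_real_, df = length(x) - 1L,
                error = "zero-variance differences: paired t test undefined"))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), error = NULL)
}
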