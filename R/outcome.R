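#' Long-term urinary toxicity label from an IPSS series
#'
#' A patient's urinary symptoms are considered resolved once a post-implant
#' IPSS returns to within `tolerance` points of baseline; resolution at or
#' below the horizon (12 months by default) means no long-term toxicity
#' (label 0), failure to resolve by then is long-term toxicity (label 1).
#' Scores below baseline count as resolved: the band is one-sided, since a
#' symptom improvement cannot indicate persistent toxicity.
#'
#' @param baseline baseline IPSS (integer 0-35).
#' @param times follow-up times, months since implant (positive,
#'   increasing).
#' @param scores follow-up IPSS values (0-35), same length as `times`.
#' @param horizon_months resolution horizon (default 12).
#' @param tolerance_points resolution band above baseline (default 2).
#' @return integer label: 0 = resolved within the horizon, 1 = long-term
#'   toxicity.
#' @export
label_toxicity <- function(baseline, times, scores, horizon_months = 12,
                           tolerance_points = 2) {
  if (baseline < 0 || baseline > 35) stop("baseline IPSS must be in [0, 35]")
  if (length(times) != length(scores) || length(times) == 0L)
    stop("times and scores must be non-empty and matched")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("follow-up times must be positive and increasing")
  if (any(scores < 0 | scores > 35)) stop("IPSS scores must be in [0, 35]")
  within <- times <= horizon_months
  if (!any(within))
    stop("no follow-up within the horizon; patient must be excluded upstream")
  resolved <- any(scores[within] <= baseline + tolerance_points)
  as.integer(!resolved)
}
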