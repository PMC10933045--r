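#' Extract the composite FT/WL endpoint
#'
#' The endpoint is positive when a feeding tube was inserted within 90 days
#' after radiotherapy completion, or when the minimum recorded weight in that
#' window is strictly more than 10% below baseline. Baseline weight is the
#' record closest to the RT start date within a +/- 2-week window; a patient
#' without an eligible baseline weight is flagged ineligible rather than
#' classified.
#'
#' @param ft_days numeric vector of feeding-tube insertion days (relative to
#'   the same day-0 convention as `rt_end_day`); may be empty.
#' @param weight_records data.frame with columns `day` and `kg`.
#' @param rt_start_day,rt_end_day RT start and completion days.
#' @return a list: `outcome` (0/1, or `NA` when ineligible), `eligible`,
#'   `baseline_kg`, `ft` (feeding-tube component), `wl` (weight-loss
#'   component), `loss_frac` (max fractional loss in window, `NA` if no
#'   in-window weights).
#' @export
extract_endpoint <- function(ft_days, weight_records, rt_start_day, rt_end_day) {
  stopifnot(is.data.frame(weight_records),
            all(c("day", "kg") %in% names(weight_records)))
  near <- abs(weight_records$day - rt_start_day) <= 14
  if (!any(near)) {
    return(list(outcome = NA, eligible = FALSE, baseline_kg = NA,
                ft = NA, wl = NA, loss_frac = NA))
  }
  cand <- weight_records[near, , drop = FALSE]
  baseline <- cand$kg[which.min(abs(cand$day - rt_start_day))]
  if (baseline <= 0) stop("baseline weight must be positive")

  ft <- any(ft_days > rt_end_day & ft_days <= rt_end_day + 90)
  inwin <- weight_records$day > rt_end_day & weight_records$day <= rt_end_day + 90
  if (any(inwin)) {
    wmin <- min(weight_records$kg[inwin])
    loss_frac <- (baseline - wmin) / baseline
    wl <- loss_frac > 0.1            # strictly greater than 10%
  } else {
    loss_frac <- NA
    wl <- FALSE
  }
  list(outcome = as.integer(ft || wl), eligible = TRUE, baseline_kg = baseline,
       ft = ft, wl = wl, loss_frac = loss_frac)
}
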