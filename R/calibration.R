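#' Estimate the sigma ratio from a measured concentration
#'
#' Since `x_i = (sigma_p/sigma_s) * (v_p/v_s)`, a measured concentration in
#' a reference condition together with a range for the relevant flux ratio
#' yields an interval estimate of the condition-invariant constant
#' `sigma_p/sigma_s`: `[x / r_max, x / r_min]`.
#'
#' @param x_meas Measured concentration (> 0), mmol/gDW.
#' @param ratio_range Length-2 numeric `c(min, max)` for the relevant flux
#'   ratio, strictly positive.
#' @return `c(lower =, upper =)` interval for the sigma ratio.
#' @export
estimate_sigma_ratio <- function(x_meas, ratio_range) {
  if (x_meas <= 0) abort("measured concentration must be > 0")
  r <- sort(as.numeric(ratio_range)[1:2])
  if (r[1] <= 0) abort("flux-ratio range touching zero gives an unbounded sigma estimate")
  c(lower = x_meas / r[2], upper = x_meas / r[1])
}

#' Combine per-replicate interval estimates
#'
#' Envelope combination: the combined interval spans from the smallest lower
#' bound to the largest upper bound over the replicates. Pairwise overlap of
#' the replicate intervals is reported; absence of overlap indicates poor
#' reproducibility between replicates.
#'
#' @param intervals List of length-2 numeric intervals, or a data frame with
#'   `lower`/`upper` columns.
#' @param method `"envelope"` (default) or `"intersection"`.
#' @return List with `lower`, `upper`, `overlap` (do all replicate intervals
#'   share a common point?).
#' @export
combine_replicates <- function(intervals, method = c("envelope", "intersection")) {
  method <- match.arg(method)
  if (is.data.frame(intervals)) {
    lo <- intervals$lower; up <- intervals$upper
  } else {
    lo <- map_dbl(intervals, 1); up <- map_dbl(intervals, 2)
  }
  if (length(lo) == 0L) abort("need at least one interval")
  overlap <- max(lo) <= min(up) + .tol_zero
  if (method == "envelope") {
    list(lower = min(lo), upper = max(up), overlap = overlap)
  } else {
    list(lower = max(lo), upper = min(up), overlap = overlap)
  }
}

#' Predict a concentration range in a new condition
#'
#' Multiplies the calibrated sigma-ratio interval with the flux-ratio range
#' estimated for the new condition; the result feeds [intersect_ranges()]
#' when a metabolite has several certificates.
#'
#' @param sigma_interval Length-2 positive interval for `sigma_p/sigma_s`.
#' @param new_ratio_range Length-2 positive interval for the relevant flux
#'   ratio in the new condition.
#' @return `c(lower =, upper =)` concentration interval.
#' @export
predict_new_condition <- function(sigma_interval, new_ratio_range) {
  s <- sort(as.numeric(sigma_interval)[1:2])
  r <- sort(as.numeric(new_ratio_range)[1:2])
  if (s[1] <= 0 || r[1] <= 0) abort("intervals must be strictly positive")
  c(lower = s[1] * r[1], upper = s[2] * r[2])
}

#' Convert volumetric concentrations to per-dry-weight units
#'
#' Measured volumetric concentrations (mmol/L) are converted to mmol/gDW
#' with a cell-volume-to-dry-weight factor.
#'
#' @param conc_mM Numeric vector of volumetric concentrations (mmol/L).
#' @param volume_per_gdw Aqueous cell volume per gram dry weight
#'   (L/g; default 0.0023).
#' @return Concentrations in mmol/gDW.
#' @export
volumetric_to_gdw <- function(conc_mM, volume_per_gdw = 0.0023) {
  conc_mM * volume_per_gdw
}

#' Calibrate sigma ratios from replicate measurements and predict
#'
#' For each replicate of a reference condition the sigma ratio is estimated
#' from the measured concentration and the replicate-specific flux-ratio
#' range; the per-replicate estimates are combined (envelope by default) and
#' multiplied with the new condition's flux-ratio range.
#'
#' @param measurements Data frame with columns `replicate` and
#'   `concentration` (mmol/gDW) for one metabolite in the reference
#'   condition.
#' @param reference_ratios Data frame with columns `replicate`, `min`, `max`:
#'   the relevant flux-ratio range per replicate in the reference condition.
#' @param new_ratio_range Length-2 positive interval for the new condition.
#' @param method Replicate combination method (see [combine_replicates()]).
#' @return A tibble with the per-replicate predictions and one `combined`
#'   row; columns `replicate`, `sigma_lower`, `sigma_upper`, `lower`,
#'   `upper`, `overlap`.
#' @export
calibrate_and_predict <- function(measurements, reference_ratios,
                                  new_ratio_range,
                                  method = c("envelope", "intersection")) {
  method <- match.arg(method)
  merged <- left_join(as_tibble(measurements), as_tibble(reference_ratios),
                      by = "replicate")
  if (any(is.na(merged$min))) {
    abort("every measurement replicate needs a reference flux-ratio range")
  }
  per_rep <- list_rbind(lapply(seq_len(nrow(merged)), function(k) {
    s <- estimate_sigma_ratio(merged$concentration[k],
                              c(merged$min[k], merged$max[k]))
    p <- predict_new_condition(s, new_ratio_range)
    tibble(replicate = as.character(merged$replicate[k]),
           sigma_lower = s[["lower"]], sigma_upper = s[["upper"]],
           lower = p[["lower"]], upper = p[["upper"]])
  }))
  comb_sigma <- combine_replicates(
    tibble(lower = per_rep$sigma_lower, upper = per_rep$sigma_upper), method)
  p <- predict_new_condition(c(comb_sigma$lower, comb_sigma$upper),
                             new_ratio_range)
  bind_rows(
    mutate(per_rep, overlap = comb_sigma$overlap),
    tibble(replicate = "combined", sigma_lower = comb_sigma$lower,
           sigma_upper = comb_sigma$upper, lower = p[["lower"]],
           upper = p[["upper"]], overlap = comb_sigma$overlap)
  )
}
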