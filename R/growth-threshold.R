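#' Standard-normal z-score for a percentile
#'
#' Converts a percentile of a normally distributed birth-weight population to
#' its standard-deviation equivalent.  Clinical FGR cutoffs quoted as the
#' 3rd-10th percentile correspond to -1.88 to -1.28 SD, and the 5th
#' percentile to -1.64 SD.
#'
#' @param q percentile as a proportion, strictly between 0 and 1.
#' @return The standard normal quantile, in SD units (full double precision;
#'   round only for display).
#' @examples
#' z_from_percentile(0.10)  # -1.28 SD
#' z_from_percentile(0.05)  # -1.64 SD
#' z_from_percentile(0.03)  # -1.88 SD
#' @export
z_from_percentile <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("`q` must lie strictly inside (0, 1)", call. = FALSE)
  qnorm(q)
}

#' Birth-weight threshold rule for FGR classification
#'
#' A threshold of `reference_mean_g - k_sd * reference_sd_g` defines fetal
#' growth restriction relative to an untreated reference group.  The default
#' `k_sd = 1.5` reflects the -1.5 SD diagnostic convention; with a reference
#' of 7.01 +/- 0.55 g this gives 6.185 g (printed as 6.18 g at 2 decimals).
#'
#' @param reference_mean_g reference-group mean birth weight in grams (> 0).
#' @param reference_sd_g reference-group SD in grams (>= 0).
#' @param k_sd number of SDs below the mean (> 0).
#' @return An object of class `"threshold_rule"`.
#' @examples
#' rule <- threshold_rule(7.01, 0.55)
#' fgr_threshold(rule)
#' @export
threshold_rule <- function(reference_mean_g, reference_sd_g, k_sd = 1.5) {
  stop_if_not_number(reference_mean_g, "reference_mean_g", positive = TRUE)
  stop_if_not_number(reference_sd_g, "reference_sd_g")
  if (reference_sd_g < 0) stop("`reference_sd_g` must be >= 0", call. = FALSE)
  stop_if_not_number(k_sd, "k_sd", positive = TRUE)
  structure(
    list(reference_mean_g = reference_mean_g,
         reference_sd_g = reference_sd_g,
         k_sd = k_sd),
    class = "threshold_rule"
  )
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("FGR threshold rule: mean %.3f g - %.2g x SD %.3f g = %.3f g\n",
              x$reference_mean_g, x$k_sd, x$reference_sd_g, fgr_threshold(x)))
  invisible(x)
}

#' FGR birth-weight threshold in grams
#'
#' @param rule a [threshold_rule()].
#' @return Threshold weight in grams (unrounded).
#' @export
fgr_threshold <- function(rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  rule$reference_mean_g - rule$k_sd * rule$reference_sd_g
}

#' Classify pups as FGR by birth weight
#'
#' Sets `is_fgr = birth_weight_g < threshold` (strict inequality: a pup
#' exactly at the threshold is not FGR, matching a "below this threshold"
#' rule).
#'
#' @param pups data frame with columns `pup_id` and `birth_weight_g`.
#' @param threshold threshold weight in grams (> 0), e.g. from
#'   [fgr_threshold()].
#' @return `pups` with a logical `is_fgr` column set.
#' @export
classify_pups <- function(pups, threshold) {
  stopifnot(is.data.frame(pups))
  stop_if_not_number(threshold, "threshold", positive = TRUE)
  if (!all(c("pup_id", "birth_weight_g") %in% names(pups)))
    stop("`pups` needs columns `pup_id` and `birth_weight_g`", call. = FALSE)
  w <- pups$birth_weight_g
  bad <- !is.finite(w)
  if (any(bad))
    stop("missing birth weight for pup(s): ",
         paste(pups$pup_id[bad], collapse = ", "), call. = FALSE)
  pups$is_fgr <- w < threshold
  pups
}

#' Fraction of pups below the FGR threshold
#'
#' @inheritParams classify_pups
#' @return Proportion in \[0, 1\] of pups with birth weight strictly below
#'   the threshold.
#' @export
below_fraction <- function(pups, threshold) {
  if (NROW(pups) == 0L) stop("empty pup list", call. = FALSE)
  mean(classify_pups(pups, threshold)$is_fgr)
}
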