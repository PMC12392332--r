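#' Albumin-referenced densitometry normalization
#'
#' Divides a band density by the albumin (endogenous control) density from
#' the same lane.
#'
#' @param band nonnegative band density.
#' @param albumin positive albumin density.
#' @return `band / albumin`.
#' @export
albumin_normalize <- function(band, albumin) {
  if (any(!is.finite(band)) || any(band < 0))
    stop("`band` must be nonnegative and finite", call. = FALSE)
  if (any(!is.finite(albumin)) || any(albumin <= 0))
    stop("`albumin` must be > 0", call. = FALSE)
  band / albumin
}

#' Scale ratios relative to a reference group's mean
#'
#' Divides each ratio by the arithmetic mean of the reference ratios, so
#' the reference group's mean becomes exactly 1 (e.g. "sham on day 4 set
#' as 1").
#'
#' @param ratios numeric vector of albumin-normalized ratios.
#' @param reference_ratios ratios of the reference group; non-empty with a
#'   positive mean.
#' @return `ratios / mean(reference_ratios)`.
#' @export
relative_to_reference <- function(ratios, reference_ratios) {
  if (length(reference_ratios) == 0L)
    stop("empty reference", call. = FALSE)
  ref <- mean(reference_ratios)
  if (!is.finite(ref) || ref <= 0)
    stop("reference mean must be > 0", call. = FALSE)
  ratios / ref
}

#' Normalize a densitometry time course
#'
#' Applies [albumin_normalize()] per measurement, then scales each analyte
#' relative to a sham reference mean: either the sham group on the earliest
#' day (`reference = "global"`, the day-4-anchored convention) or the sham
#' group of the same day (`reference = "per_day"`).
#'
#' @param timecourse data frame with columns `analyte`, `day`, `group`,
#'   `band_density`, `albumin_density` (e.g. from [gen_timecourse()]).
#' @param reference `"global"` or `"per_day"`.
#' @param reference_group group label used as the reference (default
#'   `"sham"`).
#' @return The input with a `relative_expression` column appended.
#' @export
normalize_timecourse <- function(timecourse,
                                 reference = c("global", "per_day"),
                                 reference_group = "sham") {
  reference <- match.arg(reference)
  need <- c("analyte", "day", "group", "band_density", "albumin_density")
  missing <- setdiff(need, names(timecourse))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tc <- timecourse
  tc$.ratio <- albumin_normalize(tc$band_density, tc$albumin_density)
  tc$relative_expression <- NA_real_
  for (an in unique(tc$analyte)) {
    sel <- tc$analyte == an
    if (reference == "global") {
      ref_day <- min(tc$day[sel & tc$group == reference_group])
      ref <- tc$.ratio[sel & tc$group == reference_group & tc$day == ref_day]
      tc$relative_expression[sel] <- relative_to_reference(tc$.ratio[sel], ref)
    } else {
      for (d in unique(tc$day[sel])) {
        sd_sel <- sel & tc$day == d
        ref <- tc$.ratio[sd_sel & tc$group == reference_group]
        tc$relative_expression[sd_sel] <-
          relative_to_reference(tc$.ratio[sd_sel], ref)
      }
    }
  }
  tc$.ratio <- NULL
  tc
}

#' Rescale immunofluorescence intensities to the 1-100 display range
#'
#' Affine map sending the background to 1 and the panel maximum to 100:
#' `v -> 1 + 99 * (v - background) / (maximum - background)`.  Values
#' outside `[background, maximum]` are clamped to the anchors; the number
#' clamped is reported in a message.
#'
#' @param values numeric intensities.
#' @param background background intensity (maps to 1).
#' @param maximum highest intensity (maps to 100); must exceed
#'   `background`.
#' @return Rescaled values in \[1, 100\].
#' @examples
#' fluorescence_rescale(60, background = 10, maximum = 110)  # 50.5
#' @export
fluorescence_rescale <- function(values, background, maximum) {
  stop_if_not_number(background, "background")
  stop_if_not_number(maximum, "maximum")
  if (maximum <= background)
    stop("`maximum` must exceed `background`", call. = FALSE)
  clamped <- sum(values < background | values > maximum)
  if (clamped > 0)
    message(clamped, " value(s) outside [background, maximum] clamped")
  v <- pmin(pmax(values, background), maximum)
  1 + 99 * (v - background) / (maximum - background)
}
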