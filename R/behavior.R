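#' Negative-geotaxis climb-up score
#'
#' Scores the latency to rotate 180 degrees and face up-slope on a 0-5
#' ordinal scale: 5 points for under 15 s, 4 for 15-30 s, 3 for 30-45 s,
#' 2 for 45-60 s, 1 for 60 s or more, and 0 for no reaction or falling.
#' Bins are left-closed/right-open, so exactly 15 s scores 4 points.
#'
#' @param latency_s latency in seconds (>= 0; finite when `reacted`).
#' @param reacted did the pup react at all?
#' @param fell did the pup fall off the slope?
#' @return Integer score in 0..5.
#' @examples
#' climb_up_score(10, reacted = TRUE, fell = FALSE)  # 5
#' @export
climb_up_score <- function(latency_s, reacted = TRUE, fell = FALSE) {
  if (isTRUE(fell) || !isTRUE(reacted)) return(0L)
  if (!is.finite(latency_s) || latency_s < 0)
    stop("`latency_s` must be a finite nonnegative number", call. = FALSE)
  if (latency_s < 15) 5L
  else if (latency_s < 30) 4L
  else if (latency_s < 45) 3L
  else if (latency_s < 60) 2L
  else 1L
}

#' Y-maze spontaneous alternation index
#'
#' Counts windows of three consecutive arm entries that visit three
#' distinct arms (1-2-3, 1-3-2, 2-1-3, 2-3-1, 3-1-2, 3-2-1), divides by
#' the total number of entries minus one, and multiplies by 100.  The
#' `(entries - 1)` denominator is the scoring rule as printed in the
#' protocol this package follows; set `denominator = "entries_minus_2"`
#' for the conventional maximum-triads denominator.
#'
#' @param arm_sequence integer vector of arm entries over `{1, 2, 3}`,
#'   length >= 3.
#' @param denominator `"entries_minus_1"` (default) or
#'   `"entries_minus_2"`.
#' @return Alternation index (percent).
#' @examples
#' alternation_index(c(1, 2, 3, 1, 2))  # 75
#' @export
alternation_index <- function(arm_sequence,
                              denominator = c("entries_minus_1",
                                              "entries_minus_2")) {
  denominator <- match.arg(denominator)
  if (length(arm_sequence) < 3L)
    stop("need at least 3 arm entries", call. = FALSE)
  if (!all(arm_sequence %in% 1:3))
    stop("arm entries must be 1, 2 or 3", call. = FALSE)
  n <- length(arm_sequence)
  triads <- vapply(seq_len(n - 2L), function(i)
    length(unique(arm_sequence[i:(i + 2L)])) == 3L, TRUE)
  den <- if (denominator == "entries_minus_1") n - 1L else n - 2L
  sum(triads) / den * 100
}

#' Novel-object recognition index
#'
#' Time spent with the novel object divided by total object-exploration
#' time.
#'
#' @param t_novel_s,t_familiar_s exploration times in seconds (>= 0, not
#'   both zero).
#' @return Recognition index in \[0, 1\].
#' @examples
#' recognition_index(45, 15)  # 0.75
#' @export
recognition_index <- function(t_novel_s, t_familiar_s) {
  if (t_novel_s < 0 || t_familiar_s < 0)
    stop("times must be >= 0", call. = FALSE)
  total <- t_novel_s + t_familiar_s
  if (total == 0) stop("recognition index undefined: no exploration",
                       call. = FALSE)
  t_novel_s / total
}

#' Rota-rod motor-learning gain
#'
#' Difference between the second and first trial latencies of the
#' accelerating rota-rod (4 to 40 rpm over 5 min).  Latencies above the
#' 300 s protocol cap are clamped with a warning.
#'
#' @param trial1_latency_s,trial2_latency_s latencies to fall, in seconds.
#' @param cap_s protocol cap (default 300 s).
#' @return `trial2 - trial1` after capping, in seconds.
#' @export
rotarod_learning <- function(trial1_latency_s, trial2_latency_s,
                             cap_s = 300) {
  if (trial1_latency_s < 0 || trial2_latency_s < 0)
    stop("latencies must be >= 0", call. = FALSE)
  if (trial1_latency_s > cap_s || trial2_latency_s > cap_s) {
    warning("latency above the ", cap_s, " s cap; clamped")
    trial1_latency_s <- min(trial1_latency_s, cap_s)
    trial2_latency_s <- min(trial2_latency_s, cap_s)
  }
  trial2_latency_s - trial1_latency_s
}

#' Score a long-format behavior table
#'
#' Turns the long `(pup_id, arm, test, day, key, value)` trial table (as
#' written by [gen_behavior()]) into per-pup, per-day scores: climb-up
#' score and latency for geotaxis, alternation index for the Y-maze,
#' recognition index for novel-object recognition, and learning gain for
#' the rota-rod.
#'
#' @param trials long-format behavior data frame.
#' @param test one of `"geotaxis"`, `"ymaze"`, `"nor"`, `"rotarod"`.
#' @return A data frame of per-pup scores with `pup_id`, `arm`, `day` and
#'   test-specific score columns, ready for [steel_dwass_test()].
#' @export
score_behavior <- function(trials, test = c("geotaxis", "ymaze", "nor",
                                            "rotarod")) {
  test <- match.arg(test)
  tr <- trials[trials$test == test, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no trials for test `", test, "`", call. = FALSE)
  wide <- function(keys) {
    out <- unique(tr[, c("pup_id", "arm", "day")])
    for (k in keys) {
      sub <- tr[tr$key == k, c("pup_id", "day", "value")]
      idx <- match(paste(out$pup_id, out$day),
                   paste(sub$pup_id, sub$day))
      out[[k]] <- sub$value[idx]
    }
    out
  }
  switch(test,
    geotaxis = {
      w <- wide(c("latency_s", "reacted", "fell"))
      w$latency_s <- as.numeric(w$latency_s)
      w$score <- mapply(climb_up_score, w$latency_s,
                        w$reacted == "TRUE", w$fell == "TRUE")
      w
    },
    ymaze = {
      w <- wide("arm_sequence")
      w$alternation <- vapply(strsplit(w$arm_sequence, ","), function(s)
        alternation_index(as.integer(s)), 0.0)
      w
    },
    nor = {
      w <- wide(c("t_novel_s", "t_familiar_s"))
      w$recognition <- mapply(recognition_index,
                              as.numeric(w$t_novel_s),
                              as.numeric(w$t_familiar_s))
      w
    },
    rotarod = {
      w <- wide(c("trial1_latency_s", "trial2_latency_s"))
      w$learning_gain <- mapply(rotarod_learning,
                                as.numeric(w$trial1_latency_s),
                                as.numeric(w$trial2_latency_s))
      w
    })
}
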