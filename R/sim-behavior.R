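#' Assign behavioral treatment arms to a classified cohort
#'
#' Splits pups into the four behavioral arms: `sham`, hypoperfusion pups
#' above the FGR threshold given vehicle (`non_fgr_vehicle`), FGR pups given
#' vehicle (`fgr_vehicle`), and FGR pups given MSCs (`fgr_msc`).  FGR pups
#' are alternated between vehicle and MSC arms; the `treatment` column is
#' updated accordingly (MSC only ever assigned to hypoperfusion pups).
#'
#' @param cohort a classified cohort ([classify_pups()] output).
#' @return `cohort` with `arm` and `treatment` columns set.
#' @export
assign_arms <- function(cohort) {
  stopifnot(is.data.frame(cohort), "is_fgr" %in% names(cohort))
  if (any(is.na(cohort$is_fgr)))
    stop("cohort must be classified first (is_fgr set)", call. = FALSE)
  arm <- rep(NA_character_, nrow(cohort))
  arm[cohort$group == "sham"] <- "sham"
  hyp <- cohort$group == "hypoperfusion"
  arm[hyp & !cohort$is_fgr] <- "non_fgr_vehicle"
  fgr_idx <- which(hyp & cohort$is_fgr)
  arm[fgr_idx] <- rep(c("fgr_vehicle", "fgr_msc"),
                      length.out = length(fgr_idx))
  cohort$arm <- arm
  cohort$treatment <- ifelse(is.na(arm), cohort$treatment,
                             ifelse(arm == "fgr_msc", "msc",
                                    ifelse(arm == "sham", "none", "vehicle")))
  cohort
}

# Per-arm generating parameters for one behavioral test battery.  `deficit`
# in [0, 1] scales every FGR-vehicle departure from the sham mean; the MSC
# arm retains 30% of the vehicle deficit (partial rescue).
.arm_shift <- function(arm, full, deficit) {
  switch(arm,
         fgr_vehicle = full * deficit,
         fgr_msc = full * deficit * 0.3,
         0)
}

#' Simulate behavioral trials
#'
#' Generates negative-geotaxis, rota-rod, Y-maze and novel-object
#' recognition trials for the four behavioral arms.  The FGR-vehicle arm
#' carries the configured deficits (longer geotaxis latency, shorter
#' rota-rod latency with no trial-2 learning gain, lower spontaneous
#' alternation); the MSC arm shows a partial rescue; `deficit = 0` makes
#' all arms exchangeable.  Y-maze entry sequences are generated by a
#' completion-biased walk: after the first two (distinct) entries, each
#' next entry completes an alternation triad with the arm's configured
#' bias, else returns to the next-to-last arm; bias 1 yields a perfect
#' rotation.
#'
#' @param config a [sim_config()]; see the `behavior` element.
#' @param cohort optional cohort with an `arm` column (see [assign_arms()]);
#'   if omitted, `config$behavior$n_per_arm` pups per arm are created.
#' @return A long data frame: `pup_id`, `arm`, `test`, `day`, `key`,
#'   `value` (character; Y-maze arm sequences are comma-joined).
#' @examples
#' bh <- gen_behavior(sim_config(seed = 5))
#' table(bh$test)
#' @export
gen_behavior <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bp <- config$behavior
  if (is.null(cohort)) {
    arms <- c("sham", "non_fgr_vehicle", "fgr_vehicle", "fgr_msc")
    cohort <- data.frame(
      pup_id = unlist(lapply(arms, function(a)
        sprintf("%s_%02d", a, seq_len(bp$n_per_arm)))),
      arm = rep(arms, each = bp$n_per_arm),
      stringsAsFactors = FALSE
    )
  }
  if (!"arm" %in% names(cohort))
    stop("cohort must carry an `arm` column; see assign_arms()", call. = FALSE)
  cohort <- cohort[!is.na(cohort$arm), , drop = FALSE]

  d <- bp$deficit
  rows <- list()
  add <- function(pup, arm, test, day, key, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pup_id = pup, arm = arm, test = test, day = day, key = key,
      value = as.character(value), stringsAsFactors = FALSE)
  }

  with_stream(stream_seed(config$seed, .STREAM[["behavior"]]), {
    for (i in seq_len(nrow(cohort))) {
      pup <- cohort$pup_id[i]; arm <- cohort$arm[i]
      # negative geotaxis: latency to reorient, plus reaction/fall flags
      for (day in bp$geotaxis_days) {
        base <- 12 + .arm_shift(arm, 30, d)
        lat <- base * exp(rnorm(1, sd = bp$noise_sd) - bp$noise_sd^2 / 2)
        fell <- runif(1) < 0.05 * .arm_shift(arm, 1, d)
        add(pup, arm, "geotaxis", day, "latency_s", format(lat, digits = 10))
        add(pup, arm, "geotaxis", day, "reacted", "TRUE")
        add(pup, arm, "geotaxis", day, "fell", if (fell) "TRUE" else "FALSE")
      }
      for (day in bp$test_days) {
        # rota-rod: two trials, learning gain suppressed in the FGR arm
        t1 <- min(300, max(0, rnorm(1, 180 - .arm_shift(arm, 80, d), 30)))
        gain <- 30 * (1 - .arm_shift(arm, 1, d))
        t2 <- min(300, max(0, t1 + gain + rnorm(1, 0, 15)))
        add(pup, arm, "rotarod", day, "trial1_latency_s", format(t1, digits = 10))
        add(pup, arm, "rotarod", day, "trial2_latency_s", format(t2, digits = 10))
        # Y-maze entry sequence
        bias_sham <- bp$alternation_bias[["sham"]]
        bias <- bias_sham - (bias_sham - bp$alternation_bias[[arm]]) * d
        seqs <- ymaze_sequence(bp$n_entries, bias)
        add(pup, arm, "ymaze", day, "arm_sequence", paste(seqs, collapse = ","))
        # novel-object recognition: no arm effect in this battery
        tn <- 30 * exp(rnorm(1, sd = bp$noise_sd) - bp$noise_sd^2 / 2)
        tf <- 20 * exp(rnorm(1, sd = bp$noise_sd) - bp$noise_sd^2 / 2)
        add(pup, arm, "nor", day, "t_novel_s", format(tn, digits = 10))
        add(pup, arm, "nor", day, "t_familiar_s", format(tf, digits = 10))
      }
    }
    do.call(rbind, rows)
  })
}

# Completion-biased Y-maze walk over arms {1,2,3}.
ymaze_sequence <- function(n_entries, bias) {
  stopifnot(n_entries >= 3, bias >= 0, bias <= 1)
  s <- integer(n_entries)
  s[1] <- sample(1:3, 1)
  s[2] <- sample(setdiff(1:3, s[1]), 1)
  for (j in 3:n_entries) {
    completing <- setdiff(1:3, s[c(j - 2L, j - 1L)])
    s[j] <- if (runif(1) < bias) completing else s[j - 2L]
  }
  s
}
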