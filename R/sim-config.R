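#' Configuration for the synthetic-study generators
#'
#' Collects every tunable of the synthetic cohort, proteome, time-course and
#' behavior generators.  Defaults emulate the study design the pipeline is
#' built for: birth weights of 7.01 +/- 0.55 g (control), 6.87 +/- 0.74 g
#' (sham) and 5.727 +/- 0.74 g (intrauterine hypoperfusion; the mean is
#' calibrated so that 73% of hypoperfusion pups fall below the 6.18 g FGR
#' threshold), a 601-protein CSF abundance matrix per postnatal day (PND) 4
#' and 5 with 10 sham + 10 hypoperfusion pups per day, and 15 planted
#' "responder" proteins whose abundance varies monotonically with birth
#' weight at a target Spearman correlation magnitude of 0.8.
#'
#' Abundances are log-normal: a responder's log-abundance is shifted by
#' `direction * beta * z(birth weight)` where `z` is the within-day
#' birth-weight z-score and `beta` is calibrated from `target_abs_rho` via
#' the bivariate-normal identity `rho_s = (6/pi) asin(r/2)` so that the
#' expected Spearman correlation magnitude matches the target.
#'
#' @param seed master seed; each generator derives its own RNG stream from it
#'   by a fixed offset, so outputs are reproducible and independent.
#' @param n_per_group pups per group (per day for the proteome screen).
#' @param n_proteins number of proteins in the CSF abundance matrix.
#' @param n_responders number of planted birth-weight-responsive proteins
#'   (must be <= `n_proteins`).
#' @param target_abs_rho target absolute Spearman correlation between a
#'   responder's abundance and birth weight, in (0, 1).
#' @param group_weight_params named list `group -> c(mean_g, sd_g)` of
#'   birth-weight normal laws; SDs must be >= 0.
#' @param noise_sd SD of the log-scale measurement noise of the proteome
#'   (> 0).
#' @param concordance_prob probability that a responder keeps the same
#'   direction of association on PND 5 as on PND 4; with the remaining
#'   probability the day-5 direction is flipped.
#' @param shared_pups if `TRUE` the same pups are profiled on both days;
#'   default `FALSE` draws an independent set of pups for day 5.
#' @param litter_size pups per dam when assigning litters round-robin.
#' @param timecourse list of time-course generator settings: `analytes`,
#'   `days`, `n_per_group`, `elevation` (fold-change of the FGR arm relative
#'   to sham), `attenuation` (fraction of the elevation removed in the MSC
#'   arm from PND 5 on, in \[0, 1\]), `noise_sd` (log-scale SD).
#' @param behavior list of behavior generator settings: `n_per_arm`,
#'   `deficit` (scale in \[0, 1\] applied to every FGR-vehicle deficit),
#'   `geotaxis_days`, `test_days` (rota-rod / Y-maze / NOR days),
#'   `alternation_bias` named per-arm probabilities of completing an
#'   alternation triad, `noise_sd`.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cohort <- gen_cohort(cfg)
#' table(cohort$group)
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 10L,
                       n_proteins = 601L,
                       n_responders = 15L,
                       target_abs_rho = 0.8,
                       group_weight_params = list(
                         control = c(mean_g = 7.01, sd_g = 0.55),
                         sham = c(mean_g = 6.87, sd_g = 0.74),
                         hypoperfusion = c(mean_g = 5.727, sd_g = 0.74)
                       ),
                       noise_sd = 0.3,
                       concordance_prob = 1.0,
                       shared_pups = FALSE,
                       litter_size = 10L,
                       timecourse = list(),
                       behavior = list()) {
  stop_if_not_number(seed, "seed")
  stop_if_not_number(n_per_group, "n_per_group", positive = TRUE)
  stop_if_not_number(n_proteins, "n_proteins", positive = TRUE)
  stop_if_not_number(n_responders, "n_responders")
  if (n_responders < 0 || n_responders > n_proteins)
    stop("`n_responders` must lie in [0, n_proteins]", call. = FALSE)
  stop_if_not_number(target_abs_rho, "target_abs_rho")
  if (target_abs_rho <= 0 || target_abs_rho >= 1)
    stop("`target_abs_rho` must lie in (0, 1)", call. = FALSE)
  stop_if_not_number(noise_sd, "noise_sd", positive = TRUE)
  stop_if_not_number(concordance_prob, "concordance_prob")
  if (concordance_prob < 0 || concordance_prob > 1)
    stop("`concordance_prob` must lie in [0, 1]", call. = FALSE)
  for (g in names(group_weight_params)) {
    p <- group_weight_params[[g]]
    if (length(p) != 2L || any(!is.finite(p)))
      stop("weight params for group `", g, "` must be c(mean_g, sd_g)",
           call. = FALSE)
    if (p[[1]] <= 0) stop("mean weight for `", g, "` must be > 0",
                          call. = FALSE)
    if (p[[2]] < 0) stop("SD for group `", g, "` must be >= 0", call. = FALSE)
  }

  tc_defaults <- list(
    analytes = c("Serpini1", "CD200", "Ubb", "A2m", "Ube1", "Otub1"),
    days = c(4L, 5L, 7L, 10L, 14L),
    n_per_group = 15L,
    elevation = 2.0,
    attenuation = 0.7,
    noise_sd = 0.3
  )
  timecourse <- utils::modifyList(tc_defaults, timecourse)
  if (timecourse$attenuation < 0 || timecourse$attenuation > 1)
    stop("`timecourse$attenuation` must lie in [0, 1]", call. = FALSE)
  if (timecourse$noise_sd < 0)
    stop("`timecourse$noise_sd` must be >= 0", call. = FALSE)

  bh_defaults <- list(
    n_per_arm = 8L,
    deficit = 1.0,
    geotaxis_days = 8:11,
    test_days = c(30L, 140L),
    n_entries = 25L,
    alternation_bias = c(sham = 0.75, non_fgr_vehicle = 0.75,
                         fgr_vehicle = 0.55, fgr_msc = 0.70),
    noise_sd = 0.25
  )
  behavior <- utils::modifyList(bh_defaults, behavior)
  if (behavior$deficit < 0 || behavior$deficit > 1)
    stop("`behavior$deficit` must lie in [0, 1]", call. = FALSE)

  structure(
    list(seed = as.integer(seed),
         n_per_group = as.integer(n_per_group),
         n_proteins = as.integer(n_proteins),
         n_responders = as.integer(n_responders),
         target_abs_rho = target_abs_rho,
         group_weight_params = group_weight_params,
         noise_sd = noise_sd,
         concordance_prob = concordance_prob,
         shared_pups = isTRUE(shared_pups),
         litter_size = as.integer(litter_size),
         timecourse = timecourse,
         behavior = behavior),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-study configuration\n")
  cat(sprintf("  seed %d; %d pups/group; %d proteins (%d responders, target |rho| %.2f)\n",
              x$seed, x$n_per_group, x$n_proteins, x$n_responders,
              x$target_abs_rho))
  for (g in names(x$group_weight_params)) {
    p <- x$group_weight_params[[g]]
    cat(sprintf("  %-14s birth weight %.3f +/- %.2f g\n", g, p[[1]], p[[2]]))
  }
  invisible(x)
}

# Fixed stream offsets per generator.
.STREAM <- c(cohort = 1L, proteome = 2L, proteome_day5 = 3L,
             timecourse = 4L, behavior = 5L)
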