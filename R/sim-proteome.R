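# Calibration of the planted log-scale effect size.  For jointly normal
# (z, log-abundance) with Pearson correlation r, the population Spearman
# correlation is rho_s = (6/pi) asin(r/2); inverting gives the Pearson r,
# and beta = noise_sd * r / sqrt(1 - r^2) achieves it when the log-abundance
# is beta * z + N(0, noise_sd^2).
beta_for_target_rho <- function(target_abs_rho, noise_sd) {
  r <- 2 * sin(pi * target_abs_rho / 6)
  noise_sd * r / sqrt(1 - r^2)
}

#' Simulate the two-day CSF proteome with planted birth-weight responders
#'
#' Generates TMT-style protein abundance matrices for postnatal days 4 and 5
#' over a screening cohort (sham + hypoperfusion pups).  A planted subset of
#' "responder" proteins varies monotonically with birth weight:
#' `abundance = baseline * exp(direction * beta * z(weight) + noise)`, with
#' `beta` calibrated so the expected absolute Spearman correlation matches
#' `config$target_abs_rho`.  All other proteins are independent of weight.
#' Each responder keeps its day-4 direction on day 5 with probability
#' `config$concordance_prob` (and is flipped otherwise).
#'
#' By default an independent set of pups is drawn for day 5 (the day-4 pups
#' come from `cohort`); set `shared_pups = TRUE` in the config to profile
#' the same pups on both days.
#'
#' @param cohort day-4 screening cohort, a data frame as from
#'   [gen_cohort()]; only `sham` and `hypoperfusion` pups are profiled (all
#'   pups are used if neither group is present).
#' @param config a [sim_config()].
#' @return An object of class `"sim_proteome"`: a list with elements
#'   `pnd4` and `pnd5` (each a list with `abundance`, a proteins x samples
#'   matrix, and `weights`, a named vector of birth weights in grams), and
#'   `truth` (list `responder_ids`, `directions` (+1/-1 named vector per
#'   responder, day-4 direction), `directions_pnd5`, `effect_sizes`).
#' @examples
#' cfg <- sim_config(seed = 7, n_proteins = 50, n_responders = 5)
#' sim <- gen_proteome(gen_cohort(cfg), cfg)
#' dim(sim$pnd4$abundance)
#' @export
gen_proteome <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  if (NROW(cohort) == 0L) stop("empty cohort", call. = FALSE)

  keep <- cohort$group %in% c("sham", "hypoperfusion")
  day4 <- if (any(keep)) cohort[keep, , drop = FALSE] else cohort
  day5 <- if (config$shared_pups) {
    day4
  } else {
    c5 <- gen_cohort(config, groups = intersect(unique(day4$group),
                                                names(config$group_weight_params)),
                     stream = .STREAM[["proteome_day5"]])
    c5$pup_id <- paste0(c5$pup_id, "_d5")
    c5
  }

  m <- config$n_proteins
  m1 <- config$n_responders
  protein_ids <- sprintf("PROT%04d", seq_len(m))

  with_stream(stream_seed(config$seed, .STREAM[["proteome"]]), {
    responder_ids <- if (m1 > 0) sort(sample(protein_ids, m1)) else character(0)
    directions <- setNames(sample(c(-1, 1), m1, replace = TRUE), responder_ids)
    flip <- runif(m1) > config$concordance_prob
    directions_d5 <- directions * ifelse(flip, -1, 1)
    beta <- beta_for_target_rho(config$target_abs_rho, config$noise_sd)
    baseline_log <- setNames(rnorm(m, mean = 13, sd = 1), protein_ids)

    make_day <- function(pups, dirs) {
      n <- nrow(pups)
      if (n < 3L) stop("need at least 3 pups per day", call. = FALSE)
      w <- pups$birth_weight_g
      z <- (w - mean(w)) / sd(w)
      eff <- matrix(0, nrow = m, ncol = n,
                    dimnames = list(protein_ids, pups$pup_id))
      if (length(dirs))
        eff[names(dirs), ] <- outer(unname(dirs) * beta, z)
      noise <- matrix(rnorm(m * n, sd = config$noise_sd), m, n)
      ab <- exp(baseline_log + eff + noise)
      list(abundance = ab, weights = setNames(w, pups$pup_id))
    }

    p4 <- make_day(day4, directions)
    p5 <- make_day(day5, directions_d5)
    attr(p4$abundance, "day") <- "PND4"
    attr(p5$abundance, "day") <- "PND5"

    structure(
      list(pnd4 = p4, pnd5 = p5,
           truth = list(responder_ids = responder_ids,
                        directions = directions,
                        directions_pnd5 = directions_d5,
                        effect_sizes = setNames(rep(beta, m1), responder_ids))),
      class = "sim_proteome"
    )
  })
}

#' @export
print.sim_proteome <- function(x, ...) {
  cat(sprintf("Simulated CSF proteome: %d proteins x %d (PND4) / %d (PND5) samples; %d planted responders\n",
              nrow(x$pnd4$abundance), ncol(x$pnd4$abundance),
              ncol(x$pnd5$abundance), length(x$truth$responder_ids)))
  invisible(x)
}
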