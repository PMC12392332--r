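#' Simulate longitudinal biomarker measurements (Western-blot style)
#'
#' Emulates densitometry time courses of the candidate biomarkers in CSF:
#' for each analyte, day and arm, a band density and an albumin
#' (endogenous-control) density are generated so that the albumin-normalized
#' level of the sham arm is centered at 1, the FGR-vehicle arm at
#' `elevation`, and the MSC-treated arm at
#' `1 + (elevation - 1) * (1 - attenuation)` from postnatal day 5 onward
#' (treatment is given on day 4, so earlier days are unattenuated).  Noise
#' is multiplicative log-normal with mean 1.
#'
#' @param config a [sim_config()]; see the `timecourse` element.
#' @return A long data frame with columns `analyte`, `day`, `group`
#'   (`sham`, `fgr_vehicle`, `fgr_msc`), `pup_id`, `band_density`,
#'   `albumin_density`.
#' @examples
#' tc <- gen_timecourse(sim_config(seed = 3))
#' head(tc)
#' @export
gen_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tc <- config$timecourse
  arms <- c("sham", "fgr_vehicle", "fgr_msc")
  msc_level <- function(day) {
    if (day >= 5) 1 + (tc$elevation - 1) * (1 - tc$attenuation) else tc$elevation
  }
  with_stream(stream_seed(config$seed, .STREAM[["timecourse"]]), {
    grid <- expand.grid(analyte = tc$analytes, day = tc$days, group = arms,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      level <- switch(g$group,
                      sham = 1,
                      fgr_vehicle = tc$elevation,
                      fgr_msc = msc_level(g$day))
      n <- tc$n_per_group
      albumin <- exp(rnorm(n, mean = log(1000), sd = 0.1))
      # mean-one multiplicative noise so arm means sit at their target level
      eps <- if (tc$noise_sd > 0)
        exp(rnorm(n, sd = tc$noise_sd) - tc$noise_sd^2 / 2) else rep(1, n)
      data.frame(
        analyte = g$analyte, day = g$day, group = g$group,
        pup_id = sprintf("%s_%s_d%02d_%02d", g$group, g$analyte, g$day,
                         seq_len(n)),
        band_density = albumin * level * eps,
        albumin_density = albumin,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
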