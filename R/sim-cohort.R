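#' Simulate a birth cohort of rat pups
#'
#' Draws `n_per_group` birth weights per experimental group from the normal
#' laws in `config$group_weight_params` and assigns pups round-robin to dams
#' of `litter_size` pups.  Deterministic for a fixed `(seed, config)`.
#'
#' @param config a [sim_config()].
#' @param groups character vector of groups to generate; defaults to all
#'   groups configured in `group_weight_params`.
#' @param stream internal RNG stream offset; leave at the default unless you
#'   need an independent replicate cohort.
#' @return A data frame with one row per pup: `pup_id`, `dam_id`, `group`,
#'   `treatment` (initially `"none"`), `birth_weight_g`, `is_fgr` (`NA`
#'   until [classify_pups()] is applied).
#' @examples
#' cohort <- gen_cohort(sim_config(seed = 42))
#' aggregate(birth_weight_g ~ group, cohort, mean)
#' @export
gen_cohort <- function(config, groups = names(config$group_weight_params),
                       stream = .STREAM[["cohort"]]) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(groups, names(config$group_weight_params))
  if (length(missing))
    stop("no weight parameters for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- config$n_per_group
  with_stream(stream_seed(config$seed, stream), {
    rows <- lapply(groups, function(g) {
      p <- config$group_weight_params[[g]]
      w <- rnorm(n, mean = p[[1]], sd = p[[2]])
      w <- pmax(w, .Machine$double.eps)  # weights are physically positive
      data.frame(
        pup_id = sprintf("%s_%03d", g, seq_len(n)),
        dam_id = sprintf("%s_dam%02d",
                         g, ((seq_len(n) - 1L) %% max(1L, ceiling(n / config$litter_size))) + 1L),
        group = g,
        treatment = "none",
        birth_weight_g = w,
        is_fgr = NA,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
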