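# Declared schemas of the pipeline's standard tables.
.SCHEMAS <- list(
  samples = c(pup_id = "character", dam_id = "character",
              group = "character", treatment = "character",
              birth_weight_g = "numeric"),
  annotations = c(protein_id = "character", region = "character",
                  cell_class = "character", level = "character"),
  timecourse = c(analyte = "character", day = "numeric",
                 group = "character", band_density = "numeric",
                 albumin_density = "numeric"),
  behavior = c(pup_id = "character", arm = "character", test = "character",
               day = "numeric", key = "character", value = "character")
)

#' Read a typed pipeline table
#'
#' Reads a UTF-8 TSV with header and validates it against one of the
#' pipeline's declared schemas (or a user-supplied `column -> type` map).
#' Unparseable numeric cells become `NA` and their count is reported.
#'
#' @param path TSV file path.
#' @param schema a schema name (`"samples"`, `"annotations"`,
#'   `"timecourse"`, `"behavior"`) or a named character vector
#'   `column -> "numeric"|"character"|"logical"`.
#' @return A data frame with the declared column types.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema))) {
    if (!schema %in% names(.SCHEMAS))
      stop("unknown schema `", schema, "`", call. = FALSE)
    schema <- .SCHEMAS[[schema]]
  }
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("`", path, "` lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "numeric") {
      raw <- df[[col]]
      out <- suppressWarnings(as.numeric(raw))
      n_na <- sum(is.na(out) & !is.na(raw) & raw != "NA" & raw != "")
      if (n_na > 0)
        message(n_na, " unparseable value(s) in `", col, "` set to NA")
      df[[col]] <- out
    } else if (type == "logical") {
      df[[col]] <- as.logical(df[[col]])
    }
  }
  df
}

#' Write a pipeline table
#'
#' UTF-8 TSV with header, `.` decimal separator, no quoting or row names;
#' `write_table()` then `read_table()` round-trips the data.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' @param sim a [sim_config()] used to generate the inputs when file paths
#'   are not supplied.
#' @param ref_group reference group for the FGR threshold rule.
#' @param k_sd SDs below the reference mean defining the threshold.
#' @param p_thresh,q_thresh screening thresholds.
#' @param pi0_mode `"smoother"` or `"fixed"`.
#' @param min_level,cell_classes brain-expression filter rule.
#' @param outdir optional directory where intermediate tables are written.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            ref_group = "control",
                            k_sd = 1.5,
                            p_thresh = 0.05,
                            q_thresh = 0.1,
                            pi0_mode = "smoother",
                            min_level = "medium",
                            cell_classes = c("neuronal", "glial", "purkinje"),
                            outdir = NULL) {
  if (p_thresh <= 0 || p_thresh >= 1 || q_thresh <= 0 || q_thresh >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(sim = sim, ref_group = ref_group, k_sd = k_sd,
                 p_thresh = p_thresh, q_thresh = q_thresh,
                 pi0_mode = pi0_mode, min_level = min_level,
                 cell_classes = cell_classes, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Orchestrates the candidate funnel end to end: simulate (or accept) a
#' cohort and two-day proteome, classify pups against the FGR threshold,
#' screen each day's proteins against birth weight, intersect the days with
#' direction concordance, apply the brain-expression filter, and assemble a
#' funnel report whose counts are checked for arithmetic consistency as
#' postconditions.  Stage-level in/out counts are logged via `message()`.
#'
#' @param config a [pipeline_config()].
#' @param proteome optional precomputed [gen_proteome()] result; default is
#'   simulated from `config$sim`.
#' @param annotations optional annotation data frame for the brain filter;
#'   `NULL` skips the filter (e.g. for fully synthetic proteins without
#'   curated annotations).
#' @return An object of class `"funnel_report"`: list with `threshold_g`,
#'   `m_quantified` (per day), `n_sig_day4`, `n_sig_day5`, `n_overlap`,
#'   `n_union`, `n_consistent`, `n_brain_filtered` (`NA` when the filter is
#'   skipped), `candidates` (the `candidate_set`), and `candidate_table`
#'   (per-day rho/p/q of the consistent candidates).
#' @export
run_full_pipeline <- function(config = pipeline_config(),
                              proteome = NULL,
                              annotations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim

  cohort <- gen_cohort(sim)
  ref <- sim$group_weight_params[[config$ref_group]]
  if (is.null(ref))
    stop("no reference group `", config$ref_group, "` in the simulation",
         call. = FALSE)
  rule <- threshold_rule(ref[[1]], ref[[2]], config$k_sd)
  thr <- fgr_threshold(rule)
  cohort <- classify_pups(cohort, thr)
  message("classified ", nrow(cohort), " pups; threshold ",
          format(thr, digits = 4), " g")

  if (is.null(proteome)) proteome <- gen_proteome(cohort, sim)
  s4 <- screen_day(proteome$pnd4$abundance, proteome$pnd4$weights,
                   p_thresh = config$p_thresh, q_thresh = config$q_thresh,
                   pi0_mode = config$pi0_mode)
  s5 <- screen_day(proteome$pnd5$abundance, proteome$pnd5$weights,
                   p_thresh = config$p_thresh, q_thresh = config$q_thresh,
                   pi0_mode = config$pi0_mode)
  message("screened PND4: ", nrow(s4), " proteins, ", sum(s4$significant),
          " significant; PND5: ", nrow(s5), " proteins, ",
          sum(s5$significant), " significant")

  cand <- concordant_candidates(s4, s5)
  message("overlap ", length(cand$overlap), " -> consistent direction ",
          length(cand$consistent_direction))

  n_filtered <- NA_integer_
  if (!is.null(annotations)) {
    cand <- brain_expression_filter(cand, annotations,
                                    min_level = config$min_level,
                                    cell_classes = config$cell_classes)
    n_filtered <- length(cand$brain_filtered)
    message("brain-expression filter retained ", n_filtered)
  }

  consistent <- cand$consistent_direction
  i4 <- match(consistent, cand$day4$protein_id)
  i5 <- match(consistent, cand$day5$protein_id)
  candidate_table <- data.frame(
    protein_id = consistent,
    direction = unname(cand$directions[consistent]),
    rho_pnd4 = cand$day4$rho[i4], p_pnd4 = cand$day4$p_value[i4],
    q_pnd4 = cand$day4$q_value[i4],
    rho_pnd5 = cand$day5$rho[i5], p_pnd5 = cand$day5$p_value[i5],
    q_pnd5 = cand$day5$q_value[i5],
    stringsAsFactors = FALSE
  )

  report <- structure(
    list(threshold_g = thr,
         m_quantified = c(PND4 = nrow(s4), PND5 = nrow(s5)),
         n_sig_day4 = length(cand$sig_day4),
         n_sig_day5 = length(cand$sig_day5),
         n_overlap = length(cand$overlap),
         n_union = union_report(length(cand$sig_day4),
                                length(cand$sig_day5),
                                length(cand$overlap)),
         n_consistent = length(consistent),
         n_brain_filtered = n_filtered,
         candidates = cand,
         candidate_table = candidate_table,
         cohort = cohort,
         truth = proteome$truth),
    class = "funnel_report"
  )
  check_funnel(report)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_table(cohort, file.path(config$outdir, "samples_classified.tsv"))
    write_table(s4, file.path(config$outdir, "screen_day4.tsv"))
    write_table(s5, file.path(config$outdir, "screen_day5.tsv"))
    write_table(candidate_table, file.path(config$outdir, "candidates.tsv"))
    jsonlite::write_json(
      report[c("threshold_g", "n_sig_day4", "n_sig_day5", "n_overlap",
               "n_union", "n_consistent", "n_brain_filtered")],
      file.path(config$outdir, "funnel_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Arithmetic-consistency postconditions of the funnel.
check_funnel <- function(r) {
  stopifnot(
    r$n_union == r$n_sig_day4 + r$n_sig_day5 - r$n_overlap,
    r$n_overlap <= min(r$n_sig_day4, r$n_sig_day5),
    r$n_consistent <= r$n_overlap,
    is.na(r$n_brain_filtered) || r$n_brain_filtered <= r$n_consistent
  )
  invisible(r)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Biomarker candidate funnel\n")
  cat(sprintf("  FGR threshold: %.3f g\n", x$threshold_g))
  cat(sprintf("  proteins screened: %d (PND4) / %d (PND5)\n",
              x$m_quantified[["PND4"]], x$m_quantified[["PND5"]]))
  cat(sprintf("  significant: %d (PND4), %d (PND5); overlap %d; union %d\n",
              x$n_sig_day4, x$n_sig_day5, x$n_overlap, x$n_union))
  cat(sprintf("  consistent direction on both days: %d\n", x$n_consistent))
  if (!is.na(x$n_brain_filtered))
    cat(sprintf("  retained by brain-expression filter: %d\n",
                x$n_brain_filtered))
  invisible(x)
}

#' @export
summary.funnel_report <- function(object, ...) {
  print(object)
  if (nrow(object$candidate_table)) {
    cat("\nConsistent candidates:\n")
    print(head(object$candidate_table, 20), digits = 3, row.names = FALSE)
  }
  invisible(object)
}
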