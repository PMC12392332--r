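#' Per-day proteome screen against birth weight
#'
#' For every protein of one postnatal day's abundance matrix, computes the
#' Spearman correlation with birth weight, a two-sided p-value, and a Storey
#' q-value calculated across all proteins screened that day.  A protein is
#' `significant` when `p < p_thresh` and `q < q_thresh` (defaults 0.05 and
#' 0.1).  Missing abundances are handled per protein with complete pairs
#' only; proteins with fewer than 4 complete pairs are flagged
#' (`n_too_small`), given `NA` statistics, and excluded from the q-value
#' calculation.
#'
#' @param abundance proteins x samples numeric matrix with row and column
#'   names (an `AbundanceMatrix`).
#' @param weights named numeric vector of birth weights (grams) covering
#'   every sample (column) of `abundance`.
#' @param p_thresh,q_thresh significance thresholds on p and q.
#' @param pi0_mode `"smoother"` or `"fixed"`; see [estimate_pi0()].
#' @param pi0_fixed pi0 used in fixed mode.
#' @param day optional day label recorded in the result (defaults to the
#'   matrix's `day` attribute).
#' @return A data frame (one row per protein): `protein_id`, `day`, `n`,
#'   `rho`, `p_value`, `q_value`, `significant`, `n_too_small`; the pi0
#'   used is attached as attribute `"pi0"`.
#' @export
screen_day <- function(abundance, weights,
                       p_thresh = 0.05, q_thresh = 0.1,
                       pi0_mode = c("smoother", "fixed"),
                       pi0_fixed = 1.0,
                       day = attr(abundance, "day") %||% NA_character_) {
  pi0_mode <- match.arg(pi0_mode)
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs protein row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(abundance)) || anyDuplicated(colnames(abundance)))
    stop("duplicate protein or sample ids", call. = FALSE)
  missing_w <- setdiff(colnames(abundance), names(weights))
  if (length(missing_w))
    stop("no birth weight for sample(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  w <- weights[colnames(abundance)]

  stats <- t(apply(abundance, 1L, function(a) {
    ok <- is.finite(a) & is.finite(w)
    n <- sum(ok)
    if (n < 4L || sd(a[ok]) == 0 || sd(w[ok]) == 0)
      return(c(n = n, rho = NA_real_, p = NA_real_))
    rho <- spearman_rho(a[ok], w[ok])
    c(n = n, rho = rho, p = spearman_pvalue(rho, n))
  }))

  res <- data.frame(
    protein_id = rownames(abundance),
    day = day,
    n = as.integer(stats[, "n"]),
    rho = stats[, "rho"],
    p_value = stats[, "p"],
    q_value = NA_real_,
    significant = FALSE,
    n_too_small = as.integer(stats[, "n"]) < 4L,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  usable <- !is.na(res$p_value)
  if (any(usable)) {
    pi0 <- estimate_pi0(res$p_value[usable], mode = pi0_mode,
                        pi0_fixed = pi0_fixed)
    res$q_value[usable] <- storey_qvalues(res$p_value[usable], pi0)
    res$significant <- usable & res$p_value < p_thresh & res$q_value < q_thresh
    attr(res, "pi0") <- pi0
  }
  attr(res, "thresholds") <- c(p = p_thresh, q = q_thresh)
  res
}

#' Cross-day concordant candidate selection
#'
#' Intersects the proteins significant on both days and retains those whose
#' correlation has the same (nonzero) sign on both days -- the dual-day
#' concordance rule of the screen.  Proteins screened on only one day are
#' excluded (with a message) since they cannot be consistent on both days.
#'
#' @param day4,day5 per-day screen tables from [screen_day()].
#' @return An object of class `"candidate_set"`: list with `sig_day4`,
#'   `sig_day5`, `overlap`, `consistent_direction`, `directions` (+1/-1
#'   named by protein), `brain_filtered` (`NULL` until
#'   [brain_expression_filter()] is applied), and the per-day tables.
#' @export
concordant_candidates <- function(day4, day5) {
  universe <- intersect(day4$protein_id, day5$protein_id)
  if (length(universe) < length(union(day4$protein_id, day5$protein_id)))
    message("restricting concordance to the ",
            length(universe), " proteins screened on both days")
  d4 <- day4[match(universe, day4$protein_id), ]
  d5 <- day5[match(universe, day5$protein_id), ]
  sig4 <- universe[d4$significant]
  sig5 <- universe[d5$significant]
  overlap <- intersect(sig4, sig5)
  r4 <- setNames(d4$rho, universe)[overlap]
  r5 <- setNames(d5$rho, universe)[overlap]
  same_sign <- sign(r4) == sign(r5) & sign(r4) != 0
  consistent <- overlap[same_sign]
  structure(
    list(sig_day4 = sig4,
         sig_day5 = sig5,
         overlap = overlap,
         consistent_direction = consistent,
         directions = setNames(sign(r4[same_sign]), consistent),
         brain_filtered = NULL,
         needs_review = character(0),
         day4 = d4, day5 = d5),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate funnel:\n")
  cat(sprintf("  significant PND4: %d   PND5: %d   both days: %d\n",
              length(x$sig_day4), length(x$sig_day5), length(x$overlap)))
  cat(sprintf("  consistent direction: %d\n", length(x$consistent_direction)))
  if (!is.null(x$brain_filtered))
    cat(sprintf("  brain-expression filtered: %d\n", length(x$brain_filtered)))
  invisible(x)
}

# ordered expression levels of the annotation vocabulary
.LEVELS <- c(not_detected = 0L, low = 1L, medium = 2L, high = 3L)

#' Brain-expression filter of the candidate set
#'
#' Retains candidates annotated at or above `min_level` in at least one of
#' the allowed brain `cell_classes`, in any region -- the operational
#' reading of "highly expressed in brain cells" used to go from the
#' concordant candidates to the final biomarker shortlist.  Candidates with
#' no annotation record are excluded from `brain_filtered` but listed in
#' `needs_review`.
#'
#' @param candidates a `candidate_set` from [concordant_candidates()], or a
#'   character vector of protein ids.
#' @param annotations data frame with columns `protein_id`, `region`,
#'   `cell_class`, `level` (levels: `not_detected < low < medium < high`);
#'   see [read_brain_annotations()].
#' @param min_level minimum level, one of `"low"`, `"medium"`, `"high"`.
#' @param cell_classes cell classes that count as brain-cell expression.
#' @return If `candidates` is a `candidate_set`, the set with
#'   `brain_filtered` (and `needs_review`) filled in; otherwise the
#'   retained character vector with attribute `"needs_review"`.
#' @export
brain_expression_filter <- function(candidates, annotations,
                                    min_level = "medium",
                                    cell_classes = c("neuronal", "glial",
                                                     "purkinje")) {
  if (!min_level %in% names(.LEVELS))
    stop("`min_level` must be one of: ",
         paste(names(.LEVELS), collapse = ", "), call. = FALSE)
  need <- c("protein_id", "region", "cell_class", "level")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(annotations$level), names(.LEVELS))
  if (length(bad))
    stop("unknown annotation level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  ids <- if (inherits(candidates, "candidate_set"))
    candidates$consistent_direction else as.character(candidates)

  hit <- annotations$cell_class %in% cell_classes &
    .LEVELS[annotations$level] >= .LEVELS[[min_level]]
  passing <- unique(annotations$protein_id[hit])
  annotated <- unique(annotations$protein_id)

  kept <- ids[ids %in% passing]
  unreviewed <- ids[!ids %in% annotated]
  if (length(unreviewed))
    message(length(unreviewed),
            " candidate(s) lack annotation records; held for review: ",
            paste(unreviewed, collapse = ", "))

  if (inherits(candidates, "candidate_set")) {
    candidates$brain_filtered <- kept
    candidates$needs_review <- unreviewed
    candidates
  } else {
    structure(kept, needs_review = unreviewed)
  }
}

#' Read a brain-annotation table
#'
#' Reads a TSV of per-protein brain-expression annotations (`protein_id`,
#' `region`, `cell_class`, `level`).  The package ships
#' `table1_annotations.tsv`, Human Protein Atlas-derived annotations of the
#' 15 concordant CSF candidates, under `inst/extdata`.
#'
#' @param path file path; defaults to the packaged candidate annotations.
#' @return A data frame suitable for [brain_expression_filter()].
#' @export
read_brain_annotations <- function(path = system.file("extdata",
                                                      "table1_annotations.tsv",
                                                      package = "fgrscreen")) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "region", "cell_class", "level")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann
}

#' Union of two day-wise significant sets from the funnel counts
#'
#' @param n_day4,n_day5 significant-protein counts per day.
#' @param n_overlap count significant on both days; must not exceed either
#'   day's count.
#' @return `n_day4 + n_day5 - n_overlap`.
#' @examples
#' union_report(140, 123, 51)  # 212
#' @export
union_report <- function(n_day4, n_day5, n_overlap) {
  if (n_overlap > min(n_day4, n_day5))
    stop("overlap exceeds a day-wise set", call. = FALSE)
  n_day4 + n_day5 - n_overlap
}
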