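make_matrix <- function(values, proteins, samples) {
  matrix(values, nrow = length(proteins), byrow = TRUE,
         dimnames = list(proteins, samples))
}

test_that("a protein tracking birth weight exactly screens as significant", {
  w <- setNames(c(5.1, 5.8, 6.2, 6.9, 7.3, 5.5, 6.0, 6.6, 7.0, 7.4),
                paste0("s", 1:10))
  set.seed(1)
  null_rows <- matrix(rnorm(990), nrow = 99)
  ab <- rbind(matrix(w, nrow = 1), null_rows)
  dimnames(ab) <- list(c("TRACKER", paste0("N", 1:99)), names(w))
  res <- screen_day(ab, w, pi0_mode = "fixed")
  tr <- res[res$protein_id == "TRACKER", ]
  expect_equal(tr$rho, 1)
  expect_true(tr$significant)
  expect_equal(tr$n, 10L)
})

test_that("screening validates ids and reports missing weights", {
  ab <- make_matrix(1:6, c("p1", "p2"), c("s1", "s2", "s3"))
  expect_error(screen_day(ab, c(s1 = 5, s2 = 6)), "s3")
  dup <- make_matrix(1:6, c("p1", "p1"), c("s1", "s2", "s3"))
  expect_error(screen_day(dup, c(s1 = 5, s2 = 6, s3 = 7)), "duplicate")
})

test_that("proteins with too few complete pairs are flagged, not q-ranked", {
  set.seed(3)
  w <- setNames(runif(8, 5, 7), paste0("s", 1:8))
  ab <- matrix(rnorm(10 * 8), nrow = 10,
               dimnames = list(paste0("p", 1:10), names(w)))
  ab[1, 4:8] <- NA  # 3 complete pairs only
  res <- screen_day(ab, w, pi0_mode = "fixed")
  expect_true(res$n_too_small[1])
  expect_true(is.na(res$q_value[1]))
  expect_false(res$significant[1])
  expect_equal(res$n[1], 3L)
  expect_false(any(res$n_too_small[-1]))
})

test_that("planted responders screen with their planted direction", {
  cfg <- sim_config(seed = 10)
  sim <- gen_proteome(gen_cohort(cfg), cfg)
  res <- screen_day(sim$pnd4$abundance, sim$pnd4$weights)
  hits <- res[res$protein_id %in% sim$truth$responder_ids &
                res$significant, ]
  expect_gt(nrow(hits), 0)
  expect_equal(sign(hits$rho),
               unname(sim$truth$directions[hits$protein_id]))
})

test_that("concordance requires significance on both days and matching sign", {
  row <- function(id, rho, sig) data.frame(
    protein_id = id, day = NA, n = 20L, rho = rho,
    p_value = 0.01, q_value = 0.05, significant = sig,
    n_too_small = FALSE, stringsAsFactors = FALSE)
  d4 <- rbind(row("A", -0.8, TRUE), row("B", -0.8, TRUE),
              row("C", 0.7, TRUE), row("D", 0.9, FALSE))
  d5 <- rbind(row("A", -0.6, TRUE), row("B", 0.6, TRUE),
              row("C", 0.5, FALSE), row("D", 0.9, TRUE))
  cand <- concordant_candidates(d4, d5)
  expect_setequal(cand$overlap, c("A", "B"))
  expect_identical(cand$consistent_direction, "A")
  expect_equal(unname(cand$directions["A"]), -1)
})

test_that("proteins screened on a single day are dropped from concordance", {
  row <- function(id, rho) data.frame(
    protein_id = id, day = NA, n = 20L, rho = rho, p_value = 0.001,
    q_value = 0.01, significant = TRUE, n_too_small = FALSE,
    stringsAsFactors = FALSE)
  d4 <- rbind(row("A", 0.8), row("ONLY4", 0.9))
  d5 <- rbind(row("A", 0.7), row("ONLY5", 0.9))
  expect_message(cand <- concordant_candidates(d4, d5), "both days")
  expect_identical(cand$overlap, "A")
})

test_that("union arithmetic matches the funnel counts", {
  expect_equal(union_report(140, 123, 51), 212)
  expect_equal(union_report(10, 10, 10), 10)
  expect_equal(union_report(3, 4, 0), 7)
  expect_error(union_report(3, 4, 4), "exceeds")
})

test_that("the packaged candidate annotations pass the brain filter as expected", {
  ann <- read_brain_annotations()
  cand <- read_table(system.file("extdata", "table1_candidates.tsv",
                                 package = "fgrscreen"),
                     c(protein_id = "character"))
  kept <- brain_expression_filter(cand$protein_id, ann)
  expect_setequal(as.character(kept),
                  c("Cd200", "A2m", "Ubb", "Serpini1", "Otub1", "Ube1"))
})

test_that("the brain filter honors its level and cell-class rule", {
  ann <- data.frame(
    protein_id = c("endo_only", "low_neuron", "med_glia", "high_purkinje"),
    region = "cerebral_cortex",
    cell_class = c("endothelial", "neuronal", "glial", "purkinje"),
    level = c("low", "low", "medium", "high"),
    stringsAsFactors = FALSE)
  ids <- c(ann$protein_id, "unannotated")
  expect_message(
    kept <- brain_expression_filter(ids, ann),
    "unannotated")
  expect_setequal(as.character(kept), c("med_glia", "high_purkinje"))
  expect_identical(attr(kept, "needs_review"), "unannotated")
  # rule is configurable
  loose <- suppressMessages(
    brain_expression_filter(ids, ann, min_level = "low",
                            cell_classes = c("neuronal", "endothelial")))
  expect_setequal(as.character(loose), c("endo_only", "low_neuron"))
})

test_that("brain-filtered candidates are always a subset of the concordant set", {
  cfg <- sim_config(seed = 30, n_proteins = 80, n_responders = 8)
  sim <- gen_proteome(gen_cohort(cfg), cfg)
  cand <- concordant_candidates(
    screen_day(sim$pnd4$abundance, sim$pnd4$weights),
    screen_day(sim$pnd5$abundance, sim$pnd5$weights))
  ann <- data.frame(protein_id = cand$consistent_direction[0:1],
                    region = "hippocampus", cell_class = "neuronal",
                    level = "high", stringsAsFactors = FALSE)
  cand2 <- suppressMessages(brain_expression_filter(cand, ann))
  expect_true(all(cand2$brain_filtered %in% cand2$consistent_direction))
})
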