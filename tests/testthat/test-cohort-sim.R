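test_that("generators are deterministic and use independent streams", {
  cfg <- sim_config(seed = 9, n_proteins = 40, n_responders = 4)
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  expect_identical(c1, c2)
  # running another generator in between must not perturb the cohort stream
  p1 <- gen_proteome(c1, cfg)
  c3 <- gen_cohort(cfg)
  expect_identical(c1, c3)
  p2 <- gen_proteome(c3, cfg)
  expect_identical(p1, p2)
  b1 <- gen_behavior(cfg)
  b2 <- gen_behavior(cfg)
  expect_identical(b1, b2)
  t1 <- gen_timecourse(cfg)
  expect_identical(t1, gen_timecourse(cfg))
})

test_that("control birth weights are calibrated to 7.01 +/- 0.55 g", {
  cfg <- sim_config(seed = 2, n_per_group = 10000)
  ctrl <- gen_cohort(cfg, groups = "control")
  w <- ctrl$birth_weight_g
  se_mean <- 0.55 / sqrt(10000)
  expect_lt(abs(mean(w) - 7.01), 3 * se_mean)
  se_sd <- 0.55 / sqrt(2 * (10000 - 1))
  expect_lt(abs(sd(w) - 0.55), 3 * se_sd)
})

test_that("zero-variance reference gives degenerate weights", {
  cfg <- sim_config(seed = 1, n_per_group = 25,
                    group_weight_params = list(control = c(7.01, 0)))
  ctrl <- gen_cohort(cfg)
  expect_true(all(ctrl$birth_weight_g == 7.01))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(group_weight_params = list(control = c(7, -1))),
               ">= 0")
  expect_error(sim_config(n_responders = 100, n_proteins = 50),
               "n_proteins")
  expect_error(sim_config(target_abs_rho = 1.2), "\\(0, 1\\)")
  expect_error(sim_config(noise_sd = 0), "> 0")
  cfg <- sim_config()
  expect_error(gen_proteome(cfg$group_weight_params$control[0], cfg),
               "empty")
})

test_that("a strong single responder is tightly correlated with weight", {
  cfg <- sim_config(seed = 13, n_per_group = 10, n_proteins = 10,
                    n_responders = 1, target_abs_rho = 0.99)
  sim <- gen_proteome(gen_cohort(cfg), cfg)
  id <- sim$truth$responder_ids
  rho <- spearman_rho(sim$pnd4$abundance[id, ], sim$pnd4$weights)
  expect_gte(abs(rho), 0.9)
  expect_equal(sign(rho), unname(sim$truth$directions[id]))
})

test_that("no responders means a fully null proteome", {
  cfg <- sim_config(seed = 4, n_proteins = 30, n_responders = 0)
  sim <- gen_proteome(gen_cohort(cfg), cfg)
  expect_length(sim$truth$responder_ids, 0)
  expect_length(sim$truth$directions, 0)
})

test_that("full concordance keeps responder directions aligned across days", {
  cfg <- sim_config(seed = 21, n_proteins = 60, n_responders = 10,
                    concordance_prob = 1)
  sim <- gen_proteome(gen_cohort(cfg), cfg)
  expect_identical(sim$truth$directions, sim$truth$directions_pnd5)
  for (id in sim$truth$responder_ids) {
    r4 <- spearman_rho(sim$pnd4$abundance[id, ], sim$pnd4$weights)
    r5 <- spearman_rho(sim$pnd5$abundance[id, ], sim$pnd5$weights)
    if (abs(r4) >= 0.5 && abs(r5) >= 0.5)
      expect_identical(sign(r4), sign(r5))
  }
  # zero concordance flips every day-5 direction
  cfg0 <- sim_config(seed = 21, n_proteins = 60, n_responders = 10,
                     concordance_prob = 0)
  sim0 <- gen_proteome(gen_cohort(cfg0), cfg0)
  expect_identical(sim0$truth$directions_pnd5, -sim0$truth$directions)
})

test_that("shared-pup profiling reuses the day-4 samples", {
  cfg <- sim_config(seed = 3, n_proteins = 20, shared_pups = TRUE)
  sim <- gen_proteome(gen_cohort(cfg), cfg)
  expect_identical(colnames(sim$pnd4$abundance), colnames(sim$pnd5$abundance))
  cfg2 <- sim_config(seed = 3, n_proteins = 20, shared_pups = FALSE)
  sim2 <- gen_proteome(gen_cohort(cfg2), cfg2)
  expect_false(any(colnames(sim2$pnd4$abundance) %in%
                     colnames(sim2$pnd5$abundance)))
})

test_that("noise-free time course hits its target arm levels exactly", {
  cfg <- sim_config(seed = 6, timecourse = list(noise_sd = 0,
                                                elevation = 2,
                                                attenuation = 1))
  tc <- normalize_timecourse(gen_timecourse(cfg), reference = "per_day")
  agg <- aggregate(relative_expression ~ group + day, tc, mean)
  sham <- tc[tc$group == "sham", "relative_expression"]
  expect_equal(sham, rep(1, length(sham)))
  fgr <- agg[agg$group == "fgr_vehicle", "relative_expression"]
  expect_equal(fgr, rep(2, length(fgr)))
  msc5plus <- agg[agg$group == "fgr_msc" & agg$day >= 5,
                  "relative_expression"]
  expect_equal(msc5plus, rep(1, length(msc5plus)))
})

test_that("time-course elevation is detectable by the Steel-Dwass test", {
  cfg <- sim_config(seed = 8, timecourse = list(n_per_group = 15,
                                                elevation = 2,
                                                noise_sd = 0.3))
  tc <- normalize_timecourse(gen_timecourse(cfg), reference = "per_day")
  d14 <- tc[tc$day == 14 & tc$analyte == "Serpini1" &
              tc$group %in% c("sham", "fgr_vehicle"), ]
  res <- steel_dwass_test(d14, value_col = "relative_expression",
                          group_col = "group")
  expect_lt(res$p_value, 0.05)
})

test_that("null behavioral deficit makes arms exchangeable", {
  cfg <- sim_config(seed = 14,
                    behavior = list(deficit = 0, n_per_arm = 60))
  bh <- gen_behavior(cfg)
  geo <- score_behavior(bh, "geotaxis")
  m <- tapply(geo$latency_s, geo$arm, mean)
  s <- tapply(geo$latency_s, geo$arm, sd)
  n <- tapply(geo$latency_s, geo$arm, length)
  se <- sqrt(s["sham"]^2 / n["sham"] + s["fgr_vehicle"]^2 / n["fgr_vehicle"])
  expect_lt(abs(m["sham"] - m["fgr_vehicle"]), 4 * se)
})

test_that("perfect alternation bias produces rotation sequences", {
  cfg <- sim_config(seed = 17,
                    behavior = list(alternation_bias = c(
                      sham = 1, non_fgr_vehicle = 1,
                      fgr_vehicle = 1, fgr_msc = 1)))
  bh <- gen_behavior(cfg)
  ym <- score_behavior(bh, "ymaze")
  entries <- lengths(strsplit(ym$arm_sequence, ","))
  expect_equal(ym$alternation,
               (entries - 2) / (entries - 1) * 100)
})

test_that("behavioral deficits run in the configured directions", {
  cfg <- sim_config(seed = 19, behavior = list(n_per_arm = 40))
  bh <- gen_behavior(cfg)
  geo <- score_behavior(bh, "geotaxis")
  expect_gt(mean(geo$latency_s[geo$arm == "fgr_vehicle"]),
            mean(geo$latency_s[geo$arm == "sham"]))
  expect_gt(mean(geo$score[geo$arm == "sham"]),
            mean(geo$score[geo$arm == "fgr_vehicle"]))
  rr <- score_behavior(bh, "rotarod")
  expect_gt(mean(as.numeric(rr$trial1_latency_s)[rr$arm == "sham"]),
            mean(as.numeric(rr$trial1_latency_s)[rr$arm == "fgr_vehicle"]))
  ym <- score_behavior(bh, "ymaze")
  expect_gt(mean(ym$alternation[ym$arm == "sham"]),
            mean(ym$alternation[ym$arm == "fgr_vehicle"]))
})
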