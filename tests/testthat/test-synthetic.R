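test_that("default cohort mirrors the 20/20/5 discovery structure", {
  sim <- simulateCohort(simulationConfig(seed = 3))
  expect_equal(ncol(sim$cohort), 45L)
  expect_equal(as.vector(table(classLabels(sim$cohort))[c("IBC", "nonIBC", "normal")]),
               c(20L, 20L, 5L))
  expect_equal(nrow(sim$cohort), 2000L)
  expect_length(sim$truth@planted_genes, 59L)
  expect_true(all(sim$truth@planted_genes %in% rownames(sim$cohort)))
})

test_that("planted effect magnitude matches the configured shift", {
  sim <- simulateCohort(simulationConfig(seed = 1))
  m <- exprValues(sim$cohort)
  lab <- classLabels(sim$cohort)
  d <- rowMeans(m[sim$truth@planted_genes, lab == "IBC"]) -
    rowMeans(m[sim$truth@planted_genes, lab == "nonIBC"])
  # signed by the planted direction, in noise-SD units
  expect_equal(mean(d * sim$truth@planted_sign), 1.5, tolerance = 0.1)
  expect_true(abs(mean(abs(d)) - 1.5) < 0.15)
  # both directions occur
  expect_true(any(sim$truth@planted_sign > 0) && any(sim$truth@planted_sign < 0))
  # normals carry no shift
  dn <- rowMeans(m[sim$truth@planted_genes, lab == "normal"]) -
    rowMeans(m[sim$truth@planted_genes, lab == "nonIBC"])
  expect_lt(abs(mean(dn * sim$truth@planted_sign)), 0.35)
})

test_that("zero effect makes planted and background genes exchangeable", {
  sim <- simulateCohort(simulationConfig(effect_size = 0, seed = 5))
  m <- exprValues(sim$cohort)
  lab <- classLabels(sim$cohort)
  tstat <- apply(m, 1, function(v)
    t.test(v[lab == "IBC"], v[lab == "nonIBC"])$statistic)
  planted <- rownames(m) %in% sim$truth@planted_genes
  ks <- ks.test(tstat[planted], tstat[!planted])
  expect_gt(ks$p.value, 0.01)
})

test_that("generation is a pure function of seed and linear in effect size", {
  cfg <- simulationConfig(n_genes = 300, seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(exprValues(a$cohort), exprValues(b$cohort))
  expect_identical(sampleAnnotations(a$cohort), sampleAnnotations(b$cohort))
  expect_identical(a$truth@planted_genes, b$truth@planted_genes)

  eff <- vapply(c(1, 2), function(e) {
    sim <- simulateCohort(simulationConfig(n_genes = 500, effect_size = e,
                                           seed = 21))
    m <- exprValues(sim$cohort); lab <- classLabels(sim$cohort)
    d <- rowMeans(m[sim$truth@planted_genes, lab == "IBC"]) -
      rowMeans(m[sim$truth@planted_genes, lab == "nonIBC"])
    mean(d * sim$truth@planted_sign)
  }, numeric(1))
  expect_equal(eff[2] / eff[1], 2, tolerance = 0.2)
})

test_that("validation cohorts keep the planted effect despite batch shift", {
  cfg <- simulationConfig(seed = 2)
  sim <- simulateCohort(cfg)
  v <- simulateValidationCohort(cfg, sim$truth, "pre")
  expect_equal(ncol(v), 61L)
  expect_equal(as.vector(table(classLabels(v))[c("IBC", "nonIBC")]),
               c(33L, 28L))
  m <- exprValues(v); lab <- classLabels(v)
  d <- rowMeans(m[sim$truth@planted_genes, lab == "IBC"]) -
    rowMeans(m[sim$truth@planted_genes, lab == "nonIBC"])
  expect_equal(mean(d * sim$truth@planted_sign), 1.5, tolerance = 0.15)
  # global batch offset present in the overall level
  expect_gt(mean(m) - mean(exprValues(sim$cohort)), 0.2)
})

test_that("post-treatment attenuation scales the planted effect", {
  cfg <- simulationConfig(seed = 4, attenuation = 0.2)
  sim <- simulateCohort(cfg)
  vp <- simulateValidationCohort(cfg, sim$truth, "post")
  expect_equal(as.vector(table(classLabels(vp))[c("IBC", "nonIBC")]),
               c(13L, 35L))
  m <- exprValues(vp); lab <- classLabels(vp)
  d <- rowMeans(m[sim$truth@planted_genes, lab == "IBC"]) -
    rowMeans(m[sim$truth@planted_genes, lab == "nonIBC"])
  expect_lt(abs(mean(d * sim$truth@planted_sign) - 0.3), 0.15)

  cfg0 <- simulationConfig(seed = 4, attenuation = 0)
  v0 <- simulateValidationCohort(cfg0, sim$truth, "post")
  m0 <- exprValues(v0); lab0 <- classLabels(v0)
  d0 <- rowMeans(m0[sim$truth@planted_genes, lab0 == "IBC"]) -
    rowMeans(m0[sim$truth@planted_genes, lab0 == "nonIBC"])
  expect_lt(abs(mean(d0 * sim$truth@planted_sign)), 0.2)
})

test_that("receptor scores admit a large exactly-matchable subset", {
  sim <- simulateCohort(simulationConfig(seed = 6))
  rec <- receptorScores(sim$cohort)
  lab <- classLabels(sim$cohort)
  strata <- paste(rec$er_score, rec$her2_score)
  pairs <- sum(vapply(unique(strata), function(s)
    min(sum(strata == s & lab == "IBC"), sum(strata == s & lab == "nonIBC")),
    numeric(1)))
  expect_gte(pairs, 18)  # >= 90% of the smaller class matchable
})

test_that("simulated survival has the configured class-dependent hazard", {
  cfg <- simulationConfig(seed = 8,
                          survival_config = list(baseline_hazard = 0.05,
                                                 hazard_ratio = 3,
                                                 censor_rate = 0))
  labels <- setNames(rep(c("IBC", "other"), c(3000, 3000)),
                     sprintf("P%04d", 1:6000))
  st <- simulateSurvival(labels, cfg)
  df <- asSurvivalFrame(st)
  expect_true(all(df$event == 1))
  # exponential means: 1/(h0*HR) vs 1/h0
  expect_equal(mean(df$time[df$group == "other"]) /
                 mean(df$time[df$group == "IBC"]), 3, tolerance = 0.2)

  cfg_cens <- simulationConfig(seed = 8,
                               survival_config = list(baseline_hazard = 0.05,
                                                      hazard_ratio = 3,
                                                      censor_rate = 1))
  st2 <- simulateSurvival(labels, cfg_cens)
  expect_true(all(asSurvivalFrame(st2)$event == 0))
  expect_error(logrankHr(st2), "zero observed events")

  expect_error(simulateSurvival(labels, simulationConfig(
    survival_config = list(baseline_hazard = 0.05, hazard_ratio = -1,
                           censor_rate = 0))), "hazard_ratio")
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(n_genes = 50, n_signal = 59), "n_signal")
  expect_error(simulationConfig(attenuation = 1.5), "attenuation")
  expect_error(simulationConfig(n_per_class = c(IBC = 0, nonIBC = 5)),
               "positive")
})
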