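panel_cohort <- function(samples) {
  # samples: named list of expression vectors over the panel genes
  panel <- readCentroidPanel(demo_panel_path())
  m <- do.call(cbind, samples)
  rownames(m) <- panel@genes
  ExpressionCohort(m)
}

test_that("a sample equal to a centroid is called that subtype with rho = 1", {
  panel <- readCentroidPanel(demo_panel_path())
  cohort <- panel_cohort(list(lumA = panel@centroids[, "LuminalA"],
                              basal = panel@centroids[, "Basallike"],
                              anti_her2 = -panel@centroids[, "HER2enriched"]))
  call <- pam50Call(cohort, panel)
  labs <- subtypeLabels(call)
  expect_identical(unname(labs[c("lumA", "basal")]),
                   c("LuminalA", "Basallike"))
  cors <- subtypeCorrelations(call)
  expect_equal(unname(cors["lumA", "LuminalA"]), 1, tolerance = 1e-12)
  expect_equal(unname(cors["basal", "Basallike"]), 1, tolerance = 1e-12)
  expect_equal(unname(cors["anti_her2", "HER2enriched"]), -1,
               tolerance = 1e-12)
})

test_that("subtype correlations equal the brute-force rank oracle", {
  panel <- readCentroidPanel(demo_panel_path())
  set.seed(19)
  vecs <- replicate(6, rnorm(10), simplify = FALSE)
  names(vecs) <- sprintf("r%d", 1:6)
  call <- pam50Call(panel_cohort(vecs), panel)
  for (s in names(vecs)) for (sub in colnames(panel@centroids)) {
    expect_equal(unname(subtypeCorrelations(call)[s, sub]),
                 spearman_bruteforce(vecs[[s]], panel@centroids[, sub]),
                 tolerance = 1e-12)
  }
})

test_that("calls are invariant to monotone per-sample transformations", {
  panel <- readCentroidPanel(demo_panel_path())
  set.seed(23)
  vecs <- replicate(5, rnorm(10, 7, 2), simplify = FALSE)
  names(vecs) <- sprintf("m%d", 1:5)
  raw <- pam50Call(panel_cohort(vecs), panel)
  warped <- pam50Call(panel_cohort(lapply(vecs, function(v) exp(v / 3))),
                      panel)
  expect_identical(subtypeLabels(raw), subtypeLabels(warped))
  expect_equal(subtypeCorrelations(raw), subtypeCorrelations(warped),
               tolerance = 1e-12)
})

test_that("low panel coverage refuses with a report; partial warns", {
  panel <- readCentroidPanel(demo_panel_path())
  m <- matrix(rnorm(8), 4, 2,
              dimnames = list(panel@genes[1:4], c("s1", "s2")))
  expect_error(pam50Call(ExpressionCohort(m), panel), "coverage 40%")
  m2 <- matrix(rnorm(14), 7, 2,
               dimnames = list(panel@genes[1:7], c("s1", "s2")))
  expect_warning(pam50Call(ExpressionCohort(m2), panel), "missing")
})

test_that("ROR is the affine-rescaled weighted correlation sum", {
  panel <- readCentroidPanel(demo_panel_path())
  subtypes <- colnames(panel@centroids)
  rho <- setNames(c(0.31, -0.12, 0.55, 0.08, -0.4), subtypes)
  call <- new("SubtypeCall", sample_ids = "x",
              subtype = subtypes[which.max(rho)],
              correlations = matrix(rho, 1, dimnames = list("x", subtypes)),
              ror_score = NA_real_)
  expected <- panel@ror_intercept +
    panel@ror_scale * sum(panel@ror_coefficients[subtypes] * rho)
  expect_equal(unname(rorScore(call, panel)), expected, tolerance = 1e-12)

  # zero correlations give the affine constant alone
  call0 <- new("SubtypeCall", sample_ids = "z", subtype = subtypes[1],
               correlations = matrix(0, 1, 5,
                                     dimnames = list("z", subtypes)),
               ror_score = NA_real_)
  expect_equal(unname(rorScore(call0, panel)), panel@ror_intercept)

  # doubling coefficients doubles (ROR - intercept)
  panel2 <- panel
  panel2@ror_coefficients <- 2 * panel@ror_coefficients
  expect_equal(unname(rorScore(call, panel2)) - panel2@ror_intercept,
               2 * (unname(rorScore(call, panel)) - panel@ror_intercept),
               tolerance = 1e-12)
})

test_that("KM product limit matches closed forms", {
  # 3 subjects, events at 1, 2, 3, no censoring
  st <- survivalTable(c("a", "b", "c"), c(1, 2, 3), c(1, 1, 1), "g")
  km <- kmCurve(st)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # complete data: S(t) = (n - #events <= t) / n
  set.seed(5)
  t10 <- sort(sample(1:50, 10))
  stc <- survivalTable(sprintf("p%d", 1:10), t10, rep(1, 10), "g")
  kmc <- kmCurve(stc)
  expect_equal(kmc$survival, (10 - seq_len(10)) / 10)

  # all censored: flat at 1
  stf <- survivalTable(c("a", "b"), c(2, 5), c(0, 0), "g")
  expect_true(all(kmCurve(stf)$survival == 1))

  # moving a censoring time that stays after the last event changes nothing
  st1 <- survivalTable(c("a", "b", "c"), c(1, 2, 9), c(1, 1, 0), "g")
  st2 <- survivalTable(c("a", "b", "c"), c(1, 2, 30), c(1, 1, 0), "g")
  k1 <- kmCurve(st1); k2 <- kmCurve(st2)
  expect_equal(k1$survival[k1$time <= 2], k2$survival[k2$time <= 2])
  expect_equal(k1$survival[k1$time <= 2], c(2 / 3, 1 / 3))

  expect_error(kmCurve(st, group = "nope"), "no subjects")
})

test_that("log-rank matches the per-event-time 2x2 tabulation oracle exactly", {
  # 10-subject toy table with ties and censoring
  time <- c(1, 2, 2, 3, 5, 5, 6, 8, 9, 11)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 0, 1)
  group <- rep(c("ibc_like", "other"), each = 5)
  st <- survivalTable(sprintf("s%d", 1:10), time, event, group)
  res <- logrankHr(st, reference = "other")
  oracle <- logrank_bruteforce(time, event, group)
  expect_equal(res$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(unname(res$observed["ibc_like"]), oracle$observed)
  expect_equal(unname(res$expected["ibc_like"]), oracle$expected,
               tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(oracle$chisq, 1, lower.tail = FALSE))
  # HR in O/E form
  hr_oracle <- (oracle$observed / oracle$expected) /
    ((sum(event) - oracle$observed) / (res$expected[["other"]]))
  expect_equal(res$hazard_ratio, hr_oracle, tolerance = 1e-10)
})

test_that("symmetric survival experience gives HR 1 and p near 1", {
  time <- rep(c(1, 3, 7, 12), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("A", "B"), each = 4)
  res <- logrankHr(survivalTable(sprintf("q%d", 1:8), time, event, group))
  expect_equal(res$hazard_ratio, 1, tolerance = 1e-10)
  expect_gt(res$p_value, 0.99)
  expect_true(res$ci_lower < 1 && res$ci_upper > 1)
})

test_that("log-rank errors on degenerate tables", {
  st <- survivalTable(c("a", "b"), c(1, 2), c(1, 1), c("A", "A"))
  expect_error(logrankHr(st), "2 groups")
  st3 <- survivalTable(c("a", "b", "c"), c(1, 2, 3), c(0, 0, 0),
                       c("A", "A", "B"))
  expect_error(logrankHr(st3), "zero observed events")
})

test_that("log-rank p-values are uniform under permuted labels", {
  cfg <- simulationConfig(seed = 41,
                          survival_config = list(baseline_hazard = 0.1,
                                                 hazard_ratio = 2.5,
                                                 censor_rate = 0.2))
  labels <- setNames(rep(c("IBC", "other"), c(40, 40)), sprintf("u%d", 1:80))
  st <- simulateSurvival(labels, cfg)
  df <- asSurvivalFrame(st)
  set.seed(17)
  pvals <- replicate(200, {
    perm <- sample(df$group)
    logrankHr(survivalTable(df$sample_id, df$time, df$event, perm))$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
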