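test_that("a separable gene yields perfect training-set scores", {
  cohort <- toy_cohort(n_pos = 6, n_neg = 6, n_sep = 1, n_noise = 5, gap = 8)
  model <- trainForest(cohort, colnames(cohort), rownames(cohort),
                       forestConfig(n_trees = 200, features_per_split = "all",
                                    seed = 1))
  res <- predictProba(model, cohort)
  lab <- classLabels(cohort)
  expect_identical(unname(predictedLabels(res)), unname(lab))
  # deep inside the positive region: scores near 1
  expect_true(all(probScores(res)[lab == "IBC"] > 0.9))
})

test_that("training is deterministic: same data and seed, identical output", {
  cohort <- toy_cohort(n_pos = 8, n_neg = 8, gap = 2, n_noise = 12)
  cfg <- forestConfig(n_trees = 150, seed = 77)
  m1 <- trainForest(cohort, colnames(cohort), rownames(cohort), cfg)
  m2 <- trainForest(cohort, colnames(cohort), rownames(cohort), cfg)
  expect_identical(probScores(predictProba(m1, cohort)),
                   probScores(predictProba(m2, cohort)))
  expect_identical(geneImportance(m1), geneImportance(m2))
  m3 <- trainForest(cohort, colnames(cohort), rownames(cohort),
                    forestConfig(n_trees = 150, seed = 78))
  expect_false(identical(probScores(predictProba(m1, cohort)),
                         probScores(predictProba(m3, cohort))))
})

test_that("scores live on the k/n_trees grid and respect the strict threshold", {
  cohort <- toy_cohort(n_pos = 6, n_neg = 6, gap = 1.5)
  model <- trainForest(cohort, colnames(cohort), rownames(cohort),
                       forestConfig(n_trees = 40, seed = 3))
  s <- probScores(predictProba(model, cohort))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s * 40, round(s * 40), tolerance = 1e-9)

  # single-tree forest votes are 0 or 1
  m1 <- trainForest(cohort, colnames(cohort), rownames(cohort),
                    forestConfig(n_trees = 1, seed = 3))
  expect_true(all(probScores(predictProba(m1, cohort)) %in% c(0, 1)))

  # a score exactly at the threshold goes negative (strict inequality)
  res <- new("ClassificationResult", sample_ids = c("a", "b"),
             prob_score = c(0.5, 0.52), predicted_label = c("nonIBC", "IBC"),
             threshold = 0.5, class_order = c("nonIBC", "IBC"))
  expect_identical(unname(predictedLabels(res)["a"]), "nonIBC")
  expect_error(new("ClassificationResult", sample_ids = "a",
                   prob_score = 0.5, predicted_label = "IBC",
                   threshold = 0.5, class_order = c("nonIBC", "IBC")),
               "positive iff")
})

test_that("label permutation drives out-of-bag accuracy to chance", {
  sim <- simulateCohort(simulationConfig(
    n_genes = 300, n_per_class = c(IBC = 40, nonIBC = 40), seed = 19))
  lab <- classLabels(sim$cohort)
  ids <- names(lab)[lab %in% c("IBC", "nonIBC")]
  set.seed(101)
  oob <- vapply(1:3, function(i) {
    perm <- setNames(sample(unname(lab[ids])), ids)
    pcohort <- ExpressionCohort(exprValues(sim$cohort)[, ids],
                                data.frame(sample_id = ids,
                                           class_label = perm))
    oobAccuracy(trainForest(pcohort, ids, rownames(pcohort),
                            forestConfig(n_trees = 400, seed = 23 + i)))
  }, numeric(1))
  expect_gt(mean(oob), 0.35)
  expect_lt(mean(oob), 0.65)
})

test_that("importance ranks a single decisive gene first", {
  cohort <- toy_cohort(n_pos = 8, n_neg = 8, n_sep = 1, n_noise = 30, gap = 6,
                       seed = 7)
  model <- trainForest(cohort, colnames(cohort), rownames(cohort),
                       forestConfig(n_trees = 300, seed = 5))
  imp <- geneImportance(model)
  expect_identical(imp$gene[1], "g01")
  expect_true(all(imp$importance >= 0))
  expect_false(is.unsorted(-imp$importance))
  expect_setequal(imp$gene, rownames(cohort))
})

test_that("under zero effect, planted importance ranks look like background", {
  sim <- simulateCohort(simulationConfig(n_genes = 400, effect_size = 0,
                                         seed = 29))
  design <- matchTrainingSet(sim$cohort, allow_unmatched = 1)
  model <- trainForest(sim$cohort, trainingIds(design), rownames(sim$cohort),
                       forestConfig(n_trees = 500, seed = 31))
  imp <- geneImportance(model)
  pos <- match(sim$truth@planted_genes, imp$gene)
  bg <- setdiff(seq_len(nrow(imp)), pos)
  expect_gt(wilcox.test(pos, bg)$p.value, 0.01)
})

test_that("noise genes do not break separability on separable data", {
  base <- toy_cohort(n_pos = 6, n_neg = 6, n_sep = 1, n_noise = 2, gap = 8)
  wide <- toy_cohort(n_pos = 6, n_neg = 6, n_sep = 1, n_noise = 60, gap = 8)
  for (cohort in list(base, wide)) {
    model <- trainForest(cohort, colnames(cohort), rownames(cohort),
                         forestConfig(n_trees = 300, seed = 2))
    res <- predictProba(model, cohort)
    expect_identical(unname(predictedLabels(res)),
                     unname(classLabels(cohort)))
  }
})

test_that("training rejects degenerate inputs with clear messages", {
  cohort <- toy_cohort(n_pos = 4, n_neg = 4)
  lab <- classLabels(cohort)
  expect_error(trainForest(cohort, names(lab)[lab == "IBC"],
                           rownames(cohort), forestConfig()),
               "2 classes")
  expect_error(trainForest(cohort, colnames(cohort), c("g01", "ghost"),
                           forestConfig()), "ghost")
  other <- ExpressionCohort(matrix(rnorm(4), 2, 2,
                                   dimnames = list(c("h1", "h2"),
                                                   c("o1", "o2"))))
  expect_error(predictProba(trainForest(cohort, colnames(cohort), "g01",
                                        forestConfig(n_trees = 10)),
                            other),
               "missing")
  expect_error(forestConfig(n_trees = 0), "n_trees")
})

test_that("mtry rules resolve within bounds", {
  expect_equal(ibcsig:::.resolve_mtry("sqrt", 100), 10L)
  expect_equal(ibcsig:::.resolve_mtry("log2", 64), 6L)
  expect_equal(ibcsig:::.resolve_mtry("all", 7), 7L)
  expect_equal(ibcsig:::.resolve_mtry(500, 20), 20L)
  expect_equal(ibcsig:::.resolve_mtry(3, 20), 3L)
})
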