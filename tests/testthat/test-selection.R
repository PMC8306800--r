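cohortFixture <- function(seed = 21, n = 80, nMirna = 3,
                          effects = c("mir-001" = -1)) {
  simulateExpressionCohort(simulationConfig(
    seed = seed, nCohort = n, nMirna = nMirna, plantedEffects = effects))
}

test_that("group expression means equal a brute-force groupby mean", {
  coh <- cohortFixture()
  cd <- as.data.frame(SummarizedExperiment::colData(coh))
  keys <- assignGroups(cd)
  groups <- sort(unique(keys))
  prof <- groupExpressionMeans(coh, groups)
  expr <- exprMatrix(coh)
  for (g in colnames(prof$means))
    for (m in rownames(prof$means))
      expect_equal(prof$means[m, g], mean(expr[m, keys == g]),
                   tolerance = 1e-12)
  expect_identical(sum(prof$n), ncol(coh))
})

test_that("population regression matches the closed-form OLS slope", {
  withr::with_seed(77, {
    x <- rnorm(16)
    y <- 3 - 2 * x + rnorm(16, sd = 0.3)
    prof <- data.frame(group = sprintf("G%02d", 1:16), rmst_months = y,
                       n = 100, n_events = 50)
    reg <- populationRegression(setNames(x, prof$group), prof)
    expect_equal(reg$slope, olsSlope(x, y), tolerance = 1e-10)
    expect_equal(reg$r, cor(x, y), tolerance = 1e-12)

    # exact proportionality: r = 1, p ~ 0
    prof2 <- prof; prof2$rmst_months <- 2 * x + 5
    reg2 <- suppressWarnings(
      populationRegression(setNames(x, prof$group), prof2))
    expect_equal(reg2$r, 1, tolerance = 1e-9)
    expect_lt(reg2$p_value, 1e-12)
  })
  expect_error(populationRegression(c(A = 1, B = 2),
                                    data.frame(group = c("A", "B"),
                                               rmst_months = c(1, 2))),
               "3 shared groups")
})

test_that("permuted group expression gives calibrated regression p-values", {
  withr::with_seed(88, {
    x <- rnorm(16)
    y <- rnorm(16)
    prof <- data.frame(group = sprintf("G%02d", 1:16), rmst_months = y,
                       n = 100, n_events = 50)
    sig <- vapply(1:200, function(i) {
      populationRegression(setNames(sample(x), prof$group),
                           prof)$p_value < 0.05
    }, logical(1))
    expect_lte(mean(sig), 0.11)
    expect_gte(mean(sig), 0.005)
  })
})

test_that("imputation is exact: group means round-trip to machine precision", {
  cfg <- simulationConfig(seed = 31, nRegistry = 2000, nCohort = 100,
                          nMirna = 2)
  reg <- simulateRegistry(cfg)
  coh <- simulateExpressionCohort(cfg)
  keys <- assignGroups(reg)
  groups <- commonGroups(assignGroups(
    as.data.frame(SummarizedExperiment::colData(coh))), keys)
  means <- groupExpressionMeans(coh, groups)$means["mir-001", ]
  imp <- imputeGroupExpression(reg, means)
  impKeys <- assignGroups(imp)
  for (g in unique(impKeys))
    expect_identical(unique(imp$pseudo_expr[impKeys == g]),
                     unname(means[g]))
  expect_identical(nrow(imp) + attr(imp, "n_dropped"), nrow(reg))
  # brute-force dictionary lookup
  expect_identical(imp$pseudo_expr, unname(means[impKeys]))
})

test_that("population Cox/KM flips direction under negation", {
  cfg <- simulationConfig(seed = 41, nRegistry = 3000)
  reg <- simulateRegistry(cfg)
  keys <- assignGroups(reg)
  sev <- (reg$t_stage - 1) + reg$n_stage + reg$m_stage + (reg$grade - 1)
  pseudo <- -sev + 0.01 * as.integer(factor(keys))  # anti-monotone w/ hazard
  p1 <- populationCoxKm(reg$time, reg$event, pseudo)
  p2 <- populationCoxKm(reg$time, reg$event, -pseudo)
  expect_lt(p1$cox$beta, 0)
  expect_identical(p1$km$direction, 1L)
  expect_equal(p1$cox$beta, -p2$cox$beta, tolerance = 1e-9)
  expect_identical(p2$km$direction, -1L)
  expect_error(populationCoxKm(reg$time, reg$event, rep(1, nrow(reg))),
               "constant")
})

test_that("discordant layers are rejected with a named reason", {
  cohortRow <- list(cohort_pass = TRUE, cohort_direction = 1L,
                    cohort_beta = -0.5)
  regression <- list(slope = 2, p_value = 0.001, r = 0.9)
  population <- list(
    cox = list(beta = -0.4, p_value = 0.001, converged = TRUE),
    km = list(logrank_p = 0.001, direction = 1L))
  ok <- selectPrognostic(cohortRow, regression, population)
  expect_identical(ok$verdict, "prognostic_selected")
  expect_identical(ok$direction, "positive")

  flipped <- population
  flipped$cox$beta <- 0.4              # significant but opposite sign
  bad <- selectPrognostic(cohortRow, regression, flipped)
  expect_identical(bad$verdict, "rejected")
  expect_true("discordant direction" %in% bad$failure_reasons)

  weak <- population
  weak$km$logrank_p <- 0.2
  miss <- selectPrognostic(cohortRow, regression, weak)
  expect_identical(miss$verdict, "rejected")
  expect_true("population KM not significant" %in% miss$failure_reasons)
})

test_that("the prognostic rule is strictly stronger than the chemo rule", {
  withr::with_seed(99, {
    for (i in 1:50) {
      cohortRow <- list(cohort_pass = TRUE,
                        cohort_direction = sample(c(-1L, 1L), 1))
      regression <- list(slope = rnorm(1), p_value = runif(1, 0, 0.1))
      population <- list(
        cox = list(beta = rnorm(1), p_value = runif(1, 0, 0.1),
                   converged = TRUE),
        km = list(logrank_p = runif(1, 0, 0.1),
                  direction = sample(c(-1L, 1L), 1)))
      prog <- selectPrognostic(cohortRow, regression, population)
      chem <- selectChemopredictive(cohortRow, regression, population)
      # prognostic-selected implies chemo-selected; equivalently, a
      # chemo rejection implies a prognostic rejection
      expect_true(prog$verdict == "rejected" ||
                    chem$verdict %in% c("chemo_sensitive",
                                        "chemo_resistant"))
    }
  })
})

test_that("chemo verdict maps direction to sensitive/resistant", {
  cohortRow <- list(cohort_pass = TRUE, cohort_direction = -1L)
  regression <- list(slope = -1.5, p_value = 0.01)
  population <- list(
    cox = list(beta = 0.3, p_value = 0.01, converged = TRUE),
    km = list(logrank_p = 0.3, direction = -1L))  # KM not significant: OK
  v <- selectChemopredictive(cohortRow, regression, population)
  expect_identical(v$verdict, "chemo_resistant")
  expect_identical(v$direction, "negative")
})

test_that("selection is invariant under miRNA renaming", {
  cfg <- simulationConfig(seed = 61, nRegistry = 3000, nCohort = 100,
                          nMirna = 3, plantedEffects = c("mir-001" = -1))
  reg <- simulateRegistry(cfg)
  coh <- simulateExpressionCohort(cfg)
  s1 <- selectMarkers(coh, reg, rule = "prognostic")
  renamed <- coh
  rownames(renamed) <- c("zzz", "mmm", "aaa")
  s2 <- selectMarkers(renamed, reg, rule = "prognostic")
  r1 <- markerRecords(s1); r2 <- markerRecords(s2)
  expect_identical(r1$verdict, r2$verdict)  # row order follows input order
  expect_identical(r1$cohort_cox_p, r2$cohort_cox_p)
})

test_that("an unlinkable cohort aborts with a diagnostic", {
  cfg <- simulationConfig(seed = 71, nRegistry = 500, nCohort = 30,
                          nMirna = 2)
  reg <- simulateRegistry(cfg)
  coh <- simulateExpressionCohort(cfg)
  reg$t_stage <- 4L; reg$n_stage <- 2L; reg$grade <- 3L  # one rare corner
  coh2 <- coh
  SummarizedExperiment::colData(coh2)$t_stage <- 1L
  SummarizedExperiment::colData(coh2)$n_stage <- 0L
  SummarizedExperiment::colData(coh2)$grade <- 1L
  expect_error(selectMarkers(coh2, reg, rule = "prognostic"),
               "cannot be linked")
})
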