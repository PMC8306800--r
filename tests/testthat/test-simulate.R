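test_that("all simulators are bit-identical under a fixed seed", {
  cfg <- simulationConfig(seed = 42, nRegistry = 300, nCohort = 40,
                          nMirna = 6, plantedEffects = c("mir-002" = 0.7))
  expect_identical(simulateRegistry(cfg), simulateRegistry(cfg))
  expect_identical(exprMatrix(simulateExpressionCohort(cfg)),
                   exprMatrix(simulateExpressionCohort(cfg)))
  reg <- simulateRegistry(cfg)
  expect_identical(simulateClaims(cfg, reg), simulateClaims(cfg, reg))
  expect_identical(simulateCellPanel(cfg, nLines = 30, plantedCorr = 0.5),
                   simulateCellPanel(cfg, nLines = 30, plantedCorr = 0.5))
  s1 <- simulateDependencyScreens(cfg, nGenes = 20,
                                  nLines = c(10, 12),
                                  essentialGenes = c("ESS01", "ESS02"))
  s2 <- simulateDependencyScreens(cfg, nGenes = 20,
                                  nLines = c(10, 12),
                                  essentialGenes = c("ESS01", "ESS02"))
  expect_identical(depScores(s1$crispr), depScores(s2$crispr))
  expect_identical(depScores(s1$rnai), depScores(s2$rnai))
})

test_that("simulators are decoupled: registry unchanged by cohort size", {
  a <- simulationConfig(seed = 5, nRegistry = 200, nCohort = 30, nMirna = 3)
  b <- simulationConfig(seed = 5, nRegistry = 200, nCohort = 80, nMirna = 9)
  expect_identical(simulateRegistry(a), simulateRegistry(b))
})

test_that("no censoring and no other-cause deaths forces event = 1", {
  cfg <- simulationConfig(seed = 2, nRegistry = 500, censorRate = 0,
                          otherCauseDeathProb = 0)
  reg <- simulateRegistry(cfg)
  expect_true(all(reg$event == 1L))
  expect_true(all(reg$cause == "disease"))
  expect_true(all(reg$time > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(nRegistry = 0), "positive")
  expect_error(simulationConfig(baselineHazard = 0), "baselineHazard")
  expect_error(simulationConfig(otherCauseDeathProb = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(nMirna = 2,
                                plantedEffects = c("mir-099" = 1)),
               "miRNA names")
  cfg <- simulationConfig(nMirna = 2)
  cfg@plantedEffects <- c("not-a-mirna" = 1)
  expect_error(simulateExpressionCohort(cfg), "miRNA")
})

test_that("group RMST decreases with the severity score", {
  cfg <- simulationConfig(seed = 9, nRegistry = 20000,
                          hazardLoadings = c(t = 0.3, n = 0.3,
                                             m = 0.3, g = 0.3))
  reg <- simulateRegistry(cfg)
  keys <- assignGroups(reg)
  prof <- groupSurvivalProfile(reg, unique(keys), minPerGroup = 50)
  sev <- with(
    data.frame(t = as.integer(substr(prof$group, 2, 2)),
               n = as.integer(substr(prof$group, 4, 4)),
               m = as.integer(substr(prof$group, 6, 6)),
               g = as.integer(substr(prof$group, 8, 8))),
    (t - 1) + n + m + (g - 1))
  expect_gt(nrow(prof), 10)
  expect_lt(cor(sev, prof$rmst_months, method = "spearman"), 0)
})

test_that("null expression is uncorrelated with severity; planted is not", {
  nullHits <- vapply(1:100, function(s) {
    cfg <- simulationConfig(seed = s, nCohort = 500, nMirna = 2)
    coh <- simulateExpressionCohort(cfg)
    cd <- as.data.frame(SummarizedExperiment::colData(coh))
    sev <- (cd$t_stage - 1) + cd$n_stage + cd$m_stage + (cd$grade - 1)
    abs(cor(exprMatrix(coh)["mir-001", ], sev)) < 0.1
  }, logical(1))
  expect_gte(mean(nullHits), 0.95)

  cfg <- simulationConfig(seed = 1, nCohort = 500, nMirna = 2,
                          plantedEffects = c("mir-001" = -1), noiseSd = 0.5)
  coh <- simulateExpressionCohort(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(coh))
  sev <- (cd$t_stage - 1) + cd$n_stage + cd$m_stage + (cd$grade - 1)
  expect_lt(cor(exprMatrix(coh)["mir-001", ], sev), -0.8)
})

test_that("claims round-trip: zero distractors recover flags exactly", {
  cfg <- simulationConfig(seed = 3, nRegistry = 400)
  reg <- simulateRegistry(cfg)
  claims <- simulateClaims(cfg, reg, distractorRate = 0)
  flags <- deriveTreatmentFlags(claims, patients = reg$patient_id)
  expect_identical(flags$chemo_agents[match(reg$patient_id,
                                            flags$patient_id)],
                   reg$chemo_agents)
})

test_that("distractor claims make naive code matching over-count", {
  cfg <- simulationConfig(seed = 8, nRegistry = 400)
  reg <- simulateRegistry(cfg)
  claims <- simulateClaims(cfg, reg, distractorRate = 2)
  cm <- defaultAgentCodeMap()
  naive <- unique(claims$patient_id[
    claims$procedure_code %in% unlist(cm$agents)])
  strict <- deriveTreatmentFlags(claims, cm, patients = reg$patient_id)
  flagged <- strict$patient_id[nzchar(strict$chemo_agents)]
  truth <- reg$patient_id[nzchar(reg$chemo_agents)]
  expect_setequal(flagged, truth)        # diagnosis check filters them out
  expect_gt(length(naive), length(truth))
})

test_that("cell panel plants the requested expression-activity correlation", {
  powered <- vapply(1:50, function(s) {
    cfg <- simulationConfig(seed = s, nMirna = 3)
    panel <- simulateCellPanel(cfg, nLines = 60, plantedCorr = 0.9,
                               plantedMirnas = "mir-001")
    res <- nci60Regression(panel$expr["mir-001", ], panel$activity,
                           claim = "sensitive")
    res$supported
  }, logical(1))
  expect_gte(mean(powered), 0.95)

  nullSig <- vapply(1:200, function(s) {
    cfg <- simulationConfig(seed = s, nMirna = 2)
    panel <- simulateCellPanel(cfg, nLines = 60, plantedCorr = 0,
                               plantedMirnas = "mir-001")
    a <- panel$activity[panel$activity$endpoint == "ln_IC50", ]
    x <- panel$expr["mir-001", a$cell_line]
    summary(lm(a$value ~ x))$coefficients[2, 4] < 0.05
  }, logical(1))
  expect_lte(mean(nullSig), 0.10)        # null slope p-value calibration
})

test_that("dependency screens plant recoverable essential genes", {
  cfg <- simulationConfig(seed = 6)
  ess <- sprintf("ESS%02d", 1:9)
  scr <- simulateDependencyScreens(cfg, nGenes = 60,
                                   nLines = c(crispr = 78, rnai = 92),
                                   essentialGenes = ess)
  fr <- essentialityFraction(normalizeDependency(scr$crispr))
  expect_true(all(fr$fraction[fr$gene %in% ess] == 1.0))

  none <- simulateDependencyScreens(cfg, nGenes = 20,
                                    nLines = c(10, 10),
                                    essentialGenes = character())
  # no essential controls: screens arrive on the normalized scale already
  hit <- intersectFullImpact(essentialityFraction(none$crispr),
                             essentialityFraction(none$rnai))
  expect_identical(hit, character(0))
})
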