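#' Simulate a cancer-registry cohort
#'
#' Generates a registry table of staged patients with disease-specific
#' survival. T, N and grade are drawn from the configured categorical
#' distributions (M is 0: metastatic patients are absent from the linkage by
#' construction, mirroring the registry/cohort intersection). Event times
#' follow a proportional-hazards exponential (or Weibull) law with rate
#' \code{baselineHazard * exp(loadings %*% progression)}; an independent
#' exponential censoring time is drawn, the observed time is the minimum,
#' and a configurable fraction of deaths is relabeled as other-cause (which
#' censors the disease-specific event indicator). Treatment flags are drawn
#' per \code{treatmentProbs}; \code{preop_radiation} is drawn only among
#' irradiated patients.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns \code{patient_id}, \code{time} (months),
#'   \code{event} (1 = disease-specific death), \code{cause}
#'   (\code{"disease"}, \code{"other"}, \code{"censored"}), \code{t_stage},
#'   \code{n_stage}, \code{m_stage}, \code{grade}, \code{surgery},
#'   \code{radiation}, \code{preop_radiation}, \code{chemo_agents}
#'   (";"-separated, \code{""} = none).
#' @examples
#' reg <- simulateRegistry(simulationConfig(seed = 7, nRegistry = 100))
#' table(reg$t_stage)
#' @export
simulateRegistry <- function(config) {
  validObject(config)
  withStream(config@seed, "registry", {
    n <- config@nRegistry
    st <- drawStages(n, config)
    surv <- drawSurvival(st, config)
    tp <- config@treatmentProbs
    surgery <- runif(n) < tp[["surgery"]]
    radiation <- runif(n) < tp[["radiation"]]
    preop <- radiation & runif(n) < tp[["preop_radiation"]]
    agents <- setdiff(names(tp), c("surgery", "radiation", "preop_radiation"))
    agentSets <- vector("list", n)
    for (a in agents) {
      hit <- runif(n) < tp[[a]]
      agentSets[hit] <- lapply(agentSets[hit], c, a)
    }
    data.frame(
      patient_id = sprintf("R%06d", seq_len(n)),
      time = surv$time,
      event = surv$event,
      cause = surv$cause,
      t_stage = st$t_stage, n_stage = st$n_stage,
      m_stage = st$m_stage, grade = st$grade,
      surgery = surgery, radiation = radiation, preop_radiation = preop,
      chemo_agents = joinAgents(agentSets),
      stringsAsFactors = FALSE
    )
  })
}

drawStages <- function(n, config) {
  sp <- config@stageProbs
  list(
    t_stage = sample(seq_along(sp$t), n, replace = TRUE, prob = sp$t),
    n_stage = sample(seq_along(sp$n) - 1L, n, replace = TRUE, prob = sp$n),
    m_stage = rep(0L, n),
    grade = sample(seq_along(sp$g), n, replace = TRUE, prob = sp$g)
  )
}

# Proportional-hazards event times: for Weibull shape k, the cumulative
# hazard is (rate * t)^k ... we keep the PH parameterization
# S(t) = exp(-rate * t^k), which reduces to the exponential at k = 1.
drawSurvival <- function(st, config) {
  n <- length(st$t_stage)
  hl <- config@hazardLoadings
  lp <- hl[["t"]] * (st$t_stage - 1L) + hl[["n"]] * st$n_stage +
    hl[["m"]] * st$m_stage + hl[["g"]] * (st$grade - 1L)
  rate <- config@baselineHazard * exp(lp)
  u <- rexp(n)                      # unit-exponential deviates
  tEvent <- (u / rate)^(1 / config@weibullShape)
  tCens <- if (config@censorRate > 0) rexp(n, config@censorRate) else
    rep(Inf, n)
  time <- pmin(tEvent, tCens)
  died <- tEvent <= tCens
  other <- died & runif(n) < config@otherCauseDeathProb
  list(
    time = time,
    event = as.integer(died & !other),
    cause = ifelse(!died, "censored", ifelse(other, "other", "disease"))
  )
}

#' Simulate an expression cohort with planted progression effects
#'
#' Draws stage/grade and survival exactly as [simulateRegistry()] does, then
#' generates a miRNA-by-sample expression matrix on an arbitrary log-like
#' scale: a planted miRNA \eqn{j} has expression \eqn{N(\mathrm{effect}_j
#' \times \mathrm{severity}, \sigma^2)} where severity is
#' \eqn{(T-1)+N+M+(G-1)}; null miRNAs are \eqn{N(0, \sigma^2)}.
#'
#' @param config a [SimulationConfig-class]; \code{plantedEffects} names must
#'   be among [mirnaNames()] of the config.
#' @return A [MirnaCohort-class].
#' @examples
#' cfg <- simulationConfig(seed = 3, nCohort = 60, nMirna = 5,
#'                         plantedEffects = c("mir-001" = -1))
#' cohort <- simulateExpressionCohort(cfg)
#' cor(exprMatrix(cohort)["mir-001", ],
#'     with(as.data.frame(SummarizedExperiment::colData(cohort)),
#'          (t_stage - 1) + n_stage + m_stage + (grade - 1)))
#' @export
simulateExpressionCohort <- function(config) {
  validObject(config)
  bad <- setdiff(names(config@plantedEffects), mirnaNames(config))
  if (length(bad))
    stop("planted effect for unknown miRNA name(s): ",
         paste(bad, collapse = ", "))
  withStream(config@seed, "cohort", {
    n <- config@nCohort
    st <- drawStages(n, config)
    surv <- drawSurvival(st, config)
    sev <- severityScore(st$t_stage, st$n_stage, st$m_stage, st$grade)
    feats <- mirnaNames(config)
    expr <- matrix(rnorm(length(feats) * n, sd = config@noiseSd),
                   nrow = length(feats), dimnames = list(feats, NULL))
    for (j in names(config@plantedEffects))
      expr[j, ] <- expr[j, ] + config@plantedEffects[[j]] * sev
    colnames(expr) <- sprintf("S%04d", seq_len(n))
    clinical <- data.frame(
      time = surv$time, event = surv$event,
      t_stage = st$t_stage, n_stage = st$n_stage,
      m_stage = st$m_stage, grade = st$grade,
      row.names = colnames(expr)
    )
    MirnaCohort(expr, clinical)
  })
}

#' Simulate a claims table for treatment-flag derivation
#'
#' Every registry patient flagged for a chemotherapy agent receives at least
#' one claim carrying one of that agent's procedure codes together with a
#' lung-cancer diagnosis code. Distractor claims are injected so that naive
#' procedure-code matching without the diagnosis check over-counts: agent
#' procedure codes paired with non-lung diagnoses, and unrelated procedure
#' codes paired with lung diagnoses.
#'
#' @param config a [SimulationConfig-class].
#' @param registry output of [simulateRegistry()].
#' @param codeMap an agent code map, see [defaultAgentCodeMap()].
#' @param distractorRate expected number of distractor claims per patient.
#' @return data.frame with columns \code{patient_id}, \code{procedure_code},
#'   \code{diagnosis_code}.
#' @export
simulateClaims <- function(config, registry,
                           codeMap = defaultAgentCodeMap(),
                           distractorRate = 0.3) {
  validObject(config)
  withStream(config@seed, "claims", {
    agentSets <- splitAgents(registry$chemo_agents)
    rows <- list()
    for (i in seq_len(nrow(registry))) {
      for (a in agentSets[[i]]) {
        codes <- codeMap$agents[[a]]
        if (is.null(codes))
          stop("registry agent '", a, "' missing from code map")
        k <- 1L + rpois(1L, 0.5)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = registry$patient_id[i],
          procedure_code = sample(codes, k, replace = TRUE),
          diagnosis_code = sample(codeMap$lung_diagnosis_codes, k,
                                  replace = TRUE),
          stringsAsFactors = FALSE
        )
      }
    }
    nDis <- rbinom(1L, nrow(registry), min(1, distractorRate))
    if (nDis > 0) {
      who <- sample(registry$patient_id, nDis, replace = TRUE)
      allAgentCodes <- unlist(codeMap$agents, use.names = FALSE)
      nonLung <- c("250.00", "401.9", "486", "714.0")
      unrelated <- c("99213", "99214", "G0008")
      half <- rbinom(nDis, 1L, 0.5) == 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = who,
        procedure_code = ifelse(half,
          sample(allAgentCodes, nDis, replace = TRUE),
          sample(unrelated, nDis, replace = TRUE)),
        diagnosis_code = ifelse(half,
          sample(nonLung, nDis, replace = TRUE),
          sample(codeMap$lung_diagnosis_codes, nDis, replace = TRUE)),
        stringsAsFactors = FALSE
      )
    }
    if (!length(rows))
      return(data.frame(patient_id = character(), procedure_code = character(),
                        diagnosis_code = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a cell-line drug-screen panel
#'
#' Generates a miRNA-by-cell-line expression matrix and a long-format drug
#' activity table with four endpoints: \code{GI50}, \code{TGI}, \code{LC50}
#' (no dose bounds) and \code{ln_IC50} (with min/max dose bounds). All
#' endpoints share one latent log-activity per line; planted miRNAs are
#' generated with correlation approximately \code{plantedCorr} against the
#' negated latent activity, so positive \code{plantedCorr} means higher
#' expression in sensitive (low-activity-value) lines. A configurable
#' fraction of lines receives \code{ln_IC50} values pushed outside the dose
#' bounds to exercise the bound-override classification.
#'
#' @param config a [SimulationConfig-class] (seed and miRNA names are used).
#' @param nLines number of cell lines.
#' @param plantedCorr correlation in [-1, 1] planted between each planted
#'   miRNA's expression and the negated latent ln(IC50).
#' @param plantedMirnas miRNA names to plant; defaults to the names of
#'   \code{plantedEffects} in \code{config}, or the first miRNA when empty.
#' @param minDose,maxDose dose bounds on the ln(IC50) scale.
#' @param outOfBoundsFrac fraction of lines forced outside the dose bounds.
#' @return list with \code{expr} (matrix, miRNAs x lines) and
#'   \code{activity} (data.frame: \code{cell_line}, \code{drug},
#'   \code{endpoint}, \code{value}, \code{min_dose}, \code{max_dose}).
#' @export
simulateCellPanel <- function(config, nLines = 60, plantedCorr = 0,
                              plantedMirnas = NULL,
                              minDose = -2, maxDose = 2,
                              outOfBoundsFrac = 0) {
  validObject(config)
  stopifnot(abs(plantedCorr) <= 1, minDose < maxDose)
  if (is.null(plantedMirnas))
    plantedMirnas <- if (length(config@plantedEffects))
      names(config@plantedEffects) else mirnaNames(config)[1]
  withStream(config@seed, "cellpanel", {
    lines <- sprintf("CL%03d", seq_len(nLines))
    z <- rnorm(nLines)                       # latent log-activity
    feats <- mirnaNames(config)
    expr <- matrix(rnorm(length(feats) * nLines),
                   nrow = length(feats), dimnames = list(feats, lines))
    for (j in intersect(plantedMirnas, feats)) {
      eps <- rnorm(nLines)
      expr[j, ] <- plantedCorr * (-z) + sqrt(1 - plantedCorr^2) * eps
    }
    lnIC50 <- z
    nOut <- floor(outOfBoundsFrac * nLines)
    if (nOut > 0) {
      out <- sample(nLines, nOut)
      hi <- out[seq_len(ceiling(nOut / 2))]
      lo <- setdiff(out, hi)
      lnIC50[hi] <- maxDose + abs(rnorm(length(hi), 1))
      lnIC50[lo] <- minDose - abs(rnorm(length(lo), 1))
    }
    mkEndpoint <- function(name, value, lower = NA_real_, upper = NA_real_)
      data.frame(cell_line = lines, drug = "agentX", endpoint = name,
                 value = value, min_dose = lower, max_dose = upper,
                 stringsAsFactors = FALSE)
    activity <- rbind(
      mkEndpoint("GI50", z + rnorm(nLines, sd = 0.3)),
      mkEndpoint("TGI", z + 0.5 + rnorm(nLines, sd = 0.3)),
      mkEndpoint("LC50", z + 1.0 + rnorm(nLines, sd = 0.3)),
      mkEndpoint("ln_IC50", lnIC50, minDose, maxDose)
    )
    list(expr = expr, activity = activity)
  })
}

#' Simulate paired CRISPR and RNAi dependency screens
#'
#' Designated essential genes have raw effects drawn from N(-1, 0.1) in
#' every line; all other genes from N(0, 0.1). The designated essential
#' genes double as the essential-control set and the null genes as the
#' nonessential controls (a gene is an essential control precisely because
#' it is essential in every line). A per-line affine distortion (positive
#' scale, shift) is then applied so that [normalizeDependency()] has real
#' work to do; the distortion is exactly invertible by the control-median
#' normalization. With no essential genes the screens cannot be normalized
#' and are returned undistorted with an empty essential-control set.
#'
#' @param config a [SimulationConfig-class] (seed is used).
#' @param nGenes total genes per screen (including the essential genes).
#' @param nLines named or unnamed length-2 vector: lines in the CRISPR and
#'   RNAi screens.
#' @param essentialGenes character vector of designated essential genes.
#' @return list with elements \code{crispr} and \code{rnai}, each a
#'   [DependencyScreen-class].
#' @export
simulateDependencyScreens <- function(config, nGenes = 100,
                                      nLines = c(crispr = 78, rnai = 92),
                                      essentialGenes = sprintf("ESS%02d",
                                                               1:9)) {
  validObject(config)
  stopifnot(length(nLines) == 2, nGenes >= length(essentialGenes))
  withStream(config@seed, "dependency", {
    nNull <- nGenes - length(essentialGenes)
    nullGenes <- sprintf("GENE%04d", seq_len(nNull))
    allGenes <- c(essentialGenes, nullGenes)
    isEss <- allGenes %in% essentialGenes
    distort <- length(essentialGenes) > 0
    mk <- function(nl, type) {
      mu <- ifelse(isEss, -1, 0)
      s <- matrix(rnorm(length(allGenes) * nl, mean = mu, sd = 0.1),
                  nrow = length(allGenes),
                  dimnames = list(allGenes, sprintf("%s_L%03d", type,
                                                    seq_len(nl))))
      if (distort) {
        a <- runif(nl, 0.5, 2)               # per-line distortion
        b <- runif(nl, -0.5, 0.5)
        s <- sweep(sweep(s, 2, a, `*`), 2, b, `+`)
      }
      DependencyScreen(s, type, essentialControls = essentialGenes,
                       nonessentialControls = nullGenes)
    }
    list(crispr = mk(nLines[[1]], "crispr"), rnai = mk(nLines[[2]], "rnai"))
  })
}
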