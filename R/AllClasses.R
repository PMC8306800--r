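#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' Simulation configuration for the synthetic cohort generators
#'
#' Bundles every parameter the synthetic-data generators share: cohort and
#' registry sizes, the log-linear hazard that ties tumor-progression severity
#' to disease-specific death, censoring and other-cause death rates, planted
#' miRNA effect sizes, treatment probabilities, and the categorical
#' distributions of T, N, M and grade.
#'
#' The hazard model is \eqn{\lambda(T,N,M,G) = \lambda_0 \exp\{\beta_T(T-1) +
#' \beta_N N + \beta_M M + \beta_G(G-1)\}} with exponential event times by
#' default (\code{weibullShape = 1}); a Weibull shape other than 1 keeps the
#' proportional-hazards structure. The severity score used for planted
#' expression effects is \eqn{(T-1) + N + M + (G-1)}.
#'
#' @slot seed integer master seed; every generator derives its own stream
#'   from (seed, generator name) so modules are decoupled.
#' @slot nRegistry,nCohort,nMirna positive integer sizes.
#' @slot plantedEffects named numeric; effect size (slope of mean expression
#'   per unit severity) for each planted miRNA. Names must be among the
#'   generated miRNA names \code{sprintf("mir-%03d", 1:nMirna)}.
#' @slot baselineHazard baseline event rate per month (> 0).
#' @slot hazardLoadings named numeric \code{c(t=, n=, m=, g=)} log-hazard
#'   increments per unit of each progression component.
#' @slot censorRate independent censoring rate per month (>= 0).
#' @slot otherCauseDeathProb probability a death is from another cause and
#'   hence censored for disease-specific survival.
#' @slot treatmentProbs named probabilities: \code{surgery}, \code{radiation},
#'   \code{preop_radiation} (conditional on radiation), plus one entry per
#'   chemotherapy agent.
#' @slot stageProbs list of categorical probabilities \code{t} (T = 1..4),
#'   \code{n} (N = 0..2), \code{g} (grade 1..3); M is fixed at 0.
#' @slot noiseSd expression noise standard deviation.
#' @slot weibullShape Weibull shape parameter (1 = exponential).
#'
#' @seealso [simulationConfig()] for the validated constructor.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nRegistry = "integer",
    nCohort = "integer",
    nMirna = "integer",
    plantedEffects = "numeric",
    baselineHazard = "numeric",
    hazardLoadings = "numeric",
    censorRate = "numeric",
    otherCauseDeathProb = "numeric",
    treatmentProbs = "numeric",
    stageProbs = "list",
    noiseSd = "numeric",
    weibullShape = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(c(object@nRegistry, object@nCohort, object@nMirna) <= 0L))
    msg <- c(msg, "nRegistry, nCohort and nMirna must be positive")
  if (object@baselineHazard <= 0)
    msg <- c(msg, "baselineHazard must be > 0")
  if (object@censorRate < 0)
    msg <- c(msg, "censorRate must be >= 0")
  if (object@otherCauseDeathProb < 0 || object@otherCauseDeathProb > 1)
    msg <- c(msg, "otherCauseDeathProb must be in [0, 1]")
  if (any(object@treatmentProbs < 0 | object@treatmentProbs > 1))
    msg <- c(msg, "treatmentProbs must be probabilities in [0, 1]")
  if (!all(c("t", "n", "m", "g") %in% names(object@hazardLoadings)))
    msg <- c(msg, "hazardLoadings must be named c(t=, n=, m=, g=)")
  if (!all(c("t", "n", "g") %in% names(object@stageProbs)))
    msg <- c(msg, "stageProbs must contain elements t, n and g")
  if (length(object@plantedEffects) &&
      !all(names(object@plantedEffects) %in% mirnaNames(object)))
    msg <- c(msg, "plantedEffects names must be generated miRNA names")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@weibullShape <= 0) msg <- c(msg, "weibullShape must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe the study conditions the synthetic module emulates: a
#' registry of 20,000 patients with stage and grade frequencies shaped like a
#' lung squamous carcinoma registry population, a 200-sample expression
#' cohort, a baseline disease-specific hazard of 0.02 per month with
#' log-hazard loadings of 0.25 per unit of each progression component,
#' independent censoring at 0.01 per month, a 20% chance that a death is
#' from another cause, and expression noise SD 0.5.
#'
#' @param seed integer master seed.
#' @param nRegistry,nCohort,nMirna sizes (see class docs).
#' @param plantedEffects named numeric vector of planted expression slopes
#'   per unit severity; empty means all-null expression.
#' @param baselineHazard,hazardLoadings,censorRate,otherCauseDeathProb
#'   survival-model parameters (see class docs).
#' @param treatmentProbs named treatment probabilities.
#' @param stageProbs list with elements \code{t}, \code{n}, \code{g}.
#' @param noiseSd expression noise SD.
#' @param weibullShape Weibull shape (1 = exponential).
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, nCohort = 50, nMirna = 10,
#'                         plantedEffects = c("mir-001" = -1))
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nRegistry = 20000L,
                             nCohort = 200L,
                             nMirna = 50L,
                             plantedEffects = numeric(),
                             baselineHazard = 0.02,
                             hazardLoadings = c(t = 0.25, n = 0.25,
                                                m = 0.25, g = 0.25),
                             censorRate = 0.01,
                             otherCauseDeathProb = 0.2,
                             treatmentProbs = c(surgery = 0.5,
                                                radiation = 0.3,
                                                preop_radiation = 0.2,
                                                cisplatin = 0.12,
                                                carboplatin = 0.15,
                                                paclitaxel = 0.15,
                                                etoposide = 0.10),
                             stageProbs = list(t = c(0.35, 0.25, 0.25, 0.15),
                                               n = c(0.55, 0.25, 0.20),
                                               g = c(0.045, 0.415, 0.54)),
                             noiseSd = 0.5,
                             weibullShape = 1) {
  obj <- new("SimulationConfig",
    seed = as.integer(seed),
    nRegistry = as.integer(nRegistry),
    nCohort = as.integer(nCohort),
    nMirna = as.integer(nMirna),
    plantedEffects = plantedEffects,
    baselineHazard = baselineHazard,
    hazardLoadings = hazardLoadings,
    censorRate = censorRate,
    otherCauseDeathProb = otherCauseDeathProb,
    treatmentProbs = treatmentProbs,
    stageProbs = stageProbs,
    noiseSd = noiseSd,
    weibullShape = weibullShape
  )
  validObject(obj)
  obj
}

#' miRNA names generated under a configuration
#' @param config a [SimulationConfig-class].
#' @return Character vector of feature names.
#' @export
mirnaNames <- function(config) sprintf("mir-%03d", seq_len(config@nMirna))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  registry n:", object@nRegistry, " cohort n:", object@nCohort,
      " miRNAs:", object@nMirna, "\n")
  cat("  baseline hazard:", object@baselineHazard, "/month, loadings:",
      paste(sprintf("%s=%.3g", names(object@hazardLoadings),
                    object@hazardLoadings), collapse = " "), "\n")
  cat("  censor rate:", object@censorRate,
      " other-cause death prob:", object@otherCauseDeathProb, "\n")
  np <- length(object@plantedEffects)
  cat("  planted effects:", if (np) paste(names(object@plantedEffects),
      sprintf("%+.2g", object@plantedEffects), collapse = ", ") else "none",
      "\n")
})

#' Expression cohort container
#'
#' A \linkS4class{SummarizedExperiment} holding a miRNA-by-sample expression
#' assay together with the per-sample survival and staging annotation the
#' selection pipeline requires: \code{time} (months), \code{event} (0/1),
#' \code{t_stage}, \code{n_stage}, \code{m_stage}, \code{grade}.
#'
#' @seealso [MirnaCohort()] for the constructor,
#'   [simulateExpressionCohort()] for the synthetic generator.
#' @export
setClass("MirnaCohort", contains = "SummarizedExperiment")

setValidity("MirnaCohort", function(object) {
  need <- c("time", "event", "t_stage", "n_stage", "m_stage", "grade")
  missing <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    return(paste("colData lacks columns:", paste(missing, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (any(cd$time <= 0, na.rm = TRUE)) return("time must be > 0")
  if (!all(cd$event %in% c(0L, 1L))) return("event must be 0/1")
  TRUE
})

#' Construct a MirnaCohort
#'
#' @param expr numeric matrix, features (miRNAs) in rows, samples in columns.
#' @param clinical data.frame with one row per sample and at least the
#'   columns \code{time}, \code{event}, \code{t_stage}, \code{n_stage},
#'   \code{m_stage}, \code{grade}.
#' @return A [MirnaCohort-class] object.
#' @export
MirnaCohort <- function(expr, clinical) {
  stopifnot(is.matrix(expr), nrow(clinical) == ncol(expr))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    colData = S4Vectors::DataFrame(clinical)
  )
  new("MirnaCohort", se)
}

#' @describeIn MirnaCohort expression assay (features x samples).
#' @param x a \code{MirnaCohort}.
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "expr")

#' @describeIn MirnaCohort survival times in months.
#' @export
survivalTime <- function(x) SummarizedExperiment::colData(x)$time

#' @describeIn MirnaCohort disease/overall-survival event indicator (0/1).
#' @export
survivalEvent <- function(x) SummarizedExperiment::colData(x)$event

#' Dependency-screen container
#'
#' A gene-by-cell-line matrix of knockout/knockdown effects plus the control
#' gene sets used for per-line normalization. \code{screenType} records
#' whether the scores come from a CRISPR knockout or an RNAi knockdown
#' screen.
#'
#' @slot scores numeric matrix, genes in rows, cell lines in columns.
#' @slot screenType \code{"crispr"} or \code{"rnai"}.
#' @slot essentialControls,nonessentialControls disjoint gene sets present in
#'   the matrix rows; required (non-empty) for [normalizeDependency()].
#' @seealso [DependencyScreen()], [normalizeDependency()],
#'   [essentialityFraction()]
#' @export
setClass("DependencyScreen",
  representation(
    scores = "matrix",
    screenType = "character",
    essentialControls = "character",
    nonessentialControls = "character"
  )
)

setValidity("DependencyScreen", function(object) {
  msg <- character()
  if (!object@screenType %in% c("crispr", "rnai"))
    msg <- c(msg, "screenType must be 'crispr' or 'rnai'")
  if (is.null(rownames(object@scores)))
    msg <- c(msg, "scores must have gene rownames")
  if (length(intersect(object@essentialControls,
                       object@nonessentialControls)))
    msg <- c(msg, "control gene sets must be disjoint")
  ctrl <- c(object@essentialControls, object@nonessentialControls)
  if (length(ctrl) && !all(ctrl %in% rownames(object@scores)))
    msg <- c(msg, "control genes must be rows of the score matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a DependencyScreen
#'
#' @param scores gene x cell-line numeric matrix with rownames.
#' @param screenType \code{"crispr"} or \code{"rnai"}.
#' @param essentialControls,nonessentialControls control gene sets.
#' @return A [DependencyScreen-class] object.
#' @export
DependencyScreen <- function(scores, screenType = c("crispr", "rnai"),
                             essentialControls = character(),
                             nonessentialControls = character()) {
  obj <- new("DependencyScreen",
    scores = scores,
    screenType = match.arg(screenType),
    essentialControls = essentialControls,
    nonessentialControls = nonessentialControls
  )
  validObject(obj)
  obj
}

#' @describeIn DependencyScreen score matrix accessor.
#' @param x a \code{DependencyScreen}.
#' @export
depScores <- function(x) x@scores

#' @describeIn DependencyScreen screen type accessor.
#' @export
screenType <- function(x) x@screenType

setMethod("show", "DependencyScreen", function(object) {
  cat("DependencyScreen (", object@screenType, "): ",
      nrow(object@scores), " genes x ", ncol(object@scores), " lines\n",
      sep = "")
  cat("  controls: ", length(object@essentialControls), " essential, ",
      length(object@nonessentialControls), " nonessential\n", sep = "")
})

#' Marker-selection result set
#'
#' One row per (miRNA, stratum, agent) with every layer of the selection
#' statistics: cohort Cox fit and cutoff scan, group-level regression,
#' population-level Cox and Kaplan-Meier re-evaluation, the direction label,
#' the verdict, and the reasons a miRNA failed.
#'
#' @slot records data.frame of per-miRNA results (see [selectMarkers()] for
#'   the column contract).
#' @slot alpha significance level used in every layer.
#' @slot rule \code{"prognostic"} (population Cox AND KM) or
#'   \code{"chemopredictive"} (population Cox OR KM).
#' @slot stratum,agent the treatment view the registry was filtered to.
#' @slot groups the common progression-group keys the linkage used.
#' @export
setClass("MarkerSelection",
  representation(
    records = "data.frame",
    alpha = "numeric",
    rule = "character",
    stratum = "character",
    agent = "character",
    groups = "character"
  )
)

setValidity("MarkerSelection", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (!object@rule %in% c("prognostic", "chemopredictive"))
    return("rule must be 'prognostic' or 'chemopredictive'")
  TRUE
})

#' @describeIn MarkerSelection full per-miRNA record table.
#' @param x a \code{MarkerSelection}.
#' @export
markerRecords <- function(x) x@records

#' @describeIn MarkerSelection names of the selected miRNAs.
#' @export
selectedMarkers <- function(x) {
  r <- x@records
  r$mirna[r$verdict %in% c("prognostic_selected", "chemo_sensitive",
                           "chemo_resistant")]
}

setMethod("show", "MarkerSelection", function(object) {
  r <- object@records
  sel <- selectedMarkers(object)
  cat("MarkerSelection (", object@rule, ") stratum=", object@stratum,
      " agent=", object@agent, "\n", sep = "")
  cat("  ", nrow(r), " miRNAs screened over ", length(object@groups),
      " common progression groups; alpha=", object@alpha, "\n", sep = "")
  cat("  selected: ", if (length(sel)) paste(sel, collapse = ", ")
      else "none", "\n", sep = "")
})
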