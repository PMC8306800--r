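#' Screen miRNAs for survival association in the expression cohort
#'
#' First selection layer: for each miRNA an independent univariate Cox model
#' and a Kaplan-Meier cutoff scan ([kmCutoffScan()]) against the cohort's
#' survival. A miRNA passes iff both p-values are below \code{alpha} and the
#' Cox sign agrees with the scan direction (protective expression means
#' beta < 0 and the over-expression group survives longer, direction +1).
#' Constant-expression miRNAs are skipped and recorded.
#'
#' @param cohort a [MirnaCohort-class] with at least 2 samples.
#' @param alpha significance level.
#' @param qLo,qHi,nGrid,minPerSide passed to [kmCutoffScan()].
#' @param lazyKm skip the cutoff scan for miRNAs the Cox layer already
#'   rules out (their \code{cohort_km_p} is NA). Passing requires both
#'   layers significant, so verdicts are identical either way; this is a
#'   screening shortcut for large null panels.
#' @return data.frame, one row per miRNA: \code{mirna}, \code{cohort_beta},
#'   \code{cohort_cox_p}, \code{cohort_km_p}, \code{cohort_cutoff},
#'   \code{cohort_direction}, \code{cohort_pass}, \code{skipped}.
#' @export
cohortScreen <- function(cohort, alpha = 0.05, qLo = 0.05, qHi = 0.95,
                         nGrid = 20, minPerSide = 3, lazyKm = FALSE) {
  stopifnot(is(cohort, "MirnaCohort"))
  if (ncol(cohort) < 2) stop("cohort must contain at least 2 samples")
  expr <- exprMatrix(cohort)
  times <- survivalTime(cohort)
  events <- survivalEvent(cohort)
  out <- lapply(rownames(expr), function(m) {
    x <- expr[m, ]
    if (length(unique(x)) < 2)
      return(data.frame(mirna = m, cohort_beta = NA_real_,
                        cohort_cox_p = NA_real_, cohort_km_p = NA_real_,
                        cohort_cutoff = NA_real_,
                        cohort_direction = NA_integer_,
                        cohort_pass = FALSE, skipped = TRUE))
    cox <- coxUnivariate(times, events, x)
    if (lazyKm && !(isTRUE(cox$converged) && cox$p_value < alpha))
      return(data.frame(mirna = m, cohort_beta = cox$beta,
                        cohort_cox_p = cox$p_value, cohort_km_p = NA_real_,
                        cohort_cutoff = NA_real_,
                        cohort_direction = NA_integer_,
                        cohort_pass = FALSE, skipped = FALSE))
    km <- kmCutoffScan(x, times, events, qLo = qLo, qHi = qHi,
                       nGrid = nGrid, minPerSide = minPerSide)
    pass <- isTRUE(cox$converged) &&
      cox$p_value < alpha && km$min_logrank_p < alpha &&
      ((cox$beta < 0) == (km$direction == 1L))
    data.frame(mirna = m, cohort_beta = cox$beta,
               cohort_cox_p = cox$p_value, cohort_km_p = km$min_logrank_p,
               cohort_cutoff = km$best_cutoff,
               cohort_direction = km$direction,
               cohort_pass = pass, skipped = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-mean expression profile of the clinical cohort
#'
#' Arithmetic mean expression per (miRNA, progression group) on the
#' expression scale provided (log-like by default in the synthetic data),
#' restricted to the supplied common-group keys. Groups without cohort
#' members are excluded.
#'
#' @param cohort a [MirnaCohort-class].
#' @param groupKeys character vector of progression-group keys to keep.
#' @return list with \code{means} (miRNA x group matrix) and \code{n}
#'   (named member counts per group).
#' @export
groupExpressionMeans <- function(cohort, groupKeys) {
  stopifnot(is(cohort, "MirnaCohort"), length(groupKeys) > 0)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  keys <- assignGroups(cd)
  keep <- !is.na(keys) & keys %in% groupKeys
  keys <- factor(keys[keep], levels = sort(unique(keys[keep])))
  expr <- exprMatrix(cohort)[, keep, drop = FALSE]
  sums <- t(apply(expr, 1, function(r) tapply(r, keys, mean)))
  if (nlevels(keys) == 1L) {                  # tapply drops to a vector
    sums <- matrix(sums, ncol = 1,
                   dimnames = list(rownames(expr), levels(keys)))
  }
  list(means = sums, n = table(keys))
}

#' Group-level survival profile of a registry subset
#'
#' Restricted mean survival (Kaplan-Meier area, [rmst()]) per progression
#' group, computed on a registry subset already filtered to the treatment
#' stratum / agent of interest. The truncation time defaults to the maximum
#' observed time in the whole subset (stratum-wide), so group areas are
#' comparable. Groups below \code{minPerGroup} members are dropped.
#'
#' @param registrySubset registry rows (see [simulateRegistry()] schema).
#' @param groupKeys keys to evaluate.
#' @param minPerGroup minimum group size.
#' @param tau truncation time; default stratum-wide maximum observed time.
#' @return data.frame: \code{group}, \code{rmst_months}, \code{n},
#'   \code{n_events}; attribute \code{tau}.
#' @export
groupSurvivalProfile <- function(registrySubset, groupKeys,
                                 minPerGroup = 10, tau = NULL) {
  keys <- assignGroups(registrySubset)
  if (is.null(tau)) tau <- max(registrySubset$time)
  rows <- lapply(sort(intersect(unique(keys), groupKeys)), function(g) {
    idx <- which(keys == g)
    if (length(idx) < minPerGroup) return(NULL)
    curve <- kmEstimate(registrySubset$time[idx], registrySubset$event[idx])
    data.frame(group = g, rmst_months = rmst(curve, tau),
               n = length(idx), n_events = sum(registrySubset$event[idx]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), rmst_months = numeric(),
                      n = integer(), n_events = integer())
  rownames(out) <- NULL
  attr(out, "tau") <- tau
  out
}

#' Group-level regression of registry survival on cohort expression
#'
#' Ordinary least squares of the registry groups' restricted mean survival
#' on the clinical cohort's group-mean expression, across the shared
#' progression groups. This is the population-correlation layer: a
#' significant positive slope means progression groups in which the cohort
#' expresses the miRNA more highly survive longer in the registry.
#'
#' @param exprMeans named numeric vector (group key -> mean expression),
#'   e.g. one row of [groupExpressionMeans()]'s matrix.
#' @param survProfile output of [groupSurvivalProfile()].
#' @return list with \code{slope}, \code{p_value}, \code{r},
#'   \code{n_groups}.
#' @export
populationRegression <- function(exprMeans, survProfile) {
  shared <- intersect(names(exprMeans), survProfile$group)
  if (length(shared) < 3) stop("need at least 3 shared groups")
  x <- exprMeans[shared]
  y <- survProfile$rmst_months[match(shared, survProfile$group)]
  if (var(x) == 0) stop("zero expression variance across groups")
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]),
       p_value = unname(sm[2, 4]),
       r = unname(cor(x, y)),
       n_groups = length(shared))
}

#' Impute cohort group-mean expression onto registry patients
#'
#' Every registry patient receives exactly the clinical cohort's mean
#' expression of their progression group; patients whose group is absent
#' from the profile are dropped and counted. By construction the group-wise
#' means of the imputed column equal the profile entries to machine
#' precision.
#'
#' @param registrySubset registry rows.
#' @param exprMeans named numeric vector (group key -> mean expression).
#' @return data.frame of the kept rows plus a \code{pseudo_expr} column;
#'   attribute \code{n_dropped}.
#' @export
imputeGroupExpression <- function(registrySubset, exprMeans) {
  keys <- assignGroups(registrySubset)
  keep <- !is.na(keys) & keys %in% names(exprMeans)
  out <- registrySubset[keep, , drop = FALSE]
  out$pseudo_expr <- unname(exprMeans[keys[keep]])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Population-level Cox and Kaplan-Meier re-evaluation
#'
#' Fits a univariate Cox model on the imputed pseudo-expression and runs a
#' Kaplan-Meier log-rank comparison splitting the registry at the median
#' imputed value (the pseudo-expression takes only as many values as there
#' are groups, so the quantile scan of the cohort layer would degenerate;
#' set \code{scan = TRUE} to scan the distinct imputed values instead).
#'
#' @param times,events registry survival outcome.
#' @param pseudoExpr imputed expression (>= 2 distinct values).
#' @param scan use a cutoff scan over distinct values instead of the
#'   median split.
#' @return list with \code{cox} (see [coxUnivariate()]) and \code{km}
#'   (list: \code{logrank_p}, \code{direction}, \code{cutoff}).
#' @export
populationCoxKm <- function(times, events, pseudoExpr, scan = FALSE) {
  if (length(unique(pseudoExpr)) < 2) stop("constant pseudo-expression")
  cox <- coxUnivariate(times, events, pseudoExpr)
  if (scan) {
    sc <- kmCutoffScan(pseudoExpr, times, events, qLo = 0, qHi = 1,
                       nGrid = length(unique(pseudoExpr)),
                       useAllValues = TRUE)
    km <- list(logrank_p = sc$min_logrank_p, direction = sc$direction,
               cutoff = sc$best_cutoff)
  } else {
    med <- median(pseudoExpr)
    over <- pseudoExpr > med
    if (!sum(over) || !sum(!over)) {          # median hit the maximum
      cand <- sort(unique(pseudoExpr))
      cand <- cand[-length(cand)]
      bal <- vapply(cand, function(ct)
        abs(sum(pseudoExpr > ct) - length(pseudoExpr) / 2), numeric(1))
      med <- cand[which.min(bal)]
      over <- pseudoExpr > med
    }
    lr <- logrankTest(times[over], events[over], times[!over], events[!over])
    tau <- max(times)
    dir <- if (rmst(kmEstimate(times[over], events[over]), tau) >=
               rmst(kmEstimate(times[!over], events[!over]), tau)) 1L else -1L
    km <- list(logrank_p = lr$p_value, direction = dir, cutoff = med)
  }
  list(cox = cox, km = km)
}

# Direction labels per layer under the project-wide convention:
# positive = higher expression <-> longer survival.
layerDirections <- function(cohortDirection, slope, popBeta, popKmDirection) {
  c(cohort = cohortDirection,
    regression = if (slope > 0) 1L else -1L,
    pop_cox = if (popBeta < 0) 1L else -1L,
    pop_km = popKmDirection)
}

#' Prognostic-marker verdict for one miRNA
#'
#' Conjunctive three-layer rule on the no-chemotherapy registry population:
#' the miRNA must pass the cohort screen, the group-level regression must be
#' significant, BOTH population-level models (Cox and Kaplan-Meier on the
#' imputed expression) must be significant, and every layer must point the
#' same way (positive direction = slope > 0 = Cox beta < 0 = over-expression
#' group survives longer). The strict both-population reading is the
#' default; \code{requireBothPopulation = FALSE} relaxes it to the
#' either-model rule used for chemopredictive selection.
#'
#' @param cohortRow one row of the [cohortScreen()] table (list-like).
#' @param regression output of [populationRegression()].
#' @param population output of [populationCoxKm()].
#' @param alpha significance level.
#' @param requireBothPopulation require both population models significant.
#' @return list with \code{verdict} (\code{"prognostic_selected"} or
#'   \code{"rejected"}), \code{direction} (\code{"positive"},
#'   \code{"negative"} or NA), \code{failure_reasons}.
#' @export
selectPrognostic <- function(cohortRow, regression, population,
                             alpha = 0.05, requireBothPopulation = TRUE) {
  fails <- character()
  if (!isTRUE(cohortRow$cohort_pass)) fails <- c(fails, "cohort screen failed")
  if (regression$p_value >= alpha)
    fails <- c(fails, "regression not significant")
  coxSig <- population$cox$p_value < alpha && population$cox$converged
  kmSig <- population$km$logrank_p < alpha
  if (requireBothPopulation) {
    if (!coxSig) fails <- c(fails, "population Cox not significant")
    if (!kmSig) fails <- c(fails, "population KM not significant")
  } else if (!coxSig && !kmSig) {
    fails <- c(fails, "no significant population model")
  }
  dirs <- layerDirections(cohortRow$cohort_direction, regression$slope,
                          population$cox$beta, population$km$direction)
  if (length(unique(dirs)) > 1L) fails <- c(fails, "discordant direction")
  list(verdict = if (length(fails)) "rejected" else "prognostic_selected",
       direction = if (length(fails)) NA_character_ else
         if (dirs[["regression"]] == 1L) "positive" else "negative",
       failure_reasons = fails)
}

#' Chemopredictive-marker verdict for one miRNA
#'
#' Evaluated on the agent-treated registry subset. The rule requires the
#' cohort screen, a significant group-level regression, and significance on
#' at least ONE of the population Cox / Kaplan-Meier models, with direction
#' consistency among the cohort screen, the regression and every
#' significant population layer. A positive direction (higher expression,
#' longer disease-specific survival under the agent) labels the miRNA
#' chemo-sensitive; negative labels it chemo-resistant. Prognostic selection
#' is not a prerequisite.
#'
#' @inheritParams selectPrognostic
#' @return list with \code{verdict} (\code{"chemo_sensitive"},
#'   \code{"chemo_resistant"} or \code{"rejected"}), \code{direction},
#'   \code{failure_reasons}.
#' @export
selectChemopredictive <- function(cohortRow, regression, population,
                                  alpha = 0.05) {
  fails <- character()
  if (!isTRUE(cohortRow$cohort_pass)) fails <- c(fails, "cohort screen failed")
  if (regression$p_value >= alpha)
    fails <- c(fails, "regression not significant")
  coxSig <- population$cox$p_value < alpha && population$cox$converged
  kmSig <- population$km$logrank_p < alpha
  if (!coxSig && !kmSig)
    fails <- c(fails, "no significant population model")
  dirs <- layerDirections(cohortRow$cohort_direction, regression$slope,
                          population$cox$beta, population$km$direction)
  use <- c(TRUE, TRUE, coxSig, kmSig)          # concordance among
  if (length(unique(dirs[use])) > 1L)          # significant layers only
    fails <- c(fails, "discordant direction")
  if (length(fails))
    return(list(verdict = "rejected", direction = NA_character_,
                failure_reasons = fails))
  dir <- if (dirs[["regression"]] == 1L) "positive" else "negative"
  list(verdict = if (dir == "positive") "chemo_sensitive" else
         "chemo_resistant",
       direction = dir, failure_reasons = character())
}

#' Run the full marker-selection pipeline on one (stratum, agent) view
#'
#' Orchestrates the three selection layers: cohort screen, progression-group
#' linkage (group means, group survival, group-level regression), and
#' population-level re-evaluation after imputing cohort group means onto
#' registry patients. Downstream layers are only computed for miRNAs that
#' pass the cohort screen; the rest are recorded as rejected with the
#' failing layer named.
#'
#' @param cohort a [MirnaCohort-class].
#' @param registry registry data.frame ([simulateRegistry()] schema).
#' @param rule \code{"prognostic"} (registry restricted to patients without
#'   chemotherapy; both population models required) or
#'   \code{"chemopredictive"} (agent-treated patients; either model).
#' @param agent chemotherapy filter passed to [chemoSubset()]; defaults to
#'   \code{"none"} for the prognostic rule and \code{"any"} otherwise.
#' @param stratum \code{"all"} or one of the [stratifyTreatment()] views.
#' @param alpha significance level used in every layer.
#' @param minGroupCohort,minGroupRegistry minimum progression-group size on
#'   the cohort / registry side for a group to enter the linkage.
#' @param minAgentSubset minimum registry subset size for a
#'   chemopredictive run.
#' @param scanPopulationKm use a cutoff scan instead of the median split in
#'   the population KM layer.
#' @param ... passed to [cohortScreen()].
#' @return A [MarkerSelection-class].
#' @examples
#' cfg <- simulationConfig(seed = 11, nRegistry = 4000, nCohort = 120,
#'                         nMirna = 4, plantedEffects = c("mir-001" = -1))
#' sel <- selectMarkers(simulateExpressionCohort(cfg),
#'                      simulateRegistry(cfg), rule = "prognostic")
#' sel
#' @export
selectMarkers <- function(cohort, registry,
                          rule = c("prognostic", "chemopredictive"),
                          agent = NULL, stratum = "all", alpha = 0.05,
                          minGroupCohort = 1L, minGroupRegistry = 10L,
                          minAgentSubset = 50L, scanPopulationKm = FALSE,
                          ...) {
  rule <- match.arg(rule)
  if (is.null(agent)) agent <- if (rule == "prognostic") "none" else "any"
  stopifnot(is(cohort, "MirnaCohort"))
  subset <- registry
  if (stratum != "all") {
    strata <- stratifyTreatment(registry)
    if (!stratum %in% names(strata))
      stop("unknown stratum: ", stratum)
    subset <- subset[subset$patient_id %in% strata[[stratum]], , drop = FALSE]
  }
  subset <- chemoSubset(subset, agent)
  if (rule == "chemopredictive" && nrow(subset) < minAgentSubset)
    stop("agent subset too small (", nrow(subset), " < ", minAgentSubset,
         ") for stratum=", stratum, ", agent=", agent)
  if (nrow(subset) == 0) stop("empty registry subset")

  cohortKeys <- assignGroups(
    as.data.frame(SummarizedExperiment::colData(cohort)))
  registryKeys <- assignGroups(subset)
  groups <- commonGroups(cohortKeys, registryKeys,
                         minA = minGroupCohort, minB = minGroupRegistry)
  if (!length(groups))
    stop("no progression groups common to the cohort and the registry ",
         "subset (stratum=", stratum, ", agent=", agent, "): the cohorts ",
         "cannot be linked")

  screen <- cohortScreen(cohort, alpha = alpha, ...)
  profile <- groupExpressionMeans(cohort, groups)
  survProf <- groupSurvivalProfile(subset, groups,
                                   minPerGroup = minGroupRegistry)

  rows <- lapply(seq_len(nrow(screen)), function(i) {
    sr <- screen[i, ]
    base <- data.frame(
      sr,
      reg_slope = NA_real_, reg_p = NA_real_, reg_r = NA_real_,
      pop_beta = NA_real_, pop_cox_p = NA_real_,
      pop_km_p = NA_real_, pop_km_direction = NA_integer_,
      direction = NA_character_, verdict = "rejected",
      failure_reasons = if (isTRUE(sr$skipped)) "constant expression"
        else "cohort screen failed",
      stringsAsFactors = FALSE)
    if (!isTRUE(sr$cohort_pass)) return(base)
    means <- profile$means[sr$mirna, ]
    layers <- tryCatch({
      regression <- populationRegression(means, survProf)
      imputed <- imputeGroupExpression(subset, means)
      population <- populationCoxKm(imputed$time, imputed$event,
                                    imputed$pseudo_expr,
                                    scan = scanPopulationKm)
      list(regression = regression, population = population)
    }, error = function(e) e)
    if (inherits(layers, "error")) {
      base$failure_reasons <- paste("population layer failed:",
                                    conditionMessage(layers))
      return(base)
    }
    regression <- layers$regression
    population <- layers$population
    verdict <- if (rule == "prognostic")
      selectPrognostic(sr, regression, population, alpha = alpha)
    else
      selectChemopredictive(sr, regression, population, alpha = alpha)
    base$reg_slope <- regression$slope
    base$reg_p <- regression$p_value
    base$reg_r <- regression$r
    base$pop_beta <- population$cox$beta
    base$pop_cox_p <- population$cox$p_value
    base$pop_km_p <- population$km$logrank_p
    base$pop_km_direction <- population$km$direction
    base$direction <- verdict$direction
    base$verdict <- verdict$verdict
    base$failure_reasons <- paste(verdict$failure_reasons, collapse = "; ")
    base
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  new("MarkerSelection", records = records, alpha = alpha, rule = rule,
      stratum = stratum, agent = agent, groups = groups)
}
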