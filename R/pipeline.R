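#' Run the end-to-end pipeline on synthetic inputs
#'
#' Chains simulate -> derive treatment flags -> prognostic selection ->
#' chemopredictive selection into one reproducible run: the registry,
#' expression cohort and claims table are generated from \code{config},
#' chemotherapy flags are re-derived from the claims (exercising the
#' claims/diagnosis filter rather than trusting the generator's flags), and
#' the marker-selection rules are applied per requested agent. Reruns with
#' the same config are bit-identical.
#'
#' @param config a [SimulationConfig-class].
#' @param agents chemotherapy agents for the chemopredictive runs
#'   (\code{"any"} and/or specific agent names); \code{character()} skips
#'   chemopredictive selection.
#' @param stratum treatment stratum for all runs (\code{"all"} = no
#'   stratum filter).
#' @param alpha significance level.
#' @param outDir optional output directory; when given, writes
#'   \code{registry.tsv}, \code{cohort_expression.tsv},
#'   \code{claims.tsv}, one \code{selection_*.tsv} per run and a
#'   \code{run_summary.json}.
#' @param ... passed to [selectMarkers()].
#' @return list with \code{registry}, \code{cohort}, \code{claims},
#'   \code{selections} (named list of [MarkerSelection-class]) and
#'   \code{summary} (the run summary list).
#' @export
runPipeline <- function(config, agents = "any", stratum = "all",
                        alpha = 0.05, outDir = NULL, ...) {
  validObject(config)
  registry <- simulateRegistry(config)
  cohort <- simulateExpressionCohort(config)
  claims <- simulateClaims(config, registry)
  flags <- deriveTreatmentFlags(claims, patients = registry$patient_id)
  registry$chemo_agents <- flags$chemo_agents[
    match(registry$patient_id, flags$patient_id)]

  selections <- list()
  skipped <- character()
  sel <- selectMarkers(cohort, registry, rule = "prognostic",
                       stratum = stratum, alpha = alpha, ...)
  selections[["prognostic"]] <- sel
  for (agent in agents) {
    nm <- paste0("chemo_", agent)
    res <- tryCatch(
      selectMarkers(cohort, registry, rule = "chemopredictive",
                    agent = agent, stratum = stratum, alpha = alpha, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, paste0(nm, ": ", conditionMessage(res)))
    } else {
      selections[[nm]] <- res
    }
  }

  summary <- list(
    seed = config@seed,
    n_registry = nrow(registry),
    n_cohort = ncol(cohort),
    n_mirna = nrow(cohort),
    stratum = stratum,
    alpha = alpha,
    runs = lapply(selections, function(s) list(
      rule = s@rule, agent = s@agent,
      n_groups = length(s@groups), groups = s@groups,
      n_selected = length(selectedMarkers(s)),
      selected = selectedMarkers(s))),
    skipped_runs = skipped
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeRegistry(registry, file.path(outDir, "registry.tsv"))
    writeExpressionMatrix(exprMatrix(cohort),
                          file.path(outDir, "cohort_expression.tsv"),
                          idColumn = "mirna")
    write.table(claims, file.path(outDir, "claims.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (nm in names(selections))
      write.table(markerRecords(selections[[nm]]),
                  file.path(outDir, paste0("selection_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(registry = registry, cohort = cohort, claims = claims,
       selections = selections, summary = summary)
}
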