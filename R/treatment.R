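#' Default agent procedure-code map
#'
#' Synthetic placeholder map from chemotherapy agents to procedure codes
#' (HCPCS-like) plus the set of lung-cancer diagnosis codes (ICD-9-like)
#' that a claim must carry for the agent to count as lung-cancer treatment.
#' Real code lists are user-supplied configuration; this map matches the
#' codes emitted by [simulateClaims()].
#'
#' @return list with elements \code{agents} (named list of character code
#'   sets) and \code{lung_diagnosis_codes}.
#' @export
defaultAgentCodeMap <- function() {
  list(
    agents = list(
      cisplatin = c("J9060", "J9062"),
      carboplatin = "J9045",
      paclitaxel = c("J9265", "J9267"),
      etoposide = c("J9181", "J9182")
    ),
    lung_diagnosis_codes = c("162.2", "162.3", "162.4", "162.5",
                             "162.8", "162.9")
  )
}

#' Derive chemotherapy flags from a claims table
#'
#' An agent is attributed to a patient iff at least one claim matches both
#' one of the agent's procedure codes and a lung-cancer diagnosis code —
#' procedure-code matching alone over-counts because agents are also billed
#' for other diseases.
#'
#' @param claims data.frame with columns \code{patient_id},
#'   \code{procedure_code}, \code{diagnosis_code}.
#' @param codeMap see [defaultAgentCodeMap()].
#' @param patients optional character vector of patient ids that must appear
#'   in the result even with no qualifying claim (empty agent set).
#' @return data.frame with \code{patient_id} and \code{chemo_agents}
#'   (";"-separated sorted agent names, \code{""} = none).
#' @export
deriveTreatmentFlags <- function(claims, codeMap = defaultAgentCodeMap(),
                                 patients = NULL) {
  if (is.null(patients)) patients <- unique(claims$patient_id)
  sets <- setNames(vector("list", length(patients)), patients)
  lungOk <- claims$diagnosis_code %in% codeMap$lung_diagnosis_codes
  for (agent in names(codeMap$agents)) {
    hit <- claims$procedure_code %in% codeMap$agents[[agent]] & lungOk
    for (p in intersect(unique(claims$patient_id[hit]), patients))
      sets[[p]] <- c(sets[[p]], agent)
  }
  data.frame(patient_id = patients,
             chemo_agents = joinAgents(sets),
             stringsAsFactors = FALSE)
}

#' Partition the registry into treatment strata
#'
#' The four analysis views: surgery without radiation (and in particular
#' without preoperative radiation), radiation without surgery, both
#' surgery and radiation, and any treatment at all (surgery, radiation or
#' chemotherapy). The first three are disjoint; \code{any_treatment}
#' contains each of them, so the strata are overlapping analysis views
#' rather than a partition.
#'
#' @param registry data.frame with logical \code{surgery}, \code{radiation},
#'   \code{preop_radiation} columns and \code{chemo_agents}.
#' @return named list of patient-id character vectors with elements
#'   \code{surgery_only}, \code{radiation_only}, \code{surgery_and_radiation},
#'   \code{any_treatment}.
#' @export
stratifyTreatment <- function(registry) {
  s <- registry$surgery
  r <- registry$radiation
  pre <- registry$preop_radiation
  chemo <- nzchar(registry$chemo_agents)
  id <- registry$patient_id
  list(
    surgery_only = id[s & !pre & !r],
    radiation_only = id[r & !s],
    surgery_and_radiation = id[s & r],
    any_treatment = id[s | r | chemo]
  )
}

#' Subset the registry by chemotherapy exposure
#'
#' \code{"none"} selects patients with an empty agent set (the prognostic
#' analysis population); \code{"any"} selects patients with any agent; a
#' specific agent name selects patients whose set contains it.
#'
#' @param registry registry data.frame.
#' @param agent \code{"none"}, \code{"any"}, or an agent name.
#' @param knownAgents agents considered valid; defaults to those in
#'   [defaultAgentCodeMap()] plus any observed in the registry.
#' @return the selected registry rows.
#' @export
chemoSubset <- function(registry, agent, knownAgents = NULL) {
  if (is.null(knownAgents))
    knownAgents <- union(names(defaultAgentCodeMap()$agents),
                         unlist(splitAgents(registry$chemo_agents)))
  if (agent == "none") return(registry[!nzchar(registry$chemo_agents), ,
                                       drop = FALSE])
  if (agent == "any") return(registry[nzchar(registry$chemo_agents), ,
                                      drop = FALSE])
  if (!agent %in% knownAgents) stop("unknown agent: ", agent)
  hit <- vapply(splitAgents(registry$chemo_agents),
                function(a) agent %in% a, logical(1))
  registry[hit, , drop = FALSE]
}
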