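#' @importFrom stats coef cor cor.test lm median pchisq pnorm pt quantile
#'   rbinom rexp rnorm rpois runif sd setNames t.test var cooks.distance
#'   hatvalues complete.cases
#' @importFrom utils read.delim write.table head
NULL

# Deterministic sub-seed for a named generator stream. Keeps every module on
# its own RNG stream so re-running one simulator never perturbs another.
# Result stays below 2^31 - 1 (R integers are 32-bit).
deriveSeed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483646) + 1L
}

# Run code under a derived seed without disturbing the caller's RNG state.
withStream <- function(seed, stream, code) {
  withr::with_seed(deriveSeed(seed, stream), code)
}

# Severity score: monotone composite of the progression components.
severityScore <- function(t_stage, n_stage, m_stage, grade) {
  (t_stage - 1L) + n_stage + m_stage + (grade - 1L)
}

# Collapse an agent set to its TSV form ("" = no chemotherapy).
joinAgents <- function(sets) {
  vapply(sets, function(a) paste(sort(unique(a)), collapse = ";"),
         character(1))
}

splitAgents <- function(s) {
  lapply(strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE),
         function(a) a[nzchar(a)])
}
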