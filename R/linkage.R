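#' Canonical progression-group key
#'
#' Builds the composite tumor-progression label "T{t}N{n}M{m}G{g}" from the
#' four staging components. This key is what links the expression cohort to
#' the registry cohort: patients sharing a key are assumed to occupy the
#' same point on the tumor-progression scale. Keys order canonically by
#' plain lexicographic sort (all components are single digits).
#'
#' @param t_stage integer 1-4.
#' @param n_stage integer 0-3.
#' @param m_stage integer 0-1.
#' @param grade integer 1-4.
#' @return character vector of keys.
#' @examples
#' makeGroupKey(1, 0, 0, 1)  # "T1N0M0G1"
#' @export
makeGroupKey <- function(t_stage, n_stage, m_stage, grade) {
  ok <- !is.na(t_stage) & t_stage %in% 1:4 &
    !is.na(n_stage) & n_stage %in% 0:3 &
    !is.na(m_stage) & m_stage %in% 0:1 &
    !is.na(grade) & grade %in% 1:4
  if (!all(ok))
    stop("ungroupable patient(s): missing or out-of-range staging at ",
         "position(s) ", paste(head(which(!ok), 5), collapse = ", "))
  sprintf("T%dN%dM%dG%d", t_stage, n_stage, m_stage, grade)
}

#' Assign progression-group keys to a patient table
#'
#' Tolerant, vectorized companion to [makeGroupKey()]: patients with missing
#' or out-of-range staging get \code{NA} and are counted in the
#' \code{"n_ungroupable"} attribute (they are excluded from any linkage).
#'
#' @param patients data.frame with columns \code{t_stage}, \code{n_stage},
#'   \code{m_stage}, \code{grade}.
#' @return character vector (with NAs) plus attribute \code{n_ungroupable}.
#' @export
assignGroups <- function(patients) {
  with(patients, {
    ok <- !is.na(t_stage) & t_stage %in% 1:4 &
      !is.na(n_stage) & n_stage %in% 0:3 &
      !is.na(m_stage) & m_stage %in% 0:1 &
      !is.na(grade) & grade %in% 1:4
    keys <- rep(NA_character_, length(ok))
    keys[ok] <- sprintf("T%dN%dM%dG%d", t_stage[ok], n_stage[ok],
                        m_stage[ok], grade[ok])
    structure(keys, n_ungroupable = sum(!ok))
  })
}

#' Progression groups common to two cohorts
#'
#' Returns the keys represented with at least \code{minA} members in the
#' first key multiset and \code{minB} in the second, sorted canonically.
#' An empty result signals that the cohorts cannot be linked.
#'
#' @param keysA,keysB character vectors of group keys (NAs ignored).
#' @param minA,minB minimum member count per side. The clinical side
#'   defaults to 1 (small cohorts are the reality of the design); the
#'   registry side should be held to a stabler minimum (10 by default in
#'   [selectMarkers()]).
#' @return sorted character vector of common keys.
#' @export
commonGroups <- function(keysA, keysB, minA = 1L, minB = 1L) {
  stopifnot(minA >= 1L, minB >= 1L)
  ta <- table(keysA[!is.na(keysA)])
  tb <- table(keysB[!is.na(keysB)])
  keep <- intersect(names(ta)[ta >= minA], names(tb)[tb >= minB])
  sort(keep)
}

#' Leverage and influence diagnostics for the group-level regression
#'
#' For the simple linear regression of group survival on group expression,
#' computes per-group hat values \eqn{h_i = 1/n + (x_i - \bar x)^2 /
#' \sum_j (x_j - \bar x)^2} and Cook's distances, flagging groups with
#' Cook's D above \code{flagFactor / n} (4/n by default). Used to check
#' that no single progression group drives the regression.
#'
#' @param x per-group predictor values (group-mean expression).
#' @param y per-group responses (group restricted mean survival).
#' @param flagFactor numerator of the Cook's distance flag rule.
#' @return list with \code{leverage}, \code{cooks_distance}, \code{flagged},
#'   \code{rule}.
#' @export
leverageDiagnostics <- function(x, y, flagFactor = 4) {
  if (length(x) < 3) stop("need at least 3 groups")
  if (length(unique(x)) < 2) stop("degenerate design: constant predictor")
  stopifnot(length(x) == length(y))
  fit <- lm(y ~ x)
  n <- length(x)
  h <- unname(hatvalues(fit))
  d <- unname(cooks.distance(fit))
  list(leverage = h,
       cooks_distance = d,
       flagged = d > flagFactor / n,
       rule = sprintf("cooks_distance > %g/n", flagFactor))
}
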