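#' Kaplan-Meier survival curve container
#'
#' Stores the product-limit estimate at the distinct event times together
#' with the risk-set sizes and the maximum follow-up in the data. S(0) = 1
#' is implicit; the curve is a right-continuous step function constant
#' between event times.
#'
#' @slot time increasing positive event times.
#' @slot surv survival probabilities at those times (non-increasing).
#' @slot nRisk,nEvent numbers at risk / events at each event time.
#' @slot maxFollowUp largest observed time (event or censoring).
#' @seealso [kmEstimate()], [rmst()]
#' @export
setClass("SurvivalCurve",
  representation(time = "numeric", surv = "numeric",
                 nRisk = "numeric", nEvent = "numeric",
                 maxFollowUp = "numeric"))

setValidity("SurvivalCurve", function(object) {
  if (is.unsorted(object@time, strictly = TRUE)) return("times must increase")
  if (any(object@surv < 0 | object@surv > 1)) return("surv must be in [0,1]")
  if (any(diff(object@surv) > 1e-12)) return("surv must be non-increasing")
  TRUE
})

setMethod("show", "SurvivalCurve", function(object) {
  cat("SurvivalCurve:", length(object@time), "event times, max follow-up",
      format(object@maxFollowUp, digits = 4), "\n")
  if (length(object@time)) {
    i <- unique(round(seq(1, length(object@time),
                          length.out = min(5, length(object@time)))))
    print(data.frame(time = object@time[i], surv = object@surv[i]))
  }
})

#' Product-limit (Kaplan-Meier) estimate
#'
#' Thin wrapper over [survival::survfit()] retaining only the event times
#' (censorings enter through the risk sets, as usual).
#'
#' @param times positive observation times.
#' @param events 0/1 event indicators (1 = event).
#' @return A [SurvivalCurve-class].
#' @examples
#' kmEstimate(c(1, 2, 2, 3), c(1, 0, 1, 1))
#' @export
kmEstimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- sf$n.event > 0
  new("SurvivalCurve",
      time = sf$time[keep], surv = sf$surv[keep],
      nRisk = sf$n.risk[keep], nEvent = sf$n.event[keep],
      maxFollowUp = max(times))
}

#' Restricted mean survival time (area under the KM curve)
#'
#' Integrates the step function S(t) over [0, min(tau, max follow-up)].
#' With no truncation time supplied, tau defaults to the maximum observed
#' time, i.e. the area under the whole estimated curve.
#'
#' @param curve a [SurvivalCurve-class].
#' @param tau truncation time (months); must be positive.
#' @return Mean survival in months, in (0, tau].
#' @examples
#' rmst(kmEstimate(c(5), c(1)), tau = 10)  # single event at 5 -> 5
#' @export
rmst <- function(curve, tau = NULL) {
  stopifnot(is(curve, "SurvivalCurve"))
  if (is.null(tau)) tau <- curve@maxFollowUp
  if (tau <= 0) stop("tau must be positive")
  end <- min(tau, curve@maxFollowUp)
  keep <- curve@time < end
  knots <- c(0, curve@time[keep], end)
  heights <- c(1, curve@surv[keep])
  sum(diff(knots) * heights)
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank chi-square via [survival::survdiff()].
#' With zero events in the pooled sample the statistic is 0 and p = 1.
#'
#' @param timesA,eventsA,timesB,eventsB the two samples.
#' @return list with \code{chi_square} and \code{p_value}.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) stop("both groups must be non-empty")
  if (sum(eventsA) + sum(eventsB) == 0)
    return(list(chi_square = 0, p_value = 1))
  grp <- factor(rep(c("A", "B"), c(length(timesA), length(timesB))))
  sd <- survival::survdiff(
    survival::Surv(c(timesA, timesB), c(eventsA, eventsB)) ~ grp)
  list(chi_square = unname(sd$chisq),
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial likelihood by Newton iteration
#' (convergence tolerance 1e-9, at most 100 iterations) through
#' [survival::coxph()]; reports the Wald two-sided p-value. A monotone
#' partial likelihood (perfect separation) is flagged via
#' \code{converged = FALSE} rather than an error.
#'
#' @param times,events survival outcome.
#' @param x numeric covariate, non-constant, with at least 2 events.
#' @param ties tie handling, \code{"breslow"} (default) or \code{"efron"}.
#' @return list with \code{beta}, \code{hazard_ratio}, \code{se},
#'   \code{p_value}, \code{converged}, \code{n}, \code{n_events}.
#' @export
coxUnivariate <- function(times, events, x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (length(unique(x)) < 2) stop("covariate is constant")
  if (sum(events) < 2) stop("need at least 2 events")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be|NaN|NA", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- suppressWarnings(sqrt(unname(fit$var[1, 1])))
  if (!is.finite(beta) || !is.finite(se) || se <= 0) converged <- FALSE
  list(beta = beta,
       hazard_ratio = exp(beta),
       se = se,
       p_value = if (is.finite(beta) && is.finite(se) && se > 0)
         2 * pnorm(-abs(beta / se)) else NA_real_,
       converged = converged,
       n = fit$n, n_events = fit$nevent)
}

#' Expression-cutoff scan for Kaplan-Meier separation
#'
#' Scans candidate cutoffs between the \code{qLo} and \code{qHi} quantiles
#' of the covariate; at each cutoff the sample is split into over-expression
#' (x > cutoff) and under-expression groups and a log-rank test is run.
#' The candidate set is the distinct covariate values inside the quantile
#' window, capped at \code{nGrid} evenly spaced quantiles (set
#' \code{useAllValues = TRUE} to scan every distinct value). Cutoffs leaving
#' fewer than \code{minPerSide} observations on a side are skipped. The
#' minimum p over the grid is reported uncorrected, together with the
#' number of cutoffs actually tested so the multiplicity is visible.
#'
#' @param x covariate (e.g. one miRNA's expression), >= 2 distinct values.
#' @param times,events survival outcome.
#' @param qLo,qHi quantile window for candidate cutoffs.
#' @param nGrid cap on the number of candidate cutoffs.
#' @param minPerSide minimum group size on each side of a cutoff.
#' @param useAllValues scan every distinct value in the window.
#' @return list with \code{best_cutoff} (smallest cutoff attaining the
#'   minimum p), \code{min_logrank_p}, \code{direction} (+1 if the
#'   over-expression group has the larger restricted mean survival),
#'   \code{n_cutoffs_tested}.
#' @export
kmCutoffScan <- function(x, times, events, qLo = 0.05, qHi = 0.95,
                         nGrid = 20, minPerSide = 3, useAllValues = FALSE) {
  if (length(unique(x)) < 2) stop("covariate is constant")
  stopifnot(nGrid >= 1, qLo < qHi)
  qs <- quantile(x, c(qLo, qHi), names = FALSE)
  cand <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  if (!useAllValues && length(cand) > nGrid)
    cand <- sort(unique(quantile(x, seq(qLo, qHi, length.out = nGrid),
                                 names = FALSE)))
  bestP <- Inf; bestCut <- NA_real_; nTested <- 0L
  for (cut in cand) {
    over <- x > cut
    if (sum(over) < minPerSide || sum(!over) < minPerSide) next
    lr <- logrankTest(times[over], events[over], times[!over], events[!over])
    nTested <- nTested + 1L
    if (lr$p_value < bestP - 1e-15) {        # ties keep the smaller cutoff
      bestP <- lr$p_value
      bestCut <- cut
    }
  }
  if (nTested == 0L)
    stop("all candidate cutoffs degenerate (one side below minPerSide)")
  over <- x > bestCut
  tau <- max(times)
  dir <- if (rmst(kmEstimate(times[over], events[over]), tau) >=
             rmst(kmEstimate(times[!over], events[!over]), tau)) 1L else -1L
  list(best_cutoff = bestCut, min_logrank_p = bestP,
       direction = dir, n_cutoffs_tested = nTested)
}
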