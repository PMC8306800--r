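#' Trichotomize cell-line drug response
#'
#' Classifies each cell line as sensitive, partial or resistant to a drug.
#' Dose-bound overrides are applied first where bounds exist: an activity
#' value above the maximum tested dose is resistant, below the minimum dose
#' sensitive, regardless of the distribution. The remaining (informative,
#' in-bounds) lines are trichotomized by mean +/- 0.5 * SD (sample SD,
#' n - 1) of those remaining values: above mean + 0.5 SD resistant, below
#' mean - 0.5 SD sensitive, in between (or exactly at a threshold) partial.
#' With \code{includeOverridden = TRUE} the bound-overridden lines are kept
#' in the mean/SD computation instead of excluded.
#'
#' Activity values may be on the concentration or log-concentration scale;
#' the classification is invariant to translation and positive scaling, so
#' the scale only needs to match the dose bounds.
#'
#' @param values named numeric vector (cell line -> activity value, e.g.
#'   IC50 or ln(IC50)); NAs are dropped as uninformative.
#' @param minDose,maxDose optional dose bounds on the same scale.
#' @param includeOverridden include bound-overridden lines in the mean/SD.
#' @return named character vector of labels (\code{"sensitive"},
#'   \code{"partial"}, \code{"resistant"}) over the informative lines.
#' @examples
#' classifyDrugResponse(setNames(c(0, 0, 0, 4, 4, 4), paste0("L", 1:6)))
#' @export
classifyDrugResponse <- function(values, minDose = NA, maxDose = NA,
                                 includeOverridden = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no informative activity values")
  if (length(values) < 2) stop("need at least 2 informative values")
  if (!is.na(minDose) && !is.na(maxDose) && minDose >= maxDose)
    stop("minDose must be below maxDose")
  labels <- setNames(rep(NA_character_, length(values)), names(values))
  overHi <- !is.na(maxDose) & values > maxDose
  overLo <- !is.na(minDose) & values < minDose
  labels[overHi] <- "resistant"
  labels[overLo] <- "sensitive"
  rest <- !(overHi | overLo)
  pool <- if (includeOverridden) values else values[rest]
  m <- mean(pool)
  s <- sd(pool)
  if (is.na(s)) s <- 0                       # single remaining line
  labels[rest & values > m + 0.5 * s] <- "resistant"
  labels[rest & values < m - 0.5 * s] <- "sensitive"
  labels[rest & is.na(labels)] <- "partial"
  labels
}

#' Differential expression between resistant and sensitive lines
#'
#' Pooled-variance two-sample t-test of a marker's expression in resistant
#' versus sensitive cell lines (partial responders excluded), plus the fold
#' change mean(resistant) / mean(sensitive) on the linear scale. If the
#' expression is on a log scale, declare it so the means are
#' back-transformed before the ratio (the t-test stays on the scale
#' provided).
#'
#' @param expr named numeric vector (cell line -> expression).
#' @param labels named character vector from [classifyDrugResponse()].
#' @param exprScale \code{"linear"}, \code{"log2"} or \code{"ln"}.
#' @return list with \code{t_statistic}, \code{p_two_sided},
#'   \code{fold_change}, \code{n_resistant}, \code{n_sensitive}.
#' @export
differentialExpression <- function(expr, labels,
                                   exprScale = c("linear", "log2", "ln")) {
  exprScale <- match.arg(exprScale)
  common <- intersect(names(expr), names(labels))
  res <- expr[common[labels[common] == "resistant"]]
  sen <- expr[common[labels[common] == "sensitive"]]
  if (length(res) < 2 || length(sen) < 2)
    stop("need >= 2 resistant and >= 2 sensitive lines")
  if (var(res) == 0 && var(sen) == 0) {      # degenerate pooled variance
    d <- mean(res) - mean(sen)
    tt <- if (d == 0) list(statistic = 0, p.value = 1)
      else list(statistic = sign(d) * Inf, p.value = 0)
  } else {
    tt <- t.test(res, sen, var.equal = TRUE)
  }
  back <- switch(exprScale, linear = identity,
                 log2 = function(v) 2^v, ln = exp)
  list(t_statistic = unname(tt$statistic),
       p_two_sided = tt$p.value,
       fold_change = mean(back(res)) / mean(back(sen)),
       n_resistant = length(res), n_sensitive = length(sen))
}

#' Expression-vs-activity regression across a cell panel
#'
#' For each drug-activity endpoint, ordinary least squares of the activity
#' value on the marker's expression across cell lines, after removing lines
#' without informative activity (NA or a declared sentinel). A marker is
#' "supported" if any endpoint is significant with slope direction
#' consistent with the claimed response call: a chemosensitivity claim
#' expects higher expression in lines needing less drug (negative slope on
#' GI50/TGI/LC50/IC50-type endpoints), a resistance claim the opposite.
#'
#' @param expr named numeric vector (cell line -> expression).
#' @param activity long-format data.frame with columns \code{cell_line},
#'   \code{endpoint}, \code{value} (as produced by [simulateCellPanel()]).
#' @param claim \code{"sensitive"} or \code{"resistant"}.
#' @param alpha significance level.
#' @param sentinel activity values treated as non-informative.
#' @param minLines minimum informative lines per endpoint.
#' @return list with \code{per_endpoint} (data.frame: endpoint, n, slope,
#'   p_value, skipped) and \code{supported} (logical).
#' @export
nci60Regression <- function(expr, activity, claim = c("sensitive",
                                                      "resistant"),
                            alpha = 0.05, sentinel = numeric(),
                            minLines = 3) {
  claim <- match.arg(claim)
  eps <- split(activity, activity$endpoint)
  per <- lapply(names(eps), function(ep) {
    a <- eps[[ep]]
    a <- a[!is.na(a$value) & !(a$value %in% sentinel), ]
    common <- intersect(names(expr), a$cell_line)
    if (length(common) < minLines)
      return(data.frame(endpoint = ep, n = length(common),
                        slope = NA_real_, p_value = NA_real_,
                        skipped = TRUE))
    x <- expr[common]
    y <- a$value[match(common, a$cell_line)]
    fit <- summary(lm(y ~ x))$coefficients
    data.frame(endpoint = ep, n = length(common),
               slope = fit[2, 1], p_value = fit[2, 4], skipped = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  wantNegative <- claim == "sensitive"
  hit <- !per$skipped & per$p_value < alpha &
    (if (wantNegative) per$slope < 0 else per$slope > 0)
  list(per_endpoint = per, supported = any(hit, na.rm = TRUE))
}
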