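#' Normalize dependency scores to control gene sets
#'
#' Per cell line, applies the affine map \eqn{s' = (s - m_{ne}) /
#' (m_{ne} - m_e)} where \eqn{m_{ne}} and \eqn{m_e} are that line's median
#' nonessential-control and essential-control scores, so that after
#' normalization the nonessential-control median is 0 and the
#' essential-control median is -1 in every line. Lines whose control
#' medians coincide (the map is undefined) are dropped with a message.
#' The map is idempotent: renormalizing a normalized screen changes
#' nothing.
#'
#' @param screen a [DependencyScreen-class] with both control sets.
#' @return A [DependencyScreen-class] with normalized scores (possibly
#'   fewer columns).
#' @export
normalizeDependency <- function(screen) {
  stopifnot(is(screen, "DependencyScreen"))
  if (!length(screen@essentialControls) ||
      !length(screen@nonessentialControls))
    stop("both control gene sets are required for normalization")
  s <- depScores(screen)
  mNe <- apply(s[screen@nonessentialControls, , drop = FALSE], 2, median,
               na.rm = TRUE)
  mE <- apply(s[screen@essentialControls, , drop = FALSE], 2, median,
              na.rm = TRUE)
  denom <- mNe - mE
  bad <- !is.finite(denom) | denom == 0
  if (any(bad)) {
    message("dropping ", sum(bad), " line(s) with equal control medians")
    s <- s[, !bad, drop = FALSE]
    mNe <- mNe[!bad]; denom <- denom[!bad]
  }
  out <- sweep(sweep(s, 2, mNe, `-`), 2, denom, `/`)
  DependencyScreen(out, screenType(screen),
                   essentialControls = screen@essentialControls,
                   nonessentialControls = screen@nonessentialControls)
}

#' Fraction of cell lines in which each gene is essential
#'
#' Per gene, the fraction of lines with a (normalized) dependency score at
#' or below the threshold; -0.5 marks a significant proliferation effect in
#' both CRISPR knockout and shRNA knockdown screens. Missing scores are
#' excluded per gene with the denominator adjusted.
#'
#' @param screen a normalized [DependencyScreen-class].
#' @param threshold score threshold (inclusive, i.e. score <= threshold).
#' @return data.frame: \code{gene}, \code{fraction}, \code{n_lines}
#'   (non-missing lines for that gene).
#' @export
essentialityFraction <- function(screen, threshold = -0.5) {
  s <- depScores(screen)
  nOk <- rowSums(!is.na(s))
  if (any(nOk == 0))
    warning(sum(nOk == 0), " gene(s) with no informative lines")
  hits <- rowSums(s <= threshold, na.rm = TRUE)
  data.frame(gene = rownames(s),
             fraction = ifelse(nOk > 0, hits / nOk, NA_real_),
             n_lines = nOk,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes with full (or near-full) impact in both screens
#'
#' Intersects two essentiality reports: genes whose essentiality fraction
#' reaches \code{minFraction} in both the CRISPR and the RNAi screen,
#' sorted by name. Genes absent from either report are excluded.
#'
#' @param crisprReport,rnaiReport outputs of [essentialityFraction()].
#' @param minFraction minimum fraction required in both screens (1.0 =
#'   significant effect in 100% of lines).
#' @return sorted character vector of gene names.
#' @export
intersectFullImpact <- function(crisprReport, rnaiReport,
                                minFraction = 1.0) {
  a <- crisprReport$gene[!is.na(crisprReport$fraction) &
                           crisprReport$fraction >= minFraction]
  b <- rnaiReport$gene[!is.na(rnaiReport$fraction) &
                         rnaiReport$fraction >= minFraction]
  sort(intersect(a, b))
}

#' Pearson correlation between two expression vectors
#'
#' Pearson's r with the two-sided t-based p-value over pairwise-complete
#' observations (at least 3 required).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{r} and \code{p_value}.
#' @export
expressionCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 paired complete observations")
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    stop("zero variance in one of the vectors")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
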