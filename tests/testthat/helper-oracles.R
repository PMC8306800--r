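# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the survival package) so that agreement is
# evidence, not tautology.

# Textbook two-group log-rank: observed-minus-expected over hypergeometric
# variance, summed over distinct event times.
logrankOracle <- function(t1, e1, t2, e2) {
  times <- c(t1, t2)
  events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (tt in ts) {
    atRisk <- times >= tt
    n <- sum(atRisk)
    n1 <- sum(atRisk & grp == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O1 - E1)^2 / V
  list(chi_square = chi,
       p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood for a univariate Cox model; maximized by
# golden-section search as a brute-force check on the Newton fit.
breslowLogLik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

coxGridOracle <- function(times, events, x) {
  optimize(function(b) breslowLogLik(b, times, events, x),
           interval = c(-10, 10), maximum = TRUE, tol = 1e-7)$maximum
}

# Closed-form simple-regression slope.
olsSlope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
  sum((x - mean(x))^2)

# Pooled-variance two-sample t from the textbook formula.
pooledTOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Small staged-patient table for linkage tests.
makeStagedDf <- function(t, n, m, g, time = NULL, event = NULL) {
  k <- length(t)
  data.frame(patient_id = sprintf("P%03d", seq_len(k)),
             time = if (is.null(time)) rep(10, k) else time,
             event = if (is.null(event)) rep(1L, k) else event,
             t_stage = t, n_stage = n, m_stage = m, grade = g,
             stringsAsFactors = FALSE)
}
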