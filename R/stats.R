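# Disproportionality statistics on 2x2 contingency tables.
#
# The table for a (drug, event) pair, counted over (report, term) pairs:
#     a = target drug & target event     b = target drug, other events
#     c = other drugs, target event      d = other drugs, other events
# N = a + b + c + d.
#
# All four estimators are the canonical pharmacovigilance forms:
#   ROR  = ad/bc, Woolf (log-scale) 95% CI
#   PRR  = [a/(a+b)] / [c/(c+d)], paired with the Pearson chi-squared
#   IC   = log2( aN / ((a+b)(a+c)) ), BCPNN closed-form posterior for IC025
#   EBGM = aN / ((a+b)(a+c)) (observed/expected), log-normal EB05
# Zero cells are reported as "degenerate" by default (no Haldane +0.5 unless
# asked for): corrections silently change published-style values.

#' A 2x2 drug-event contingency table
#'
#' @param a,b,c,d non-negative integer cell counts; `a` counts the target
#'   drug with the target event, `b` the target drug with other events, `c`
#'   other drugs with the target event, `d` the rest.
#' @return object of class `"contingency_table"` with fields a, b, c, d, N.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  N <- a + b + c + d
  if (N <= 0) stop("empty contingency table (N = 0)", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, N = N),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

as_cells <- function(t) {
  if (inherits(t, "contingency_table")) {
    list(a = t$a, b = t$b, c = t$c, d = t$d)
  } else {
    stopifnot(all(c("a", "b", "c", "d") %in% names(t)))
    list(a = t$a, b = t$b, c = t$c, d = t$d)
  }
}

haldane <- function(cells) {
  deg <- cells$a == 0 | cells$b == 0 | cells$c == 0 | cells$d == 0
  lapply(cells, function(x) x + 0.5 * deg)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; `CI = exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' Tables with any zero cell are degenerate: the estimate is `NA` under the
#' default `zero_policy = "degenerate"`, or computed on `+0.5`-smoothed
#' cells under `"haldane"`.
#'
#' @param t a [contingency_table()], or a list/data.frame with numeric
#'   (possibly vector) fields `a`, `b`, `c`, `d`.
#' @param zero_policy `"degenerate"` (default) or `"haldane"`.
#' @return data.frame with columns `ror`, `ror_lo`, `ror_hi`, `degenerate`.
#' @export
ror <- function(t, zero_policy = c("degenerate", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  cl <- as_cells(t)
  deg <- cl$a == 0 | cl$b == 0 | cl$c == 0 | cl$d == 0
  if (zero_policy == "haldane") cl <- haldane(cl)
  est <- (cl$a * cl$d) / (cl$b * cl$c)
  se <- sqrt(1 / cl$a + 1 / cl$b + 1 / cl$c + 1 / cl$d)
  lo <- exp(log(est) - 1.96 * se)
  hi <- exp(log(est) + 1.96 * se)
  if (zero_policy == "degenerate") {
    est[deg] <- NA_real_; lo[deg] <- NA_real_; hi[deg] <- NA_real_
  }
  data.frame(ror = est, ror_lo = lo, ror_hi = hi, degenerate = deg)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic uses expected
#' counts from the fixed margins, without Yates continuity correction unless
#' `yates = TRUE`.
#'
#' @inheritParams ror
#' @param yates apply the Yates continuity correction to chi-squared.
#' @return data.frame with columns `prr`, `chi2`, `degenerate`.
#' @export
prr <- function(t, zero_policy = c("degenerate", "haldane"), yates = FALSE) {
  zero_policy <- match.arg(zero_policy)
  cl <- as_cells(t)
  deg <- cl$a == 0 | cl$c == 0 | (cl$a + cl$b) == 0 | (cl$c + cl$d) == 0
  clp <- if (zero_policy == "haldane") haldane(cl) else cl
  est <- (clp$a / (clp$a + clp$b)) / (clp$c / (clp$c + clp$d))
  # chi-squared always from the raw cells: smoothing has no place in a
  # goodness-of-fit statistic
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  N <- a + b + c + d
  e_a <- (a + b) * (a + c) / N
  e_b <- (a + b) * (b + d) / N
  e_c <- (c + d) * (a + c) / N
  e_d <- (c + d) * (b + d) / N
  dev <- function(o, e) {
    x <- abs(o - e)
    if (yates) x <- pmax(x - 0.5, 0)
    out <- x^2 / e
    out[e == 0] <- 0
    out
  }
  chi2 <- dev(a, e_a) + dev(b, e_b) + dev(c, e_c) + dev(d, e_d)
  if (zero_policy == "degenerate") est[deg] <- NA_real_
  data.frame(prr = est, chi2 = chi2, degenerate = deg)
}

#' BCPNN information component with closed-form IC025
#'
#' The point estimate is the observed/expected log-ratio
#' `IC = log2( a N / ((a+b)(a+c)) )`. The lower credibility bound uses the
#' closed-form posterior moments of the Bayesian confidence propagation
#' neural network with the standard priors `alpha1 = beta1 = 1`,
#' `alpha = beta = 2`, `gamma11 = 1`:
#' `IC025 = E(IC) - 2 sqrt(V(IC))`. `a = 0` is allowed (the prior keeps the
#' posterior moments finite); an all-zero table is an error upstream.
#'
#' @inheritParams ror
#' @return data.frame with columns `ic`, `ic025`, `ic_e` (posterior mean).
#' @export
bcpnn_ic <- function(t) {
  cl <- as_cells(t)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  N <- a + b + c + d
  ic <- log2(a * N / ((a + b) * (a + c)))
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  g <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + g) * (a + b + a1) * (a + c + b1)))
  v_ic <- ((N - a + g - g11) / ((a + g11) * (1 + N + g)) +
             (N - a - b + al - a1) / ((a + b + a1) * (1 + N + al)) +
             (N - a - c + be - b1) / ((a + c + b1) * (1 + N + be))) / log(2)^2
  data.frame(ic = ic, ic025 = e_ic - 2 * sqrt(v_ic), ic_e = e_ic)
}

#' Empirical Bayes geometric mean (simplified closed form) and EB05
#'
#' `EBGM = a N / ((a+b)(a+c))` — the observed/expected reporting ratio under
#' independence — with the one-sided lower 5% bound
#' `EB05 = exp(log EBGM - 1.64 sqrt(1/a+1/b+1/c+1/d))`. EB05 is degenerate
#' (NA) when any cell is zero; EBGM itself only needs positive margins.
#' For the full DuMouchel gamma-mixture backend see [ebgm_mgps()].
#'
#' @inheritParams ror
#' @return data.frame with columns `ebgm`, `eb05`, `degenerate`.
#' @export
ebgm <- function(t, zero_policy = c("degenerate", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  cl <- as_cells(t)
  deg <- cl$a == 0 | cl$b == 0 | cl$c == 0 | cl$d == 0
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  N <- a + b + c + d
  est <- a * N / ((a + b) * (a + c))
  clp <- if (zero_policy == "haldane") haldane(cl) else cl
  estp <- clp$a * (clp$a + clp$b + clp$c + clp$d) /
    ((clp$a + clp$b) * (clp$a + clp$c))
  se <- sqrt(1 / clp$a + 1 / clp$b + 1 / clp$c + 1 / clp$d)
  lo <- exp(log(estp) - 1.64 * se)
  if (zero_policy == "degenerate") lo[deg] <- NA_real_
  data.frame(ebgm = est, eb05 = lo, degenerate = deg)
}

#' Signal thresholds for the four algorithms
#'
#' Defaults are the standard literature cutoffs: a term must have at least
#' `min_a = 3` reports; ROR signals when the lower 95% bound exceeds 1; PRR
#' when `PRR >= 2` and `chi2 >= 4`; BCPNN when `IC025 > 0`; EBGM when
#' `EB05 > 2`. Each rule can be disabled individually.
#'
#' @param min_a minimum `a` cell (reported count) to evaluate a term.
#' @param ror_lo_gt,ebgm_eb05_gt,bcpnn_ic025_gt numeric cutoffs.
#' @param prr_ge,chi2_ge numeric cutoffs for the PRR rule.
#' @param use named logical vector enabling each algorithm's rule.
#' @return list of class `"signal_thresholds"`.
#' @export
signal_thresholds <- function(min_a = 3L, ror_lo_gt = 1, prr_ge = 2,
                              chi2_ge = 4, bcpnn_ic025_gt = 0,
                              ebgm_eb05_gt = 2,
                              use = c(ror = TRUE, prr = TRUE,
                                      bcpnn = TRUE, ebgm = TRUE)) {
  stopifnot(min_a >= 1)
  structure(list(min_a = as.integer(min_a), ror_lo_gt = ror_lo_gt,
                 prr_ge = prr_ge, chi2_ge = chi2_ge,
                 bcpnn_ic025_gt = bcpnn_ic025_gt,
                 ebgm_eb05_gt = ebgm_eb05_gt, use = use),
            class = "signal_thresholds")
}

#' DuMouchel MGPS gamma-mixture EBGM (optional backend)
#'
#' Fits the two-component gamma-mixture prior of the Multi-item Gamma
#' Poisson Shrinker to the observed counts `a` with baseline expectations
#' `E = (a+b)(a+c)/N`, by maximizing the negative-binomial mixture marginal
#' likelihood. Returns the posterior geometric mean `EBGM` and the posterior
#' 5% quantile `EB05` per table. Off by default in [evaluate_signals()]
#' because the simplified closed form is what this family of studies
#' reports; provided for methodological comparison.
#'
#' @param a integer vector of observed counts.
#' @param E numeric vector of expected counts (same length).
#' @return data.frame with columns `ebgm`, `eb05`, plus the fitted prior as
#'   `attr(, "theta")` = (alpha1, beta1, alpha2, beta2, w).
#' @export
ebgm_mgps <- function(a, E) {
  stopifnot(length(a) == length(E), all(E > 0))
  nb_loglik <- function(a, E, al, be) {
    # marginal of a | lambda ~ Gamma(al, be), a ~ Poisson(lambda E)
    lgamma(a + al) - lgamma(al) - lgamma(a + 1) +
      al * log(be / (be + E)) + a * log(E / (be + E))
  }
  nll <- function(p) {
    al1 <- exp(p[1]); be1 <- exp(p[2]); al2 <- exp(p[3]); be2 <- exp(p[4])
    w <- stats::plogis(p[5])
    l1 <- nb_loglik(a, E, al1, be1)
    l2 <- nb_loglik(a, E, al2, be2)
    m <- pmax(l1, l2)
    -sum(m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m)))
  }
  fit <- stats::optim(c(log(0.2), log(0.1), log(2), log(4), 0), nll,
                      method = "BFGS", control = list(maxit = 500))
  al1 <- exp(fit$par[1]); be1 <- exp(fit$par[2])
  al2 <- exp(fit$par[3]); be2 <- exp(fit$par[4])
  w <- stats::plogis(fit$par[5])
  l1 <- nb_loglik(a, E, al1, be1)
  l2 <- nb_loglik(a, E, al2, be2)
  q <- w * exp(l1) / (w * exp(l1) + (1 - w) * exp(l2))
  # posterior: mixture of Gamma(a+al1, be1+E) and Gamma(a+al2, be2+E)
  eglm <- q * (digamma(a + al1) - log(be1 + E)) +
    (1 - q) * (digamma(a + al2) - log(be2 + E))
  ebgm_v <- exp(eglm)
  eb05 <- vapply(seq_along(a), function(i) {
    f <- function(x) {
      q[i] * stats::pgamma(x, a[i] + al1, be1 + E[i]) +
        (1 - q[i]) * stats::pgamma(x, a[i] + al2, be2 + E[i]) - 0.05
    }
    stats::uniroot(f, lower = 1e-10, upper = max(ebgm_v[i] * 20, 10),
                   extendInt = "upX")$root
  }, 0)
  out <- data.frame(ebgm = ebgm_v, eb05 = eb05)
  attr(out, "theta") <- c(alpha1 = al1, beta1 = be1, alpha2 = al2,
                          beta2 = be2, w = w)
  out
}
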