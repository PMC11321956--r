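# Hand-checked reference table: a=10, b=90, c=100, d=9900, N=10100.
#   ROR  = (10*9900)/(90*100)            = 11
#   CI   = exp(ln 11 +/- 1.96*sqrt(1/10+1/90+1/100+1/9900))
#        = (5.559515, 21.764489)   (direct evaluation of the closed form)
#   PRR  = (10/100)/(100/10000)          = 10
#   IC   = log2(10*10100/(100*110))      = log2(9.18182) = 3.198857
#   EBGM = 9.18182
ref <- list(a = 10, b = 90, c = 100, d = 9900)

test_that("ROR point estimate and Woolf CI match hand evaluation", {
  t <- contingency_table(10, 90, 100, 9900)
  r <- ror(t)
  expect_equal(r$ror, 11)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r$ror_lo, exp(log(11) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$ror_hi, exp(log(11) + 1.96 * se), tolerance = 1e-12)
  expect_equal(round(c(r$ror_lo, r$ror_hi), 6), c(5.559515, 21.764489))

  expect_equal(ror(contingency_table(5, 50, 10, 100))$ror, 1)
})

test_that("PRR and chi-squared match hand evaluation", {
  p <- prr(ref)
  expect_equal(p$prr, 10)
  # independence margins: equal row proportions -> PRR 1, chi2 0
  ind <- list(a = 5, b = 50, c = 10, d = 100)
  expect_equal(prr(ind)$prr, 1)
  expect_equal(prr(ind)$chi2, 0)
  # chi2 against stats::chisq.test (no Yates)
  m <- matrix(c(10, 100, 90, 9900), 2)
  expect_equal(p$chi2, unname(suppressWarnings(
    stats::chisq.test(m, correct = FALSE))$statistic), tolerance = 1e-12)
  my <- prr(ref, yates = TRUE)
  expect_equal(my$chi2, unname(suppressWarnings(
    stats::chisq.test(m, correct = TRUE))$statistic), tolerance = 1e-12)
})

test_that("IC point estimate and limits behave as stated", {
  b <- bcpnn_ic(ref)
  expect_equal(b$ic, log2(10 * 10100 / (100 * 110)))
  expect_equal(round(b$ic, 3), 3.199)
  # independence at large N -> IC ~ 0; degenerate one-cell table -> IC = 0
  expect_equal(bcpnn_ic(list(a = 100, b = 900, c = 900, d = 8100))$ic, 0)
  expect_equal(bcpnn_ic(list(a = 50, b = 0, c = 0, d = 0))$ic, 0)
  # a = 0 stays finite through the prior
  z <- bcpnn_ic(list(a = 0, b = 10, c = 10, d = 100))
  expect_true(is.finite(z$ic025))
})

test_that("EBGM closed form and EB05 match hand evaluation", {
  e <- ebgm(ref)
  expect_equal(e$ebgm, 10 * 10100 / (100 * 110))
  expect_equal(round(e$ebgm, 2), 9.18)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(e$eb05, exp(log(e$ebgm) - 1.64 * se), tolerance = 1e-12)
  expect_lt(e$eb05, e$ebgm)
  expect_equal(ebgm(list(a = 5, b = 50, c = 10, d = 100))$ebgm, 1)
})

test_that("zero cells: degenerate by default, Haldane on request", {
  z <- list(a = 0, b = 10, c = 5, d = 100)
  expect_true(is.na(ror(z)$ror))
  expect_true(ror(z)$degenerate)
  rh <- ror(z, zero_policy = "haldane")
  expect_equal(rh$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_true(is.na(ebgm(z)$eb05))
  expect_false(is.na(ebgm(z, zero_policy = "haldane")$eb05))
})

test_that("algebraic invariants hold on a randomized table grid", {
  set.seed(7)
  a <- sample(1:60, 300, TRUE); b <- sample(1:60, 300, TRUE)
  c <- sample(1:60, 300, TRUE); d <- sample(1:60, 300, TRUE)
  tabs <- list(a = a, b = b, c = c, d = d)
  swapped <- list(a = c, b = d, c = a, d = b)
  expect_equal(ror(tabs)$ror, 1 / ror(swapped)$ror, tolerance = 1e-12)
  # IC is exactly log2 of the simplified EBGM
  expect_equal(bcpnn_ic(tabs)$ic, log2(ebgm(tabs)$ebgm), tolerance = 1e-12)
  # CI bounds bracket the estimate
  r <- ror(tabs)
  expect_true(all(r$ror_lo <= r$ror & r$ror <= r$ror_hi))
})

test_that("statistics are strictly increasing in a (b, c, d fixed)", {
  # in the sparse-reporting regime (a well below the margins); the
  # observed/expected ratio is provably non-monotone once a rivals b and c
  a <- 1:50
  t <- list(a = a, b = 400, c = 250, d = 90000)
  for (v in list(ror(t)$ror, prr(t)$prr, bcpnn_ic(t)$ic, ebgm(t)$ebgm)) {
    expect_true(all(diff(v) > 0))
  }
})

test_that("MGPS backend shrinks small counts and tracks large ones", {
  set.seed(21)
  n <- 400
  E <- stats::runif(n, 0.5, 30)
  lam <- c(rep(1, n - 20), rep(5, 20))
  a <- stats::rpois(n, lam * E)
  keep <- a > 0
  fit <- ebgm_mgps(a[keep], E[keep])
  lam_true <- lam[keep]
  # null rows shrink to ~1 and rarely clear the EB05 > 2 cutoff
  nulls <- lam_true == 1
  expect_lt(mean(abs(log(fit$ebgm[nulls]))), 0.5)
  expect_lt(mean(fit$eb05[nulls] > 2), 0.05)
  # elevated, well-measured rows are recovered near their true lambda
  hot <- lam_true == 5 & E[keep] > 5
  expect_equal(mean(fit$ebgm[hot]), 5, tolerance = 0.3)
  # a huge, well-measured signal is barely shrunk
  big <- ebgm_mgps(c(a[keep], 500), c(E[keep], 100))
  expect_equal(big$ebgm[length(big$ebgm)], 5, tolerance = 0.15)
})

test_that("evaluate_signals screens, flags, ranks", {
  tab <- data.table::data.table(
    term = c("low-count", "strong", "null"),
    a = c(2L, 30L, 20L), b = c(10L, 70L, 980L),
    c = c(50L, 70L, 200L), d = c(5000L, 4900L, 9800L))
  res <- evaluate_signals(tab, signal_thresholds(), drug = "x")
  expect_false("low-count" %in% res$term)  # a < 3 screened out
  strong <- res[res$term == "strong", ]
  expect_true(strong$flag_ror & strong$flag_prr & strong$flag_bcpnn &
                strong$flag_ebgm)
  expect_identical(strong$n_positive, 4L)
  expect_identical(res$term[1], "strong")  # descending ROR
  nul <- res[res$term == "null", ]
  expect_identical(nul$n_positive, 0L)

  # rules can be disabled individually
  th <- signal_thresholds(use = c(ror = FALSE, prr = TRUE, bcpnn = TRUE,
                                  ebgm = TRUE))
  res2 <- evaluate_signals(tab, th)
  expect_false(any(res2$flag_ror))
})
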