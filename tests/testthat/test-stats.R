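test_that("percent change follows the baseline-normalized definition", {
  expect_equal(percent_change(2.0, 1.0), -50)
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_true(is.na(percent_change(0, 1)))
  expect_true(is.na(percent_change(NA, 1)))
  expect_equal(percent_change(c(2, 4), c(3, 2)), c(50, -50))
})

test_that("mismatch ratios divide metabolism by perfusion with NA rules", {
  m <- list(mrfdg = 0.1, suvmax = 4, k1 = 0.08, peak_pe = 1.25,
            peak_ser = 1.25)
  r <- mismatch_ratios(m)
  expect_equal(r$mrfdg_peak_ser, 0.08)
  expect_equal(r$mrfdg_peak_pe, 0.08)
  expect_equal(r$mrfdg_k1, 1.25)
  expect_equal(r$suvmax_peak_pe, 3.2)
  r0 <- mismatch_ratios(list(mrfdg = 0, suvmax = 4, k1 = 0.08,
                             peak_pe = 1.25, peak_ser = 1.25))
  expect_equal(r0$mrfdg_peak_pe, 0)
  expect_equal(r0$mrfdg_k1, 0)
  rna <- mismatch_ratios(list(mrfdg = 0.1, suvmax = 4, k1 = 0.08,
                              peak_pe = NA, peak_ser = 1.25))
  expect_true(is.na(rna$mrfdg_peak_pe))
  expect_equal(rna$mrfdg_peak_ser, 0.08)
})

test_that("Spearman correlation works on ranks with t-approximate p", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(spearman_assoc(x, x^3)$estimate, 1)   # rank invariance
  expect_equal(spearman_assoc(x, -x)$estimate, -1)
  # 10-pair fixture with a tie: brute-force average-rank oracle
  y <- c(2, 1, 4, 4, 5, 7, 6, 8, 10, 9)
  res <- spearman_assoc(x, y)
  r_oracle <- stats::cor(rank(x), rank(y))
  t_oracle <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), 8)
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  expect_equal(res$p_raw, p_oracle, tolerance = 1e-9)
  # constant input is flagged, not raised
  flag <- spearman_assoc(rep(1, 5), 1:5)
  expect_true(is.na(flag$estimate))
  expect_match(flag$note, "constant")
  expect_true(is.na(spearman_assoc(1:2, 2:1)$p_raw))  # < 3 pairs
})

test_that("Wilcoxon rank-sum: exact small-sample and approximate p", {
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2))$p_raw, 1)
  # fully separated groups of 3: 2 of the 20 assignments are as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_raw, 0.1)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p_raw, 0.1)
  # exact and normal-approximate p agree reasonably for n >= 15
  set.seed(42)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(9, 0.3)
    pe <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    pa <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_true(is.na(wilcoxon_rank_sum(numeric(0), 1:3)$p_raw))
})

test_that("BH adjustment is the step-up procedure, idempotent and capped", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))    # monotone in rank
  # hand step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j
  o <- order(p); m <- length(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(adj[o], pmin(q, 1))
  # thresholding adjusted values reproduces the step-up rejection set
  for (alpha in c(0.01, 0.05, 0.1)) {
    k <- which(p[o] <= alpha * seq_len(m) / m)
    rej_stepup <- if (length(k)) o[seq_len(max(k))] else integer(0)
    expect_setequal(which(adj <= alpha), rej_stepup)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Cox HR per 5% change is the rescaled per-1% fit", {
  set.seed(9)
  n <- 80
  x <- rnorm(n, 0, 20)
  t_ev <- rexp(n, 0.1 * exp(0.01 * x))
  cens <- runif(n, 1, 12)
  ti <- pmin(t_ev, cens); ev <- as.integer(t_ev <= cens)
  f5 <- cox_univariate(x, ti, ev, unit = 5)
  f1 <- cox_univariate(x, ti, ev, unit = 1)
  expect_equal(log(f5$estimate), 5 * log(f1$estimate), tolerance = 1e-8)
  expect_equal(f5$p_raw, f1$p_raw, tolerance = 1e-8)
  expect_true(f5$estimate > 0)
  expect_true(f5$ci_lo < f5$estimate && f5$estimate < f5$ci_hi)
})

test_that("Cox estimates concentrate on the planted log-hazard as n grows", {
  planted <- 0.01   # per 1% change
  med_hr <- function(n, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      x <- rnorm(n, 0, 20)
      t_ev <- rexp(n, 0.08 * exp(planted * x))
      cens <- runif(n, 1, 12)
      cox_univariate(x, pmin(t_ev, cens), as.integer(t_ev <= cens),
                     unit = 1)$estimate
    }, numeric(1))
  }
  e100 <- median(med_hr(100, 1:30))
  e1000 <- median(med_hr(1000, 1:30))
  expect_lt(abs(log(e1000) - planted), abs(log(e100) - planted) + 5e-4)
  expect_equal(log(e1000), planted, tolerance = 0.15)
})

test_that("Cox degenerate inputs are flagged, not raised", {
  expect_match(cox_univariate(1:5, rep(1, 5), rep(0, 5))$note, "no events")
  expect_match(cox_univariate(rep(2, 5), 1:5, rep(1, 5))$note, "constant")
  # perfect separation: monotone likelihood flagged
  x <- 1:12
  res <- cox_univariate(x, rev(x) + 0.01, rep(1, 12), unit = 1)
  expect_match(res$note, "monotone")
})

test_that("Q3 Kaplan-Meier split matches hand-computed curves and log-rank", {
  chg <- c(-80, -70, -60, -50, -40, -30, -20, -10)
  expect_equal(unname(stats::quantile(chg, 0.75, type = 7)), -27.5)
  ti <- c(5, 6, 7, 8, 4.5, 5.5, 1, 2)
  ev <- c(1, 0, 1, 0, 1, 0, 1, 1)
  res <- km_logrank_q3(chg, ti, ev)
  expect_equal(res$q3, -27.5)
  expect_equal(as.integer(table(res$group)), c(6L, 2L))
  # hand product-limit for the larger-decrease arm:
  # events at 4.5 (6 at risk), 5 (5 at risk), 7 (2 at risk)
  sf <- res$survfit
  s1 <- summary(sf[1])
  expect_equal(s1$surv, c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 1 / 2))
  # independent log-rank oracle: hypergeometric O-E and variance
  g <- as.integer(res$group == "larger_decrease")
  evt <- sort(unique(ti[ev == 1]))
  O <- Exp <- V <- 0
  for (tt in evt) {
    at <- ti >= tt
    d <- sum(ev == 1 & ti == tt)
    n1 <- sum(at & g == 1); ntot <- sum(at)
    d1 <- sum(ev == 1 & ti == tt & g == 1)
    O <- O + d1
    Exp <- Exp + d * n1 / ntot
    if (ntot > 1)
      V <- V + d * (n1 / ntot) * (1 - n1 / ntot) * (ntot - d) / (ntot - 1)
  }
  expect_equal(res$result$statistic, (O - Exp)^2 / V, tolerance = 1e-9)
  expect_equal(res$result$p_raw,
               stats::pchisq((O - Exp)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  chg <- rnorm(20, -30, 15)
  ti <- rexp(20, 0.3)
  res <- km_logrank_q3(chg, ti, rep(1, 20))
  for (arm in 1:2) {
    s <- summary(res$survfit[arm])
    grp <- levels(res$group)[arm]
    tg <- ti[res$group == grp]
    emp <- vapply(s$time, function(tt) mean(tg > tt), numeric(1))
    expect_equal(s$surv, emp, tolerance = 1e-12)
  }
})

test_that("KM degenerate splits and event-free cohorts are flagged", {
  expect_match(km_logrank_q3(rep(-10, 8), 1:8, rep(1, 8))$result$note,
               "degenerate")
  r <- km_logrank_q3(c(-40, -30, -20, -10, -5, -1), 1:6, rep(0, 6))
  expect_match(r$result$note, "no events")
  expect_null(r$survfit)
})
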