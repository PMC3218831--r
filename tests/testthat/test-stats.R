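test_that("wilson interval matches an independently coded formula", {
  # direct formula, written separately from the implementation
  wilson_oracle <- function(x, n, conf = 0.95) {
    z <- qnorm((1 + conf) / 2)
    phat <- x / n
    c((phat + z^2 / (2 * n) - z * sqrt(phat * (1 - phat) / n +
                                         z^2 / (4 * n^2))) / (1 + z^2 / n),
      (phat + z^2 / (2 * n) + z * sqrt(phat * (1 - phat) / n +
                                         z^2 / (4 * n^2))) / (1 + z^2 / n))
  }
  w <- wilson_interval(30, 100)
  expect_equal(unname(w[1, ]), wilson_oracle(30, 100), tolerance = 1e-12)
  for (case in list(c(5, 10), c(0, 10), c(10, 10), c(1, 1000))) {
    w <- wilson_interval(case[1], case[2], conf = 0.99)
    expect_equal(unname(w[1, ]), wilson_oracle(case[1], case[2], 0.99),
                 tolerance = 1e-12)
  }
  # symmetry about 0.5 and exact bound behavior
  w5 <- wilson_interval(5, 10)
  expect_equal(unname(w5[1, "lo"] + w5[1, "hi"]), 1, tolerance = 1e-12)
  expect_equal(unname(wilson_interval(0, 10)[1, "lo"]), 0)
  expect_equal(unname(wilson_interval(0, 0)[1, ]), c(0, 1))
})

test_that("binomial change test equals exhaustive pmf enumeration", {
  # independent oracle: explicit enumeration of the two-tailed rejection
  # region from first principles
  enum_oracle <- function(g1, g2, q2) {
    g <- g1 + g2
    if (g == 0) return(1)
    pk <- vapply(0:g, function(k)
      exp(lchoose(g, k) + k * log(q2) + (g - k) * log1p(-q2)), 1)
    sum(pk[pk <= pk[g2 + 1] * (1 + 1e-7)])
  }
  for (q2 in c(0.25, 0.5, 0.8)) {
    for (g in c(0, 1, 7, 15)) {
      for (g2 in 0:g) {
        expect_equal(binomial_change_test(g - g2, g2, 1 - q2, q2),
                     enum_oracle(g - g2, g2, q2), tolerance = 1e-12)
      }
    }
  }
  # fixed cases forced by symmetry
  expect_equal(binomial_change_test(0, 0, 50, 50), 1)
  expect_equal(binomial_change_test(10, 0, 50, 50), 2 * (1 / 2)^10)
  expect_equal(binomial_change_test(5, 5, 50, 50), 1)
})

test_that("event test picks fisher vs chi-squared by expected values", {
  # balanced table: chi-squared branch, statistic 0 after capped correction
  r <- event_test(10, 10, 10, 10)
  expect_equal(r$method, "chisq")
  expect_equal(r$p, 1)
  # small table: fisher, exact value from hypergeometric enumeration
  r2 <- event_test(1, 5, 5, 1)
  expect_equal(r2$method, "fisher")
  expect_equal(r2$p, 74 / 924, tolerance = 1e-12)
  # branch rule on a larger table
  expect_equal(event_test(20, 30, 40, 10)$method, "chisq")
  expect_equal(event_test(0, 0, 0, 0)$p, 1)

  # randomized sweep: branch matches direct expected-value computation and
  # p matches R's own tests
  set.seed(5)
  for (i in 1:200) {
    t <- as.vector(stats::rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    e <- outer(c(t[1] + t[2], t[3] + t[4]),
               c(t[1] + t[3], t[2] + t[4])) / sum(t)
    r <- event_test(t[1], t[2], t[3], t[4])
    expect_equal(r$method, if (all(e > 5)) "chisq" else "fisher")
    m <- matrix(t, 2, byrow = TRUE)
    oracle <- if (all(e > 5)) stats::chisq.test(m)$p.value else
      stats::fisher.test(m)$p.value
    expect_equal(r$p, oracle, tolerance = 1e-9)
  }
})

test_that("fisher branch is conservative on null tables", {
  set.seed(29)
  n <- 4000
  hits <- 0; used <- 0
  for (i in 1:n) {
    r1 <- 1 + stats::rbinom(1, 25, 0.5); r2 <- 1 + stats::rbinom(1, 25, 0.5)
    p0 <- runif(1, 0.2, 0.8)
    a1 <- stats::rbinom(1, r1, p0); a2 <- stats::rbinom(1, r2, p0)
    r <- event_test(a1, r1 - a1, a2, r2 - a2)
    if (r$method == "fisher") {
      used <- used + 1
      hits <- hits + (r$p <= 0.05)
    }
  }
  mc_se <- sqrt(0.05 * 0.95 / used)
  expect_lte(hits / used, 0.05 + 3 * mc_se)
})

test_that("minimize_significant_changes finds the consensus window", {
  # all genes identical and balanced: symmetric tie resolves to 0.5
  r <- minimize_significant_changes(rep(50, 100), rep(50, 100))
  expect_equal(r$q2, 0.5, tolerance = 1e-9)
  expect_equal(r$n1 + r$n2, r$N)
  expect_equal(r$N, 100 * 100)

  # single gene: the estimate lies inside its own interval, at the mode
  r1 <- minimize_significant_changes(30, 70)
  ci <- wilson_interval(70, 100)
  expect_gte(r1$q2, ci[1, "lo"]); expect_lte(r1$q2, ci[1, "hi"])
  expect_equal(r1$q2, mean(ci[1, ]), tolerance = 1e-4 + 1e-9)

  expect_error(minimize_significant_changes(0, 0), "at least one read")
})

test_that("msc recovers a known depth ratio from unchanged-dominated counts", {
  set.seed(37)
  lam <- stats::rlnorm(2000, log(200), 1.5)
  for (q2 in c(0.3, 0.7)) {
    g1 <- stats::rpois(2000, lam * (1 - q2))
    g2 <- stats::rpois(2000, lam * q2)
    ch <- sample(2000, 100)
    g2[ch] <- stats::rpois(100, lam[ch] * q2 *
                             sample(c(8, 1 / 8), 100, replace = TRUE))
    r <- minimize_significant_changes(g1, g2)
    expect_lt(abs(r$q2 - q2), 0.005)
  }
})

test_that("bh adjustment is monotone and matches step-up arithmetic", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_lte(max(adj), 1)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance calls combine p and fold cutoffs", {
  expect_equal(call_changes(1e-5, 25, 1e-4, 20), "up")
  expect_equal(call_changes(1e-5, 1.5, 1e-4, 20), "unchanged")
  expect_equal(call_changes(0.5, 100, 1e-4, 20), "unchanged")
  expect_equal(call_changes(1e-5, 1 / 25, 1e-4, 20), "down")
  expect_equal(call_changes(c(1e-6, 1e-6), c(Inf, 0), 1e-4, 2),
               c("up", "down"))
})

test_that("expected false positives is the global-null bound", {
  expect_equal(expected_false_positives(27389, 1e-4), 2.7389)
  expect_lte(expected_false_positives(27389, 1e-4), 3)
  expect_equal(expected_false_positives(100, 0.05), 5)
  expect_equal(expected_false_positives(1, 1), 1)
})

test_that("fold changes carry explicit infinity markers", {
  expect_equal(fold_change(10, 20, 100, 100), 2)
  expect_equal(fold_change(0, 5, 100, 100), Inf)
  expect_equal(fold_change(5, 0, 100, 100), 0)
  expect_true(is.na(fold_change(0, 0, 100, 100)))
})

test_that("correlation matrix works on log-RPKM profiles", {
  m <- cbind(a = c(1, 10, 100), b = c(1, 10, 100), c = c(100, 10, 1))
  r <- correlation_matrix(m)
  expect_equal(r$r["a", "b"], 1)
  expect_lt(r$r["a", "c"], 0)
  # direct formula oracle on the anti-monotone pair
  la <- log2(m[, "a"] + 1); lc <- log2(m[, "c"] + 1)
  oracle <- sum((la - mean(la)) * (lc - mean(lc))) /
    sqrt(sum((la - mean(la))^2) * sum((lc - mean(lc))^2))
  expect_equal(r$r["a", "c"], oracle, tolerance = 1e-12)
  expect_length(r$order, 3)
  # zero-variance sample reported missing
  m2 <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_true(all(is.na(correlation_matrix(m2)$r["b", ])))
})

test_that("background sets match counts greedily without replacement", {
  expect_equal(unname(background_set(c(B = 99, C = 1000), c(A = 100))), "B")
  # equal-distance tie goes to the lexicographically smaller id
  expect_equal(unname(background_set(c(D = 100, B = 100), c(A = 100))), "B")
  expect_error(background_set(c(B = 1), c(A = 1, C = 2)), "pool")
  # without replacement: two targets use two distinct candidates
  out <- background_set(c(X = 10, Y = 11, Z = 500), c(A = 10, B = 11))
  expect_length(unique(out), 2)
})

test_that("probe summarization keeps all-positive probes and medians them", {
  m <- rbind(p1 = c(1, 2), p2 = c(-1, 5), p3 = c(3, 4))
  colnames(m) <- c("a1", "a2")
  g <- summarize_probes(m, c(p1 = "g1", p2 = "g1", p3 = "g1"))
  expect_equal(unname(g["g1", ]), c(2, 3))
  # all probes negative somewhere -> gene missing
  g2 <- summarize_probes(rbind(p1 = c(-1, 2), p2 = c(1, -2)),
                         c(p1 = "g1", p2 = "g1"))
  expect_true(all(is.na(g2["g1", ])))
  # single detected probe passes through
  g3 <- summarize_probes(rbind(p1 = c(7, 9)), c(p1 = "g1"))
  expect_equal(unname(g3["g1", ]), c(7, 9))
})

test_that("welch t-test matches an independently coded formula", {
  expect_equal(two_sample_t(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_lt(two_sample_t(c(0, 0.01, -0.01), c(10, 10.01, 9.99)), 1e-6)
  x <- c(1.2, 2.3, 0.8, 1.9); y <- c(2.8, 3.1, 2.2)
  tstat <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  df <- (var(x) / length(x) + var(y) / length(y))^2 /
    ((var(x) / length(x))^2 / (length(x) - 1) +
       (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(two_sample_t(x, y), 2 * pt(-abs(tstat), df),
               tolerance = 1e-12)
})

test_that("gene_test assembles counts, folds, p-values and calls", {
  set.seed(7)
  g1 <- c(gA = 100L, gB = 40L, gC = 0L, gD = 500L)
  g2 <- c(gA = 105L, gB = 400L, gC = 12L, gD = 480L)
  tt <- gene_test(g1, g2, p_cutoff = 1e-4, fold_cutoff = 2)
  expect_s3_class(tt, "gene_test_table")
  expect_equal(tt$gene_id, names(g1))
  norm <- attr(tt, "norm")
  expect_equal(norm$n1 + norm$n2, norm$N)
  expect_equal(tt$call[tt$gene_id == "gB"], "up")
  expect_equal(tt$fold_change[tt$gene_id == "gC"], Inf)
  expect_true(all(tt$p >= 0 & tt$p <= 1))
})
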