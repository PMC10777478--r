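test_that("contingency tables match a brute-force row scan", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                TRUE, FALSE, TRUE, FALSE), ncol = 2,
              dimnames = list(NULL, c("i", "j")))
  t1 <- contingency_table(pm_from_matrix(m), "i", "j")
  expect_equal(unlist(t1), c(a = 1, b = 1, c = 1, d = 1, n = 4))

  # identical columns: perfect co-occurrence
  m2 <- cbind(i = c(TRUE, TRUE, TRUE, FALSE, FALSE),
              j = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  t2 <- contingency_table(pm_from_matrix(m2), "i", "j")
  expect_equal(unlist(t2), c(a = 3, b = 0, c = 0, d = 2, n = 5))

  set.seed(5)
  m3 <- random_presence(20, 2, p = 0.4)
  colnames(m3) <- c("i", "j")
  t3 <- contingency_table(pm_from_matrix(m3), "i", "j")
  expect_equal(t3$a, sum(m3[, 1] & m3[, 2]))
  expect_equal(t3$b, sum(m3[, 1] & !m3[, 2]))
  expect_equal(t3$c, sum(!m3[, 1] & m3[, 2]))
  expect_equal(t3$d, sum(!m3[, 1] & !m3[, 2]))
  expect_error(contingency_table(pm_from_matrix(m3), "i", "nope"),
               "unknown ingredient")
})

test_that("sample odds ratio follows the closed form with zero-cell conventions", {
  expect_equal(odds_ratio_sample(10, 10, 10, 10), 1)
  expect_equal(odds_ratio_sample(20, 5, 5, 20), 16)
  expect_equal(odds_ratio_sample(5, 0, 3, 12), Inf)
  expect_true(is.na(odds_ratio_sample(0, 0, 3, 0)))
  # symmetry: OR(a,b,c,d) = OR(d,c,b,a) and invariance under i/j swap
  set.seed(9)
  for (rep in 1:50) {
    t <- stats::rmultinom(1, 40, c(0.3, 0.2, 0.2, 0.3))
    expect_equal(odds_ratio_sample(t[1], t[2], t[3], t[4]),
                 odds_ratio_sample(t[4], t[3], t[2], t[1]))
    expect_equal(odds_ratio_sample(t[1], t[2], t[3], t[4]),
                 odds_ratio_sample(t[1], t[3], t[2], t[4]))
  }
})

test_that("conditional MLE handles symmetric and boundary tables", {
  expect_equal(odds_ratio_cmle(10, 10, 10, 10), 1, tolerance = 1e-8)
  # a at its conditional maximum given margins
  expect_equal(odds_ratio_cmle(5, 0, 3, 12), Inf)
  expect_equal(odds_ratio_cmle(3, 2, 0, 5), Inf)  # hi = min(k1,k2) = 3
  expect_equal(odds_ratio_cmle(0, 5, 3, 12), 0)
  # degenerate margins: single-point support
  expect_true(is.na(odds_ratio_cmle(0, 0, 3, 12)))
  expect_true(is.na(odds_ratio_cmle(5, 0, 0, 0)))
  # the CMLE of the 20/5/5/20 table differs from the sample OR of 16
  psi <- odds_ratio_cmle(20, 5, 5, 20)
  expect_lt(abs(psi - oracle_cmle(20, 5, 5, 20)), 1e-4 * psi)
  expect_false(isTRUE(all.equal(psi, 16)))
})

test_that("CMLE is nondecreasing in a with margins fixed", {
  n <- 30; k1 <- 14; k2 <- 11
  lo <- max(0, k1 + k2 - n); hi <- min(k1, k2)
  vals <- vapply((lo + 1):(hi - 1), function(a) {
    odds_ratio_cmle(a, k1 - a, k2 - a, n - k1 - k2 + a)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("CMLE agrees with fisher.test's conditional estimate", {
  set.seed(31)
  for (rep in 1:25) {
    t <- stats::rmultinom(1, sample(15:60, 1), c(0.35, 0.2, 0.2, 0.25))
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    lo <- max(0, (a + b) + (a + c) - sum(t)); hi <- min(a + b, a + c)
    if (a <= lo || a >= hi) next
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2))
    # fisher.test optimizes to a looser internal tolerance, so the two
    # independent routes agree to ~1e-3 relative
    expect_equal(odds_ratio_cmle(a, b, c, d),
                 unname(ft$estimate), tolerance = 1e-3)
  }
})

test_that("exact-test p-values match fisher.test", {
  set.seed(17)
  for (rep in 1:20) {
    t <- stats::rmultinom(1, sample(10:50, 1), c(0.3, 0.2, 0.2, 0.3))
    pm <- pm_from_matrix(table_to_matrix(t[1], t[2], t[3], t[4]))
    got <- find_significant_pairs(pm, estimator = "sample")
    ft <- stats::fisher.test(matrix(c(t[1], t[3], t[2], t[4]), 2))
    expect_equal(got$p_value, unname(ft$p.value), tolerance = 1e-9)
  }
})

test_that("significance threshold is the larger of the two criteria", {
  expect_equal(significance_threshold_count(200), 10)
  expect_equal(significance_threshold_count(1000), 30)
  expect_equal(significance_threshold_count(33179), 996)
  expect_equal(significance_threshold_count(0), 10)
  rule <- significance_rule(min_fraction = 0.1, min_count = 3)
  expect_equal(significance_threshold_count(25, rule), 3)
})

test_that("a planted pair passes the compound rule with hand-computed cells", {
  # 50 products: X and Y together in 20, X alone 2, Y alone 2
  m <- matrix(FALSE, 50, 2, dimnames = list(NULL, c("X", "Y")))
  m[1:20, ] <- TRUE
  m[21:22, "X"] <- TRUE
  m[23:24, "Y"] <- TRUE
  pairs <- find_significant_pairs(pm_from_matrix(m), estimator = "sample")
  expect_equal(pairs$a, 20)
  expect_equal(pairs$co_fraction, 0.4)
  expect_equal(pairs$odds_ratio, 20 * 26 / (2 * 2))
  expect_true(pairs$significant)  # threshold max(2, 10) = 10 <= 20

  # identical columns of sufficient sum: infinite OR is significant
  m2 <- matrix(FALSE, 40, 2, dimnames = list(NULL, c("X", "Y")))
  m2[1:15, ] <- TRUE
  p2 <- find_significant_pairs(pm_from_matrix(m2))
  expect_equal(p2$odds_ratio, Inf)
  expect_true(p2$significant)
})

test_that("all unordered pairs are enumerated and sorted by odds ratio", {
  set.seed(41)
  m <- random_presence(30, 8, p = 0.4)
  pairs <- find_significant_pairs(pm_from_matrix(m), estimator = "sample")
  expect_equal(nrow(pairs), choose(8, 2))
  expect_true(all(pairs$ingredient_i < pairs$ingredient_j))
  finite_or <- pairs$odds_ratio[is.finite(pairs$odds_ratio)]
  expect_true(!is.unsorted(rev(finite_or), na.rm = TRUE))
  expect_equal(pairs$a + pairs$b + pairs$c + pairs$d, pairs$n)
})

test_that("tightening any rule parameter never adds a significant pair", {
  set.seed(43)
  m <- random_presence(60, 10, p = 0.35)
  m[, 2] <- m[, 1]  # plant one strong pair
  pm <- pm_from_matrix(m)
  base <- find_significant_pairs(
    pm, significance_rule(0.03, 5, 2), estimator = "sample"
  )
  base_set <- paste(base$ingredient_i, base$ingredient_j)[base$significant]
  stricter <- list(
    significance_rule(0.2, 5, 2),
    significance_rule(0.03, 12, 2),
    significance_rule(0.03, 5, 10)
  )
  for (rule in stricter) {
    got <- find_significant_pairs(pm, rule, estimator = "sample")
    got_set <- paste(got$ingredient_i, got$ingredient_j)[got$significant]
    expect_true(all(got_set %in% base_set))
  }
})
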