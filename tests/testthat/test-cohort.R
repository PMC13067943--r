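test_that("DLL3 fraction stratification uses the 25/75 cutoffs with >= at the boundary", {
  s <- stratify_patient(c(33, 20, 25, 76, 8, NA))
  expect_equal(as.character(s$stratum),
               c("Pos", "Low", "Pos", "Pos", "Low", NA))
  expect_equal(s$high, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_error(stratify_patient(120), "\\[0, 100\\]")

  # monotone in cutoff: raising it never moves a patient Low -> Pos
  set.seed(5)
  fr <- runif(50, 0, 100)
  for (cut in c(10, 25, 50, 80)) {
    lo <- stratify_patient(fr, cutoff = cut)$stratum == "Low"
    hi <- stratify_patient(fr, cutoff = cut + 10)$stratum == "Low"
    expect_true(all(hi[lo]))  # once Low, stays Low at a higher cutoff
  }
})

test_that("the contingency table counts benefit by stratum and excludes missing responses", {
  summ <- data.frame(
    patient_id = sprintf("P%02d", 1:20),
    stratum = factor(rep(c("Pos", "Low"), c(11, 9)), levels = c("Low", "Pos")),
    response = factor(c(rep("PR", 6), rep("SD", 5),
                        "PR", "SD", rep("PD", 7)),
                      levels = c("PR", "SD", "PD")))
  summ$benefit <- summ$response %in% c("PR", "SD")
  tab <- build_contingency(summ)
  expect_equal(c(tab$TP, tab$FN, tab$FP, tab$TN), c(11, 2, 0, 7))

  # empty input -> all-zero table
  tab0 <- build_contingency(summ[0, ])
  expect_equal(c(tab0$TP, tab0$FN, tab0$FP, tab0$TN), c(0, 0, 0, 0))

  # all Pos/PR
  allpr <- summ; allpr$stratum[] <- "Pos"; allpr$response[] <- "PR"
  allpr$benefit <- TRUE
  tab1 <- build_contingency(allpr)
  expect_equal(c(tab1$TP, tab1$FN, tab1$FP, tab1$TN), c(20, 0, 0, 0))

  summ$response[3] <- NA
  expect_warning(tab2 <- build_contingency(summ), "excluded")
  expect_equal(tab2$TP + tab2$FN + tab2$FP + tab2$TN, 19)
})

test_that("exact binomial intervals match the closed form and a tail-root oracle", {
  # interior case
  ci <- clopper_pearson(11, 13)
  want <- oracle_cp_bounds(11, 13)
  expect_equal(ci$lower, unname(want["lower"]), tolerance = 1e-8)
  expect_equal(ci$upper, unname(want["upper"]), tolerance = 1e-8)
  expect_false(ci$one_sided)
  # agreement with stats::binom.test as an independent implementation
  bt <- binom.test(11, 13)$conf.int
  expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-8)

  # x = n: one-sided lower bound (alpha/2)^(1/n)
  ci1 <- clopper_pearson(7, 7)
  expect_true(ci1$one_sided)
  expect_equal(ci1$lower, 0.025^(1 / 7))
  expect_equal(ci1$upper, 1)
  # x = 0 of 5: one-sided upper 1 - 0.025^(1/5), checked against the oracle
  ci0 <- clopper_pearson(0, 5)
  expect_equal(ci0$upper, 1 - 0.025^(1 / 5))
  expect_equal(ci0$upper, unname(oracle_cp_bounds(0, 5)["upper"]),
               tolerance = 1e-8)
})

test_that("predictive metrics report undefined (not zero) on empty denominators", {
  tab <- structure(list(TP = 0L, FN = 0L, FP = 3L, TN = 4L, n_excluded = 0L),
                   class = "contingency_table")
  m <- predictive_metrics(tab)
  expect_true(is.na(m$sensitivity$estimate_pct))  # TP + FN = 0
  expect_equal(m$specificity$estimate_pct, 100 * 4 / 7)
  expect_equal(m$ppv$estimate_pct, 0)
  expect_true(m$ppv$one_sided)
})

test_that("pooled group totals equal the count-weighted mean of patient fractions", {
  set.seed(21)
  n <- 12
  summ <- data.frame(
    response = factor(sample(c("PR", "SD", "PD"), n, replace = TRUE),
                      levels = c("PR", "SD", "PD")),
    ctc_raw = rpois(n, 150))
  summ$ctc_dll3_raw <- rbinom(n, summ$ctc_raw, 0.6)
  gt <- group_marker_totals(summ)
  for (g in c("PR", "SD", "PD")) {
    s <- summ[summ$response == g, ]
    expect_equal(gt$ctc_total[gt$response == g], sum(s$ctc_raw))
    # pooled percent = weighted mean of per-patient fractions
    want <- if (sum(s$ctc_raw) > 0)
      100 * weighted.mean(s$ctc_dll3_raw / pmax(s$ctc_raw, 1), s$ctc_raw)
    else 0
    expect_equal(gt$pct[gt$response == g], want)
  }
  # zero-positive group reports 0 percent
  one <- data.frame(response = factor("PR", levels = c("PR", "SD", "PD")),
                    ctc_raw = 10, ctc_dll3_raw = 0)
  expect_equal(group_marker_totals(one)$pct, 0)
})

test_that("rank statistics match enumeration, Holm hand-computation and handle degeneracy", {
  # exact Wilcoxon on {1,2} vs {3,4}: 1 of 6 assignments as extreme,
  # two-sided p = 2/6
  w <- rank_stats(c(1, 2), c(3, 4), method = "wilcoxon")
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)

  # exact Wilcoxon agrees with full permutation enumeration (combined n <= 10)
  set.seed(9)
  for (rep in 1:5) {
    x <- sample(1:50, 4)
    y <- sample(51:99, 4)[1:3]
    pool <- c(x, y)
    w_obs <- sum(rank(pool)[seq_along(x)])
    combs <- combn(length(pool), length(x))
    w_all <- apply(combs, 2, function(idx) sum(rank(pool)[idx]))
    mu <- length(x) * (length(pool) + 1) / 2
    p_perm <- mean(abs(w_all - mu) >= abs(w_obs - mu))
    expect_equal(rank_stats(x, y, method = "wilcoxon")$p_value, p_perm,
                 tolerance = 1e-12)
  }

  # Holm by the step-down definition
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  p <- runif(6)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  # order-preserving (weakly: max-accumulation can tie adjusted values)
  expect_true(all(diff(adj[order(p)]) >= 0))

  # identical groups: degenerate flag, p = 1; rho of a variable with itself = 1
  d <- rank_stats(rep(2, 5), rep(2, 5), method = "wilcoxon")
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  v <- c(3, 1, 4, 1, 5)
  expect_equal(rank_stats(v, v, method = "spearman")$estimate, 1)

  # Kruskal-Wallis and t-tests run through the same surface
  k <- rank_stats(method = "kruskal", groups = list(1:5, 6:10, 11:15))
  expect_lt(k$p_value, 0.05)
  expect_error(rank_stats(1:4, 1:5, method = "t_paired"), "equal lengths")
})

test_that("H-score is the intensity-weighted percentage sum on 0-300", {
  expect_equal(h_score(c(0, 0, 0, 100))$score, 300)
  expect_equal(h_score(c(100, 0, 0, 0))$score, 0)
  expect_equal(h_score(c(0, 50, 50, 0))$score, 150)
  expect_error(h_score(c(0, 60, 60, 0)), "sum above 100")
})

test_that("Clopper-Pearson coverage meets the nominal level in simulation", {
  set.seed(123)
  for (n in c(7, 11, 13)) {
    for (p in c(0.5, 0.85, 1.0)) {
      x <- rbinom(10000, n, p)
      lower <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
      lower[x == n] <- 0.025^(1 / n)
      upper <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
      upper[x == 0] <- 1 - 0.025^(1 / n)
      # the vectorized bounds reproduce clopper_pearson() exactly
      for (xi in unique(x)[1:min(3, length(unique(x)))]) {
        ci <- clopper_pearson(xi, n)
        expect_equal(ci$lower, lower[match(xi, x)])
        expect_equal(ci$upper, upper[match(xi, x)])
      }
      expect_gte(mean(lower <= p & p <= upper), 0.95)
    }
  }
})
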