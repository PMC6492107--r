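test_that("deviation metric is the mean squared regional error", {
  x <- rep(0, 104)
  expect_equal(deviation_metric(x, x), 0)
  xhat <- x
  xhat[1] <- -2  # one region with residual 2
  expect_equal(deviation_metric(x, xhat), 4 / 104)
  # homogeneity: scaling residuals by c scales the metric by c^2
  set.seed(1)
  a <- rnorm(104); b <- rnorm(104)
  expect_equal(deviation_metric(a, a + 3 * (b - a)) ,
               9 * deviation_metric(a, b), tolerance = 1e-12)
  expect_error(deviation_metric(a, b[1:10]), "length")
})

test_that("Mann-Whitney U and p match brute-force enumeration (exact branch)", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  set.seed(42)
  for (i in 1:120) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- round(rnorm(na), 2); b <- round(rnorm(nb, sd = 2), 2)
    if (anyDuplicated(c(a, b))) next  # ties route to the approximate branch
    mw <- mann_whitney_u(a, b)
    expect_equal(mw$method, "exact")
    expect_equal(mw$u, sum(outer(a, b, ">")), tolerance = 1e-12)
    expect_equal(mw$p, mw_enumerate(a, b), tolerance = 1e-9)
  }
})

test_that("approximate branch applies tie and continuity corrections", {
  # identical samples: no evidence, p in the no-evidence region
  a <- c(1, 2, 3, 4, 5)
  mw <- mann_whitney_u(a, a)
  expect_equal(mw$method, "normal_approx")
  expect_gte(mw$p, 0.99)
  # agreement with the reference implementation, with and without ties
  set.seed(7)
  for (i in 1:80) {
    na <- sample(c(5, 12, 25), 1); nb <- sample(c(5, 12, 25), 1)
    vals <- if (i %% 2) rnorm(na + nb) else sample(1:6, na + nb, TRUE)
    a <- vals[1:na]; b <- vals[-(1:na)]
    mw <- mann_whitney_u(a, b, exact = FALSE)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mw$u, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
  }
  # approximate and exact p agree closely at moderate sizes
  set.seed(8)
  a <- rnorm(18); b <- rnorm(18) + 0.5
  expect_lt(abs(mann_whitney_u(a, b, exact = FALSE)$p -
                  mann_whitney_u(a, b, exact = TRUE)$p), 0.02)
  expect_error(mann_whitney_u(numeric(0), a), "nonempty")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3), exact = TRUE), "ties")
})

test_that("Cliff's delta matches pair enumeration and its U relation", {
  expect_equal(cliffs_delta(c(3, 4), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 3), c(2, 4)), -0.5)
  expect_equal(cliffs_delta(c(2, 5, 7), c(2, 5, 7)), 0)
  set.seed(9)
  for (i in 1:100) {
    a <- sample(1:8, sample(2:10, 1), TRUE)
    b <- sample(1:8, sample(2:10, 1), TRUE)
    expect_equal(cliffs_delta(a, b), cliff_brute(a, b), tolerance = 1e-12)
  }
  # tie-free relation to the U statistic
  for (i in 1:50) {
    a <- rnorm(7); b <- rnorm(9)
    u <- mann_whitney_u(a, b)$u
    expect_equal(cliffs_delta(a, b), 2 * u / (7 * 9) - 1, tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise dominance probability", {
  expect_equal(auc_from_scores(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_from_scores(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc_from_scores(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(10)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    scores <- sample(1:6, n, TRUE)  # ties included
    expect_equal(auc_from_scores(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
    # tie-free AUC/U identity
    sc <- rnorm(n)
    u <- mann_whitney_u(sc[labels], sc[!labels], exact = FALSE)$u
    expect_equal(auc_from_scores(sc, labels), u / (sum(labels) * sum(!labels)),
                 tolerance = 1e-12)
  }
})

test_that("group comparison reports medians, effect size and refuses mixed datasets", {
  set.seed(11)
  err_a <- matrix(rexp(50 * 10), 50, 10)
  dev_a <- forge_deviations(err_a, "PAT")
  dev_b <- forge_deviations(err_a, "HC")  # identical distributions
  cmp <- compare_groups(dev_a, dev_b)
  expect_equal(cmp$abs_cliffs_delta, 0)
  expect_gt(cmp$p, 0.99)
  expect_equal(cmp$group_a$median, cmp$group_b$median)

  dev_c <- forge_deviations(err_a + 100, "PAT")  # complete separation
  cmp2 <- compare_groups(dev_c, dev_b)
  expect_equal(cmp2$abs_cliffs_delta, 1)
  expect_lt(cmp2$p, 1e-10)
  expect_equal(cmp2$u, 2500)

  dev_other <- forge_deviations(err_a, "HC", dataset = "other_site")
  expect_error(compare_groups(dev_a, dev_other), "same dataset")
})

test_that("regional comparison ranks by effect size and applies the threshold", {
  set.seed(12)
  n <- 40
  err_hc <- matrix(rexp(n * 20), n, 20)
  err_pat <- matrix(rexp(n * 20), n, 20)
  err_pat[, 7] <- err_pat[, 7] + 5  # one region strongly shifted
  dev_pat <- forge_deviations(err_pat, "PAT")
  dev_hc <- forge_deviations(err_hc, "HC")
  reg <- regional_comparison(dev_pat, dev_hc)
  expect_equal(reg$region[1], "region007")
  expect_true(reg$significant[1])
  expect_true(all(diff(reg$abs_cliffs_delta) <= 0))
  expect_equal(reg$significant, reg$p < 0.01)
  # threshold 0 switches every region off
  reg0 <- regional_comparison(dev_pat, dev_hc, threshold = 0)
  expect_false(any(reg0$significant))
})

test_that("row subsets of a deviation result keep regional errors aligned", {
  set.seed(13)
  err <- matrix(rexp(30 * 8), 30, 8)
  dev <- forge_deviations(err, rep(c("HC", "PAT"), 15))
  sub <- dev[dev$group == "PAT", ]
  expect_equal(nrow(sub), 15)
  re <- regional_errors(sub)
  expect_equal(nrow(re), 15)
  expect_identical(rownames(re), sub$subject_id)
  expect_equal(unname(rowMeans(re)), sub$deviation_metric, tolerance = 1e-12)
  # the subset's regional matrix is the matching rows of the original
  expect_equal(re, regional_errors(dev)[dev$group == "PAT", ])
})

test_that("deviation results round-trip through CSV", {
  set.seed(15)
  err <- matrix(rexp(10 * 6), 10, 6)
  dev <- forge_deviations(err, "HC")
  path <- withr_local_file("dev.csv")
  write_deviations(dev, path)
  back <- read_deviations(path)
  expect_equal(back$deviation_metric, dev$deviation_metric, tolerance = 1e-12)
  expect_equal(regional_errors(back), regional_errors(dev), tolerance = 1e-12)
})

test_that("mass-univariate analysis applies the same machinery to raw features", {
  co <- generate_cohort(cohort_spec(n_reference = 2, n_controls = 80,
                                    n_patients = 80, affected_regions = 9,
                                    shift_sizes = 2.5, seed = 14))
  hc <- co$clinical[co$clinical$group == "HC", ]
  pat <- co$clinical[co$clinical$group == "PAT", ]
  mu <- mass_univariate(pat, hc)
  target <- default_schema()$name[9]
  expect_equal(mu$region[1], target)
  expect_true(mu$significant[mu$region == target])
  # a 2.5 SD shift is overwhelming; most other regions stay quiet
  expect_lt(sum(mu$significant), 10)
})
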