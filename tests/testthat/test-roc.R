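test_that("ROC curves contain the operating points of exhaustive enumeration", {
  # perfect separation includes the (1, 1) point
  r <- build_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(r$sensitivities == 1 & r$specificities == 1))

  # all-tied scores yield only the two trivial operating points
  rt <- build_roc(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(length(rt$thresholds), 2L)
  expect_setequal(rt$sensitivities, c(0, 1))

  # mixed example with ties: every point matches the brute-force oracle
  sc <- c(1, 2, 2, 3, 4, 4)
  lab <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  r6 <- build_roc(sc, lab, direction = "higher_is_case")
  for (i in seq_along(r6$thresholds)) {
    op <- oracle_operating_point(sc, lab, r6$thresholds[i])
    expect_equal(r6$sensitivities[i], unname(op["sens"]))
    expect_equal(r6$specificities[i], unname(op["spec"]))
  }
  expect_true(all(diff(r6$sensitivities) <= 0))  # non-increasing in threshold

  expect_error(build_roc(1:4, rep(TRUE, 4)), "case and .* control")
})

test_that("AUC equals the Mann-Whitney pair count, with half-credit ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                       direction = "higher_is_case")$auc, 1)
  # hand count: cases (1, 4) vs controls (2, 3) -> 2 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 4, 2, 3), c(TRUE, TRUE, FALSE, FALSE),
                       direction = "higher_is_case")$auc, 0.5)

  set.seed(51)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    sc <- sample(1:6, n, replace = TRUE)  # heavy ties
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lab, direction = "higher_is_case")$auc,
                 oracle_auc_pairs(sc, lab))
  }
})

test_that("AUC is invariant under monotone transforms and flips with negation", {
  set.seed(52)
  sc <- rnorm(40)
  lab <- rep(c(TRUE, FALSE), 20)
  a <- roc_auc(sc, lab, direction = "higher_is_case")$auc
  expect_equal(roc_auc(exp(2 * sc), lab, direction = "higher_is_case")$auc, a)
  expect_equal(roc_auc(-sc, lab, direction = "higher_is_case")$auc, 1 - a)
})

test_that("direction auto orients the AUC to at least 0.5", {
  set.seed(53)
  lab <- rep(c(TRUE, FALSE), 30)
  sc <- rnorm(60) - lab  # cases LOWER, the AHRR-like situation
  a <- roc_auc(sc, lab)
  expect_identical(a$direction, "lower_is_case")
  expect_gte(a$auc, 0.5)
  expect_true(a$ci95[1] <= a$auc && a$auc <= a$ci95[2])
})

test_that("AUC, DeLong variance/CI and the best threshold match pROC", {
  set.seed(54)
  for (i in 1:5) {
    lab <- rep(c(1, 0), c(25, 35))
    sc <- rnorm(60) + lab * runif(1, 0.3, 1.5)
    r <- pROC::roc(lab, sc, direction = "<", quiet = TRUE)
    a <- roc_auc(sc, lab == 1, direction = "higher_is_case")
    expect_equal(a$auc, as.numeric(pROC::auc(r)))
    expect_equal(a$variance, pROC::var(r))
    ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
    expect_equal(a$ci95, ci[c(1, 3)])
    best <- pROC::coords(r, "best", best.method = "closest.topleft",
                         transpose = FALSE)
    expect_equal(optimal_threshold(build_roc(sc, lab == 1,
                                             direction = "higher_is_case")),
                 best$threshold)
  }
})

test_that("the optimal threshold equals brute-force enumeration", {
  # arithmetic by hand: points (sens, spec) = (1, 0.5) and (0.6, 1) have
  # distances 0.5 and 0.4; the second must win
  expect_equal(min(0.5, sqrt((1 - 0.6)^2)), 0.4)
  set.seed(55)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    sc <- round(rnorm(n), 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- build_roc(sc, lab, direction = "higher_is_case")
    expect_identical(optimal_threshold(r), oracle_best_threshold(sc, lab))
  }
  # perfect separation: the midpoint between the two groups' extremes
  expect_equal(optimal_threshold(build_roc(c(1, 2, 5, 6),
                                           c(FALSE, FALSE, TRUE, TRUE))),
               3.5)
  expect_error(optimal_threshold(build_roc(rep(1, 4),
                                           c(TRUE, TRUE, FALSE, FALSE))),
               "uninformative")
})

test_that("DeLong test is antisymmetric and null on identical scores", {
  set.seed(56)
  lab <- rep(c(TRUE, FALSE), 25)
  sa <- rnorm(50) + lab
  sb <- rnorm(50) + 0.5 * lab
  d <- delong_test(sa, sb, lab)
  dswap <- delong_test(sb, sa, lab)
  expect_equal(dswap$z, -d$z)
  expect_equal(dswap$p, d$p)
  d0 <- delong_test(sa, sa, lab)
  expect_identical(d0$z, 0)
  expect_identical(d0$p, 1)

  # matches pROC's paired DeLong test
  ra <- pROC::roc(lab, sa, direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, sb, direction = "<", quiet = TRUE)
  rt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  dd <- delong_test(sa, sb, lab, direction_a = "higher_is_case",
                    direction_b = "higher_is_case")
  expect_equal(dd$z, as.numeric(rt$statistic))
  expect_equal(dd$p, rt$p.value)

  expect_error(delong_test(setNames(sa, paste0("x", 1:50)),
                           setNames(sb, paste0("y", 1:50)), lab),
               "different sample sets")
})

test_that("DeLong confidence intervals cover the true AUC at about 95%", {
  # binormal model: cases N(mu, 1) vs controls N(0, 1), true AUC phi(mu/sqrt2)
  set.seed(57)
  mu <- 1
  true_auc <- pnorm(mu / sqrt(2))
  lab <- rep(c(TRUE, FALSE), each = 50)
  cover <- vapply(1:1000, function(i) {
    sc <- rnorm(100) + mu * lab
    ci <- roc_auc(sc, lab, direction = "higher_is_case")$ci95
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})
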