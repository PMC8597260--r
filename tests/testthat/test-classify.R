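test_that("binary rules use strict inequality, ties to control", {
  b <- make_beta(c(0.4, 0.6, 0.5), cpgs = "cgA",
                 samples = c("s1", "s2", "s3"))
  rule <- binary_rule(score_model("cgA", 1), 0.5, "higher_is_case")
  lab <- apply_binary(rule, b)
  expect_identical(unname(lab), c("control", "case", "control"))  # tie -> control

  low <- binary_rule(score_model("cgA", 1), 0.5, "lower_is_case")
  lab2 <- apply_binary(low, b)
  expect_identical(unname(lab2), c("case", "control", "control"))
  # non-boundary samples flip between the two orientations
  expect_true(all(lab[1:2] != lab2[1:2]))

  expect_identical(predict(rule, b), lab)
})

test_that("ternary application short-circuits never and partitions all samples", {
  # stage 1 on cgE (higher = ever), stage 2 on cgC (higher = current)
  clf <- ternary_classifier(
    binary_rule(score_model("cgE", 1), 0.5, "higher_is_case", "ever", "never"),
    binary_rule(score_model("cgC", 1), 0.5, "higher_is_case", "current",
                "former"))
  # four samples hitting every stage1 x stage2 cell:
  #   s1 low/low, s2 low/high (stage2 must be ignored), s3 high/low,
  #   s4 high/high
  b <- make_beta(matrix(c(0.2, 0.2, 0.2, 0.9, 0.8, 0.1, 0.8, 0.9), 2),
                 cpgs = c("cgE", "cgC"))
  pred <- apply_ternary(clf, b)
  expect_identical(unname(pred), c("never", "never", "former", "current"))
  expect_identical(sum(table(pred)), 4L)
})

test_that("training fits both thresholds and reapplies self-consistently", {
  cfg <- synthetic_config(n_current = 60, n_former = 60, n_never = 60,
                          n_persistent = 20, n_reverting = 20, n_partial = 10,
                          n_null = 50)
  g <- generate_methylation(cfg, seed = 61)
  m_en <- oracle_score_model(g$truth, "ever_never")
  m_cf <- oracle_score_model(g$truth, "current_former")
  clf <- train_ternary(g$beta, g$sheet, m_en, m_cf)
  expect_s3_class(clf, "ternary_classifier")
  expect_true(is.finite(clf$stage1$threshold))

  # development accuracy beats the NIR on well-separated data
  st <- setNames(as.character(g$sheet$status), g$sheet$sample_id)
  cs <- confusion_summary(apply_ternary(clf, g$beta), st[colnames(g$beta)])
  expect_gt(cs$accuracy, cs$nir)

  # retraining on identical input is bit-exact
  clf2 <- train_ternary(g$beta, g$sheet, m_en, m_cf)
  expect_identical(clf2$stage1$threshold, clf$stage1$threshold)
  expect_identical(clf2$stage2$threshold, clf$stage2$threshold)

  # applying the trained classifier twice reproduces the same matrix
  expect_identical(apply_ternary(clf, g$beta), apply_ternary(clf, g$beta))
})

test_that("training requires all three classes", {
  cfg <- synthetic_config(n_current = 30, n_former = 30, n_never = 30,
                          n_persistent = 5, n_reverting = 5, n_partial = 0,
                          n_null = 10)
  g <- generate_methylation(cfg, seed = 62)
  m_en <- oracle_score_model(g$truth, "ever_never")
  m_cf <- oracle_score_model(g$truth, "current_former")
  sheet <- g$sheet
  sheet$status[sheet$status == "former"] <- "current"
  expect_error(train_ternary(g$beta, sheet, m_en, m_cf), "former")
})

test_that("an all-never cohort is labelled never almost everywhere", {
  cfg_train <- synthetic_config()
  g <- generate_methylation(cfg_train, seed = 63)
  clf <- train_ternary(g$beta, g$sheet,
                       oracle_score_model(g$truth, "ever_never"),
                       oracle_score_model(g$truth, "current_former"))
  # a never-only cohort over the same CpG universe (shared truth table)
  cfg_nev <- synthetic_config(n_current = 0, n_former = 0, n_never = 200)
  gn <- generate_methylation(cfg_nev, seed = 64, truth = g$truth)
  expect_identical(gn$truth$mean_never, g$truth$mean_never)
  pred <- apply_ternary(clf, gn$beta)
  expect_gte(mean(pred == "never"), 0.95)
})

test_that("classifier JSON is self-contained and frozen", {
  cfg <- synthetic_config(n_current = 40, n_former = 40, n_never = 40,
                          n_persistent = 10, n_reverting = 10, n_partial = 5,
                          n_null = 25)
  g <- generate_methylation(cfg, seed = 65)
  clf <- train_ternary(g$beta, g$sheet,
                       oracle_score_model(g$truth, "ever_never"),
                       oracle_score_model(g$truth, "current_former"))
  p <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, p)
  clf2 <- read_classifier(p)
  expect_identical(clf2$stage1$threshold, clf$stage1$threshold)
  expect_identical(clf2$stage2$direction, clf$stage2$direction)
  expect_identical(clf2$stage1$model$weights, clf$stage1$model$weights)
  # applying the deserialised classifier uses stored thresholds only:
  # predictions on fresh data agree exactly with the in-memory classifier
  g2 <- generate_methylation(cfg, seed = 66)
  expect_identical(apply_ternary(clf2, g2$beta), apply_ternary(clf, g2$beta))
})
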