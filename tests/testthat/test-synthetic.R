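test_that("generation is deterministic and strictly inside (0, 1)", {
  cfg <- synthetic_config(n_current = 30, n_former = 30, n_never = 30,
                          n_persistent = 10, n_reverting = 10, n_partial = 10,
                          n_null = 20)
  g1 <- generate_methylation(cfg, seed = 11)
  g2 <- generate_methylation(cfg, seed = 11)
  expect_identical(unclass(g1$beta), unclass(g2$beta))
  expect_identical(g1$truth, g2$truth)
  expect_true(all(g1$beta > 0 & g1$beta < 1))
  expect_identical(dim(g1$beta), c(50L, 90L))
  expect_identical(as.character(g1$sheet$status),
                   rep(c("current", "former", "never"), each = 30))

  g3 <- generate_methylation(cfg, seed = 12)
  expect_false(identical(unclass(g1$beta), unclass(g3$beta)))
})

test_that("class means converge to the configured truth", {
  cfg <- synthetic_config(n_current = 1000, n_former = 1000, n_never = 1000,
                          n_persistent = 8, n_reverting = 8, n_partial = 8,
                          n_null = 8)
  g <- generate_methylation(cfg, seed = 13)
  st <- as.character(g$sheet$status)
  for (cls in c("current", "former", "never")) {
    emp <- rowMeans(unclass(g$beta)[, st == cls])
    expect_lt(max(abs(emp - g$truth[[paste0("mean_", cls)]])), 0.02)
  }
  # behaviour structure: persistent shifts ever smokers jointly, reverting
  # shifts current only, partial puts former in between, null nothing
  tr <- g$truth
  per <- tr$behaviour == "persistent"
  expect_equal(tr$mean_former[per], tr$mean_current[per])
  rev <- tr$behaviour == "reverting"
  expect_equal(tr$mean_former[rev], tr$mean_never[rev])
  par <- tr$behaviour == "partial"
  expect_true(all(tr$mean_former[par] > pmin(tr$mean_never[par],
                                             tr$mean_current[par]) &
                  tr$mean_former[par] < pmax(tr$mean_never[par],
                                             tr$mean_current[par])))
  nul <- tr$behaviour == "null"
  expect_equal(tr$mean_current[nul], tr$mean_never[nul])
})

test_that("oracle scores separate their target classes at default settings", {
  g <- generate_methylation(synthetic_config(), seed = 14)
  st <- setNames(as.character(g$sheet$status), g$sheet$sample_id)
  s_en <- compute_score(g$beta, oracle_score_model(g$truth, "ever_never"))
  expect_gt(roc_auc(s_en, st != "never")$auc, 0.9)
  ever <- which(st != "never")
  be <- beta_matrix(unclass(g$beta)[, ever, drop = FALSE])
  s_cf <- compute_score(be, oracle_score_model(g$truth, "current_former"))
  expect_gt(roc_auc(s_cf, st[ever] == "current")$auc, 0.9)
  # the single-CpG reference has one persistent term with unit-signed weight
  ref <- oracle_score_model(g$truth, "ahrr_like")
  expect_length(ref$cpgs, 1)
  expect_true(abs(ref$weights) == 1)
})

test_that("a zero-effect generator carries no ever/never signal", {
  cfg <- synthetic_config(n_current = 250, n_former = 250, n_never = 500,
                          effect_persistent = 0, effect_reverting = 0,
                          effect_partial = 0)
  g <- generate_methylation(cfg, seed = 15)
  st <- as.character(g$sheet$status)
  # unit-weight score over the would-be persistent CpGs
  per <- g$truth$cpg_id[g$truth$behaviour == "persistent"]
  s <- compute_score(g$beta, score_model(per, rep(1, length(per))))
  a <- roc_auc(s, st != "never", direction = "higher_is_case")$auc
  expect_gt(a, 0.45)
  expect_lt(a, 0.55)
})

test_that("presets are valid and match the study compositions", {
  pr <- synthetic_presets()
  expect_true(all(c("paperlike-dev", "paperlike-val", "weak-former") %in%
                  names(pr)))
  for (p in pr) expect_s3_class(p, "synthetic_config")
  dev <- pr[["paperlike-dev"]]
  expect_identical(dev$n_current + dev$n_former + dev$n_never, 1063)
  expect_identical(c(dev$n_current, dev$n_former, dev$n_never),
                   c(364, 334, 365))
  val <- pr[["paperlike-val"]]
  expect_identical(val$n_current + val$n_former + val$n_never, 717)
  expect_identical(c(val$n_current, val$n_former, val$n_never),
                   c(260, 263, 194))
  expect_gt(pr[["weak-former"]]$former_fraction_partial, 0.8)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(baseline_range = c(0.8, 0.3)),
               "baseline_range")
  expect_error(synthetic_config(former_fraction_partial = 1.5),
               "former_fraction")
  expect_error(synthetic_config(n_current = -1), "counts")
  # shifted means must stay inside (0, 1)
  expect_error(synthetic_config(baseline_range = c(0.05, 0.5),
                                effect_persistent = -0.1),
               "leave \\(0, 1\\)")
})
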