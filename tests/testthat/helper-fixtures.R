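# shared fixtures and independent oracles used across test files

make_beta <- function(values, cpgs = NULL, samples = NULL) {
  if (is.null(cpgs)) cpgs <- sprintf("cg%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  beta_matrix(matrix(values, nrow = length(cpgs),
                     dimnames = list(cpgs, samples)))
}

random_beta <- function(n_cpg, n_samp) {
  make_beta(matrix(runif(n_cpg * n_samp), n_cpg, n_samp))
}

# brute-force ROC oracles: direct probability computation per threshold,
# independent of the package's findInterval-based construction
oracle_operating_point <- function(scores, is_case, thr,
                                   direction = "higher_is_case") {
  if (direction == "higher_is_case")
    c(sens = mean(scores[is_case] > thr), spec = mean(scores[!is_case] <= thr))
  else
    c(sens = mean(scores[is_case] < thr), spec = mean(scores[!is_case] >= thr))
}

oracle_candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
}

oracle_best_threshold <- function(scores, is_case,
                                  direction = "higher_is_case") {
  thr <- oracle_candidate_thresholds(scores)
  d <- vapply(thr, function(t) {
    op <- oracle_operating_point(scores, is_case, t, direction)
    sqrt((1 - op["sens"])^2 + (1 - op["spec"])^2)
  }, numeric(1))
  min(thr[d == min(d)])
}

# Mann-Whitney AUC by exhaustive pair counting
oracle_auc_pairs <- function(scores, is_case) {
  x <- scores[is_case]
  y <- scores[!is_case]
  g <- outer(x, y, `>`) + 0.5 * outer(x, y, `==`)
  mean(g)
}

# development / validation cohort label sets matching a realistic study
dev_status <- rep(c("current", "former", "never"), c(364, 334, 365))
val_status <- rep(c("current", "former", "never"), c(260, 263, 194))
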