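test_that("the default grid has 32 geometric points from 1e-3 to 300 uM", {
  g <- default_grid()
  expect_length(g, 32L)
  expect_identical(g[1], 1e-3)
  expect_identical(g[32], 300)
  ratios <- g[-1] / g[-32]
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-12)
})

test_that("QC pruning drops rising tails recursively and gates on points and floor", {
  g <- default_grid()
  # clean monotone-decreasing series reaching 0.1: everything kept
  v <- ll4_curve(g, 1.5, 0.05, 1, 1)
  qc <- qc_prune(g, v)
  expect_equal(qc$qc_status, "ok")
  expect_length(qc$kept, 32L)
  # minimum viability above 0.4: no curve is fit
  flat <- ll4_curve(g, 1.5, 0.45, 1, 1)
  expect_equal(qc_prune(g, flat)$qc_status, "reject_no_response")
  # fewer than 5 points rejects immediately
  expect_equal(qc_prune(g[1:4], v[1:4])$qc_status, "reject_too_few")
})

test_that("a 17-point series where the rise rule fires twice ends reject_too_few", {
  conc <- 2^(0:16)
  v <- rep(0.3, 17)
  # 5th largest (index 13) is the reference for points 14:17; a 0.2+ rise at
  # the top point triggers a drop, after which the rule fires again
  v[17] <- 0.55   # vs ref v[13] = 0.3 -> rise 0.25, drop index 17
  v[16] <- 0.54   # new top 4 = 13:16, ref v[12] = 0.3 -> drop index 16
  v[1:5] <- c(0.9, 0.85, 0.8, 0.7, 0.6)
  qc <- qc_prune(conc, v)
  expect_equal(length(qc$kept), 15L)
  expect_equal(qc$qc_status, "reject_too_few")
})

test_that("QC pruning is deterministic and idempotent", {
  set.seed(2)
  g <- default_grid()
  v <- ll4_curve(g, 1, 0.05, 1, 0.5) + rnorm(32, sd = 0.08)
  q1 <- qc_prune(g, v)
  q2 <- qc_prune(g[q1$kept], v[q1$kept])
  expect_equal(length(q2$kept), length(q1$kept))
  expect_equal(v[q1$kept][q2$kept], v[q1$kept])
})

test_that("noise-free LL4 data is recovered within 1e-4 relative", {
  g <- default_grid()
  v <- ll4_curve(g, 1.2, 0.05, 1.0, 3.0)
  fit <- fit_curve(g, v)
  expect_equal(fit$family, "LL4")
  expect_equal(fit$b, 1.2, tolerance = 1e-4)
  expect_equal(fit$c, 0.05, tolerance = 1e-4)
  expect_equal(fit$d, 1.0, tolerance = 1e-4)
  expect_equal(fit$e, 3.0, tolerance = 1e-4)
})

test_that("LL4 fit of LL2-generated data recovers c = 0, d = 1", {
  g <- default_grid()
  v <- ll4_curve(g, 1.5, 0, 1, 0.8)
  fit <- fit_curve(g, v)
  expect_equal(fit$c, 0, tolerance = 1e-3)
  expect_equal(fit$d, 1, tolerance = 1e-3)
  expect_equal(fit$e, 0.8, tolerance = 1e-3)
})

test_that("constant viability exhausts the cascade", {
  g <- default_grid()
  expect_equal(fit_curve(g, rep(0.7, 32))$status, "failed")
})

test_that("fits are filtered on EC50 range and undetermined parameters", {
  g <- default_grid()
  ok <- fit_curve(g, ll4_curve(g, 1.2, 0.05, 1, 1))
  out_of_range <- ok; out_of_range$e <- 500
  undet <- ok; undet$vcov[1, 1] <- NaN
  failed <- fit_curve(g, rep(0.7, 32))
  fl <- filter_fits(list(ok, out_of_range, undet, failed))
  expect_equal(fl$reasons, c("ok", "filtered_ec50", "undetermined", "failed"))
  expect_equal(fl$kept_idx, 1L)
})

test_that("absolute IC50 follows the closed form and inverse identity", {
  g <- default_grid()
  # c = 0, d = 1: symmetric curve, ic50 = e
  f1 <- fit_curve(g, ll4_curve(g, 1.5, 0, 1, 2))
  expect_equal(ic50_abs(f1), 2, tolerance = 1e-6)
  # d = 0.45: never reaches 50% viability
  f2 <- f1; f2$d <- 0.45; f2$c <- 0.1
  expect_true(is.na(ic50_abs(f2)))
  # hand case b=1, c=0, d=1.2, e=10 -> 10 * (0.7/0.5) = 14
  f3 <- f1; f3$b <- 1; f3$c <- 0; f3$d <- 1.2; f3$e <- 10
  expect_equal(ic50_abs(f3), 14.0, tolerance = 1e-12)
  # inverse identity wherever defined
  for (fit in list(f1, f3))
    expect_equal(predict_curve(fit, ic50_abs(fit)), 0.5, tolerance = 1e-9)
})

test_that("noisy refits recover log-IC50 within 0.1 median absolute error", {
  g <- default_grid()
  set.seed(31)
  errs <- replicate(100, {
    e_true <- 10^runif(1, -1.5, 1.5)
    v <- ll4_curve(g, 1.2, 0.05, 1, e_true) + rnorm(32, sd = 0.05)
    fit <- fit_curve(g, v)
    if (identical(fit$status, "ok")) abs(log10(fit$e / e_true)) else NA
  })
  expect_lt(median(errs, na.rm = TRUE), 0.1)
})

test_that("AUC uses a log10 trapezoid and per-drug min-max scaling", {
  g <- default_grid()
  base <- data.frame(compound_id = "d1", cell_line_id = "s1",
                     concentration_uM = g, viability = 1)
  a <- auc_and_scale(base)
  expect_equal(a$auc, log10(300) - log10(1e-3), tolerance = 1e-12)
  expect_equal(a$flag, "single_sample")
  expect_true(is.na(a$scaled_auc))
  # three samples: min -> 0, max -> 1
  tri <- rbind(
    transform(base, cell_line_id = "s1", viability = ll4_curve(g, 1, 0, 1, 0.1)),
    transform(base, cell_line_id = "s2", viability = ll4_curve(g, 1, 0, 1, 1)),
    transform(base, cell_line_id = "s3", viability = ll4_curve(g, 1, 0, 1, 10)))
  a3 <- auc_and_scale(tri)
  expect_equal(min(a3$scaled_auc), 0)
  expect_equal(max(a3$scaled_auc), 1)
  mid <- a3$scaled_auc[a3$cell_line_id == "s2"]
  expect_gt(mid, 0.3); expect_lt(mid, 0.7)
  # the most potent curve (lowest e) holds the minimum AUC
  expect_equal(a3$cell_line_id[which.min(a3$auc)], "s1")
  # identical AUCs: degenerate range flagged at 0.5
  dup <- rbind(base, transform(base, cell_line_id = "s2"))
  ad <- auc_and_scale(dup)
  expect_equal(ad$scaled_auc, c(0.5, 0.5))
  expect_equal(unique(ad$flag), "degenerate_range")
})

test_that("pointwise-lower viability never wins a higher AUC", {
  g <- default_grid()
  set.seed(12)
  for (i in 1:20) {
    e1 <- 10^runif(1, -2, 2)
    lower <- ll4_curve(g, 1.3, 0, 1, e1)
    higher <- lower + runif(32, 0, 0.3)
    df <- rbind(data.frame(compound_id = "d", cell_line_id = "lo",
                           concentration_uM = g, viability = lower),
                data.frame(compound_id = "d", cell_line_id = "hi",
                           concentration_uM = g, viability = higher))
    a <- auc_and_scale(df)
    expect_lt(a$auc[a$cell_line_id == "lo"], a$auc[a$cell_line_id == "hi"])
  }
})

test_that("ED50 comparison is null for identical fits and detects a 2-fold shift", {
  g <- default_grid()
  set.seed(41)
  v <- ll4_curve(g, 1.2, 0.05, 1, 2) + rnorm(32, sd = 0.02)
  fit <- fit_curve(g, v)
  same <- compare_ed50(fit, fit)
  expect_equal(same$ed50_ratio, 1)
  expect_equal(same$t_value, 0)
  expect_equal(same$p_value, 1)
  # true 2-fold potency difference at low noise
  vA <- ll4_curve(g, 1.2, 0.05, 1, 4) + rnorm(32, sd = 0.02)
  vB <- ll4_curve(g, 1.2, 0.05, 1, 2) + rnorm(32, sd = 0.02)
  cmp <- compare_ed50(fit_curve(g, vA), fit_curve(g, vB))
  expect_gt(cmp$ed50_ratio, 1.8)
  expect_lt(cmp$ed50_ratio, 2.2)
  expect_lt(cmp$p_value, 0.01)
  # missing covariance
  broken <- fit; broken$vcov <- NULL
  expect_error(compare_ed50(broken, fit), class = "filmsens_comparison_error")
})

test_that("ED50 comparison keeps approximate type-I control under the null", {
  g <- default_grid()
  set.seed(42)
  hits <- replicate(400, {
    vA <- ll4_curve(g, 1.2, 0.05, 1, 2) + rnorm(32, sd = 0.05)
    vB <- ll4_curve(g, 1.2, 0.05, 1, 2) + rnorm(32, sd = 0.05)
    fA <- fit_curve(g, vA); fB <- fit_curve(g, vB)
    if (identical(fA$status, "ok") && identical(fB$status, "ok"))
      compare_ed50(fA, fB)$p_value < 0.05 else NA
  })
  rate <- mean(hits, na.rm = TRUE)
  # binomial 99% band around 0.05 at n = 400 is roughly [0.02, 0.08]
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("responder classification and ROC follow the Mann-Whitney identity", {
  # perfectly separated scores
  perfect <- classify_and_roc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0),
                              threshold = 0.5)
  expect_equal(perfect$auroc, 1.0)
  expect_equal(unname(perfect$confusion[c("tp", "tn")]), c(2L, 2L))
  # hand 3v3 table: auROC = concordant-pair fraction by enumeration
  scores <- c(0.2, 0.5, 0.9, 0.3, 0.6, 0.7)
  labels <- c(1, 1, 1, 0, 0, 0)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- expand.grid(p = pos, n = neg)
  auroc_oracle <- mean(pairs$p < pairs$n) + 0.5 * mean(pairs$p == pairs$n)
  r <- classify_and_roc(scores, labels, threshold = 0.5)
  expect_equal(r$auroc, auroc_oracle)
  # label-independent scores sit near 0.5
  set.seed(77)
  null <- classify_and_roc(runif(1000), rep(c(0, 1), 500), threshold = 0.5)
  expect_lt(abs(null$auroc - 0.5), 0.05)
  expect_error(classify_and_roc(runif(5), rep(1, 5)),
               class = "filmsens_roc_error")
})

test_that("macro-averaged ROC aggregates per-drug auROCs", {
  set.seed(8)
  scores <- c(runif(40, 0, 0.5), runif(40, 0.3, 1))
  labels <- rep(c(1, 0), each = 40)
  groups <- rep(rep(c("d1", "d2"), each = 20), 2)
  r <- classify_and_roc(scores, labels, threshold = 0.4, groups = groups)
  expect_length(r$per_group, 2L)
  expect_equal(r$macro_auroc, mean(r$per_group))
})
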