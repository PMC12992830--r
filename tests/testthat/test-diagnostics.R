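test_that("reduction classification is inclusive at the cutoff", {
  expect_true(classify_by_reduction(89.51))   # paclitaxel hIEC TEER
  expect_false(classify_by_reduction(49.84))  # ketoprofen, just below
  expect_true(classify_by_reduction(50))      # boundary is positive
  expect_false(classify_by_reduction(49.999999))
})

test_that("confusion counts tally the reference panel as published", {
  p <- bundled_panel()
  ht <- combo_reductions(p, "hIEC", "TEER")
  cnt <- confusion(classify_by_reduction(ht$reduction), ht$label)
  expect_equal(unlist(cnt), c(tp = 11, fn = 1, tn = 5, fp = 0))

  ct <- combo_reductions(p, "Caco-2", "TEER")
  cnt2 <- confusion(classify_by_reduction(ct$reduction), ct$label)
  expect_equal(unlist(cnt2), c(tp = 10, fn = 2, tn = 3, fp = 2))

  expect_equal(unlist(confusion(ht$label, ht$label)),
               c(tp = 12, fn = 0, tn = 5, fp = 0))  # perfect predictions
  expect_error(confusion(ht$label, rep(TRUE, 17)), "single class")
  expect_error(confusion(c(TRUE, FALSE), c(TRUE, FALSE, FALSE)), "length")
})

test_that("rates follow the standard definitions, undefined stays NA", {
  m <- confusion_metrics(list(tp = 11, fn = 1, tn = 5, fp = 0))
  expect_equal(m$sensitivity, 11 / 12)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 16 / 17)
  expect_equal(m$youden_j, m$sensitivity + m$specificity - 1)

  m2 <- confusion_metrics(list(tp = 10, fn = 2, tn = 3, fp = 2))
  expect_equal(round(100 * m2$sensitivity), 83)
  expect_equal(round(100 * m2$specificity), 60)
  expect_equal(round(100 * m2$accuracy), 76)

  deg <- confusion_metrics(list(tp = 0, fn = 0, tn = 3, fp = 2))
  expect_true(is.na(deg$sensitivity))
  expect_false(is.na(deg$specificity))
  deg2 <- confusion_metrics(list(tp = 0, fn = 2, tn = 3, fp = 0))
  expect_true(is.na(deg2$ppv))    # nothing called positive
  expect_equal(deg2$sensitivity, 0)
})

test_that("rank AUC equals the exhaustive pair-counting oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(round(rnorm(n), 1))  # rounded: forces ties
    expect_equal(rank_auc(scores, labels), pair_count_auc(scores, labels))
  }
})

test_that("rank AUC on binary decisions equals (sens + spec) / 2", {
  combos <- expand.grid(tp = 0:3, fn = 0:3, tn = 0:3, fp = 0:3)
  combos <- combos[(combos$tp + combos$fn) > 0 & (combos$tn + combos$fp) > 0, ]
  for (k in seq_len(nrow(combos))) {
    cc <- combos[k, ]
    pred <- c(rep(TRUE, cc$tp), rep(FALSE, cc$fn),
              rep(FALSE, cc$tn), rep(TRUE, cc$fp))
    lab <- c(rep(TRUE, cc$tp + cc$fn), rep(FALSE, cc$tn + cc$fp))
    sens <- cc$tp / (cc$tp + cc$fn)
    spec <- cc$tn / (cc$tn + cc$fp)
    expect_equal(rank_auc(pred, lab), (sens + spec) / 2)
  }
})

test_that("panel AUCs match the published values under both conventions", {
  p <- bundled_panel()
  ht <- combo_reductions(p, "hIEC", "TEER")
  dec <- classify_by_reduction(ht$reduction)
  expect_equal(rank_auc(dec, ht$label), (11 / 12 + 1) / 2)     # 0.958
  expect_equal(round(rank_auc(dec, ht$label), 2), 0.96)
  expect_equal(rank_auc(ht$reduction, ht$label), 56 / 60)      # continuous
  expect_equal(rank_auc(c(3, 4, 5, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               1)  # perfect separation
})

test_that("DeLong interval behaves at the degenerate and regular ends", {
  sep <- c(5, 6, 7, 1, 2)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  ci <- delong_ci(sep, lab)
  expect_true(ci$degenerate)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))

  p <- bundled_panel()
  ht <- combo_reductions(p, "hIEC", "TEER")
  ci2 <- delong_ci(as.numeric(classify_by_reduction(ht$reduction)), ht$label)
  expect_false(ci2$degenerate)
  expect_equal(ci2$ci_high, 1)  # truncated at 1
  expect_lt(ci2$ci_low, ci2$auc)

  # cross-check variance against an independent implementation
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- c(rnorm(30, 1), rnorm(25))
  lb <- rep(c(TRUE, FALSE), c(30, 25))
  ours <- delong_ci(sc, lb)
  ref <- pROC::ci.auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<"),
                      method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("DeLong intervals reach nominal coverage in simulation", {
  set.seed(7)
  delta <- sqrt(2) * qnorm(0.8)  # binormal model with true AUC 0.8
  hits <- 0
  reps <- 1000
  for (r in seq_len(reps)) {
    sc <- c(rnorm(100, delta), rnorm(100))
    lb <- rep(c(TRUE, FALSE), each = 100)
    ci <- delong_ci(sc, lb)
    if (ci$ci_low <= 0.8 && 0.8 <= ci$ci_high) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.925)
  expect_lt(hits / reps, 0.975)
})

test_that("Mann-Whitney p-values behave against a permutation oracle", {
  # identical score distributions: no evidence in either direction
  same <- rep(c(1, 2, 3, 4), 4)
  lab <- rep(c(TRUE, FALSE), each = 8)
  expect_gt(mann_whitney_p(same, lab, "two.sided"), 0.95)

  # perfect separation at n = 12 vs 5: exact permutation p = 1/C(17,5)
  sep <- c(rep(1, 12), rep(0, 5)) + seq(0, 0.16, 0.01)
  lab2 <- rep(c(TRUE, FALSE), c(12, 5))
  p_perm <- 1 / choose(17, 5)
  expect_lt(mann_whitney_p(sep, lab2), 0.001)
  expect_lt(abs(log10(mann_whitney_p(sep, lab2)) - log10(p_perm)), 1.5)

  # Caco-2 ATP decisions are not significant at the 5% level
  pn <- bundled_panel()
  ca <- combo_reductions(pn, "Caco-2", "ATP")
  p_ca <- mann_whitney_p(as.numeric(classify_by_reduction(ca$reduction)),
                         ca$label)
  expect_gt(p_ca, 0.05)
})

test_that("threshold sweep reproduces pointwise evaluation and plateaus", {
  p <- bundled_panel()
  ht <- combo_reductions(p, "hIEC", "TEER")
  sw <- threshold_sweep(ht$reduction, ht$label)

  at50 <- sw[sw$cutoff == 50, ]
  expect_equal(at50$youden_j, 11 / 12)
  expect_equal(at50$accuracy, 16 / 17)

  # composition: each row equals classify + confusion + metrics at c
  for (cut in c(0, 35, 50, 70)) {
    cnt <- confusion(classify_by_reduction(ht$reduction, cut), ht$label)
    expect_equal(sw[sw$cutoff == cut, c("tp", "fn", "tn", "fp")],
                 cnt, ignore_attr = TRUE)
    expect_equal(sw$youden_j[sw$cutoff == cut],
                 confusion_metrics(cnt)$youden_j)
  }

  # hIEC TEER plateaus at J ~0.92 across 50-65%
  plat <- attr(sw, "plateau")
  expect_equal(plat$lo, 50)
  expect_equal(plat$hi, 65)
  expect_equal(round(plat$youden_j, 2), 0.92)

  # Caco-2 TEER reaches its lower plateau (J ~0.75) only at >= 60%
  ct <- combo_reductions(p, "Caco-2", "TEER")
  sw2 <- threshold_sweep(ct$reduction, ct$label)
  plat2 <- attr(sw2, "plateau")
  expect_equal(round(plat2$youden_j, 2), 0.75)
  expect_gte(plat2$lo, 60)
  expect_true(all(sw2$youden_j[sw2$cutoff < 60] < 0.75 - 1e-9))

  # a cutoff below every reduction calls everything positive: J = 0
  swp <- threshold_sweep(c(10, 60, 70, 20), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(swp$youden_j[swp$cutoff == 0], 0)
  expect_equal(swp$sensitivity[swp$cutoff == 0], 1)
  expect_equal(swp$specificity[swp$cutoff == 0], 0)
})

test_that("Pearson r matches a two-pass textbook implementation", {
  set.seed(29)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1))
    y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), two_pass_pearson(x, y), tolerance = 1e-12)
    # affine invariance; sign flips with negative scale
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(a * x + b, y), pearson_r(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(-a * x + b, y), -pearson_r(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_warning(r0 <- pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("the endpoint correlation matrix matches the published heat map", {
  cm <- correlation_matrix(bundled_panel())
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_equal(round(cm["hIEC TEER", "GI score"], 2), 0.64)
  expect_equal(round(cm["Caco-2 TEER", "GI score"], 2), 0.58)
  expect_equal(round(cm["hIEC ATP", "GI score"], 2), 0.25)
  expect_equal(round(cm["Caco-2 ATP", "GI score"], 2), -0.04)
})

test_that("end-to-end assay evaluation assembles the full report", {
  p <- bundled_panel()
  r <- evaluate_assay(p, "hIEC", "TEER", rule = "reduction")
  expect_s3_class(r, "diagnostic_report")
  expect_equal(r$metrics$accuracy, 16 / 17)
  expect_equal(round(r$auc_binary$auc, 2), 0.96)
  expect_equal(r$auc_continuous$auc, 56 / 60)
  expect_lt(r$auc_binary$p, 0.001)
  expect_equal(nrow(r$predictions), 17)
  expect_equal(sum(r$predictions$outcome == "TP"), 11)

  m <- evaluate_assay(p, "hIEC", "TEER", rule = "mos15")
  expect_equal(round(100 * m$metrics$sensitivity), 58)
  expect_equal(round(100 * m$metrics$specificity), 80)
  expect_equal(round(100 * m$metrics$accuracy), 65)

  ca <- evaluate_assay(p, "Caco-2", "ATP", rule = "reduction")
  expect_equal(round(ca$auc_binary$auc, 2), 0.61)
  expect_gt(ca$auc_binary$p, 0.05)

  expect_error(evaluate_assay(p, "hIEC", "NADPH"), "no assay summaries")
})
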