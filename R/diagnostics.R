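#' Binary classification by percent reduction
#'
#' The prespecified decision rule: a drug is called toxic when its percent
#' reduction at the top dose is at least `cutoff` (inclusive; "at least
#' 50% reduction" is the unified default across assays).
#'
#' @param pct_reduction percent reduction values.
#' @param cutoff decision cutoff, % (default 50).
#' @return logical predictions.
#' @export
classify_by_reduction <- function(pct_reduction, cutoff = 50) {
  pct_reduction >= cutoff
}

#' Confusion counts
#'
#' Tallies predictions against reference labels.  Requires both classes
#' to be present in the labels, otherwise sensitivity or specificity is
#' undefined and evaluation is refused.
#'
#' @param predictions logical predicted labels.
#' @param labels logical reference labels (`TRUE` = toxic).
#' @return a one-row tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    abort("predictions and labels must have equal length")
  }
  if (anyNA(predictions) || anyNA(labels)) {
    abort("predictions and labels must not contain NA")
  }
  if (!any(labels) || all(labels)) {
    abort("labels contain a single class; sensitivity or specificity undefined")
  }
  tibble(
    tp = sum(predictions & labels),
    fn = sum(!predictions & labels),
    tn = sum(!predictions & !labels),
    fp = sum(predictions & !labels)
  )
}

#' Diagnostic rates from confusion counts
#'
#' Standard definitions: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' accuracy (TP+TN)/n, PPV TP/(TP+FP), NPV TN/(TN+FN), and Youden's
#' J = sensitivity + specificity - 1.  A rate whose denominator is zero
#' is reported as `NA` (undefined), never coerced to 0 or 1.
#'
#' @param counts a tibble/list with elements `tp`, `fn`, `tn`, `fp`.
#' @return a one-row tibble of the six rates (proportions in \[0, 1\];
#'   `youden_j` in \[-1, 1\]).
#' @examples
#' confusion_metrics(list(tp = 11, fn = 1, tn = 5, fp = 0))
#' @export
confusion_metrics <- function(counts) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, {
    sens <- rate(tp, tp + fn)
    spec <- rate(tn, tn + fp)
    tibble(
      sensitivity = sens,
      specificity = spec,
      accuracy = rate(tp + tn, tp + tn + fp + fn),
      ppv = rate(tp, tp + fp),
      npv = rate(tn, tn + fn),
      youden_j = sens + spec - 1
    )
  })
}

#' Rank (Mann-Whitney) AUC
#'
#' Area under the ROC curve in its rank formulation with midrank tie
#' handling: the probability that a randomly drawn positive scores higher
#' than a randomly drawn negative, counting ties as one half.  Applied to
#' binary 0/1 decisions of a prespecified rule this reduces exactly to
#' (sensitivity + specificity) / 2, the single-operating-point trapezoid
#' -- the convention used for the headline AUCs of the evaluation.
#'
#' @param scores numeric predictor (larger = more toxic); binary decisions
#'   may be passed as logical or 0/1.
#' @param labels logical reference labels.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  .check_two_class(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.check_two_class <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels)) abort("NA in scores or labels")
  if (!any(labels) || all(labels)) {
    abort("labels contain a single class; AUC undefined")
  }
  invisible(TRUE)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from DeLong's
#' structural components: per-positive and per-negative placement values
#' whose empirical variances combine to
#' `var(AUC) = S10/m + S01/n`.  The normal-approximation interval is
#' truncated to \[0, 1\].  When the variance is zero (perfect separation,
#' or all scores tied) the interval degenerates to the point AUC and is
#' flagged.
#'
#' @param scores,labels as in [rank_auc()].
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return a list: `auc`, `se`, `ci_low`, `ci_high`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  scores <- as.numeric(scores)
  .check_two_class(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  m <- length(pos)
  n <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # placement of each positive among negatives
  v01 <- colMeans(psi)  # placement of each negative among positives
  v <- var(v10) / m + var(v01) / n
  degenerate <- !is.finite(v) || v <= .Machine$double.eps
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - alpha / 2)
  list(
    auc = auc, se = se,
    ci_low = if (degenerate) auc else max(0, auc - z * se),
    ci_high = if (degenerate) auc else min(1, auc + z * se),
    degenerate = degenerate
  )
}

#' Mann-Whitney test that the AUC exceeds 0.5
#'
#' Two-group rank-sum test of the positive-class scores against the
#' negative-class scores, using the tie-corrected normal approximation.
#' `alternative = "greater"` (default) tests AUC > 0.5; the two-sided
#' variant is also exposed.
#'
#' @param scores,labels as in [rank_auc()].
#' @param alternative `"greater"` or `"two.sided"`.
#' @return p-value.
#' @export
mann_whitney_p <- function(scores, labels,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  scores <- as.numeric(scores)
  .check_two_class(scores, labels)
  suppressWarnings(
    wilcox.test(scores[labels], scores[!labels],
                alternative = alternative, exact = FALSE)$p.value
  )
}

#' Threshold sweep over reduction cutoffs
#'
#' Re-evaluates the reduction rule at every cutoff in `grid`, recording
#' the confusion counts, Youden's J and accuracy, and locates the
#' performance plateau: the longest contiguous run of cutoffs whose J is
#' within `tol` of the maximum.
#'
#' @param reductions percent-reduction values, one per drug.
#' @param labels logical reference labels.
#' @param grid cutoffs to evaluate (default 0-100 in steps of 5).
#' @param tol tolerance for membership in the maximal-J plateau.
#' @return a tibble with one row per cutoff (`cutoff`, `tp`, `fn`, `tn`,
#'   `fp`, `sensitivity`, `specificity`, `accuracy`, `youden_j`), with the
#'   plateau stored in `attr(, "plateau")` as
#'   `list(lo, hi, youden_j)`.
#' @examples
#' p <- bundled_panel()
#' a <- panel_assays(p)
#' red <- a$pct_reduction[a$model == "hIEC" & a$assay == "TEER"]
#' lab <- score_panel(p)$reference_positive
#' sw <- threshold_sweep(red, lab)
#' attr(sw, "plateau")
#' @export
threshold_sweep <- function(reductions, labels, grid = seq(0, 100, by = 5),
                            tol = 1e-9) {
  if (!length(grid)) abort("cutoff grid must be nonempty")
  grid <- sort(grid)
  rows <- lapply(grid, function(cut) {
    cnt <- confusion(classify_by_reduction(reductions, cut), labels)
    dplyr::bind_cols(tibble(cutoff = cut), cnt, confusion_metrics(cnt))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("cutoff", "tp", "fn", "tn", "fp",
                 "sensitivity", "specificity", "accuracy", "youden_j")]
  jmax <- max(out$youden_j, na.rm = TRUE)
  at_max <- !is.na(out$youden_j) & out$youden_j >= jmax - tol
  runs <- rle(at_max)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  attr(out, "plateau") <- list(
    lo = out$cutoff[starts[best]],
    hi = out$cutoff[ends[best]],
    youden_j = jmax
  )
  out
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation
#' `r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)) /
#' sqrt(sum((y - mean(y))^2))`, computed via [stats::cor()].  Zero
#' variance in either argument makes r undefined (`NA`, with a warning).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return r in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (anyNA(x) || anyNA(y)) abort("NA in x or y")
  if (var(x) == 0 || var(y) == 0) {
    warn("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Pairwise correlation matrix over panel endpoints
#'
#' Pearson correlations between the four assay percent-reduction columns,
#' the total GI toxicity score and clinical C_max, over the drugs of a
#' panel.
#'
#' @param panel a [drug_panel()] with summaries for all four model/assay
#'   combinations.
#' @return a symmetric numeric matrix with unit diagonal; row/column
#'   names are `hIEC TEER`, `Caco-2 TEER`, `hIEC ATP`, `Caco-2 ATP`,
#'   `GI score`, `Cmax`.
#' @examples
#' round(correlation_matrix(bundled_panel()), 2)
#' @export
correlation_matrix <- function(panel) {
  wide <- .panel_wide(panel)
  m <- as.matrix(wide[, c("hIEC TEER", "Caco-2 TEER", "hIEC ATP",
                          "Caco-2 ATP", "GI score", "Cmax")])
  cor(m)
}

# one row per drug: reduction per combo + score + cmax + label
.panel_wide <- function(panel, threshold = 4) {
  a <- panel_assays(panel)
  a$combo <- paste(a$model, a$assay)
  wide <- tidyr::pivot_wider(a[, c("drug", "combo", "pct_reduction")],
                             names_from = "combo",
                             values_from = "pct_reduction")
  sc <- score_panel(panel, threshold)
  d <- panel_drugs(panel)
  wide <- dplyr::inner_join(wide, tibble(drug = sc$drug,
                                         `GI score` = sc$total,
                                         label = sc$reference_positive),
                            by = "drug")
  dplyr::inner_join(wide, tibble(drug = d$drug, Cmax = d$cmax_uM),
                    by = "drug")
}

#' End-to-end diagnostic evaluation of one assay
#'
#' Runs a prespecified decision rule over a panel and evaluates it
#' against the clinical reference labels (total GI toxicity score
#' dichotomized at `label_threshold`): confusion counts, rates, Youden's
#' J, and ROC AUC with DeLong 95% CI and Mann-Whitney p-value.
#'
#' Two AUC conventions are reported side by side.  The *headline* AUC
#' applies the rank AUC to the rule's binarized decisions -- the
#' single-operating-point trapezoid (sensitivity + specificity)/2, the
#' convention matching prespecified-rule reporting.  The *continuous* AUC
#' uses the underlying continuous predictor (percent reduction, or -MOS
#' for exposure rules, with censored MOS entered at its lower bound) and
#' is labeled as secondary.
#'
#' @param panel a [drug_panel()].
#' @param model `"hIEC"` or `"Caco-2"`.
#' @param assay `"TEER"` or `"ATP"`.
#' @param rule `"reduction"` (>= cutoff % reduction at the top dose),
#'   `"mos15"` or `"mos50"` (MOS strictly below `mos_threshold`).
#' @param cutoff reduction cutoff, % (default 50).
#' @param mos_threshold MOS risk threshold (default 1).
#' @param label_threshold reference-positive threshold on the total score.
#' @param alpha error rate for the DeLong CI.
#' @return an object of class `diagnostic_report`: a list with elements
#'   `model`, `assay`, `rule`, `n`, `counts`, `metrics`,
#'   `auc_binary` (list: auc, se, ci_low, ci_high, degenerate, p),
#'   `auc_continuous` (same shape), `predictions` (per-drug tibble).
#' @examples
#' evaluate_assay(bundled_panel(), "hIEC", "TEER", rule = "reduction")
#' @export
evaluate_assay <- function(panel, model, assay,
                           rule = c("reduction", "mos15", "mos50"),
                           cutoff = 50, mos_threshold = 1,
                           label_threshold = 4, alpha = 0.05) {
  rule <- match.arg(rule)
  a <- panel_assays(panel)
  a <- a[a$model == model & a$assay == assay, ]
  if (nrow(a) == 0) abort(paste0("no assay summaries for ", model, " ", assay))
  sc <- score_panel(panel, label_threshold)
  a <- dplyr::inner_join(a, sc[, c("drug", "total", "reference_positive")],
                         by = "drug")
  labels <- a$reference_positive

  if (rule == "reduction") {
    if (anyNA(a$pct_reduction)) {
      drop <- a$drug[is.na(a$pct_reduction)]
      warn(paste0("excluding drugs with missing reduction: ",
                  paste(drop, collapse = ", ")))
      a <- a[!is.na(a$pct_reduction), ]
      labels <- a$reference_positive
    }
    pred <- classify_by_reduction(a$pct_reduction, cutoff)
    cont <- a$pct_reduction
  } else {
    ic <- if (rule == "mos15") {
      mos(a$ic15_uM, .cmax_for(panel, a$drug), a$ic15_censored,
          a$censor_limit_uM)
    } else {
      mos(a$ic50_uM, .cmax_for(panel, a$drug), a$ic50_censored,
          a$censor_limit_uM)
    }
    pred <- mos_classify(ic, mos_threshold)
    # continuous predictor: more toxic = smaller MOS; censored values
    # enter at their lower bound (a conservative placement)
    cont <- -ic$mos_lower
  }

  counts <- confusion(pred, labels)
  metr <- confusion_metrics(counts)
  bin <- delong_ci(as.numeric(pred), labels, alpha)
  bin$p <- mann_whitney_p(as.numeric(pred), labels)
  cnt <- delong_ci(cont, labels, alpha)
  cnt$p <- mann_whitney_p(cont, labels)

  structure(list(
    model = model, assay = assay, rule = rule,
    cutoff = if (rule == "reduction") cutoff else mos_threshold,
    n = nrow(a),
    counts = counts, metrics = metr,
    auc_binary = bin, auc_continuous = cnt,
    predictions = tibble(drug = a$drug, label = labels, predicted = pred,
                         outcome = ifelse(pred & labels, "TP",
                                   ifelse(!pred & !labels, "TN",
                                   ifelse(pred, "FP", "FN"))))
  ), class = "diagnostic_report")
}

.cmax_for <- function(panel, drugs) {
  d <- panel_drugs(panel)
  d$cmax_uM[match(drugs, d$drug)]
}

#' @export
print.diagnostic_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<diagnostic_report> %s %s, rule=%s (threshold %s), n=%d\n",
              x$model, x$assay, x$rule, format(x$cutoff), x$n))
  cat(sprintf("  TP=%d FN=%d TN=%d FP=%d\n",
              x$counts$tp, x$counts$fn, x$counts$tn, x$counts$fp))
  cat(sprintf("  sensitivity %.0f%%, specificity %.0f%%, accuracy %.0f%%, J=%.2f\n",
              100 * m$sensitivity, 100 * m$specificity,
              100 * m$accuracy, m$youden_j))
  cat(sprintf("  AUC (binarized rule) %.2f (%.2f-%.2f), P=%.3g%s\n",
              x$auc_binary$auc, x$auc_binary$ci_low, x$auc_binary$ci_high,
              x$auc_binary$p,
              if (x$auc_binary$degenerate) " [degenerate CI]" else ""))
  cat(sprintf("  AUC (continuous predictor) %.2f (%.2f-%.2f), P=%.3g\n",
              x$auc_continuous$auc, x$auc_continuous$ci_low,
              x$auc_continuous$ci_high, x$auc_continuous$p))
  invisible(x)
}
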