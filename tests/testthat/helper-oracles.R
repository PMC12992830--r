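# independent brute-force oracles used to check the fast implementations

# AUC by exhaustive pair counting over all positive-negative pairs
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# textbook two-pass Pearson correlation
two_pass_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / (sqrt(sum(dx^2)) * sqrt(sum(dy^2)))
}

# dose at which a 4PL fit crosses `level` (% of control), by bisection on
# the predicted curve; NA when there is no crossing in (lo, hi)
bisect_ic <- function(fit, level, lo = 1e-9, hi = 1e6, tol = 1e-13) {
  f <- function(d) predict(fit, d) - level
  if (f(lo) * f(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)  # bisection in log-dose
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# the printed total GI toxicity scores of the 17-drug reference panel,
# in fixture row order
printed_totals <- c(
  Paclitaxel = 6, Docetaxel = 9, Capecitabine = 9, Cyclophosphamide = 4,
  Cisplatin = 3, `5-FU` = 9, Doxorubicin = 4, Gefitinib = 6,
  Crizotinib = 6, Sunitinib = 6, Sorafenib = 6, Lapatinib = 9,
  Ibuprofen = 2, Diclofenac = 2, Naproxen = 2, Ketoprofen = 2,
  Ketorolac = 4
)

# reductions and labels for one model/assay combination of a panel
combo_reductions <- function(panel, model, assay) {
  a <- panel_assays(panel)
  a <- a[a$model == model & a$assay == assay, ]
  sc <- score_panel(panel)
  list(drug = a$drug,
       reduction = a$pct_reduction,
       label = sc$reference_positive[match(a$drug, sc$drug)])
}
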