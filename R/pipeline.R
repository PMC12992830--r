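#' Run the full evaluation pipeline and write a report bundle
#'
#' Ties the stages together for one panel: per-drug GI toxicity scores,
#' exposure (MOS) tables, diagnostic reports for each model/assay and
#' rule, the endpoint correlation matrix, and threshold sweeps for the
#' reduction rule.  All tables are written as CSV into `out_dir`,
#' together with `summary.json` holding the headline metrics.  The run
#' is fully deterministic: identical inputs give byte-identical outputs.
#'
#' @param panel a [drug_panel()]; defaults to the bundled 17-drug panel.
#'   Alternatively pass `panel_path` to load one from disk.
#' @param out_dir output directory, created if needed.
#' @param panel_path optional path to a panel CSV (ignored when `panel`
#'   is given).
#' @param rules decision rules to evaluate, a subset of
#'   `c("reduction", "mos15", "mos50")`.
#' @param cutoff reduction cutoff, % (default 50).
#' @param mos_threshold MOS risk threshold (default 1).
#' @param label_threshold reference-positive threshold on the total score.
#' @param grid cutoffs for the threshold sweep.
#' @param verbose emit progress messages.
#' @return invisibly, a list with elements `scores`, `exposure`,
#'   `reports`, `correlations`, `sweeps`, `summary`, `files`.
#' @examples
#' \donttest{
#' res <- run_pipeline(out_dir = tempfile())
#' res$summary$`hIEC TEER reduction`
#' }
#' @export
run_pipeline <- function(panel = NULL, out_dir, panel_path = NULL,
                         rules = c("reduction", "mos15"),
                         cutoff = 50, mos_threshold = 1,
                         label_threshold = 4,
                         grid = seq(0, 100, by = 5), verbose = TRUE) {
  bad <- setdiff(rules, c("reduction", "mos15", "mos50"))
  if (length(bad)) {
    abort(paste0("unknown rule(s): ", paste(bad, collapse = ", "),
                 " -- valid rules are reduction, mos15, mos50"))
  }
  if (is.null(panel)) {
    panel <- if (is.null(panel_path)) bundled_panel() else
      load_panel(panel_path)
  }
  stopifnot(inherits(panel, "drug_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- character()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, path)
    path
  }

  say("scoring ", nrow(panel_drugs(panel)), " drugs")
  scores <- score_panel(panel, label_threshold)
  emit(scores, "scores.csv")

  combos <- unique(panel_assays(panel)[, c("model", "assay")])
  exposure <- list()
  reports <- list()
  sweeps <- list()
  summary <- list()
  for (k in seq_len(nrow(combos))) {
    model <- combos$model[k]
    assay <- combos$assay[k]
    tag <- paste(model, assay)
    slug <- tolower(gsub("[^A-Za-z0-9]+", "_", tag))

    ex <- exposure_table(panel, model, assay, mos_threshold)
    exposure[[tag]] <- ex
    emit(ex, paste0("exposure_", slug, ".csv"))
    n_cens <- sum(ex$mos15_censored)
    if (n_cens) {
      say(tag, ": ", n_cens,
          " censored IC15 value(s) classified nontoxic by policy")
    }

    for (rule in rules) {
      rep <- evaluate_assay(panel, model, assay, rule = rule,
                            cutoff = cutoff, mos_threshold = mos_threshold,
                            label_threshold = label_threshold)
      key <- paste(tag, rule)
      reports[[key]] <- rep
      m <- rep$metrics
      summary[[key]] <- list(
        sensitivity = m$sensitivity, specificity = m$specificity,
        accuracy = m$accuracy, youden_j = m$youden_j,
        ppv = m$ppv, npv = m$npv,
        auc_binarized = rep$auc_binary$auc,
        auc_binarized_ci = c(rep$auc_binary$ci_low, rep$auc_binary$ci_high),
        auc_continuous = rep$auc_continuous$auc,
        p_binarized = rep$auc_binary$p
      )
      say(sprintf("%s [%s]: sens %.0f%%, spec %.0f%%, acc %.0f%%, AUC %.2f",
                  tag, rule, 100 * m$sensitivity, 100 * m$specificity,
                  100 * m$accuracy, rep$auc_binary$auc))
    }

    if ("reduction" %in% rules) {
      red <- panel_assays(panel)
      red <- red[red$model == model & red$assay == assay, ]
      lab <- scores$reference_positive[match(red$drug, scores$drug)]
      sw <- threshold_sweep(red$pct_reduction, lab, grid)
      sweeps[[tag]] <- sw
      emit(sw, paste0("threshold_sweep_", slug, ".csv"))
    }
  }

  diag_tbl <- dplyr::bind_rows(lapply(names(reports), function(key) {
    r <- reports[[key]]
    dplyr::bind_cols(
      tibble(model = r$model, assay = r$assay, rule = r$rule, n = r$n),
      r$counts, r$metrics,
      tibble(auc_binarized = r$auc_binary$auc,
             auc_ci_low = r$auc_binary$ci_low,
             auc_ci_high = r$auc_binary$ci_high,
             auc_continuous = r$auc_continuous$auc,
             p_value = r$auc_binary$p)
    )
  }))
  emit(diag_tbl, "diagnostics.csv")

  corr <- tryCatch(correlation_matrix(panel), error = function(e) NULL)
  if (!is.null(corr)) {
    cm <- as_tibble(corr, rownames = "endpoint")
    emit(cm, "correlation_matrix.csv")
  } else {
    say("correlation matrix skipped: panel lacks all four combinations")
  }

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  files <- c(files, json_path)

  invisible(list(scores = scores, exposure = exposure, reports = reports,
                 correlations = corr, sweeps = sweeps, summary = summary,
                 files = files))
}
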