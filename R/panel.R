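#' Drug panels
#'
#' A drug panel couples per-drug clinical annotations (pharmacological
#' class, CTCAE severity grade, incidence category, peak plasma
#' concentration C_max) with per drug x epithelium model x assay summaries
#' (IC15, IC50, percent reduction at the top dose).  Panels are stored as
#' two tibbles:
#'
#' * `drugs`: one row per drug with columns `drug`, `class`,
#'   `severity_grade`, `incidence`, `cmax_uM`, `route`;
#' * `assays`: one row per drug/model/assay with columns `drug`, `model`,
#'   `assay`, `ic15_uM`, `ic15_censored`, `ic50_uM`, `ic50_censored`,
#'   `pct_reduction`, `censor_limit_uM`.
#'
#' @param drugs,assays tibbles as described above.
#' @return an object of class `drug_panel`.
#' @seealso [load_panel()], [bundled_panel()], [write_panel()]
#' @export
drug_panel <- function(drugs, assays) {
  drugs <- as_tibble(drugs)
  assays <- as_tibble(assays)
  need_d <- c("drug", "class", "severity_grade", "incidence", "cmax_uM")
  need_a <- c("drug", "model", "assay", "ic15_uM", "ic15_censored",
              "ic50_uM", "ic50_censored", "pct_reduction")
  miss <- c(setdiff(need_d, names(drugs)), setdiff(need_a, names(assays)))
  if (length(miss)) {
    abort(paste0("panel schema error: missing columns ",
                 paste(miss, collapse = ", ")))
  }
  if (!"route" %in% names(drugs)) drugs$route <- "unspecified"
  if (!"censor_limit_uM" %in% names(assays)) assays$censor_limit_uM <- 100

  if (anyDuplicated(drugs$drug)) {
    abort("panel integrity error: duplicate drug names")
  }
  if (!all(is.finite(drugs$cmax_uM)) || any(drugs$cmax_uM <= 0)) {
    abort("panel parse error: cmax_uM must be positive and numeric")
  }
  if (!all(drugs$severity_grade %in% 1:4)) {
    abort("panel parse error: severity_grade must be an integer in 1..4")
  }
  .check_incidence(drugs$incidence)
  if (!all(assays$model %in% c("hIEC", "Caco-2"))) {
    abort("panel parse error: model must be 'hIEC' or 'Caco-2'")
  }
  if (!all(assays$assay %in% c("TEER", "ATP"))) {
    abort("panel parse error: assay must be 'TEER' or 'ATP'")
  }
  key <- paste(assays$drug, assays$model, assays$assay)
  if (anyDuplicated(key)) {
    abort(paste0("panel integrity error: duplicate (drug, model, assay): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  if (!all(assays$drug %in% drugs$drug)) {
    abort("panel integrity error: assay rows refer to unknown drugs")
  }
  ok_red <- is.na(assays$pct_reduction) | assays$pct_reduction <= 100
  if (!all(ok_red)) {
    abort("panel parse error: pct_reduction cannot exceed 100")
  }
  structure(list(drugs = drugs, assays = assays), class = "drug_panel")
}

.check_incidence <- function(x) {
  ok <- tolower(trimws(x)) %in% c("uncommon", "common", "very common")
  if (!all(ok)) {
    abort(paste0("panel parse error: unknown incidence category: ",
                 paste(unique(x[!ok]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.drug_panel <- function(x, ...) {
  cat("<drug_panel> ", nrow(x$drugs), " drugs, ",
      nrow(x$assays), " assay summaries\n", sep = "")
  print(x$drugs, n = 5)
  invisible(x)
}

#' @rdname drug_panel
#' @param panel a `drug_panel`.
#' @export
panel_drugs <- function(panel) {
  stopifnot(inherits(panel, "drug_panel"))
  panel$drugs
}

#' @rdname drug_panel
#' @export
panel_assays <- function(panel) {
  stopifnot(inherits(panel, "drug_panel"))
  panel$assays
}

#' Read a drug panel from delimited text
#'
#' Expects one row per drug/model/assay with header columns `drug`,
#' `class`, `severity_grade`, `incidence`, `cmax_uM`, `model`, `assay`,
#' `ic15_uM`, `ic50_uM`, `pct_reduction` (plus optional `route`).
#' Drug-level fields are repeated on each row and must be consistent.
#' Right-censored IC entries are written as a greater-than token
#' (`">100"` by default, unit suffixes tolerated).
#'
#' @param path file path to a CSV/TSV panel table.
#' @param censor_limit_uM default censoring limit used when a censored
#'   token carries no number (the panel's highest tested dose).
#' @param delim field delimiter; guessed from the file extension when `NULL`.
#' @return a [drug_panel()].
#' @examples
#' p <- bundled_panel()
#' tmp <- tempfile(fileext = ".csv")
#' write_panel(p, tmp)
#' identical_panel <- load_panel(tmp)
#' @export
load_panel <- function(path, censor_limit_uM = 100, delim = NULL) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  if (is.null(delim)) delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  need <- c("drug", "class", "severity_grade", "incidence", "cmax_uM",
            "model", "assay", "ic15_uM", "ic50_uM", "pct_reduction")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("panel schema error in ", path, ": missing columns ",
                 paste(miss, collapse = ", ")))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      abort(paste0("panel parse error: non-numeric ", what, " in row(s) ",
                   paste(bad, collapse = ", ")))
    }
    v
  }
  ic15 <- parse_conc(raw$ic15_uM, censor_limit_uM)
  ic50 <- parse_conc(raw$ic50_uM, censor_limit_uM)
  drugs <- dplyr::distinct(tibble(
    drug = raw$drug,
    class = raw$class,
    severity_grade = num("severity_grade", "severity_grade"),
    incidence = tolower(trimws(raw$incidence)),
    cmax_uM = num("cmax_uM", "cmax_uM"),
    route = if ("route" %in% names(raw)) raw$route else "unspecified"
  ))
  if (anyDuplicated(drugs$drug)) {
    abort("panel integrity error: inconsistent drug-level fields across rows")
  }
  assays <- tibble(
    drug = raw$drug, model = raw$model, assay = raw$assay,
    ic15_uM = ic15$value_uM, ic15_censored = ic15$censored,
    ic50_uM = ic50$value_uM, ic50_censored = ic50$censored,
    pct_reduction = num("pct_reduction", "pct_reduction"),
    censor_limit_uM = pmax(ic15$limit_uM, ic50$limit_uM)
  )
  drug_panel(drugs, assays)
}

#' Write a drug panel to delimited text
#'
#' Inverse of [load_panel()]: censored ICs are serialized as `">limit"`
#' tokens and numeric fields keep full precision, so a write/load
#' round-trip reproduces the panel exactly.
#'
#' @param panel a [drug_panel()].
#' @param path output file path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "drug_panel"))
  long <- dplyr::inner_join(panel$drugs, panel$assays, by = "drug")
  out <- tibble(
    drug = long$drug, class = long$class,
    severity_grade = long$severity_grade, incidence = long$incidence,
    cmax_uM = long$cmax_uM, route = long$route,
    model = long$model, assay = long$assay,
    ic15_uM = format_conc(long$ic15_uM, long$ic15_censored, long$censor_limit_uM),
    ic50_uM = format_conc(long$ic50_uM, long$ic50_censored, long$censor_limit_uM),
    pct_reduction = long$pct_reduction
  )
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' The bundled 17-drug reference panel
#'
#' The panel of 17 clinically characterized drugs (seven cell-cycle
#' inhibitors, five tyrosine kinase inhibitors, five NSAIDs) shipped with
#' the package: CTCAE severity grades, incidence categories, clinical
#' C_max, and IC15/IC50/percent-reduction summaries for all four
#' epithelium model x assay combinations (hIEC and Caco-2, TEER and ATP
#' viability), with right-censored ICs marked `">100"` uM.  This table is
#' the reference input for the diagnostic-accuracy evaluation.
#'
#' @return a [drug_panel()] with 17 drugs and 68 assay summaries.
#' @examples
#' p <- bundled_panel()
#' panel_drugs(p)
#' @export
bundled_panel <- function() {
  load_panel(system.file("extdata", "gi_drug_panel.csv",
                         package = "barriertox", mustWork = TRUE))
}
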