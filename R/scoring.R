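#' Clinical GI toxicity scoring
#'
#' The clinical reference standard combines CTCAE v5.0 severity grades
#' (1-4) with an incidence category.  Incidence is scored 1 (uncommon),
#' 2 (common) or 3 (very common), and
#' `total score = severity grade score x incidence score`,
#' ranging from 1 (grade 1, uncommon) to 12 (grade 4, very common).
#' Risk bands: low (total <= 3), moderate (4-8), high (>= 9).  Drugs with
#' total score at or above the reference threshold (default 4, i.e.
#' moderate or high risk) are the reference-positive ("toxic") class for
#' all diagnostic evaluation.
#'
#' @param category incidence category: `"uncommon"`, `"common"` or
#'   `"very common"` (case- and whitespace-insensitive).
#' @return `incidence_score()`: integer score 1-3.
#' @examples
#' incidence_score("Very common")   # 3
#' total_score(3, "very common")    # total 9, high risk
#' risk_class(c(3, 6, 9))
#' @export
incidence_score <- function(category) {
  key <- tolower(trimws(category))
  map <- c("uncommon" = 1L, "common" = 2L, "very common" = 3L)
  bad <- !key %in% names(map)
  if (any(bad)) {
    abort(paste0("unknown incidence category: ",
                 paste(unique(category[bad]), collapse = ", ")))
  }
  unname(map[key])
}

#' @rdname incidence_score
#' @param total total GI toxicity score(s), integer in 1..12.
#' @return `risk_class()`: character vector `"low"`/`"moderate"`/`"high"`.
#' @export
risk_class <- function(total) {
  if (any(!is.finite(total)) || any(total < 1) || any(total > 12) ||
      any(total != round(total))) {
    abort("total score must be an integer in 1..12")
  }
  ifelse(total <= 3, "low", ifelse(total <= 8, "moderate", "high"))
}

#' @rdname incidence_score
#' @param severity_grade CTCAE severity grade score(s), integer 1-4.
#'   Grades printed as a range (e.g. "~1-2") resolve to their assigned
#'   score before entering here.
#' @param incidence incidence categories, recycled against
#'   `severity_grade`.
#' @param threshold reference-positive threshold on the total score.
#' @return `total_score()`: a tibble with columns `severity_score`,
#'   `incidence_score`, `total`, `risk_class`, `reference_positive`.
#' @export
total_score <- function(severity_grade, incidence, threshold = 4) {
  if (any(!severity_grade %in% 1:4)) {
    abort("severity grade must be an integer in 1..4")
  }
  inc <- incidence_score(incidence)
  total <- as.integer(severity_grade) * inc
  tibble(
    severity_score = as.integer(severity_grade),
    incidence_score = inc,
    total = total,
    risk_class = risk_class(total),
    reference_positive = reference_label(total, threshold)
  )
}

#' @rdname incidence_score
#' @return `reference_label()`: logical, `TRUE` for reference-positive
#'   (total >= threshold).
#' @export
reference_label <- function(total, threshold = 4) {
  total >= threshold
}

#' Score every drug in a panel
#'
#' Applies the severity x incidence scoring to a panel's drug table.
#'
#' @param panel a [drug_panel()].
#' @param threshold reference-positive threshold (default 4).
#' @return tibble with one row per drug: `drug`, `severity_score`,
#'   `incidence_score`, `total`, `risk_class`, `reference_positive`.
#' @examples
#' score_panel(bundled_panel())
#' @export
score_panel <- function(panel, threshold = 4) {
  d <- panel_drugs(panel)
  dplyr::bind_cols(
    tibble(drug = d$drug),
    total_score(d$severity_grade, d$incidence, threshold)
  )
}
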