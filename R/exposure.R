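#' Margin of safety (MOS)
#'
#' The margin of safety relates assay potency to clinical exposure:
#' `MOS = IC value / clinical C_max`, in consistent uM units.  An
#' IC15:C_max ratio below 1 flags potential clinical risk -- therapeutic
#' plasma concentrations reach the concentration producing a 15% decrement
#' in the assay readout.  Right-censored ICs (no crossing within the
#' tested range) yield a censored MOS for which only a lower bound
#' `limit / C_max` is known; by the censoring policy such drugs are
#' classified nontoxic within the assay range even when that lower bound
#' falls below the threshold, and the flag is carried in the output for
#' transparency.
#'
#' @param ic_uM IC value(s) in uM (`NA` where censored).
#' @param cmax_uM clinical peak plasma concentration(s), uM, positive.
#' @param censored logical, `TRUE` where the IC is right-censored.
#' @param limit_uM censoring limit(s) in uM.
#' @return `mos()`: a tibble with columns `mos` (`NA` when censored),
#'   `mos_censored`, and `mos_lower` (the ratio, or its lower bound when
#'   censored).
#' @examples
#' mos(2.71, 5.1)                          # paclitaxel, hIEC TEER
#' mos(NA, 145, censored = TRUE)           # ibuprofen: censored, bound ~0.69
#' mos_classify(mos(3.80, 0.5))            # gefitinib: MOS 7.6, nontoxic
#' @export
mos <- function(ic_uM, cmax_uM, censored = FALSE, limit_uM = 100) {
  if (any(!is.finite(cmax_uM)) || any(cmax_uM <= 0)) {
    abort("cmax_uM must be positive")
  }
  n <- max(length(ic_uM), length(cmax_uM), length(censored))
  ic_uM <- rep_len(ic_uM, n)
  cmax_uM <- rep_len(cmax_uM, n)
  censored <- rep_len(censored, n)
  limit_uM <- rep_len(limit_uM, n)
  if (any(!censored & (is.na(ic_uM) | ic_uM <= 0))) {
    abort("uncensored IC values must be positive")
  }
  ratio <- ifelse(censored, NA_real_, ic_uM / cmax_uM)
  tibble(mos = ratio,
         mos_censored = censored,
         mos_lower = ifelse(censored, limit_uM / cmax_uM, ratio))
}

#' @rdname mos
#' @param m a tibble from `mos()`, or a numeric vector of MOS ratios.
#' @param threshold risk threshold; strictly-below flags risk.
#' @return `mos_classify()`: logical, `TRUE` for predicted toxic
#'   (uncensored MOS strictly below `threshold`).
#' @export
mos_classify <- function(m, threshold = 1) {
  if (is.numeric(m)) m <- tibble(mos = m, mos_censored = FALSE)
  !m$mos_censored & !is.na(m$mos) & m$mos < threshold
}

#' Exposure-anchored classification of a panel
#'
#' Computes MOS ratios (IC15:C_max primary, IC50:C_max secondary) and the
#' MOS-rule predicted label for every drug in one model/assay combination.
#'
#' @param panel a [drug_panel()].
#' @param model `"hIEC"` or `"Caco-2"`.
#' @param assay `"TEER"` or `"ATP"`.
#' @param threshold MOS risk threshold (default 1).
#' @return tibble with one row per drug: `drug`, `cmax_uM`, `mos15`,
#'   `mos15_censored`, `mos15_lower`, `mos50`, `mos50_censored`,
#'   `mos50_lower`, `predicted_toxic_mos15`, `predicted_toxic_mos50`.
#' @examples
#' exposure_table(bundled_panel(), "hIEC", "TEER")
#' @export
exposure_table <- function(panel, model, assay, threshold = 1) {
  a <- panel_assays(panel)
  a <- a[a$model == model & a$assay == assay, ]
  if (nrow(a) == 0) {
    abort(paste0("no assay summaries for ", model, " ", assay))
  }
  d <- panel_drugs(panel)
  a <- dplyr::inner_join(a, d[, c("drug", "cmax_uM")], by = "drug")
  m15 <- mos(a$ic15_uM, a$cmax_uM, a$ic15_censored, a$censor_limit_uM)
  m50 <- mos(a$ic50_uM, a$cmax_uM, a$ic50_censored, a$censor_limit_uM)
  tibble(
    drug = a$drug, cmax_uM = a$cmax_uM,
    mos15 = m15$mos, mos15_censored = m15$mos_censored,
    mos15_lower = m15$mos_lower,
    mos50 = m50$mos, mos50_censored = m50$mos_censored,
    mos50_lower = m50$mos_lower,
    predicted_toxic_mos15 = mos_classify(m15, threshold),
    predicted_toxic_mos50 = mos_classify(m50, threshold)
  )
}
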