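#' Censorable concentrations
#'
#' IC values interpolated from fitted dose-response curves are only
#' observable inside the tested concentration range.  When the fitted curve
#' never crosses the target level below the highest tested dose, the IC is
#' *right-censored*: all that is known is that it exceeds the assay limit
#' (100 uM on the panel's dose grid).  Such values are carried through the
#' pipeline as a flag plus a numeric limit, never as a plug-in number.
#'
#' `censored_conc()` builds a concentration record; `parse_conc()` converts
#' the textual representation used in panel files (a number, or a
#' greater-than token such as `">100"`, `">100 uM"` or the typographic
#' variant `">100 μм"`) into its numeric parts, and
#' `format_conc()` is its inverse.
#'
#' @param value_uM numeric concentration in uM, `NA` when censored.
#' @param censored logical; `TRUE` when the value is only known to exceed
#'   `limit_uM`.
#' @param limit_uM censoring limit in uM (the highest tested dose).
#' @return `censored_conc()` returns a list with class `"censored_conc"`
#'   and fields `value_uM`, `censored`, `limit_uM`.  `parse_conc()` returns
#'   a tibble with those three columns, one row per input element.
#'   `format_conc()` returns a character vector.
#' @examples
#' parse_conc(c("2.71", ">100"))
#' format_conc(c(2.71, NA), c(FALSE, TRUE))
#' @export
censored_conc <- function(value_uM = NA_real_, censored = FALSE, limit_uM = 100) {
  stopifnot(length(censored) == 1L, is.logical(censored))
  if (!censored && (is.na(value_uM) || value_uM <= 0)) {
    abort("an uncensored concentration must be a positive number")
  }
  structure(
    list(value_uM = if (censored) NA_real_ else as.numeric(value_uM),
         censored = censored,
         limit_uM = as.numeric(limit_uM)),
    class = "censored_conc"
  )
}

#' @export
print.censored_conc <- function(x, ...) {
  cat(format_conc(x$value_uM, x$censored, x$limit_uM), "uM\n")
  invisible(x)
}

# regex accepting ">100", "> 100 uM", ">100 µM" and the Cyrillic-glyph
# variant seen in printed tables; case-insensitive, optional unit suffix
.censor_pattern <- "^>\\s*([0-9]+\\.?[0-9]*)\\s*(µm|μm|μм|um)?$"

#' @rdname censored_conc
#' @param x character (or numeric) vector of concentration entries.
#' @export
parse_conc <- function(x, limit_uM = 100) {
  x_chr <- trimws(as.character(x))
  cens <- grepl(.censor_pattern, x_chr, ignore.case = TRUE, perl = TRUE)
  lim <- rep(as.numeric(limit_uM), length(x_chr))
  lim[cens] <- as.numeric(sub(.censor_pattern, "\\1", x_chr[cens],
                              ignore.case = TRUE, perl = TRUE))
  val <- suppressWarnings(as.numeric(x_chr))
  val[cens] <- NA_real_
  bad <- !cens & is.na(val) & !is.na(x_chr) & nzchar(x_chr)
  if (any(bad)) {
    abort(paste0("unparseable concentration entries: ",
                 paste(unique(x_chr[bad]), collapse = ", ")))
  }
  tibble(value_uM = val, censored = cens, limit_uM = lim)
}

#' @rdname censored_conc
#' @param value,cens,limit vectors of parsed concentration parts.
#' @export
format_conc <- function(value, cens, limit = 100) {
  limit <- rep_len(limit, length(value))
  ifelse(cens, paste0(">", format(limit, trim = TRUE)),
         as.character(value))
}
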