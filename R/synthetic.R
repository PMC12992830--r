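#' Configuration for the synthetic dose-response generator
#'
#' Describes the simulated study: the 6-point dose grid (vehicle plus
#' 1-100 uM), four replicates per dose, multiplicative Gaussian noise on
#' the readout, model-specific baseline TEER windows (hIEC 80-240
#' Ohm.cm2; Caco-2 400-1,000 Ohm.cm2) and an arbitrary-unit luminescence
#' window for ATP assays, and a drug panel of 12 toxic (deep
#' dose-response drop) and 5 nontoxic (shallow drop) compounds with
#' clinical annotations drawn consistently with the ground-truth label.
#'
#' @param n_toxic,n_nontoxic number of drugs per ground-truth class
#'   (at least 2 each, so diagnostic evaluation is defined).
#' @param doses_uM dose grid including vehicle 0.
#' @param n_replicates replicates per dose.
#' @param noise_sd multiplicative noise s.d. as a fraction of signal
#'   (0.05 = 5%).
#' @param models,assays model/assay combinations to simulate.
#' @param baseline model -> baseline readout window (raw units) for TEER;
#'   ATP assays use `atp_baseline` for either model.
#' @param atp_baseline luminescence window, arbitrary units.
#' @param toxic_params,nontoxic_params per-class ranges (`c(lo, hi)`) for
#'   the true 4PL parameters `top`, `bottom`, `hill`, `log_ic`.
#' @param cmax_log10_range range of log10 C_max (uM) for synthetic drugs.
#' @param seed integer seed; mandatory, for reproducibility.
#' @return a list of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(
    n_toxic = 12, n_nontoxic = 5,
    doses_uM = c(0, 1, 5, 10, 50, 100),
    n_replicates = 4, noise_sd = 0.05,
    models = c("hIEC", "Caco-2"), assays = c("TEER", "ATP"),
    baseline = list("hIEC" = c(80, 240), "Caco-2" = c(400, 1000)),
    atp_baseline = c(1e5, 5e5),
    toxic_params = list(top = c(95, 105), bottom = c(0, 25),
                        hill = c(1, 3), log_ic = c(0, 1.3)),
    nontoxic_params = list(top = c(95, 105), bottom = c(55, 95),
                           hill = c(0.5, 2), log_ic = c(0.5, 1.5)),
    cmax_log10_range = c(-0.5, 2),
    seed) {
  if (missing(seed)) abort("a seed is required for reproducibility")
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (!0 %in% doses_uM) abort("dose grid must include the vehicle (0)")
  if (is.unsorted(doses_uM, strictly = TRUE)) {
    abort("doses must be strictly increasing")
  }
  structure(list(
    n_toxic = n_toxic, n_nontoxic = n_nontoxic, doses_uM = doses_uM,
    n_replicates = n_replicates, noise_sd = noise_sd,
    models = models, assays = assays, baseline = baseline,
    atp_baseline = atp_baseline,
    toxic_params = toxic_params, nontoxic_params = nontoxic_params,
    cmax_log10_range = cmax_log10_range, seed = as.integer(seed)
  ), class = "synthetic_panel_config")
}

#' Simulate one dose-response series
#'
#' Raw replicate readouts on the dose grid: a per-series baseline is
#' drawn uniformly from the baseline window, and each replicate response
#' is `baseline * 4PL(dose)/100 * (1 + eps)` with
#' `eps ~ N(0, noise_sd^2)` (truncated below at zero -- resistances and
#' luminescence are nonnegative).  With `noise_sd = 0` the normalized
#' responses lie exactly on the true curve.
#'
#' @param true_params named list/vector with `top`, `bottom`, `hill`,
#'   `log_ic` (see [fourpl()]).
#' @param doses_uM dose grid including vehicle 0.
#' @param n_replicates replicates per dose.
#' @param noise_sd multiplicative noise s.d. (fraction of signal).
#' @param baseline_range window for the raw vehicle-level readout.
#' @param seed optional integer seed for this series.
#' @return tibble with columns `dose_uM`, `replicate`, `response` (raw
#'   units); the true parameters and baseline are attached as attributes
#'   `true_params` and `baseline`.
#' @examples
#' s <- generate_series(list(top = 100, bottom = 0, hill = 1, log_ic = 1),
#'                      seed = 1)
#' head(s)
#' @export
generate_series <- function(true_params,
                            doses_uM = c(0, 1, 5, 10, 50, 100),
                            n_replicates = 4, noise_sd = 0.05,
                            baseline_range = c(80, 240), seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(true_params)
  baseline <- runif(1, baseline_range[1], baseline_range[2])
  grid <- expand.grid(replicate = seq_len(n_replicates), dose_uM = doses_uM)
  mu <- fourpl(grid$dose_uM, p$top, p$bottom, p$hill, p$log_ic)
  eps <- if (noise_sd == 0) 0 else rnorm(nrow(grid), 0, noise_sd)
  out <- tibble(
    dose_uM = grid$dose_uM,
    replicate = grid$replicate,
    response = pmax(baseline * mu / 100 * (1 + eps), 0)
  )
  out <- out[order(out$dose_uM, out$replicate), ]
  attr(out, "true_params") <- p
  attr(out, "baseline") <- baseline
  out
}

# draw a (grade, incidence) pair whose product is >= 4 (toxic) or <= 3
.draw_annotation <- function(toxic) {
  pool <- if (toxic) {
    list(c(2, "common"), c(2, "very common"), c(3, "common"),
         c(3, "very common"), c(4, "uncommon"), c(4, "common"))
  } else {
    list(c(1, "uncommon"), c(1, "common"), c(1, "very common"),
         c(2, "uncommon"), c(3, "uncommon"))
  }
  pool[[sample.int(length(pool), 1)]]
}

#' Simulate a full drug panel with known ground truth
#'
#' Draws true 4PL parameters per drug from its class range, simulates
#' raw series for every model/assay combination, then runs the summary
#' stage of the pipeline (normalization, percent reduction, optional 4PL
#' fit + IC interpolation) to produce a [drug_panel()] whose true labels
#' are known.  Toxic drugs have deep response drops (large reductions at
#' the top dose), nontoxic drugs shallow ones, so at moderate noise the
#' reduction rule should recover the labels.
#'
#' @param config a [synthetic_panel_config()].
#' @param compute_ic fit the 4PL and interpolate IC15/IC50 per series
#'   (`TRUE`, default); with `FALSE` the IC columns are left `NA`, which
#'   is faster when only reductions are needed.
#' @return a [drug_panel()]; the ground truth is attached as
#'   `attr(, "truth")`, a tibble with `drug`, `toxic` and the true
#'   parameters, and the raw series as `attr(, "series")`.
#' @examples
#' cfg <- synthetic_panel_config(n_toxic = 3, n_nontoxic = 3, seed = 7,
#'                               models = "hIEC", assays = "TEER")
#' p <- generate_panel(cfg, compute_ic = FALSE)
#' attr(p, "truth")
#' @export
generate_panel <- function(config, compute_ic = TRUE) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  if (config$n_toxic < 2 || config$n_nontoxic < 2) {
    abort("need at least 2 drugs per ground-truth class")
  }
  set.seed(config$seed)
  n <- config$n_toxic + config$n_nontoxic
  toxic <- rep(c(TRUE, FALSE), c(config$n_toxic, config$n_nontoxic))
  draw <- function(rng) runif(1, rng[1], rng[2])
  max_dose <- max(config$doses_uM)

  drugs <- vector("list", n)
  assay_rows <- list()
  series_store <- list()
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (toxic[i]) config$toxic_params else config$nontoxic_params
    pars <- lapply(cls, draw)
    ann <- .draw_annotation(toxic[i])
    name <- sprintf("drug_%02d", i)
    drugs[[i]] <- tibble(
      drug = name,
      class = if (toxic[i]) "synthetic-toxic" else "synthetic-nontoxic",
      severity_grade = as.numeric(ann[1]),
      incidence = ann[2],
      cmax_uM = 10^draw(config$cmax_log10_range),
      route = "unspecified"
    )
    truth[[i]] <- tibble(drug = name, toxic = toxic[i],
                         top = pars$top, bottom = pars$bottom,
                         hill = pars$hill, log_ic = pars$log_ic)
    for (model in config$models) {
      for (assay in config$assays) {
        rng <- if (assay == "TEER") config$baseline[[model]] else
          config$atp_baseline
        s <- generate_series(pars, config$doses_uM, config$n_replicates,
                             config$noise_sd, baseline_range = rng)
        series_store[[paste(name, model, assay)]] <- s
        ctrl <- mean(s$response[s$dose_uM == 0])
        red <- percent_reduction(
          ctrl, mean(s$response[s$dose_uM == max_dose]))
        if (compute_ic) {
          norm <- s
          norm$response <- normalize_to_control(s$response, ctrl)
          fit <- fit_4pl(norm)
          ic15 <- interpolate_ic(fit, 85, max_dose)
          ic50 <- interpolate_ic(fit, 50, max_dose)
        } else {
          ic15 <- list(value_uM = NA_real_, censored = FALSE)
          ic50 <- list(value_uM = NA_real_, censored = FALSE)
        }
        assay_rows[[length(assay_rows) + 1L]] <- tibble(
          drug = name, model = model, assay = assay,
          ic15_uM = ic15$value_uM, ic15_censored = ic15$censored,
          ic50_uM = ic50$value_uM, ic50_censored = ic50$censored,
          pct_reduction = red, censor_limit_uM = max_dose
        )
      }
    }
  }
  panel <- drug_panel(dplyr::bind_rows(drugs), dplyr::bind_rows(assay_rows))
  attr(panel, "truth") <- dplyr::bind_rows(truth)
  attr(panel, "series") <- series_store
  panel
}
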