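# Energy-efficacy and operational energy-footprint accounting.

#' Energy efficacy of a model
#'
#' \deqn{EFF(M, A) = \lambda M / A} estimates the number of
#' performance-metric units delivered per kW-h of a model's data-engineering
#' energy footprint.
#'
#' @param metricValue performance metric M, nominally in [0, 1].
#' @param footprintKwh total data-engineering footprint A in kW-h, > 0.
#' @param lambda scaling factor (default 100).
#' @param digits if non-NULL, round half away from zero to this many
#'   decimals for reporting.
#' @return the EFF value.
#' @examples
#' energyEfficacy(0.28, 170.74, digits = 2)  # 0.16
#' energyEfficacy(0.17, 39.8, digits = 2)    # 0.43
#' @export
energyEfficacy <- function(metricValue, footprintKwh, lambda = 100,
                           digits = NULL) {
  checkScalarNumber(metricValue, "metricValue")
  checkScalarNumber(lambda, "lambda")
  if (!is.numeric(footprintKwh) || length(footprintKwh) != 1L ||
      is.na(footprintKwh) || footprintKwh <= 0) {
    stopInput("footprintKwh must be a single number > 0")
  }
  eff <- lambda * metricValue / footprintKwh
  if (is.null(digits)) eff else roundHalfUp(eff, digits)
}

#' Total data-engineering footprint of a ledger
#'
#' @param ledger an [EnergyLedger-class].
#' @param digits if non-NULL, round half away from zero for reporting.
#' @return sum of the four CPA entries in kW-h.
#' @examples
#' ledgerTotal(EnergyLedger(11.6, 155.89, 0.063, 3.19), digits = 2)  # 170.74
#' @export
ledgerTotal <- function(ledger, digits = NULL) {
  validObject(ledger)
  total <- ledger@curationKwh + ledger@trainingKwh + ledger@evalRunKwh +
    ledger@evalManualKwh
  if (is.null(digits)) total else roundHalfUp(total, digits)
}

#' Monthly energy footprint of the inference computer
#'
#' \code{hoursPerMonth * modelRateKwhPerH}, i.e. 24 x 7 x 4 x p by default.
#'
#' @param profile a [PowerProfile-class].
#' @param digits optional reporting rounding.
#' @return kW-h per month.
#' @examples
#' monthlyModelFootprint(PowerProfile(0.210))  # 141.12
#' @export
monthlyModelFootprint <- function(profile, digits = NULL) {
  validObject(profile)
  v <- profile@hoursPerMonth * profile@modelRateKwhPerH
  if (is.null(digits)) v else roundHalfUp(v, digits)
}

#' Monthly and seasonal operational energy footprint of a deployment
#'
#' Monthly OEF = model monthly footprint + nLoggers x per-logger monthly
#' footprint; seasonal OEF = monthsPerSeason x monthly OEF. The per-logger
#' monthly amount is rounded to 2 decimals before multiplying by the logger
#' count, matching the reporting convention of the published arithmetic
#' (672 x 0.003 = 2.016 -> 2.02, so 141.12 + 10 x 2.02 = 161.32); the
#' unrounded value is also returned.
#'
#' @param profile a [PowerProfile-class].
#' @return named list: \code{monthlyKwh}, \code{seasonalKwh},
#'   \code{perLoggerMonthlyKwh} (rounded), \code{perLoggerMonthlyKwhExact}.
#' @examples
#' pipelineOEF(PowerProfile(0.210))$monthlyKwh  # 161.32
#' @export
pipelineOEF <- function(profile) {
  validObject(profile)
  perLoggerExact <- profile@hoursPerMonth * profile@loggerRateKwhPerH
  perLogger <- roundHalfUp(perLoggerExact, 2)
  monthly <- monthlyModelFootprint(profile) + profile@nLoggers * perLogger
  list(
    monthlyKwh = monthly,
    seasonalKwh = profile@monthsPerSeason * monthly,
    perLoggerMonthlyKwh = perLogger,
    perLoggerMonthlyKwhExact = perLoggerExact
  )
}

#' Manual labeling rate
#'
#' @param nLabels number of objects labeled.
#' @param hours physical hours spent, > 0.
#' @param digits optional reporting rounding.
#' @return labels per hour.
#' @examples
#' labelingRate(23173, 220.33, digits = 2)  # 105.17
#' @export
labelingRate <- function(nLabels, hours, digits = NULL) {
  checkScalarNumber(nLabels, "nLabels", min = 0)
  if (!is.numeric(hours) || length(hours) != 1L || is.na(hours) || hours <= 0) {
    stopInput("hours must be a single number > 0")
  }
  v <- nLabels / hours
  if (is.null(digits)) v else roundHalfUp(v, digits)
}

#' Energy-efficacy table across models and metrics
#'
#' Applies [energyEfficacy()] to every (metric, footprint) pair. Metric
#' values are first rounded half away from zero to 2 decimals, matching the
#' printed-table convention where EFF cells are computed from the reported
#' (2-decimal) metric values.
#'
#' @param metrics data.frame with one row per model and numeric metric
#'   columns (e.g. precision, recall, f1, iou); a \code{model} column, if
#'   present, is carried through.
#' @param footprints numeric vector of total footprints (kW-h), one per row.
#' @param lambda scaling factor.
#' @return data.frame of EFF values rounded to 2 decimals.
#' @export
effTable <- function(metrics, footprints, lambda = 100) {
  metricCols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (length(footprints) != nrow(metrics)) {
    stopInput("need one footprint per metrics row")
  }
  out <- metrics[, setdiff(names(metrics), metricCols), drop = FALSE]
  for (col in metricCols) {
    out[[col]] <- vapply(seq_len(nrow(metrics)), function(i) {
      energyEfficacy(roundHalfUp(metrics[[col]][i], 2), footprints[i],
                     lambda = lambda, digits = 2)
    }, numeric(1))
  }
  out
}
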