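# CSV/JSON input-output. Dialects (UTF-8, header row, period decimals):
#   growth/segregation CSV: replicate,time_h,cfu_total_per_ml,cfu_plasmid_per_ml,volume_ml
#   counts CSV:             culture,mutants,final_cfu_per_ml,volume_ml,plating_fraction
#   profile CSV:            time_h,size,death_rate   (death_rate on the row that
#                           closes the interval; empty on the first row)

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
}

#' Read segregation/growth time series from CSV
#'
#' One row per (replicate, timepoint); counts are per mL and converted to
#' whole-culture cells via `volume_ml`. Malformed rows are reported with line
#' numbers (line 1 is the header).
#'
#' @param path CSV file with columns `replicate,time_h,cfu_total_per_ml,
#'   cfu_plasmid_per_ml,volume_ml`.
#' @return named list of [SegregationSeries-class], one per replicate.
#' @export
readGrowthCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("replicate", "time_h", "cfu_total_per_ml",
                        "cfu_plasmid_per_ml", "volume_ml"), path)
  line <- seq_len(nrow(df)) + 1L
  bad <- which(!is.finite(df$cfu_total_per_ml) | df$cfu_total_per_ml <= 0 |
               !is.finite(df$cfu_plasmid_per_ml) | df$cfu_plasmid_per_ml <= 0 |
               df$cfu_plasmid_per_ml > df$cfu_total_per_ml |
               !is.finite(df$volume_ml) | df$volume_ml <= 0)
  if (length(bad))
    .stopf("%s: invalid counts on line(s) %s", path,
           paste(line[bad], collapse = ", "))
  dup <- duplicated(df[c("replicate", "time_h")])
  if (any(dup))
    .stopf("%s: duplicate (replicate, time) key on line(s) %s", path,
           paste(line[dup], collapse = ", "))
  out <- lapply(split(df, df$replicate), function(g) {
    g <- g[order(g$time_h), ]
    SegregationSeries(g$time_h, g$cfu_total_per_ml * g$volume_ml,
                      g$cfu_plasmid_per_ml * g$volume_ml)
  })
  out
}

#' Read fluctuation-assay mutant counts from CSV
#'
#' @param path CSV file with columns `culture,mutants,final_cfu_per_ml,
#'   volume_ml,plating_fraction` (final CFU and plating fraction constant
#'   across rows).
#' @param initialSize inoculum (cells), not part of the file format.
#' @return a [FluctuationDataset-class].
#' @export
readCountsCsv <- function(path, initialSize = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("culture", "mutants", "final_cfu_per_ml", "volume_ml",
                        "plating_fraction"), path)
  line <- seq_len(nrow(df)) + 1L
  bad <- which(!is.finite(df$mutants) | df$mutants < 0 |
               df$mutants != floor(df$mutants))
  if (length(bad))
    .stopf("%s: invalid mutant count on line(s) %s", path,
           paste(line[bad], collapse = ", "))
  FluctuationDataset(df$mutants,
                     finalSize = df$final_cfu_per_ml[1] * df$volume_ml[1],
                     initialSize = initialSize,
                     platingFraction = df$plating_fraction[1])
}

#' Write / read a GrowthProfile as CSV
#'
#' Columns `time_h,size,death_rate`, the death rate sitting on the row that
#' closes its interval (first row empty). Writing then reading is the
#' identity.
#'
#' @param profile a [GrowthProfile-class].
#' @param path output CSV path.
#' @return `writeProfileCsv` the path, invisibly; `readProfileCsv` the profile.
#' @export
writeProfileCsv <- function(profile, path) {
  stopifnot(is(profile, "GrowthProfile"))
  df <- data.frame(time_h = profile@times, size = profile@sizes,
                   death_rate = c(NA, profile@deathRates))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeProfileCsv
#' @export
readProfileCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .requireColumns(df, c("time_h", "size", "death_rate"), path)
  GrowthProfile(df$time_h, df$size, df$death_rate[-1])
}

#' Write per-interval death-rate table with a JSON fit sidecar
#'
#' The tabular output of the segregation pipeline: one row per interval with
#' generations and raw/capped death rates, plus `<path>.json` carrying the
#' fitted retention parameter and diagnostics.
#'
#' @param profile a [GrowthProfile-class] from [profileFromSegregation()].
#' @param param the fitted [SegregationParameter-class].
#' @param path output CSV path.
#' @param replicate replicate label for the CSV.
#' @return the path, invisibly.
#' @export
writeDeathRateCsv <- function(profile, param, path, replicate = "r1") {
  t <- profile@times
  md <- profile@metadata
  df <- data.frame(replicate = replicate,
                   interval_start_h = t[-length(t)], interval_end_h = t[-1],
                   generations = if (!is.null(md$generations)) md$generations else NA,
                   death_rate_raw = if (!is.null(md$rawDeathRates)) md$rawDeathRates else NA,
                   death_rate = profile@deathRates)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(sigma = param@sigma, res = param@res,
                            diagnostics = param@diagnostics),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a rate estimate as JSON
#'
#' @param estimate a [RateEstimate-class].
#' @param path output JSON path.
#' @param extras named list merged into the JSON (settings echo, diagnostics).
#' @return `writeEstimateJson` the path invisibly; `readEstimateJson` a
#'   [RateEstimate-class].
#' @export
writeEstimateJson <- function(estimate, path, extras = list()) {
  stopifnot(is(estimate, "RateEstimate"))
  payload <- c(list(rate = estimate@rate, ciLow = estimate@ciLow,
                    ciHigh = estimate@ciHigh, method = estimate@method,
                    mHat = estimate@mHat), extras)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEstimateJson
#' @export
readEstimateJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RateEstimate(rate = x$rate, ciLow = x$ciLow, ciHigh = x$ciHigh,
               method = x$method, mHat = if (is.null(x$mHat)) NA_real_ else x$mHat)
}
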