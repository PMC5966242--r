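# Accessor generics and show methods. Slot access from user code should go
# through these.

#' @name accessors
#' @title Accessors for deathFluct domain objects
#' @description Small accessor functions returning slot contents of the
#'   domain classes; user code should prefer these over direct slot access.
#' @param x a deathFluct domain object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("popSizes", function(x) standardGeneric("popSizes"))
#' @rdname accessors
#' @export
setGeneric("deathRates", function(x) standardGeneric("deathRates"))
#' @rdname accessors
#' @export
setGeneric("initialSize", function(x) standardGeneric("initialSize"))
#' @rdname accessors
#' @export
setGeneric("plasmidFraction", function(x) standardGeneric("plasmidFraction"))
#' @rdname accessors
#' @export
setGeneric("retentionSigma", function(x) standardGeneric("retentionSigma"))
#' @rdname accessors
#' @export
setGeneric("residualReplication", function(x) standardGeneric("residualReplication"))
#' @rdname accessors
#' @export
setGeneric("mutantCounts", function(x) standardGeneric("mutantCounts"))
#' @rdname accessors
#' @export
setGeneric("finalSize", function(x) standardGeneric("finalSize"))
#' @rdname accessors
#' @export
setGeneric("platingFraction", function(x) standardGeneric("platingFraction"))
#' @rdname accessors
#' @export
setGeneric("rateValue", function(x) standardGeneric("rateValue"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("estMethod", function(x) standardGeneric("estMethod"))
#' @rdname accessors
#' @export
setGeneric("mHat", function(x) standardGeneric("mHat"))
#' @rdname accessors
#' @export
setGeneric("meanMutants", function(x) standardGeneric("meanMutants"))
#' @rdname accessors
#' @export
setGeneric("perCultureMutants", function(x) standardGeneric("perCultureMutants"))
#' @rdname accessors
#' @export
setGeneric("ldProbs", function(x) standardGeneric("ldProbs"))
#' @rdname accessors
#' @export
setGeneric("tailMass", function(x) standardGeneric("tailMass"))

#' @rdname accessors
#' @export
setMethod("timePoints", "GrowthProfile", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("timePoints", "SegregationSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("popSizes", "GrowthProfile", function(x) x@sizes)
#' @rdname accessors
#' @export
setMethod("popSizes", "SegregationSeries", function(x) x@total)
#' @rdname accessors
#' @export
setMethod("deathRates", "GrowthProfile", function(x) x@deathRates)
#' @rdname accessors
#' @export
setMethod("initialSize", "GrowthProfile", function(x) x@initialSize)
#' @rdname accessors
#' @export
setMethod("initialSize", "FluctuationDataset", function(x) x@initialSize)
#' @rdname accessors
#' @export
setMethod("plasmidFraction", "SegregationSeries",
          function(x) x@plasmidBearing / x@total)
#' @rdname accessors
#' @export
setMethod("retentionSigma", "SegregationParameter", function(x) x@sigma)
#' @rdname accessors
#' @export
setMethod("residualReplication", "SegregationParameter", function(x) x@res)
#' @rdname accessors
#' @export
setMethod("mutantCounts", "FluctuationDataset", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("finalSize", "FluctuationDataset", function(x) x@finalSize)
#' @rdname accessors
#' @export
setMethod("finalSize", "GrowthProfile", function(x) x@sizes[length(x@sizes)])
#' @rdname accessors
#' @export
setMethod("platingFraction", "FluctuationDataset", function(x) x@platingFraction)
#' @rdname accessors
#' @export
setMethod("rateValue", "RateEstimate", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("confInt", "RateEstimate", function(x) c(x@ciLow, x@ciHigh))
#' @rdname accessors
#' @export
setMethod("estMethod", "RateEstimate", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("mHat", "RateEstimate", function(x) x@mHat)
#' @rdname accessors
#' @export
setMethod("meanMutants", "EvolvabilitySummary", function(x) x@meanMutants)
#' @rdname accessors
#' @export
setMethod("perCultureMutants", "EvolvabilitySummary", function(x) x@perCulture)
#' @rdname accessors
#' @export
setMethod("ldProbs", "LDDistribution", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("tailMass", "LDDistribution", function(x) x@tailMass)

setMethod("show", "GrowthProfile", function(object) {
  cat("GrowthProfile with", length(object@times), "timepoints\n")
  cat("  times (h):  ", paste(signif(object@times, 4), collapse = ", "), "\n")
  cat("  sizes:      ", paste(signif(object@sizes, 3), collapse = ", "), "\n")
  cat("  death rates:", paste(signif(object@deathRates, 3), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "SegregationSeries", function(object) {
  cat("SegregationSeries with", length(object@times), "timepoints\n")
  cat("  times (h):        ", paste(signif(object@times, 4), collapse = ", "), "\n")
  cat("  total:            ", paste(signif(object@total, 3), collapse = ", "), "\n")
  cat("  plasmid fraction: ",
      paste(signif(plasmidFraction(object), 3), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "SegregationParameter", function(object) {
  cat(sprintf("SegregationParameter: sigma = %.6f (res = %.4f)\n",
              object@sigma, object@res))
  cat(sprintf("  plasmid-bearing fraction retained per generation: %.4f\n",
              2^object@sigma))
  invisible(object)
})

setMethod("show", "FluctuationDataset", function(object) {
  cat("FluctuationDataset:", length(object@counts), "parallel cultures\n")
  cat(sprintf("  final size %.3g cells, inoculum %.3g, plating fraction %.3g\n",
              object@finalSize, object@initialSize, object@platingFraction))
  cat("  mutant counts: median", median(object@counts),
      "max", max(object@counts), "zeros", sum(object@counts == 0), "\n")
  invisible(object)
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate (%s): %.3g per division [%.3g, %.3g]\n",
              object@method, object@rate, object@ciLow, object@ciHigh))
  if (is.finite(object@mHat))
    cat(sprintf("  implied mutational events per culture m = %.3g\n", object@mHat))
  invisible(object)
})

setMethod("show", "EvolvabilitySummary", function(object) {
  cat(sprintf("EvolvabilitySummary (%s): mean %.3g mutants per culture (n = %d)\n",
              object@source, object@meanMutants, length(object@perCulture)))
  invisible(object)
})

setMethod("show", "LDDistribution", function(object) {
  cat(sprintf("LDDistribution: m = %.4g, kmax = %d, tail mass %.3g\n",
              object@m, as.integer(object@kmax), object@tailMass))
  invisible(object)
})

setMethod("show", "SimulationSettings", function(object) {
  cat(sprintf("SimulationSettings: %s algorithm, seed %s, scale %.3g\n",
              object@algorithm,
              ifelse(is.na(object@seed), "unset", format(object@seed)),
              object@scale))
  invisible(object)
})

setMethod("show", "InferenceSettings", function(object) {
  cat(sprintf("InferenceSettings: %s, %d sims/rate, smoothing %.3g, %s\n",
              object@distance, as.integer(object@simsPerRate), object@smoothing,
              if (length(object@rateGrid))
                sprintf("grid %d points [%.3g, %.3g]", length(object@rateGrid),
                        min(object@rateGrid), max(object@rateGrid))
              else "auto grid"))
  invisible(object)
})
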