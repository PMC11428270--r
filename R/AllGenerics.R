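#' @rdname StromaCohort
#' @export
setGeneric("cohortDesign", function(x, ...) standardGeneric("cohortDesign"))

#' @rdname StromaCohort
#' @export
setGeneric("stromaSamples", function(x, ...) standardGeneric("stromaSamples"))

#' @rdname StromaCohort
#' @export
setGeneric("epitheliumSamples",
           function(x, ...) standardGeneric("epitheliumSamples"))

#' @rdname StromaCohort
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname housekeepingNormalize
#' @export
setGeneric("housekeepingNormalize", function(x, housekeepingProbe = "217398_x_at")
    standardGeneric("housekeepingNormalize"))

#' @rdname seRatio
#' @export
setGeneric("seRatio", function(x, probes = NULL,
                               mode = c("mean_of_paired_ratios",
                                        "ratio_of_means"), ...)
    standardGeneric("seRatio"))

#' @rdname anchorCorrelation
#' @export
setGeneric("anchorCorrelation",
           function(x, anchorProbe, probes = NULL, samples = NULL, ...)
    standardGeneric("anchorCorrelation"))

#' @rdname screenGenes
#' @export
setGeneric("screenGenes", function(x, config, ...)
    standardGeneric("screenGenes"))

#' @rdname ScreenResult-accessors
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname ScreenResult-accessors
#' @export
setGeneric("screenConfig", function(x) standardGeneric("screenConfig"))

#' @rdname overlapWithReference
#' @export
setGeneric("overlapWithReference",
           function(screen, reference, rMin = NULL, rule = c("best_probe",
                                                             "any_probe"))
    standardGeneric("overlapWithReference"))

#' @rdname subgroupMeanSE
#' @export
setGeneric("subgroupMeanSE", function(screen, reference, rMin = NULL,
                                      rule = c("best_probe", "any_probe"))
    standardGeneric("subgroupMeanSE"))

#' @rdname subtypeRestrictedScreen
#' @export
setGeneric("subtypeRestrictedScreen",
           function(x, subtype = "TNBC", anchorProbe, rSubsetMin = 0.9,
                    rFullMax = 0.6)
    standardGeneric("subtypeRestrictedScreen"))

#' @rdname ReferenceGeneSet
#' @export
setGeneric("refGenes", function(x) standardGeneric("refGenes"))

#' @rdname ReferenceGeneSet
#' @export
setGeneric("refSourceSE", function(x) standardGeneric("refSourceSE"))

#' @rdname simulateCohort
#' @export
setGeneric("simulateCohort", function(params, ...)
    standardGeneric("simulateCohort"))
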