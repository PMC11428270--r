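#' Housekeeping (GAPDH) correction
#'
#' Divides every value in each sample by that sample's intensity of a single
#' housekeeping probe, the GAPDH probe \code{217398_x_at} by default.  After
#' correction the housekeeping probe's row is exactly 1 in every sample, the
#' operation is idempotent, and any per-sample positive rescaling of the raw
#' data (array scale effects) is removed.  All downstream statistics (SE
#' ratios, anchor correlations, expression-amount ranking) are computed on
#' corrected values.
#'
#' @param x a [StromaCohort-class] (any SummarizedExperiment with an
#'   \code{exprs} assay also works)
#' @param housekeepingProbe probe id of the housekeeping gene; must be
#'   present with a strictly positive value in every sample
#' @return the cohort with corrected intensities;
#'   \code{isNormalized()} becomes \code{TRUE} and
#'   \code{metadata()$housekeeping_probe} records the probe used
#' @examples
#' sim <- simulateCohort(SimParams(nTumors = 4, nBackground = 5, seed = 1))
#' norm <- housekeepingNormalize(sim$cohort)
#' range(assay(norm, "exprs")["217398_x_at", ])  # exactly 1
#' @export
setMethod("housekeepingNormalize", "StromaCohort",
    function(x, housekeepingProbe = "217398_x_at") {
    if (!housekeepingProbe %in% rownames(x))
        stop("housekeeping probe '", housekeepingProbe,
             "' not present in the matrix")
    m <- assay(x, "exprs")
    hk <- m[housekeepingProbe, ]
    bad <- which(!is.finite(hk) | hk <= 0)
    if (length(bad))
        stop("housekeeping value not strictly positive in sample '",
             colnames(m)[bad[1L]], "'")
    assay(x, "exprs") <- sweep(m, 2L, hk, "/")
    metadata(x)$normalized <- TRUE
    metadata(x)$housekeeping_probe <- housekeepingProbe
    validObject(x)
    x
})
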