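#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.COMPARTMENTS <- c("stroma", "epithelium")
.SUBTYPES <- c("luminal", "HER2", "TNBC", "unknown")
.TIERS <- c("CAFG", "semi_CAFG", "L_CAFG")

#' StromaCohort: paired stroma/epithelium expression cohort
#'
#' A \linkS4class{SummarizedExperiment} holding probe-level linear-scale
#' intensities (assay \code{"exprs"}) for microdissected tumors profiled in
#' two compartments.  \code{colData} carries \code{tumor_id},
#' \code{compartment} (\code{"stroma"} or \code{"epithelium"}) and
#' \code{subtype} (\code{"luminal"}, \code{"HER2"}, \code{"TNBC"} or
#' \code{"unknown"}); \code{rowData} carries \code{gene_symbol}.  Each tumor
#' has exactly one sample per compartment; tumors missing a compartment are
#' dropped (and recorded) at construction.
#'
#' @aliases StromaCohort-class
#' @seealso [StromaCohort()] the constructor, [cohortDesign()],
#'   [housekeepingNormalize()], [screenGenes()]
#' @exportClass StromaCohort
setClass("StromaCohort", contains = "SummarizedExperiment")

.validStromaCohort <- function(object) {
    msg <- character()
    if (!"exprs" %in% assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        x <- assay(object, "exprs")
        if (!is.numeric(x))
            msg <- c(msg, "assay 'exprs' must be numeric")
        else {
            if (any(!is.finite(x)))
                msg <- c(msg, "assay 'exprs' contains non-finite values")
            else if (any(x < 0))
                msg <- c(msg, "assay 'exprs' contains negative values")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    cd <- colData(object)
    need <- c("tumor_id", "compartment", "subtype")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must contain",
                            paste(need, collapse = ", ")))
    else {
        if (!all(cd$compartment %in% .COMPARTMENTS))
            msg <- c(msg, "compartment must be 'stroma' or 'epithelium'")
        if (!all(cd$subtype %in% .SUBTYPES))
            msg <- c(msg, paste("subtype must be one of",
                                paste(.SUBTYPES, collapse = ", ")))
        key <- paste(cd$tumor_id, cd$compartment)
        if (anyDuplicated(key))
            msg <- c(msg, paste0("duplicated (tumor_id, compartment) pair: ",
                                 key[duplicated(key)][1L]))
    }
    if (!"gene_symbol" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain gene_symbol")
    if (length(msg)) msg else TRUE
}
setValidity("StromaCohort", .validStromaCohort)

#' Screening configuration
#'
#' Thresholds and settings for the CAFG screen: the anchor probe (the SPARC
#' role; \code{anchorProbe}), the R-index thresholds (\code{rStrong},
#' \code{rMid}, \code{rWeak}; defaults 0.9 / 0.8 / 0.6, all inclusive), the
#' SE-ratio tier boundaries (\code{seHigh} = 10, \code{seMid} = 5, both
#' inclusive), the reference sample used for expression-amount ranking
#' (the GSM272720 role; \code{NA} ranks by mean stromal expression), and the
#' SE-ratio estimator (\code{ratioMode}, \code{"mean_of_paired_ratios"} or
#' \code{"ratio_of_means"}).
#'
#' @aliases ScreenConfig-class
#' @exportClass ScreenConfig
setClass("ScreenConfig",
    representation(anchorProbe = "character",
                   rStrong = "numeric", rMid = "numeric", rWeak = "numeric",
                   seHigh = "numeric", seMid = "numeric",
                   referenceSample = "character",
                   ratioMode = "character"),
    prototype(rStrong = 0.9, rMid = 0.8, rWeak = 0.6,
              seHigh = 10, seMid = 5,
              referenceSample = NA_character_,
              ratioMode = "mean_of_paired_ratios"))

setValidity("ScreenConfig", function(object) {
    msg <- character()
    if (length(object@anchorProbe) != 1L || is.na(object@anchorProbe) ||
        !nzchar(object@anchorProbe))
        msg <- c(msg, "anchorProbe must be a single non-empty probe id")
    r <- c(object@rWeak, object@rMid, object@rStrong)
    if (any(is.na(r)) || r[1L] <= 0 || any(diff(r) < 0) || r[3L] > 1)
        msg <- c(msg, "need 0 < rWeak <= rMid <= rStrong <= 1")
    if (is.na(object@seMid) || is.na(object@seHigh) ||
        object@seMid <= 0 || object@seMid >= object@seHigh)
        msg <- c(msg, "need 0 < seMid < seHigh")
    if (!object@ratioMode %in% c("mean_of_paired_ratios", "ratio_of_means"))
        msg <- c(msg, "ratioMode must be 'mean_of_paired_ratios' or 'ratio_of_means'")
    if (length(msg)) msg else TRUE
})

#' Result of a CAFG screen
#'
#' One row per probe with the SE ratio, the anchor correlation (R-index),
#' the CAFG tier, mean stromal expression, the expression amount in the
#' reference sample and the rank by that amount.  Rows are ordered by rank.
#' Retrieve the table with [screenTable()] and the settings with
#' [screenConfig()].
#'
#' @aliases ScreenResult-class
#' @exportClass ScreenResult
setClass("ScreenResult",
    representation(table = "DataFrame", config = "ScreenConfig",
                   nTumors = "integer", stromaSamples = "character"))

setValidity("ScreenResult", function(object) {
    need <- c("probe_id", "gene_symbol", "se_ratio", "anchor_r", "tier",
              "mean_stroma_expr", "ref_expression", "rank_by_expression")
    if (!all(need %in% colnames(object@table)))
        return(paste("screen table must contain columns:",
                     paste(setdiff(need, colnames(object@table)),
                           collapse = ", ")))
    r <- object@table$anchor_r
    if (any(!is.na(r) & (r < -1 - 1e-12 | r > 1 + 1e-12)))
        return("anchor_r outside [-1, 1]")
    se <- object@table$se_ratio
    if (any(!is.na(se) & se <= 0))
        return("se_ratio must be positive where defined")
    TRUE
})

#' Reference gene set
#'
#' A named external gene list (for example the CRC-derived CAFG, semi-CAFG
#' and L-CAFG lists) used for cross-cohort overlap and subgroup SE averages.
#' \code{sourceSE} optionally carries the SE ratios reported for the genes in
#' their cohort of origin.
#'
#' @aliases ReferenceGeneSet-class
#' @exportClass ReferenceGeneSet
setClass("ReferenceGeneSet",
    representation(name = "character", genes = "character",
                   sourceSE = "numeric"))

setValidity("ReferenceGeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@genes) == 0L)
        msg <- c(msg, "genes must be non-empty")
    if (anyDuplicated(object@genes))
        msg <- c(msg, paste0("duplicated gene symbol: ",
                             object@genes[duplicated(object@genes)][1L]))
    if (length(object@sourceSE) &&
        !all(names(object@sourceSE) %in% object@genes))
        msg <- c(msg, "sourceSE names must be a subset of genes")
    if (length(msg)) msg else TRUE
})

#' Cross-cohort overlap report
#'
#' Result of [overlapWithReference()]: how many reference genes are on the
#' chip, how many pass the anchor-correlation threshold, the passing
#' fraction, and the mean SE ratio of the passing genes.
#'
#' @aliases OverlapReport-class
#' @exportClass OverlapReport
setClass("OverlapReport",
    representation(referenceName = "character", rMin = "numeric",
                   nReference = "integer", nOnChip = "integer",
                   nPassing = "integer", fractionPassing = "numeric",
                   meanSEPassing = "numeric", passingGenes = "character",
                   flagged = "logical"))

#' Simulation parameters for a synthetic paired-compartment cohort
#'
#' Defines the planted structure of a simulated cohort: cohort size, the
#' anchor-correlated stromal block driven by a per-tumor latent
#' CAF-activation factor, a subtype-restricted block synchronized with that
#' factor only in subtype-labelled tumors, per-gene target SE ratios
#' (\code{rho}), latent-factor loadings (\code{lambda}), multiplicative
#' log-normal noise, a constant housekeeping probe and per-sample scale
#' jitter.  Construct with [SimParams()].
#'
#' @aliases SimParams-class
#' @exportClass SimParams
setClass("SimParams",
    representation(nTumors = "integer", nBackground = "integer",
                   nAnchorBlock = "integer", nSubtypeBlock = "integer",
                   nSubtypeTumors = "integer", subtype = "character",
                   anchorRho = "numeric", anchorLambda = "numeric",
                   blockLambda = "numeric", blockRho = "numeric",
                   subtypeLambda = "numeric", subtypeRho = "numeric",
                   backgroundRho = "numeric",
                   baselineLog2Range = "numeric",
                   noiseSigmaLog2 = "numeric",
                   housekeepingValue = "numeric",
                   housekeepingProbe = "character",
                   sampleScaleSigmaLog2 = "numeric",
                   seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    if (object@nTumors < 2L)
        msg <- c(msg, "nTumors must be at least 2")
    if (object@nSubtypeTumors > object@nTumors)
        msg <- c(msg, "nSubtypeTumors cannot exceed nTumors")
    if (object@nSubtypeTumors < 0L || object@nBackground < 0L ||
        object@nAnchorBlock < 0L || object@nSubtypeBlock < 0L)
        msg <- c(msg, "gene/tumor counts must be non-negative")
    for (nm in c("anchorRho", "blockRho", "subtypeRho", "backgroundRho")) {
        v <- slot(object, nm)
        if (length(v) && any(!is.finite(v) | v <= 0))
            msg <- c(msg, paste(nm, "must be strictly positive"))
    }
    for (nm in c("anchorLambda", "blockLambda", "subtypeLambda")) {
        v <- slot(object, nm)
        if (length(v) && any(!is.finite(v) | v < 0))
            msg <- c(msg, paste(nm, "must be non-negative"))
    }
    if (object@noiseSigmaLog2 < 0 || object@sampleScaleSigmaLog2 < 0)
        msg <- c(msg, "noise standard deviations must be >= 0")
    if (object@housekeepingValue <= 0)
        msg <- c(msg, "housekeepingValue must be positive")
    if (length(object@baselineLog2Range) != 2L ||
        diff(object@baselineLog2Range) < 0)
        msg <- c(msg, "baselineLog2Range must be an increasing pair")
    if (length(msg)) msg else TRUE
})
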