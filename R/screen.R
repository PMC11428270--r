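#' Create a screening configuration
#'
#' @param anchorProbe probe id of the anchor stromal marker (the SPARC
#'   role; \code{ACTA2} is the usual alternative anchor)
#' @param rStrong,rMid,rWeak R-index thresholds, all inclusive
#'   ("0.9 or beyond"); defaults 0.9, 0.8, 0.6
#' @param seHigh,seMid SE-ratio tier boundaries, inclusive
#'   ("10 or beyond", "5 or beyond and below 10"); defaults 10 and 5
#' @param referenceSample stroma sample id used for expression-amount
#'   ranking (the GSM272720 role); \code{NA} ranks by mean stromal
#'   expression
#' @param ratioMode SE-ratio estimator: \code{"mean_of_paired_ratios"}
#'   (default; pairing controls inter-tumor scale) or
#'   \code{"ratio_of_means"}
#' @return a validated [ScreenConfig-class]
#' @examples
#' ScreenConfig(anchorProbe = "SPARC_at")
#' @export
ScreenConfig <- function(anchorProbe, rStrong = 0.9, rMid = 0.8,
                         rWeak = 0.6, seHigh = 10, seMid = 5,
                         referenceSample = NA_character_,
                         ratioMode = c("mean_of_paired_ratios",
                                       "ratio_of_means")) {
    new("ScreenConfig", anchorProbe = as.character(anchorProbe),
        rStrong = rStrong, rMid = rMid, rWeak = rWeak,
        seHigh = seHigh, seMid = seMid,
        referenceSample = as.character(referenceSample),
        ratioMode = match.arg(ratioMode))
}

#' @export
setMethod("show", "ScreenConfig", function(object) {
    cat("ScreenConfig: anchor", object@anchorProbe,
        "| R thresholds", object@rStrong, object@rMid, object@rWeak,
        "| SE tiers", object@seHigh, object@seMid,
        "| mode", object@ratioMode, "\n")
    if (!is.na(object@referenceSample))
        cat("  reference sample:", object@referenceSample, "\n")
    invisible(NULL)
})

#' Stroma-to-epithelium (SE) expression ratio
#'
#' The stroma-specificity statistic, computed on housekeeping-corrected
#' intensities over the paired design.  Two estimators:
#' \code{mean_of_paired_ratios} averages the per-tumor stroma/epithelium
#' ratios; \code{ratio_of_means} divides the mean stromal by the mean
#' epithelial intensity.  In paired mode a tumor whose epithelium value is 0
#' is skipped (with a warning naming the affected probes); a probe with no
#' usable tumor is returned as \code{NA}.
#'
#' @param x a [StromaCohort-class]
#' @param probes probe ids (default: all probes)
#' @param mode SE-ratio estimator
#' @param ... unused
#' @return named numeric vector of SE ratios (NA where undefined)
#' @examples
#' sim <- simulateCohort(SimParams(nTumors = 6, nBackground = 4,
#'                                 noiseSigmaLog2 = 0, seed = 1))
#' norm <- housekeepingNormalize(sim$cohort)
#' seRatio(norm, probes = "SPARC_at")
#' @export
setMethod("seRatio", "StromaCohort",
    function(x, probes = NULL,
             mode = c("mean_of_paired_ratios", "ratio_of_means"), ...) {
    mode <- match.arg(mode)
    if (is.null(probes)) probes <- rownames(x)
    miss <- setdiff(probes, rownames(x))
    if (length(miss))
        stop("probe(s) not in matrix: ", paste(miss, collapse = ", "))
    d <- cohortDesign(x)
    S <- assay(x, "exprs")[probes, d$stroma_sample_id, drop = FALSE]
    E <- assay(x, "exprs")[probes, d$epithelium_sample_id, drop = FALSE]
    if (mode == "ratio_of_means") {
        denom <- rowMeans(E)
        se <- rowMeans(S) / denom
        se[denom == 0] <- NA_real_
    } else {
        ratio <- S / E            # Inf/NaN where epithelium is 0
        ok <- E > 0
        se <- rowSums(ifelse(ok, ratio, 0)) / rowSums(ok)
        se[rowSums(ok) == 0L] <- NA_real_
        skipped <- rowSums(!ok) > 0L
        if (any(skipped))
            warning(sum(skipped), " probe(s) had tumors skipped for ",
                    "epithelium value 0 (e.g. ",
                    probes[which(skipped)[1L]], ")")
    }
    names(se) <- probes
    se
})

#' Anchor-marker Pearson correlation (R-index)
#'
#' Pearson product-moment correlation between each probe and the anchor
#' probe across stroma samples (the "strSPARC" R-index).  Correlations are
#' computed in the stroma compartment only.  A probe (or anchor) with zero
#' variance across the chosen samples yields \code{NA} ("undefined"), which
#' downstream threshold counts exclude rather than treat as 0.
#'
#' @param x a [StromaCohort-class]
#' @param anchorProbe probe id of the anchor
#' @param probes probe ids (default: all probes)
#' @param samples sample ids to correlate across (default: all stroma
#'   samples); at least 3 are required
#' @param ... unused
#' @return named numeric vector of correlations in [-1, 1], NA where
#'   undefined
#' @export
setMethod("anchorCorrelation", "StromaCohort",
    function(x, anchorProbe, probes = NULL, samples = NULL, ...) {
    if (is.null(probes)) probes <- rownames(x)
    if (is.null(samples)) samples <- stromaSamples(x)
    if (!anchorProbe %in% rownames(x))
        stop("anchor probe '", anchorProbe, "' not in matrix")
    miss <- setdiff(probes, rownames(x))
    if (length(miss))
        stop("probe(s) not in matrix: ", paste(miss, collapse = ", "))
    miss <- setdiff(samples, colnames(x))
    if (length(miss))
        stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))
    if (length(samples) < 3L)
        stop("subset too small for correlation: need >= 3 samples, got ",
             length(samples))
    M <- assay(x, "exprs")[probes, samples, drop = FALSE]
    a <- assay(x, "exprs")[anchorProbe, samples]
    r <- rep(NA_real_, length(probes))
    names(r) <- probes
    if (stats::var(a) > 0) {
        rv <- rowSums((M - rowMeans(M))^2)
        good <- rv > 0
        if (any(good))
            r[good] <- drop(stats::cor(t(M[good, , drop = FALSE]), a))
        r[probes == anchorProbe & good] <- 1  # identity, exactly
    }
    r
})

#' Classify SE ratios into CAFG tiers
#'
#' \code{se >= seHigh} is a CAFG (high stroma specificity),
#' \code{seMid <= se < seHigh} a semi-CAFG, \code{se < seMid} an L-CAFG.
#' Both boundaries are inclusive at the lower tier edge; every defined SE
#' maps to exactly one tier, and \code{NA} stays \code{NA} (record flagged).
#'
#' @param se numeric vector of SE ratios
#' @param seHigh,seMid tier boundaries (defaults 10 and 5), or pass a
#'   [ScreenConfig-class] as \code{seHigh}
#' @return factor with levels \code{CAFG}, \code{semi_CAFG}, \code{L_CAFG}
#' @examples
#' classifyTier(c(17.2, 10, 5, 4.999, 3.6))
#' @export
classifyTier <- function(se, seHigh = 10, seMid = 5) {
    if (is(seHigh, "ScreenConfig")) {
        seMid <- seHigh@seMid
        seHigh <- seHigh@seHigh
    }
    stopifnot(seMid > 0, seMid < seHigh)
    tier <- ifelse(is.na(se), NA_character_,
            ifelse(se >= seHigh, "CAFG",
            ifelse(se >= seMid, "semi_CAFG", "L_CAFG")))
    factor(tier, levels = .TIERS)
}

#' Rank probes by expression amount in a reference sample
#'
#' Orders probes by descending corrected intensity in one sample (the
#' paper-style "expression amounts" ranking in the reference stroma sample),
#' ties broken by probe id ascending.
#'
#' @param x a [StromaCohort-class]
#' @param referenceSample sample id to rank in
#' @param probes probe ids (default: all)
#' @return \code{DataFrame} with \code{probe_id}, \code{expression} and
#'   \code{rank}, ordered by rank
#' @export
rankByExpression <- function(x, referenceSample, probes = NULL) {
    if (is.null(probes)) probes <- rownames(x)
    if (!referenceSample %in% colnames(x))
        stop("reference sample '", referenceSample, "' not in matrix")
    miss <- setdiff(probes, rownames(x))
    if (length(miss))
        stop("probe(s) not in matrix: ", paste(miss, collapse = ", "))
    e <- assay(x, "exprs")[probes, referenceSample]
    o <- order(-e, probes)
    S4Vectors::DataFrame(probe_id = probes[o], expression = unname(e[o]),
                         rank = seq_along(o))
}

#' Count probes correlated with an anchor at or above a threshold
#'
#' Number of probes (excluding the anchor itself) whose stromal R-index with
#' the anchor is defined and \code{>= rMin} — the statistic behind
#' anchor-comparison counts such as probes at R >= 0.8 with VIM, FAP or
#' ACTA2.  Undefined (zero-variance) correlations are excluded from the
#' count.
#'
#' @param x a [StromaCohort-class]
#' @param anchorProbe anchor probe id
#' @param rMin inclusive correlation threshold
#' @param samples samples to correlate across (default: stroma)
#' @return integer count
#' @export
countProbesAtThreshold <- function(x, anchorProbe, rMin, samples = NULL) {
    r <- anchorCorrelation(x, anchorProbe, samples = samples)
    r <- r[names(r) != anchorProbe]
    sum(!is.na(r) & r >= rMin)
}

#' Run the CAFG screen
#'
#' The core screening computation: for every probe on a
#' housekeeping-corrected paired cohort, the SE ratio (stroma specificity),
#' the stromal Pearson correlation with the anchor marker (R-index), the
#' CAFG tier, the mean stromal expression, the expression amount in the
#' configured reference sample and its rank.  Records are ordered by rank
#' (descending reference expression, ties by probe id).
#'
#' @param x a normalized [StromaCohort-class] (see
#'   [housekeepingNormalize()])
#' @param config a [ScreenConfig-class]; the anchor probe must be on the
#'   chip
#' @param requireNormalized error if the cohort has not been
#'   housekeeping-corrected (set \code{FALSE} only for sensitivity
#'   analyses on raw values)
#' @param ... unused
#' @return a [ScreenResult-class]
#' @examples
#' sim <- simulateCohort(SimParams(nTumors = 8, nBackground = 10, seed = 1))
#' norm <- housekeepingNormalize(sim$cohort)
#' scr <- screenGenes(norm, ScreenConfig(anchorProbe = "SPARC_at"))
#' head(screenTable(scr))
#' @export
setMethod("screenGenes", "StromaCohort",
    function(x, config, requireNormalized = TRUE, ...) {
    stopifnot(is(config, "ScreenConfig"))
    validObject(config)
    if (requireNormalized && !isNormalized(x))
        stop("cohort is not housekeeping-normalized; run ",
             "housekeepingNormalize() first (or set requireNormalized ",
             "= FALSE for a sensitivity analysis)")
    if (!config@anchorProbe %in% rownames(x))
        stop("anchor probe '", config@anchorProbe, "' not in matrix")
    d <- cohortDesign(x)
    if (nrow(d) == 0L)
        stop("empty cohort design")
    probes <- rownames(x)
    se <- seRatio(x, mode = config@ratioMode)
    r <- anchorCorrelation(x, config@anchorProbe)
    tier <- classifyTier(se, config)
    meanStroma <- rowMeans(
        assay(x, "exprs")[, d$stroma_sample_id, drop = FALSE])
    refSample <- config@referenceSample
    refExpr <- if (is.na(refSample)) {
        meanStroma
    } else {
        if (!refSample %in% colnames(x))
            stop("reference sample '", refSample, "' not in matrix")
        assay(x, "exprs")[, refSample]
    }
    o <- order(-refExpr, probes)
    tab <- S4Vectors::DataFrame(
        probe_id = probes[o],
        gene_symbol = rowData(x)$gene_symbol[o],
        se_ratio = unname(se[o]),
        anchor_r = unname(r[o]),
        tier = tier[o],
        mean_stroma_expr = unname(meanStroma[o]),
        ref_expression = unname(refExpr[o]),
        rank_by_expression = seq_along(o),
        row.names = probes[o])
    new("ScreenResult", table = tab, config = config,
        nTumors = nrow(d), stromaSamples = d$stroma_sample_id)
})

#' Accessors for ScreenResult
#'
#' @param x a [ScreenResult-class]
#' @return \code{screenTable}: the per-probe \code{DataFrame};
#'   \code{screenConfig}: the [ScreenConfig-class] used
#' @name ScreenResult-accessors
NULL

#' @rdname ScreenResult-accessors
#' @export
setMethod("screenTable", "ScreenResult", function(x) x@table)

#' @rdname ScreenResult-accessors
#' @export
setMethod("screenConfig", "ScreenResult", function(x) x@config)

#' @export
setMethod("show", "ScreenResult", function(object) {
    tab <- object@table
    cfg <- object@config
    cat("ScreenResult:", nrow(tab), "probes over", object@nTumors,
        "paired tumors (anchor ", cfg@anchorProbe, ")\n", sep = " ")
    cat("  tiers:", paste(names(table(tab$tier)), table(tab$tier),
                          sep = "=", collapse = ", "), "\n")
    for (thr in c(cfg@rStrong, cfg@rMid, cfg@rWeak))
        cat("  probes at R >=", thr, ":",
            sum(!is.na(tab$anchor_r) & tab$anchor_r >= thr &
                tab$probe_id != cfg@anchorProbe), "\n")
    invisible(NULL)
})

#' Per-tier counts of a screen
#'
#' @param x a [ScreenResult-class]
#' @return named integer vector over the three tiers (NA-tier probes
#'   excluded)
#' @export
tierCounts <- function(x) {
    stopifnot(is(x, "ScreenResult"))
    tab <- table(x@table$tier)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
}
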