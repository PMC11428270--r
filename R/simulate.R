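#' Simulation parameters
#'
#' Builds a validated [SimParams-class].  The defaults emulate the shape of
#' the breast-cancer microdissection cohort the screen is designed for: 28
#' tumors profiled in both compartments, 5 of them TNBC, a 30-gene stromal
#' block synchronized through a per-tumor latent CAF-activation factor
#' (loading 1.0, the anchor included), a 5-gene block synchronized with that
#' factor only inside the TNBC tumors (loading 0.5), 200 background genes,
#' multiplicative log-normal noise of 0.3 on the log2 scale, a constant
#' GAPDH-role housekeeping probe and log-normal per-sample scale jitter
#' (log2-sd 0.5) that forces the normalization path to matter.
#'
#' Per-gene vectors (\code{blockRho}, \code{blockLambda}, \code{subtypeRho},
#' \code{subtypeLambda}, \code{backgroundRho}) are recycled to their block
#' size; empty vectors mean "draw from the default prior" (block SE targets
#' log-uniform in [5, 25], subtype-block in [2, 6], background log2-normal
#' around 1).  The anchor probe is part of the anchor block and always
#' carries the block's largest loading.
#'
#' @param nTumors number of paired tumors (default 28)
#' @param nBackground background (CAF-independent) genes (default 200)
#' @param nAnchorBlock anchor-correlated stromal block size, anchor
#'   excluded (default 30)
#' @param nSubtypeBlock subtype-restricted block size (default 5)
#' @param nSubtypeTumors tumors labelled with the target subtype
#'   (default 5)
#' @param subtype the target subtype label (default \code{"TNBC"})
#' @param anchorRho planted SE ratio of the anchor probe (default 17.2, a
#'   SPARC-like stroma specificity)
#' @param anchorLambda anchor loading on the latent factor (default 1.0;
#'   must be >= every block loading)
#' @param blockRho,blockLambda per-gene SE targets and loadings of the
#'   anchor block (lambda default 1.0)
#' @param subtypeRho,subtypeLambda same for the subtype block (lambda
#'   default 0.5)
#' @param backgroundRho per-gene SE targets of background genes
#' @param baselineLog2Range log2 range the per-gene baseline intensity
#'   scale is drawn from (default c(3, 10): intensities of ~8 to ~1000)
#' @param noiseSigmaLog2 sd of the multiplicative log-normal measurement
#'   noise on the log2 scale (default 0.3)
#' @param housekeepingValue constant housekeeping intensity before
#'   per-sample scale jitter (default 1000)
#' @param housekeepingProbe id of the housekeeping probe (default
#'   \code{"217398_x_at"}, the GAPDH probe the normalization step expects)
#' @param sampleScaleSigmaLog2 log2-sd of the per-sample scale jitter
#'   (default 0.5; 0 disables it)
#' @param seed integer RNG seed; simulation is fully reproducible from it
#' @return a [SimParams-class]
#' @examples
#' SimParams(nTumors = 10, seed = 7)
#' @export
SimParams <- function(nTumors = 28, nBackground = 200, nAnchorBlock = 30,
                      nSubtypeBlock = 5, nSubtypeTumors = 5,
                      subtype = "TNBC", anchorRho = 17.2,
                      anchorLambda = 1.0, blockRho = numeric(0),
                      blockLambda = 1.0, subtypeRho = numeric(0),
                      subtypeLambda = 0.5, backgroundRho = numeric(0),
                      baselineLog2Range = c(3, 10), noiseSigmaLog2 = 0.3,
                      housekeepingValue = 1000,
                      housekeepingProbe = "217398_x_at",
                      sampleScaleSigmaLog2 = 0.5, seed = 1) {
    new("SimParams", nTumors = as.integer(nTumors),
        nBackground = as.integer(nBackground),
        nAnchorBlock = as.integer(nAnchorBlock),
        nSubtypeBlock = as.integer(nSubtypeBlock),
        nSubtypeTumors = as.integer(nSubtypeTumors),
        subtype = subtype, anchorRho = anchorRho,
        anchorLambda = anchorLambda, blockRho = blockRho,
        blockLambda = blockLambda, subtypeRho = subtypeRho,
        subtypeLambda = subtypeLambda, backgroundRho = backgroundRho,
        baselineLog2Range = baselineLog2Range,
        noiseSigmaLog2 = noiseSigmaLog2,
        housekeepingValue = housekeepingValue,
        housekeepingProbe = housekeepingProbe,
        sampleScaleSigmaLog2 = sampleScaleSigmaLog2,
        seed = as.integer(seed))
}

#' @export
setMethod("show", "SimParams", function(object) {
    cat("SimParams:", object@nTumors, "tumors (",
        object@nSubtypeTumors, object@subtype, "),",
        object@nBackground, "background +", object@nAnchorBlock,
        "anchor-block +", object@nSubtypeBlock, "subtype-block genes\n")
    cat("  noise sd(log2):", object@noiseSigmaLog2,
        "| sample-scale sd(log2):", object@sampleScaleSigmaLog2,
        "| seed:", object@seed, "\n")
    invisible(NULL)
})

.recycle <- function(v, n, default) {
    if (n == 0L) return(numeric(0))
    if (length(v) == 0L) v <- default(n)
    rep_len(v, n)
}

#' Simulate a paired-compartment cohort with planted structure
#'
#' Generative model, per tumor \eqn{t} with latent CAF-activation factor
#' \eqn{f_t \sim N(0,1)} and gene \eqn{g} with baseline \eqn{b_g}, target SE
#' ratio \eqn{\rho_g} and loading \eqn{\lambda_g}: the stroma intensity is
#' \eqn{b_g \rho_g e^{\lambda_g f_t} \epsilon} and the epithelium intensity
#' \eqn{b_g \epsilon'}, with \eqn{\epsilon, \epsilon'} independent
#' log-normal noise of log2-sd \code{noiseSigmaLog2}.  Anchor-block genes
#' load on the shared factor in every tumor; subtype-block genes load on it
#' only inside subtype-labelled tumors and on an independent per-gene
#' factor (same loading, so their variance is homogeneous) elsewhere —
#' making them anchor-correlated only within the subtype.  Background genes
#' have \eqn{\lambda = 0}.  A constant housekeeping probe is always
#' included, and every sample column is multiplied by a random positive
#' per-sample scale so that only housekeeping-corrected statistics are
#' meaningful.  With \eqn{\lambda = 0} and no noise the screened SE ratio
#' equals \eqn{\rho_g} exactly; for \eqn{\lambda > 0} the paired-ratio
#' estimand is \eqn{\rho_g e^{\lambda_g^2/2}} (the log-normal mean shift).
#'
#' The generator is fully reproducible from \code{params@seed} and leaves
#' the caller's RNG state untouched.
#'
#' @param params a [SimParams-class]
#' @param ... unused
#' @return list with \code{cohort} (raw, un-normalized
#'   [StromaCohort-class]), \code{truth} (\code{DataFrame}: per-gene block
#'   label, \code{rho}, \code{lambda}, baseline) and \code{tumors}
#'   (\code{DataFrame}: latent factor and subtype per tumor)
#' @examples
#' sim <- simulateCohort(SimParams(seed = 42))
#' table(sim$truth$block)
#' @export
setMethod("simulateCohort", "SimParams", function(params, ...) {
    validObject(params)
    if (length(params@blockLambda) &&
        any(params@blockLambda > params@anchorLambda))
        stop("anchorLambda must be the largest loading of the anchor block")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(params@seed)

    nT <- params@nTumors
    tumors <- sprintf("tumor_%02d", seq_len(nT))
    f <- stats::rnorm(nT)
    subtypes <- rep("luminal", nT)
    if (nT > params@nSubtypeTumors) {
        others <- seq.int(params@nSubtypeTumors + 1L, nT)
        subtypes[others] <- rep_len(c("luminal", "HER2"), length(others))
    }
    subtypes[seq_len(params@nSubtypeTumors)] <- params@subtype
    inSubtype <- subtypes == params@subtype

    blocks <- c("anchor",
                rep("anchor_block", params@nAnchorBlock),
                rep("subtype_block", params@nSubtypeBlock),
                rep("background", params@nBackground))
    probes <- c("SPARC_at",
                sprintf("BLK_%03d_at", seq_len(params@nAnchorBlock)),
                sprintf("SUB_%03d_at", seq_len(params@nSubtypeBlock)),
                sprintf("BG_%04d_at", seq_len(params@nBackground)))
    symbols <- c("SPARC",
                 sprintf("BLKG%03d", seq_len(params@nAnchorBlock)),
                 sprintf("SUBG%03d", seq_len(params@nSubtypeBlock)),
                 sprintf("BGG%04d", seq_len(params@nBackground)))
    rho <- c(params@anchorRho,
             .recycle(params@blockRho, params@nAnchorBlock,
                      function(n) exp(stats::runif(n, log(5), log(25)))),
             .recycle(params@subtypeRho, params@nSubtypeBlock,
                      function(n) exp(stats::runif(n, log(2), log(6)))),
             .recycle(params@backgroundRho, params@nBackground,
                      function(n) 2^stats::rnorm(n, 0, 1)))
    lambda <- c(params@anchorLambda,
                .recycle(params@blockLambda, params@nAnchorBlock,
                         function(n) rep(1, n)),
                .recycle(params@subtypeLambda, params@nSubtypeBlock,
                         function(n) rep(0.5, n)),
                rep(0, params@nBackground))
    nG <- length(probes)
    b <- 2^stats::runif(nG, params@baselineLog2Range[1L],
                        params@baselineLog2Range[2L])
    sigma <- params@noiseSigmaLog2

    ## latent effect per (gene, tumor): shared factor for anchor/anchor_block;
    ## subtype_block shares it only inside the subtype and uses its own
    ## factor elsewhere; background has none
    L <- matrix(0, nrow = nG, ncol = nT)
    for (i in seq_len(nG)) {
        if (blocks[i] %in% c("anchor", "anchor_block")) {
            L[i, ] <- lambda[i] * f
        } else if (blocks[i] == "subtype_block") {
            own <- stats::rnorm(nT)
            fac <- ifelse(inSubtype, f, own)
            L[i, ] <- lambda[i] * fac
        }
    }
    noiseS <- matrix(2^stats::rnorm(nG * nT, 0, sigma), nG, nT)
    noiseE <- matrix(2^stats::rnorm(nG * nT, 0, sigma), nG, nT)
    stroma <- (b * rho) * exp(L) * noiseS
    epi <- b * noiseE

    m <- cbind(stroma, epi)
    m <- rbind(m, rep(params@housekeepingValue, 2L * nT))
    strIds <- paste0(tumors, "_S")
    epiIds <- paste0(tumors, "_E")
    dimnames(m) <- list(c(probes, params@housekeepingProbe),
                        c(strIds, epiIds))
    if (params@sampleScaleSigmaLog2 > 0) {
        scale <- 2^stats::rnorm(2L * nT, 0, params@sampleScaleSigmaLog2)
        m <- sweep(m, 2L, scale, "*")
    }

    annotation <- data.frame(
        sample_id = c(strIds, epiIds),
        tumor_id = rep(tumors, 2L),
        compartment = rep(.COMPARTMENTS, each = nT),
        subtype = rep(subtypes, 2L),
        stringsAsFactors = FALSE)
    probeMap <- data.frame(
        probe_id = c(probes, params@housekeepingProbe),
        gene_symbol = c(symbols, "GAPDH"),
        stringsAsFactors = FALSE)
    cohort <- StromaCohort(m, annotation, probeMap = probeMap)

    truth <- S4Vectors::DataFrame(
        probe_id = probes, gene_symbol = symbols, block = blocks,
        rho = rho, lambda = lambda, baseline = b, row.names = probes)
    tumorInfo <- S4Vectors::DataFrame(
        tumor_id = tumors, latent_factor = f, subtype = subtypes,
        row.names = tumors)
    list(cohort = cohort, truth = truth, tumors = tumorInfo,
         params = params)
})

#' Write the deterministic fixture family used by the test suite
#'
#' Emits five small cohorts with matching truth tables: \code{noise_free}
#' (no noise, no scale jitter), \code{noisy} (defaults at reduced size),
#' \code{subtype} (a TNBC-restricted block), \code{degenerate} (contains a
#' constant, zero-variance probe \code{CONST_at}) and
#' \code{missing_compartment} (one tumor lacks its epithelium sample).
#' Each directory receives \code{expression.tsv}, \code{annotation.tsv},
#' \code{truth.tsv} and \code{tumors.tsv}.
#'
#' @param outDir writable output directory (created if needed)
#' @param seed base seed for the family
#' @return named character vector of the fixture directories, invisibly
#' @export
writeFixtureSuite <- function(outDir, seed = 20240829) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create fixture directory '", outDir, "'")
    specs <- list(
        noise_free = SimParams(nTumors = 8, nBackground = 20,
                               nAnchorBlock = 6, nSubtypeBlock = 0,
                               nSubtypeTumors = 0, noiseSigmaLog2 = 0,
                               sampleScaleSigmaLog2 = 0, seed = seed),
        noisy = SimParams(nTumors = 12, nBackground = 30,
                          nAnchorBlock = 8, nSubtypeBlock = 3,
                          nSubtypeTumors = 4, seed = seed + 1),
        subtype = SimParams(nTumors = 16, nBackground = 20,
                            nAnchorBlock = 6, nSubtypeBlock = 4,
                            nSubtypeTumors = 5, subtypeLambda = 1.0,
                            noiseSigmaLog2 = 0,
                            sampleScaleSigmaLog2 = 0, seed = seed + 2),
        degenerate = SimParams(nTumors = 8, nBackground = 10,
                               nAnchorBlock = 4, nSubtypeBlock = 0,
                               nSubtypeTumors = 0,
                               sampleScaleSigmaLog2 = 0, seed = seed + 3),
        missing_compartment = SimParams(nTumors = 6, nBackground = 10,
                                        nAnchorBlock = 4,
                                        nSubtypeBlock = 0,
                                        nSubtypeTumors = 0,
                                        seed = seed + 4))
    dirs <- character(0)
    for (nm in names(specs)) {
        sim <- simulateCohort(specs[[nm]])
        m <- assay(sim$cohort, "exprs")
        ann <- as.data.frame(colData(sim$cohort))
        ann <- data.frame(sample_id = rownames(ann), ann,
                          stringsAsFactors = FALSE)
        if (nm == "degenerate")
            m <- rbind(m, CONST_at = rep(7, ncol(m)))
        if (nm == "missing_compartment") {
            drop <- paste0("tumor_01_E")
            m <- m[, colnames(m) != drop, drop = FALSE]
            ann <- ann[ann$sample_id != drop, , drop = FALSE]
        }
        d <- file.path(outDir, nm)
        dir.create(d, showWarnings = FALSE)
        writeExpressionTSV(m, file.path(d, "expression.tsv"))
        utils::write.table(ann, file.path(d, "annotation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(sim$truth),
                           file.path(d, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(sim$tumors),
                           file.path(d, "tumors.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dirs[nm] <- d
    }
    invisible(dirs)
}
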