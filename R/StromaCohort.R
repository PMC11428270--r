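#' Construct a paired stroma/epithelium cohort
#'
#' Assembles a [StromaCohort-class] from a probe-by-sample intensity matrix
#' and a sample annotation table.  The pairing key is \code{tumor_id} from
#' the annotation, never sample-id string patterns.  Tumors lacking one of
#' the two compartments are excluded with a message and recorded in
#' \code{metadata(x)$dropped_tumors}; if no complete pair remains the
#' constructor fails.  Probes absent from \code{probeMap} keep their probe id
#' as \code{gene_symbol} (with a warning when a map was supplied).
#'
#' @param exprs numeric matrix of linear-scale intensities, probes in rows
#'   (rownames = probe ids), samples in columns (colnames = sample ids).
#'   Values must be finite and non-negative.
#' @param annotation \code{data.frame} with columns \code{sample_id},
#'   \code{tumor_id}, \code{compartment} (\code{"stroma"} /
#'   \code{"epithelium"}) and optionally \code{subtype} (\code{"luminal"},
#'   \code{"HER2"}, \code{"TNBC"}, \code{"unknown"}).
#' @param probeMap optional \code{data.frame} with columns \code{probe_id}
#'   and \code{gene_symbol}.
#' @return a validated \code{StromaCohort}
#' @examples
#' sim <- simulateCohort(SimParams(nTumors = 4, nBackground = 5, seed = 1))
#' cohortDesign(sim$cohort)
#' @export
StromaCohort <- function(exprs, annotation, probeMap = NULL) {
    stopifnot(is.matrix(exprs), is.numeric(exprs))
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("exprs must have probe rownames and sample colnames")
    annotation <- as.data.frame(annotation)
    need <- c("sample_id", "tumor_id", "compartment")
    if (!all(need %in% colnames(annotation)))
        stop("annotation must contain columns: ",
             paste(setdiff(need, colnames(annotation)), collapse = ", "))
    if (!"subtype" %in% colnames(annotation))
        annotation$subtype <- "unknown"
    annotation$subtype[is.na(annotation$subtype)] <- "unknown"
    bad <- setdiff(annotation$sample_id, colnames(exprs))
    if (length(bad))
        stop("annotation references sample ids absent from the matrix: ",
             paste(bad, collapse = ", "))
    bad <- setdiff(annotation$compartment, .COMPARTMENTS)
    if (length(bad))
        stop("unknown compartment value: ", paste(bad, collapse = ", "))
    bad <- setdiff(annotation$subtype, .SUBTYPES)
    if (length(bad))
        stop("unknown subtype value: ", paste(bad, collapse = ", "))

    ## keep only tumors with both compartments, deterministically by tumor_id
    tab <- table(factor(annotation$tumor_id),
                 factor(annotation$compartment, levels = .COMPARTMENTS))
    complete <- rownames(tab)[tab[, "stroma", drop = TRUE] == 1L &
                              tab[, "epithelium", drop = TRUE] == 1L]
    dropped <- setdiff(unique(annotation$tumor_id), complete)
    if (length(complete) == 0L)
        stop("no paired tumors: every tumor lacks a compartment")
    if (length(dropped))
        message("excluding ", length(dropped),
                " tumor(s) without both compartments: ",
                paste(sort(dropped), collapse = ", "))
    annotation <- annotation[annotation$tumor_id %in% complete, , drop = FALSE]
    exprs <- exprs[, annotation$sample_id, drop = FALSE]

    sym <- rownames(exprs)
    if (!is.null(probeMap)) {
        probeMap <- as.data.frame(probeMap)
        stopifnot(all(c("probe_id", "gene_symbol") %in% colnames(probeMap)))
        idx <- match(rownames(exprs), probeMap$probe_id)
        unmapped <- sum(is.na(idx))
        if (unmapped)
            warning(unmapped, " probe(s) absent from the probe map keep ",
                    "their probe id as gene_symbol")
        sym[!is.na(idx)] <- probeMap$gene_symbol[idx[!is.na(idx)]]
    }

    cd <- S4Vectors::DataFrame(
        tumor_id = annotation$tumor_id,
        compartment = annotation$compartment,
        subtype = annotation$subtype,
        row.names = annotation$sample_id)
    obj <- SummarizedExperiment(
        assays = list(exprs = exprs),
        rowData = S4Vectors::DataFrame(gene_symbol = sym,
                                       row.names = rownames(exprs)),
        colData = cd)
    obj <- new("StromaCohort", obj)
    metadata(obj)$normalized <- FALSE
    metadata(obj)$dropped_tumors <- sort(dropped)
    validObject(obj)
    obj
}

#' @describeIn StromaCohort the paired design: one row per tumor with its
#'   stroma and epithelium sample ids and subtype, ordered by tumor id.
#' @param x a \code{StromaCohort}
#' @param ... unused
#' @export
setMethod("cohortDesign", "StromaCohort", function(x, ...) {
    cd <- colData(x)
    tum <- sort(unique(cd$tumor_id))
    str <- rownames(cd)[match(paste(tum, "stroma"),
                              paste(cd$tumor_id, cd$compartment))]
    epi <- rownames(cd)[match(paste(tum, "epithelium"),
                              paste(cd$tumor_id, cd$compartment))]
    S4Vectors::DataFrame(
        tumor_id = tum,
        stroma_sample_id = str,
        epithelium_sample_id = epi,
        subtype = cd$subtype[match(str, rownames(cd))],
        row.names = tum)
})

#' @describeIn StromaCohort sample ids of the stroma compartment (design
#'   order)
#' @export
setMethod("stromaSamples", "StromaCohort", function(x, ...)
    cohortDesign(x)$stroma_sample_id)

#' @describeIn StromaCohort sample ids of the epithelium compartment (design
#'   order)
#' @export
setMethod("epitheliumSamples", "StromaCohort", function(x, ...)
    cohortDesign(x)$epithelium_sample_id)

#' @describeIn StromaCohort has the cohort been housekeeping-normalized?
#' @export
setMethod("isNormalized", "StromaCohort", function(x)
    isTRUE(metadata(x)$normalized))

#' @export
setMethod("show", "StromaCohort", function(object) {
    d <- cohortDesign(object)
    cat("StromaCohort:", nrow(object), "probes x", ncol(object), "samples\n")
    cat("  tumors:", nrow(d), "paired;",
        sum(d$subtype == "TNBC"), "TNBC\n")
    cat("  normalized:", isNormalized(object))
    if (isNormalized(object))
        cat(" (housekeeping probe ", metadata(object)$housekeeping_probe,
            ")", sep = "")
    cat("\n")
    invisible(NULL)
})
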