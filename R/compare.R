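#' Construct a reference gene set
#'
#' @param name set name (e.g. \code{"CRC_CAFG"})
#' @param genes character vector of unique gene symbols
#' @param sourceSE optional named numeric vector of the genes' SE ratios in
#'   the cohort of origin
#' @return a [ReferenceGeneSet-class]
#' @examples
#' ReferenceGeneSet("demo", c("FAP", "ACTA2"),
#'                  sourceSE = c(FAP = 20.2, ACTA2 = 20.2))
#' @export
ReferenceGeneSet <- function(name, genes, sourceSE = numeric(0)) {
    new("ReferenceGeneSet", name = name, genes = as.character(genes),
        sourceSE = sourceSE)
}

#' @describeIn ReferenceGeneSet the gene symbols
#' @param x a \code{ReferenceGeneSet}
#' @export
setMethod("refGenes", "ReferenceGeneSet", function(x) x@genes)

#' @describeIn ReferenceGeneSet the source-cohort SE values (possibly empty)
#' @export
setMethod("refSourceSE", "ReferenceGeneSet", function(x) x@sourceSE)

#' @export
setMethod("show", "ReferenceGeneSet", function(object) {
    cat("ReferenceGeneSet '", object@name, "': ", length(object@genes),
        " genes (", sum(names(object@sourceSE) %in% object@genes),
        " with source SE)\n", sep = "")
    invisible(NULL)
})

#' Read a reference gene-set TSV
#'
#' Two-column tab-separated file (\code{gene_symbol}, optional
#' \code{reference_SE}), optionally preceded by a \code{# name: <set name>}
#' header line; without one the file name (sans extension) is used.
#'
#' @param path path to the file
#' @return a [ReferenceGeneSet-class]
#' @seealso [crcReferenceSets()] for the shipped CRC-derived lists
#' @export
readReferenceGeneSet <- function(path) {
    lines <- readLines(path, warn = FALSE)
    name <- sub("\\.[^.]*$", "", basename(path))
    isName <- grepl("^#\\s*name:", lines)
    if (any(isName))
        name <- trimws(sub("^#\\s*name:", "", lines[which(isName)[1L]]))
    lines <- lines[!startsWith(lines, "#")]
    df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            header = TRUE, sep = "\t",
                            check.names = FALSE)
    if (!"gene_symbol" %in% colnames(df))
        stop("reference set file must have a gene_symbol column")
    se <- numeric(0)
    if ("reference_SE" %in% colnames(df)) {
        v <- suppressWarnings(as.numeric(df$reference_SE))
        keep <- !is.na(v)
        se <- stats::setNames(v[keep], df$gene_symbol[keep])
    }
    ReferenceGeneSet(name, df$gene_symbol, sourceSE = se)
}

#' CRC-derived CAFG reference lists
#'
#' The colorectal-cancer CAFG, semi-CAFG and L-CAFG gene lists shipped with
#' the package, restricted to the genes whose names (and, where reported, SE
#' ratios) appear in the source publication's main text; the full 115-gene
#' catalogue is a user-supplied input ([readReferenceGeneSet()]).
#'
#' @return named list of three [ReferenceGeneSet-class] objects
#'   (\code{CRC_CAFG}, \code{CRC_semi_CAFG}, \code{CRC_L_CAFG})
#' @examples
#' crcReferenceSets()$CRC_CAFG
#' @export
crcReferenceSets <- function() {
    dir <- system.file("extdata", package = "CAFGscreen", mustWork = TRUE)
    files <- c(CRC_CAFG = "crc_cafg.tsv",
               CRC_semi_CAFG = "crc_semi_cafg.tsv",
               CRC_L_CAFG = "crc_l_cafg.tsv")
    lapply(files, function(f) readReferenceGeneSet(file.path(dir, f)))
}

## best probe per gene: highest mean stromal expression, ties by probe id
.bestProbeRows <- function(tab) {
    o <- order(tab$gene_symbol, -tab$mean_stroma_expr, tab$probe_id)
    tab <- tab[o, , drop = FALSE]
    tab[!duplicated(tab$gene_symbol), , drop = FALSE]
}

.resolveRMin <- function(screen, rMin) {
    if (is.null(rMin)) screen@config@rWeak else rMin
}

#' Cross-cohort overlap with a reference CAFG list
#'
#' For each reference gene present on the chip, decides whether it "passes"
#' — its representative probe has a defined anchor R-index at or above
#' \code{rMin} — and summarizes the counts, the passing fraction and the
#' mean SE ratio of the passing genes (the 59-of-92-style overlap
#' statistic).  With \code{rule = "best_probe"} (default) a gene is
#' represented by its probe with the highest mean stromal expression; with
#' \code{"any_probe"} it passes if any of its probes does (SE then comes
#' from the best passing probe).
#'
#' @param screen a [ScreenResult-class] produced with the same probe map
#' @param reference a [ReferenceGeneSet-class]
#' @param rMin inclusive R-index threshold (default: the screen's
#'   \code{rWeak}, 0.6)
#' @param rule gene-level decision rule
#' @return an [OverlapReport-class]; when no reference gene is on the chip
#'   the report is flagged and the fraction undefined
#' @export
setMethod("overlapWithReference",
          c("ScreenResult", "ReferenceGeneSet"),
    function(screen, reference, rMin = NULL,
             rule = c("best_probe", "any_probe")) {
    rule <- match.arg(rule)
    rMin <- .resolveRMin(screen, rMin)
    tab <- screen@table
    onChip <- tab[tab$gene_symbol %in% reference@genes, , drop = FALSE]
    nOnChip <- length(unique(onChip$gene_symbol))
    if (nOnChip == 0L)
        return(new("OverlapReport", referenceName = reference@name,
                   rMin = rMin, nReference = length(reference@genes),
                   nOnChip = 0L, nPassing = 0L,
                   fractionPassing = NA_real_, meanSEPassing = NA_real_,
                   passingGenes = character(0), flagged = TRUE))
    if (rule == "best_probe") {
        rep_ <- .bestProbeRows(onChip)
        pass <- rep_[!is.na(rep_$anchor_r) & rep_$anchor_r >= rMin, ,
                     drop = FALSE]
    } else {
        hits <- onChip[!is.na(onChip$anchor_r) & onChip$anchor_r >= rMin, ,
                       drop = FALSE]
        pass <- .bestProbeRows(hits)
    }
    new("OverlapReport", referenceName = reference@name, rMin = rMin,
        nReference = length(reference@genes), nOnChip = nOnChip,
        nPassing = nrow(pass),
        fractionPassing = nrow(pass) / nOnChip,
        meanSEPassing = if (nrow(pass)) mean(pass$se_ratio) else NA_real_,
        passingGenes = sort(pass$gene_symbol), flagged = FALSE)
})

#' @export
setMethod("show", "OverlapReport", function(object) {
    cat("OverlapReport vs '", object@referenceName, "' (R >= ",
        object@rMin, ")\n", sep = "")
    cat("  reference:", object@nReference, "| on chip:", object@nOnChip,
        "| passing:", object@nPassing, "\n")
    if (object@flagged) {
        cat("  flagged: no reference gene on the chip\n")
    } else {
        cat(sprintf("  fraction passing: %.2f", object@fractionPassing))
        if (!is.na(object@meanSEPassing))
            cat(sprintf(" | mean SE of passing genes: %.1f",
                        object@meanSEPassing))
        cat("\n")
    }
    invisible(NULL)
})

#' Turn an overlap report into a one-row data.frame
#'
#' @param report an [OverlapReport-class]
#' @return \code{data.frame} with the report fields (presentation rounding
#'   is left to the caller)
#' @export
overlapAsDataFrame <- function(report) {
    stopifnot(is(report, "OverlapReport"))
    data.frame(reference = report@referenceName, r_min = report@rMin,
               n_reference = report@nReference, n_on_chip = report@nOnChip,
               n_passing = report@nPassing,
               fraction_passing = report@fractionPassing,
               mean_se_passing = report@meanSEPassing,
               flagged = report@flagged)
}

#' Mean SE ratio of a reference subgroup
#'
#' Arithmetic mean of the SE ratios of the reference genes whose
#' representative probe passes the anchor R-index threshold — the
#' average-bSE statistic reported for the CAFG/semi-CAFG/L-CAFG subgroups.
#'
#' @inheritParams overlapWithReference
#' @return single numeric; \code{NA} (with a warning) when no gene passes
#' @export
setMethod("subgroupMeanSE", c("ScreenResult", "ReferenceGeneSet"),
    function(screen, reference, rMin = NULL,
             rule = c("best_probe", "any_probe")) {
    rep_ <- overlapWithReference(screen, reference, rMin = rMin,
                                 rule = match.arg(rule))
    if (rep_@flagged || rep_@nPassing == 0L) {
        warning("no reference gene passes R >= ", rep_@rMin,
                "; subgroup mean SE undefined")
        return(NA_real_)
    }
    rep_@meanSEPassing
})

#' Subtype-restricted anchor screen
#'
#' Recomputes the anchor R-index using only the stroma samples of tumors
#' with a given molecular subtype (e.g. TNBC) and contrasts it with the
#' full-cohort R-index.  \code{shared} probes associate with the anchor in
#' both (subset and full R >= \code{rSubsetMin}); \code{subtype_specific}
#' probes associate only within the subtype (subset R >= \code{rSubsetMin}
#' and full R < \code{rFullMax}) — the COL11A1/TAGLN-style pattern.  The
#' subset size is attached to the result; no significance filter is applied.
#'
#' @param x a normalized [StromaCohort-class]
#' @param subtype subtype label to restrict to (\code{"TNBC"} by default)
#' @param anchorProbe anchor probe id
#' @param rSubsetMin inclusive threshold on the subset R-index (default 0.9)
#' @param rFullMax exclusive upper bound on the full-cohort R-index for
#'   subtype-specific calls (default 0.6); must be <= \code{rSubsetMin} so
#'   the two lists are disjoint
#' @return list with \code{shared} and \code{subtype_specific}
#'   \code{DataFrame}s (probe, gene symbol, subset and full R), plus
#'   \code{n_subset}, the number of subtype tumors
#' @examples
#' sim <- simulateCohort(SimParams(seed = 2))
#' norm <- housekeepingNormalize(sim$cohort)
#' res <- subtypeRestrictedScreen(norm, "TNBC", anchorProbe = "SPARC_at")
#' res$n_subset
#' @export
setMethod("subtypeRestrictedScreen", "StromaCohort",
    function(x, subtype = "TNBC", anchorProbe, rSubsetMin = 0.9,
             rFullMax = 0.6) {
    stopifnot(rFullMax <= rSubsetMin)
    d <- cohortDesign(x)
    sub <- d[d$subtype == subtype, , drop = FALSE]
    if (nrow(sub) < 3L)
        stop("subset too small for correlation: ", nrow(sub), " ",
             subtype, " tumor(s), need >= 3")
    rSub <- anchorCorrelation(x, anchorProbe,
                              samples = sub$stroma_sample_id)
    rFull <- anchorCorrelation(x, anchorProbe,
                               samples = d$stroma_sample_id)
    probes <- rownames(x)
    keep <- probes != anchorProbe
    def <- keep & !is.na(rSub) & !is.na(rFull)
    shared <- def & rSub >= rSubsetMin & rFull >= rSubsetMin
    specific <- def & rSub >= rSubsetMin & rFull < rFullMax
    mk <- function(sel) {
        o <- order(-rSub[sel])
        S4Vectors::DataFrame(
            probe_id = probes[sel][o],
            gene_symbol = rowData(x)$gene_symbol[sel][o],
            r_subset = unname(rSub[sel][o]),
            r_full = unname(rFull[sel][o]))
    }
    list(shared = mk(shared), subtype_specific = mk(specific),
         n_subset = nrow(sub), subtype = subtype,
         rSubsetMin = rSubsetMin, rFullMax = rFullMax)
})
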