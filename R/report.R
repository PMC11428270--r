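#' Run the full screening pipeline and write the artifact bundle
#'
#' Orchestrates read (optional) -> housekeeping correction -> CAFG screen ->
#' reference overlap(s) -> optional subtype-restricted screen, and writes to
#' \code{outDir}:
#' \itemize{
#'   \item \code{screen_table.tsv} — the per-probe screen records
#'   \item \code{ranked_expression.tsv} — probes ranked by expression amount
#'     in the reference sample (when one is configured)
#'   \item \code{overlap_<set>.json} / \code{.tsv} — one per reference set
#'   \item \code{subtype_screen.json} — when \code{subtype} is given
#'   \item \code{run_manifest.json} — effective configuration, tier and
#'     R-threshold counts, input checksums (for file inputs) and package
#'     version
#' }
#' Stored tables keep full precision; presentation rounding (R to 2
#' decimals, SE to 1) is applied only inside the human-readable manifest
#' summary.
#'
#' @param x a [StromaCohort-class], or a path to an expression TSV
#'   (then \code{annotation} is required)
#' @param config a [ScreenConfig-class]
#' @param outDir output directory, created if needed
#' @param referenceSets list of [ReferenceGeneSet-class] objects to overlap
#'   against (default: none)
#' @param subtype optional subtype label for the restricted re-screen
#' @param annotation,probeMap paths to annotation / probe-map TSVs (only
#'   when \code{x} is a path)
#' @param normalize apply housekeeping correction (default TRUE; FALSE only
#'   for sensitivity analyses)
#' @param housekeepingProbe housekeeping probe id
#' @param rSubsetMin,rFullMax thresholds for the subtype screen
#' @return invisibly, a list with the \code{screen} result, the overlap
#'   reports, the subtype screen result (or NULL) and the manifest
#' @examples
#' sim <- simulateCohort(SimParams(seed = 3))
#' out <- runFullScreen(sim$cohort,
#'                      ScreenConfig(anchorProbe = "SPARC_at"),
#'                      outDir = tempfile("screen_run_"))
#' names(out)
#' @export
runFullScreen <- function(x, config, outDir,
                          referenceSets = list(), subtype = NULL,
                          annotation = NULL, probeMap = NULL,
                          normalize = TRUE,
                          housekeepingProbe = "217398_x_at",
                          rSubsetMin = 0.9, rFullMax = 0.6) {
    stopifnot(is(config, "ScreenConfig"))
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory '", outDir, "'")

    checksums <- list()
    if (is.character(x)) {
        if (is.null(annotation))
            stop("stage io: an annotation file is required with a matrix path")
        checksums$matrix <- unname(tools::md5sum(x))
        checksums$annotation <- unname(tools::md5sum(annotation))
        pm <- NULL
        if (!is.null(probeMap)) {
            checksums$probe_map <- unname(tools::md5sum(probeMap))
            pm <- readProbeMap(probeMap)
        }
        m <- readExpressionTSV(x)
        ann <- readAnnotationTSV(annotation)
        x <- StromaCohort(m, ann, probeMap = pm)
    }
    stopifnot(is(x, "StromaCohort"))

    if (normalize && !isNormalized(x))
        x <- housekeepingNormalize(x, housekeepingProbe)
    scr <- screenGenes(x, config, requireNormalized = normalize)
    tab <- as.data.frame(screenTable(scr))
    utils::write.table(tab, file.path(outDir, "screen_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.na(config@referenceSample)) {
        rk <- as.data.frame(rankByExpression(x, config@referenceSample))
        utils::write.table(rk, file.path(outDir, "ranked_expression.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    overlaps <- list()
    for (ref in referenceSets) {
        rep_ <- overlapWithReference(scr, ref)
        overlaps[[ref@name]] <- rep_
        df <- overlapAsDataFrame(rep_)
        utils::write.table(df,
            file.path(outDir, paste0("overlap_", ref@name, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            c(as.list(df), list(passing_genes = rep_@passingGenes)),
            file.path(outDir, paste0("overlap_", ref@name, ".json")),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    subRes <- NULL
    if (!is.null(subtype)) {
        subRes <- subtypeRestrictedScreen(x, subtype,
                                          anchorProbe = config@anchorProbe,
                                          rSubsetMin = rSubsetMin,
                                          rFullMax = rFullMax)
        jsonlite::write_json(
            list(subtype = subtype, n_subset = subRes$n_subset,
                 shared = as.data.frame(subRes$shared),
                 subtype_specific = as.data.frame(subRes$subtype_specific)),
            file.path(outDir, "subtype_screen.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    cnt <- tierCounts(scr)
    rdef <- !is.na(tab$anchor_r) & tab$probe_id != config@anchorProbe
    manifest <- list(
        package_version =
            as.character(utils::packageVersion("CAFGscreen")),
        config = list(anchor_probe = config@anchorProbe,
                      r_strong = config@rStrong, r_mid = config@rMid,
                      r_weak = config@rWeak, se_high = config@seHigh,
                      se_mid = config@seMid,
                      reference_sample = config@referenceSample,
                      ratio_mode = config@ratioMode,
                      normalized = normalize,
                      housekeeping_probe =
                          if (normalize) housekeepingProbe else NULL),
        n_tumors = scr@nTumors,
        n_probes = nrow(tab),
        input_checksums = checksums,
        tier_counts = as.list(cnt),
        probes_at_r = list(
            strong = sum(rdef & tab$anchor_r >= config@rStrong),
            mid = sum(rdef & tab$anchor_r >= config@rMid),
            weak = sum(rdef & tab$anchor_r >= config@rWeak)),
        summary = sprintf(
            "anchor %s: %d/%d probes at R >= %.2f; mean SE of CAFG tier %.1f",
            config@anchorProbe,
            sum(rdef & tab$anchor_r >= config@rWeak), sum(rdef),
            config@rWeak,
            if (any(tab$tier %in% "CAFG"))
                mean(tab$se_ratio[tab$tier %in% "CAFG"]) else NA_real_))
    jsonlite::write_json(manifest,
                         file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(screen = scr, overlaps = overlaps,
                   subtypeScreen = subRes, manifest = manifest))
}
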