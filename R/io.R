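## Readers and writers for the plain-text interchange formats: expression
## TSV (probes x samples), GEO series-matrix files, annotation and probe-map
## TSVs, and reference gene-set files.

#' Read a probe-by-sample expression matrix from TSV
#'
#' First column = probe ids, header row = sample ids, tab-separated,
#' linear-scale intensities.  Load order is preserved.  Duplicate ids are
#' rejected naming the duplicate; non-numeric or negative cells are rejected
#' with their row/column coordinates.
#'
#' @param path path to a tab-separated file
#' @return numeric matrix with probe rownames and sample colnames
#' @seealso [writeExpressionTSV()], [StromaCohort()]
#' @export
readExpressionTSV <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "")
    if (ncol(df) < 2L)
        stop("expression file needs a probe-id column plus >= 1 sample")
    probes <- df[[1L]]
    samples <- colnames(df)[-1L]
    if (anyDuplicated(probes))
        stop("duplicated probe id: ", probes[duplicated(probes)][1L])
    if (anyDuplicated(samples))
        stop("duplicated sample id: ", samples[duplicated(samples)][1L])
    m <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                dimnames = list(probes, samples))
    for (j in seq_along(samples)) {
        raw <- df[[j + 1L]]
        val <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(val) & !is.na(raw) & nzchar(raw))
        if (length(bad))
            stop("non-numeric value '", raw[bad[1L]], "' at probe '",
                 probes[bad[1L]], "', sample '", samples[j], "'")
        bad <- which(!is.finite(val))
        if (length(bad))
            stop("missing or non-finite value at probe '", probes[bad[1L]],
                 "', sample '", samples[j], "'")
        bad <- which(val < 0)
        if (length(bad))
            stop("negative value ", val[bad[1L]], " at probe '",
                 probes[bad[1L]], "', sample '", samples[j], "'")
        m[, j] <- val
    }
    m
}

#' Write an expression matrix (or cohort assay) to TSV
#'
#' Writes full double precision (17 significant digits) so that
#' \code{readExpressionTSV(writeExpressionTSV(x))} round-trips the numeric
#' content bit-for-bit.
#'
#' @param x numeric matrix or [StromaCohort-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeExpressionTSV <- function(x, path) {
    if (is(x, "StromaCohort"))
        x <- assay(x, "exprs")
    stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con)
    body <- apply(x, 1L, function(v)
        paste(sprintf("%.17g", v), collapse = "\t"))
    writeLines(paste(rownames(x), body, sep = "\t"), con)
    invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the conventional dialect: lines starting with \code{!} are
#' metadata; the expression table sits between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end}.
#' Per-sample \code{!Sample_characteristics_ch1} (and title) lines are
#' scanned, best-effort, for the compartment (\code{stroma} /
#' \code{epithelium}), molecular subtype and a tumor/patient/case number;
#' anything not recognised is left \code{NA} or \code{"unknown"} and can be
#' completed from a user-supplied annotation file.  If the metadata declare
#' log2-transformed values the table is un-logged (\code{2^x}) before
#' validation, since SE ratios and expression amounts are linear-scale
#' statistics.
#'
#' @param path path to a series-matrix text file
#' @return \code{list(exprs = matrix, annotation = data.frame)}; the
#'   annotation draft has columns \code{sample_id}, \code{tumor_id},
#'   \code{compartment}, \code{subtype}
#' @export
readSeriesMatrix <- function(path) {
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
        stop("series-matrix table markers not found (need ",
             "!series_matrix_table_begin / !series_matrix_table_end)")
    meta <- lines[startsWith(lines, "!")]
    tbl <- lines[(beg + 1L):(end - 1L)]

    strip <- function(x) gsub("^\"|\"$", "", x)
    cells <- strsplit(tbl, "\t", fixed = TRUE)
    ncols <- lengths(cells)
    if (length(unique(ncols)) != 1L)
        stop("ragged series-matrix table: rows have ",
             paste(sort(unique(ncols)), collapse = "/"), " columns")
    header <- strip(cells[[1L]])
    samples <- header[-1L]
    probes <- vapply(cells[-1L], function(r) strip(r[1L]), character(1))
    if (anyDuplicated(probes))
        stop("duplicated probe id: ", probes[duplicated(probes)][1L])
    vals <- vapply(cells[-1L], function(r) {
        v <- suppressWarnings(as.numeric(strip(r[-1L])))
        if (any(is.na(v)))
            stop("non-numeric cell in series-matrix table row '",
                 strip(r[1L]), "'")
        v
    }, numeric(length(samples)))
    m <- if (length(samples) == 1L) matrix(vals, ncol = 1L) else t(vals)
    dimnames(m) <- list(probes, samples)

    if (any(grepl("log2", meta, ignore.case = TRUE))) {
        message("series-matrix metadata declare log2 values; ",
                "un-logging (2^x)")
        m <- 2^m
    }
    if (any(m < 0))
        stop("negative intensities after import")

    ## best-effort annotation draft from characteristics/title lines
    perSample <- function(pattern) {
        rows <- grep(pattern, meta, ignore.case = TRUE, value = TRUE)
        out <- rep("", length(samples))
        for (r in rows) {
            f <- strip(strsplit(r, "\t", fixed = TRUE)[[1L]])[-1L]
            if (length(f) == length(samples))
                out <- paste(out, f, sep = "; ")
        }
        out
    }
    txt <- paste(perSample("^!Sample_characteristics"),
                 perSample("^!Sample_title"), sep = "; ")
    compartment <- rep(NA_character_, length(samples))
    compartment[grepl("strom", txt, ignore.case = TRUE)] <- "stroma"
    compartment[grepl("epitheli", txt, ignore.case = TRUE)] <- "epithelium"
    subtype <- rep("unknown", length(samples))
    subtype[grepl("luminal", txt, ignore.case = TRUE)] <- "luminal"
    subtype[grepl("HER2", txt, ignore.case = TRUE)] <- "HER2"
    subtype[grepl("TNBC|triple[ -]?negative", txt,
                  ignore.case = TRUE)] <- "TNBC"
    tumor <- rep(NA_character_, length(samples))
    hit <- regmatches(txt, regexpr(
        "(patient|case|tumou?r)[^0-9]{0,5}([0-9]+)", txt,
        ignore.case = TRUE))
    has <- grepl("(patient|case|tumou?r)[^0-9]{0,5}[0-9]+", txt,
                 ignore.case = TRUE)
    tumor[has] <- paste0("tumor_", gsub("[^0-9]", "", hit))

    list(exprs = m,
         annotation = data.frame(sample_id = samples, tumor_id = tumor,
                                 compartment = compartment,
                                 subtype = subtype,
                                 stringsAsFactors = FALSE))
}

#' Read a sample-annotation TSV
#'
#' Columns \code{sample_id}, \code{tumor_id}, \code{compartment} and
#' optionally \code{subtype} (missing or empty values become
#' \code{"unknown"}).
#'
#' @param path path to a tab-separated annotation file
#' @return \code{data.frame}
#' @export
readAnnotationTSV <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    need <- c("sample_id", "tumor_id", "compartment")
    if (!all(need %in% colnames(df)))
        stop("annotation file must have columns: ",
             paste(need, collapse = ", "))
    if (!"subtype" %in% colnames(df))
        df$subtype <- "unknown"
    df$subtype[is.na(df$subtype) | !nzchar(df$subtype)] <- "unknown"
    bad <- setdiff(df$compartment, .COMPARTMENTS)
    if (length(bad))
        stop("unknown compartment value: ", paste(bad, collapse = ", "))
    bad <- setdiff(df$subtype, .SUBTYPES)
    if (length(bad))
        stop("unknown subtype value: ", paste(bad, collapse = ", "))
    df[, c("sample_id", "tumor_id", "compartment", "subtype")]
}

#' Read a probe-to-gene-symbol map TSV
#'
#' Columns \code{probe_id} (unique) and \code{gene_symbol} (non-empty); many
#' probes may map to one gene.
#'
#' @param path path to a tab-separated probe map
#' @return \code{data.frame}
#' @export
readProbeMap <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
    if (!all(c("probe_id", "gene_symbol") %in% colnames(df)))
        stop("probe map must have columns probe_id, gene_symbol")
    if (anyDuplicated(df$probe_id))
        stop("duplicated probe id in map: ",
             df$probe_id[duplicated(df$probe_id)][1L])
    if (any(is.na(df$gene_symbol) | !nzchar(df$gene_symbol)))
        stop("empty gene_symbol in probe map")
    df[, c("probe_id", "gene_symbol")]
}
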