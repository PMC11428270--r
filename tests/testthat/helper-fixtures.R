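## In-code fixture builders shared across test files.

# a small cohort from explicit per-compartment matrices
# stroma/epi: probes x tumors matrices with identical dimnames
makePairedCohort <- function(stroma, epi, hk = 1000, subtype = NULL,
                             probeMap = NULL) {
  stopifnot(identical(dim(stroma), dim(epi)))
  nT <- ncol(stroma)
  tumors <- colnames(stroma)
  if (is.null(tumors)) tumors <- sprintf("T%02d", seq_len(nT))
  if (is.null(subtype)) subtype <- rep("unknown", nT)
  m <- cbind(stroma, epi)
  m <- rbind(m, "217398_x_at" = rep(hk, 2 * nT))
  colnames(m) <- c(paste0(tumors, "_S"), paste0(tumors, "_E"))
  ann <- data.frame(
    sample_id = colnames(m),
    tumor_id = rep(tumors, 2),
    compartment = rep(c("stroma", "epithelium"), each = nT),
    subtype = rep(subtype, 2),
    stringsAsFactors = FALSE)
  StromaCohort(m, ann, probeMap = probeMap)
}

# annotation data.frame of a cohort, as plain data.frame with sample_id
annotationOf <- function(cohort) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  data.frame(sample_id = rownames(cd), cd, stringsAsFactors = FALSE)
}

normalizedMatrix <- function(cohort) {
  SummarizedExperiment::assay(housekeepingNormalize(cohort), "exprs")
}
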