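## Independent brute-force oracles, written from the defining formulas and
## kept free of the package's vectorized code paths.

# Pearson correlation by the covariance / (sd * sd) formula
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# SE ratio of one probe by explicit per-tumor loops
oracleSE <- function(stromaVals, epiVals, mode) {
  stopifnot(length(stromaVals) == length(epiVals))
  if (mode == "ratio_of_means") {
    me <- mean(epiVals)
    if (me == 0) return(NA_real_)
    return(mean(stromaVals) / me)
  }
  ratios <- c()
  for (t in seq_along(stromaVals))
    if (epiVals[t] > 0)
      ratios <- c(ratios, stromaVals[t] / epiVals[t])
  if (length(ratios) == 0) return(NA_real_)
  sum(ratios) / length(ratios)
}

oracleTier <- function(se, seHigh = 10, seMid = 5) {
  if (is.na(se)) return(NA_character_)
  if (se >= seHigh) "CAFG" else if (se >= seMid) "semi_CAFG" else "L_CAFG"
}

# full screen recomputation, probe by probe, from a raw matrix + annotation
oracleScreen <- function(normMat, annotation, anchorProbe, mode,
                         referenceSample = NA) {
  str <- annotation[annotation$compartment == "stroma", , drop = FALSE]
  epi <- annotation[annotation$compartment == "epithelium", , drop = FALSE]
  tumors <- sort(intersect(str$tumor_id, epi$tumor_id))
  sIds <- str$sample_id[match(tumors, str$tumor_id)]
  eIds <- epi$sample_id[match(tumors, epi$tumor_id)]
  a <- normMat[anchorProbe, sIds]
  out <- data.frame(probe_id = rownames(normMat),
                    se_ratio = NA_real_, anchor_r = NA_real_,
                    tier = NA_character_, ref_expression = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(normMat))) {
    p <- rownames(normMat)[i]
    out$se_ratio[i] <- oracleSE(normMat[p, sIds], normMat[p, eIds], mode)
    out$anchor_r[i] <- oraclePearson(normMat[p, sIds], a)
    out$tier[i] <- oracleTier(out$se_ratio[i])
    out$ref_expression[i] <- if (is.na(referenceSample))
      mean(normMat[p, sIds]) else normMat[p, referenceSample]
  }
  out[order(-out$ref_expression, out$probe_id), , drop = FALSE]
}

oracleCountAtThreshold <- function(normMat, stromaIds, anchorProbe, rMin) {
  a <- normMat[anchorProbe, stromaIds]
  n <- 0L
  for (p in setdiff(rownames(normMat), anchorProbe)) {
    r <- oraclePearson(normMat[p, stromaIds], a)
    if (!is.na(r) && r >= rMin) n <- n + 1L
  }
  n
}

# gene-level overlap recount under the best-probe rule
oracleOverlap <- function(screenDf, geneSymbols, refGenes, rMin) {
  df <- data.frame(probe = screenDf$probe_id, gene = geneSymbols,
                   r = screenDf$anchor_r, se = screenDf$se_ratio,
                   ms = screenDf$mean_stroma_expr,
                   stringsAsFactors = FALSE)
  df <- df[df$gene %in% refGenes, , drop = FALSE]
  genes <- unique(df$gene)
  passing <- c(); ses <- c()
  for (g in genes) {
    rows <- df[df$gene == g, , drop = FALSE]
    rows <- rows[order(-rows$ms, rows$probe), , drop = FALSE]
    best <- rows[1L, ]
    if (!is.na(best$r) && best$r >= rMin) {
      passing <- c(passing, g)
      ses <- c(ses, best$se)
    }
  }
  list(n_on_chip = length(genes), n_passing = length(passing),
       fraction = if (length(genes)) length(passing) / length(genes)
                  else NA_real_,
       mean_se = if (length(ses)) sum(ses) / length(ses) else NA_real_,
       passing = sort(passing))
}
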