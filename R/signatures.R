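#' Row-wise Z-score transformation of a gene-by-stage matrix
#'
#' Standardizes each gene's profile of stage-level enrichment (typically
#' log2 fold enrichment) to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Rows with zero variance carry no stage signal
#' and are excluded and reported.
#'
#' @param M Numeric genes-by-stages matrix with row and column names;
#'   at least 2 stages.
#' @return List of class `signature_matrix`: `z` (standardized matrix of
#'   the retained rows), `excluded` (gene ids of zero-variance rows).
#' @export
zscore_transform <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) < 2L) stopf("at least 2 stages are required")
  if (is.null(rownames(M))) rownames(M) <- as.character(seq_len(nrow(M)))
  sds <- apply(M, 1, sd)
  keep <- sds > 0
  z <- t(scale(t(M[keep, , drop = FALSE])))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(list(z = z, excluded = rownames(M)[!keep]),
            class = "signature_matrix")
}

#' Call stage-specific epitranscriptome signatures
#'
#' A gene is a signature of a stage when its standardized enrichment
#' exceeds the cutoff there (strictly; Z > 1.3 by default). With four
#' stages and row standardization, at most one stage per gene can exceed
#' any cutoff above 1.
#'
#' @param sig A `signature_matrix` from [zscore_transform()].
#' @param cutoff Z-score cutoff (strict >).
#' @return Named list (one element per stage) of signature gene ids.
#' @export
call_signatures <- function(sig, cutoff = 1.3) {
  stopifnot(inherits(sig, "signature_matrix"))
  z <- sig$z
  stages <- colnames(z)
  lapply(setNames(stages, stages), function(st) {
    rownames(z)[z[, st] > cutoff]
  })
}

#' Stage-level log2 fold-enrichment matrix for signature calling
#'
#' Pivots an enrichment table into the genes-by-stages matrix that
#' [zscore_transform()] expects, restricted to genes called NAD-capped
#' in at least one stage (epitranscriptome signatures are defined over
#' NAD-RNAs only).
#'
#' @param calls An `nad_calls` object from [call_nad_rnas()].
#' @param log2 Standardize log2 fold enrichment (default) rather than
#'   linear.
#' @return Numeric matrix, rows = genes called in >= 1 stage, columns =
#'   stages in their order of appearance.
#' @export
enrichment_matrix <- function(calls, log2 = TRUE) {
  stopifnot(inherits(calls, "nad_calls"))
  tab <- calls$table[!calls$table$is_spikein, , drop = FALSE]
  genes <- unique(unlist(calls$called, use.names = FALSE))
  stages <- unique(tab$stage)
  M <- matrix(NA_real_, nrow = length(genes), ncol = length(stages),
              dimnames = list(genes, stages))
  for (st in stages) {
    sub <- tab[tab$stage == st, , drop = FALSE]
    M[, st] <- sub$fold_enrichment[match(genes, sub$gene_id)]
  }
  if (log2) log2(M) else M
}
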