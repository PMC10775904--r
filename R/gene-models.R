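#' Generate an annotated synthetic gene set
#'
#' Lays genes end-to-end along each chromosome: per-chromosome membership
#' is multinomial in `chrom_weights`, gene lengths and intergenic gaps are
#' drawn from the supplied models, and the first gene of every chromosome
#' starts at position 1. Coordinates are 1-based inclusive throughout the
#' package. Defaults emulate a compact dipteran genome: median gene about
#' 2 kb, median intergenic gap about 1.5 kb, five large chromosome arms
#' plus a small autosome and a mitochondrial scaffold.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_weights Named numeric vector of chromosome probabilities
#'   (summing to 1 after normalization).
#' @param gap_model,length_model Functions of `n` returning `n` positive
#'   integer intergenic gaps / gene lengths (bp). The gap is the number of
#'   bases strictly between two consecutive genes.
#' @param utr_model List with functions `utr5` and `utr3`, each of `n`,
#'   returning non-negative integer UTR lengths. Non-coding biotypes get
#'   UTR length 0 regardless.
#' @param biotype_weights Named probabilities over biotypes.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `stop`,
#'   `strand`, `biotype`, `utr5_len`, `utr3_len`, `gene_length`, sorted
#'   by (chrom, start).
#' @export
generate_gene_models <- function(n_genes,
                                 chrom_weights = c("2L" = 0.21, "2R" = 0.21,
                                                   "3L" = 0.21, "3R" = 0.21,
                                                   "X" = 0.12, "4" = 0.02,
                                                   "mito" = 0.02),
                                 gap_model = function(n)
                                   pmax(1L, as.integer(round(rlnorm(n, log(1500), 1)))),
                                 length_model = function(n)
                                   pmax(200L, as.integer(round(rlnorm(n, log(2000), 0.8)))),
                                 utr_model = list(
                                   utr5 = function(n)
                                     as.integer(round(rlnorm(n, log(200), 0.7))),
                                   utr3 = function(n)
                                     as.integer(round(rlnorm(n, log(300), 0.7)))),
                                 biotype_weights = c(protein_coding = 0.88,
                                                     pseudogene = 0.04,
                                                     ncRNA = 0.08),
                                 seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    stopf("'n_genes' must be a positive integer")
  }
  n_genes <- as.integer(n_genes)
  if (length(chrom_weights) == 0L || is.null(names(chrom_weights))) {
    stopf("'chrom_weights' must be a non-empty named vector")
  }
  if (any(chrom_weights < 0) || sum(chrom_weights) <= 0) {
    stopf("'chrom_weights' must be non-negative and sum to a positive value")
  }
  chrom_weights <- chrom_weights / sum(chrom_weights)

  local_seed(seed, {
    chrom <- sample(names(chrom_weights), n_genes, replace = TRUE,
                    prob = chrom_weights)
    # keep chromosome order stable, then place genes sequentially
    chrom <- factor(chrom, levels = names(chrom_weights))
    ord <- order(chrom)
    chrom <- chrom[ord]
    lens <- length_model(n_genes)
    gaps <- gap_model(n_genes)      # gap before each gene; unused for firsts
    if (any(lens < 1)) stopf("length_model must yield positive integers")
    utr5 <- utr_model$utr5(n_genes)
    utr3 <- utr_model$utr3(n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    biotype <- sample(names(biotype_weights), n_genes, replace = TRUE,
                      prob = biotype_weights)

    start <- integer(n_genes)
    stop_ <- integer(n_genes)
    for (ch in levels(chrom)) {
      idx <- which(chrom == ch)
      if (!length(idx)) next
      s <- 1L
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (j > 1L) s <- stop_[idx[j - 1L]] + gaps[i] + 1L
        start[i] <- s
        stop_[i] <- s + lens[i] - 1L
      }
    }
    coding <- biotype == "protein_coding"
    utr5[!coding] <- 0L
    utr3[!coding] <- 0L
    out <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chrom = as.character(chrom),
      start = start,
      stop = stop_,
      strand = strand,
      biotype = biotype,
      utr5_len = pmax(0L, utr5),
      utr3_len = pmax(0L, utr3),
      stringsAsFactors = FALSE
    )
    out$gene_length <- out$stop - out$start + 1L
    out <- out[order(out$chrom, out$start, out$stop, out$gene_id), ]
    rownames(out) <- NULL
    out
  })
}

# Length-bias weight: genes at the median length get weight 1; shorter
# genes get more, longer genes less. bias = 0 is flat.
length_bias_weight <- function(gene_length, bias) {
  if (bias == 0) return(rep(1, length(gene_length)))
  (median(gene_length) / gene_length)^bias
}

#' Plant NAD-capping ground truth on a gene set
#'
#' Marks a background fraction of genes as NAD-capped (optionally biased
#' toward shorter genes) and additionally plants physical clusters: runs
#' of consecutive genes on one chromosome whose adjacent gaps do not
#' exceed `max_intra_gap`, all set NAD-positive. NAD genes receive a
#' capture-gain multiplier applied to their enrichment-library abundance;
#' with `length_bias > 0` the gain is also graded so that shorter genes
#' are more strongly modified, which is what the enrichment-decile
#' analysis measures downstream.
#'
#' @param genes Gene table from [generate_gene_models()].
#' @param base_rate Background per-gene NAD probability in \[0,1\].
#' @param gain Capture-gain multiplier for NAD genes (at the median gene
#'   length when `length_bias > 0`); 1.0 means no enrichment.
#' @param n_clusters,cluster_size Number and size (>= 3) of planted
#'   clusters of consecutive genes.
#' @param max_intra_gap Maximum allowed gap (bp, start-of-next minus
#'   stop-of-previous) between adjacent members of a planted cluster.
#' @param length_bias Non-negative exponent; 0 disables the short-gene
#'   bias of both NAD probability and gain.
#' @param seed Integer seed.
#' @return Data frame aligned with `genes`: `gene_id`, `is_nad`, `gain`
#'   (1.0 for non-NAD genes), `cluster_id` (NA outside planted clusters).
#' @export
plant_truth <- function(genes, base_rate = 0.1, gain = 8,
                        n_clusters = 0L, cluster_size = 4L,
                        max_intra_gap = 2000L, length_bias = 0,
                        seed = 1L) {
  if (base_rate < 0 || base_rate > 1) stopf("'base_rate' must be in [0, 1]")
  if (gain <= 0) stopf("'gain' must be positive")
  if (n_clusters > 0 && cluster_size < 3) {
    stopf("'cluster_size' must be at least 3")
  }
  n <- nrow(genes)
  local_seed(seed, {
    w <- length_bias_weight(genes$gene_length, length_bias)
    p <- pmin(1, base_rate * w / mean(w))
    is_nad <- runif(n) < p
    cluster_id <- rep(NA_integer_, n)

    if (n_clusters > 0) {
      # candidate runs: cluster_size consecutive genes on one chromosome
      # with every adjacent gap <= max_intra_gap (annotation order)
      same_chrom <- genes$chrom[-1] == genes$chrom[-n]
      gap_ok <- same_chrom &
        (genes$start[-1] - genes$stop[-n]) <= max_intra_gap
      run_ok <- vapply(seq_len(n - cluster_size + 1L), function(i) {
        all(gap_ok[i:(i + cluster_size - 2L)])
      }, logical(1))
      candidates <- which(run_ok)
      if (!length(candidates)) {
        stopf("placement error: no run of %d genes with gaps <= %d bp",
              cluster_size, max_intra_gap)
      }
      taken <- logical(n)
      placed <- 0L
      attempts <- 0L
      max_attempts <- 200L * n_clusters
      while (placed < n_clusters && attempts < max_attempts) {
        attempts <- attempts + 1L
        i <- sample(candidates, 1L)
        span <- i:(i + cluster_size - 1L)
        if (any(taken[span])) next
        taken[span] <- TRUE
        placed <- placed + 1L
        is_nad[span] <- TRUE
        cluster_id[span] <- placed
      }
      if (placed < n_clusters) {
        stopf("placement error: could only place %d of %d clusters",
              placed, n_clusters)
      }
    }

    g <- rep(1, n)
    if (length_bias > 0) {
      g[is_nad] <- 1 + (gain - 1) * w[is_nad]
    } else {
      g[is_nad] <- gain
    }
    data.frame(gene_id = genes$gene_id, is_nad = is_nad, gain = g,
               cluster_id = cluster_id, stringsAsFactors = FALSE)
  })
}
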