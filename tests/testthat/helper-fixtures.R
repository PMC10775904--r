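# Shared fixtures and independent oracles, built in code at test time.

# Minimal gene table from coordinate vectors.
make_genes <- function(starts, stops, chrom = "2L",
                       ids = sprintf("g%03d", seq_along(starts)),
                       biotype = "protein_coding",
                       utr5 = 100L, utr3 = 150L) {
  g <- data.frame(
    gene_id = ids, chrom = chrom,
    start = as.integer(starts), stop = as.integer(stops),
    strand = "+", biotype = biotype,
    utr5_len = as.integer(utr5), utr3_len = as.integer(utr3),
    stringsAsFactors = FALSE
  )
  g$gene_length <- g$stop - g$start + 1L
  g[order(g$chrom, g$start, g$stop, g$gene_id), ]
}

# Paired count matrix from a raw matrix; columns alternate input/enrichment
# per replicate, single stage by default.
make_cm <- function(counts, stage = "s1",
                    n_scaling = 0L, scaling_value = 50L) {
  n_pairs <- ncol(counts) / 2
  stopifnot(n_pairs == floor(n_pairs))
  libs <- data.frame(
    library_id = paste0("L", seq_len(ncol(counts))),
    stage = stage,
    replicate = rep(seq_len(n_pairs), each = 2),
    fraction = rep(c("input", "enrichment"), n_pairs),
    stringsAsFactors = FALSE
  )
  ids <- sprintf("g%03d", seq_len(nrow(counts)))
  is_sp <- rep(FALSE, nrow(counts))
  cls <- rep(NA_character_, nrow(counts))
  if (n_scaling > 0) {
    counts <- rbind(counts,
                    matrix(scaling_value, n_scaling, ncol(counts)))
    ids <- c(ids, sprintf("sp%02d", seq_len(n_scaling)))
    is_sp <- c(is_sp, rep(TRUE, n_scaling))
    cls <- c(cls, rep("scaling", n_scaling))
  }
  dimnames(counts) <- list(ids, libs$library_id)
  count_matrix(counts, libs,
               data.frame(gene_id = ids, is_spikein = is_sp,
                          spikein_class = cls, stringsAsFactors = FALSE))
}

# Exhaustive cluster oracle: every maximal window of >= N_min genes whose
# adjacent gaps are all <= L_kb * 1000, found by enumeration rather than a
# single pass. Returns a sorted list of member-id vectors.
oracle_clusters <- function(genes, L_kb, N_min = 3L) {
  max_gap <- L_kb * 1000
  found <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$stop, g$gene_id), , drop = FALSE]
    k <- nrow(g)
    if (k < N_min) next
    gap_ok <- if (k > 1) (g$start[-1] - g$stop[-k]) <= max_gap else logical(0)
    for (i in seq_len(k)) {
      for (j in i:k) {
        if (j - i + 1 < N_min) next
        if (!all(gap_ok[seq(i, j - 1)])) next
        left_max <- i == 1 || !gap_ok[i - 1]
        right_max <- j == k || !gap_ok[j]
        if (left_max && right_max) {
          found[[length(found) + 1L]] <- g$gene_id[i:j]
        }
      }
    }
  }
  found[order(vapply(found, paste, "", collapse = ","))]
}

# Random gene instance on up to `n_chrom` chromosomes, with gaps spanning
# the joining threshold so cluster structure is non-trivial.
random_instance <- function(n_genes, n_chrom = 3, seed) {
  withr::with_seed(seed, {
    chrom <- sample(paste0("chr", seq_len(n_chrom)), n_genes, replace = TRUE)
    lens <- sample(200:3000, n_genes, replace = TRUE)
    gaps <- sample(c(1:2000, 2500:8000), n_genes, replace = TRUE)
    df <- do.call(rbind, lapply(split(seq_len(n_genes), chrom), function(idx) {
      s <- cumsum(c(1L, (lens[idx] + gaps[idx])[-length(idx)]))
      data.frame(idx = idx, start = s, stop = s + lens[idx] - 1L)
    }))
    make_genes(df$start, df$stop, chrom = chrom[df$idx],
               ids = sprintf("g%03d", df$idx))
  })
}

# Simulated study at the defaults used across recovery checks.
simulate_study <- function(seed, n_genes = 300, base_rate = 0.15, gain = 8,
                           depth = 1e5, replicates = 3, dispersion = 0.05,
                           length_bias = 0, spikeins = spikein_spec(),
                           gain_by_stage = NULL) {
  genes <- generate_gene_models(n_genes, seed = seed)
  truth <- plant_truth(genes, base_rate = base_rate, gain = gain,
                       length_bias = length_bias, seed = seed + 1L)
  design <- design_spec(replicates = replicates, depth = depth,
                        dispersion = dispersion, seed = seed + 2L)
  cm <- simulate_counts(genes, truth, design, spikeins = spikeins,
                        gain_by_stage = gain_by_stage)
  list(genes = genes, truth = truth, cm = cm)
}
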