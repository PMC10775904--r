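#' Genomic gap between two adjacent genes
#'
#' The distance used by the physical-cluster definition: the start
#' position of the downstream (most 3') gene minus the stop position of
#' the upstream (most 5') gene. Negative or zero values arise for
#' overlapping or abutting genes and always satisfy the cluster gap
#' rule.
#'
#' @param a,b Single gene records (one-row data frames or lists with
#'   `chrom`, `start`, `stop`); `a` must not start downstream of `b`.
#' @return Integer gap in bp (may be <= 0).
#' @export
adjacent_gap <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) {
    stopf("genes lie on different chromosomes (%s vs %s)", a$chrom, b$chrom)
  }
  if (a$start > b$start) stopf("'a' must be the upstream gene")
  as.integer(b$start - a$stop)
}

# Count maximal runs of >= N_min genes whose adjacent gaps are all
# <= max_gap, given per-selection sorted starts/stops on ONE chromosome.
count_runs <- function(starts, stops, max_gap, N_min) {
  k <- length(starts)
  if (k < N_min) return(0L)
  ok <- (starts[-1] - stops[-k]) <= max_gap
  sizes <- diff(c(0L, which(!ok), k))   # maximal-run sizes, in genes
  sum(sizes >= N_min)
}

#' Find physical clusters of called genes
#'
#' A physical cluster is a group of at least `N_min` (default 3) called
#' genes on one chromosome in which every pair of adjacent genes —
#' sorted by start, disregarding strand and any intervening uncalled
#' genes — is separated by at most `L_kb` kilobases, measured from the
#' stop of the upstream gene to the start of the downstream gene
#' (inclusive: a gap of exactly `L_kb` joins). Clusters are the maximal
#' such runs, found in a single left-to-right pass per chromosome.
#'
#' @param called_genes Gene table restricted to the called (NAD-capped)
#'   set; duplicates by `gene_id` are removed.
#' @param L_kb Maximum adjacent-gene distance in kilobases.
#' @param N_min Minimum cluster size (>= 1; 3 by definition).
#' @return Data frame, one row per cluster: `cluster_id`, `chrom`,
#'   `span_start`, `span_stop`, `size`, and a list column `members`
#'   holding the ordered member gene ids.
#' @export
find_physical_clusters <- function(called_genes, L_kb = 3, N_min = 3L) {
  if (N_min < 1L) stopf("'N_min' must be at least 1")
  if (L_kb <= 0) stopf("'L_kb' must be positive")
  max_gap <- L_kb * 1000
  g <- called_genes[!duplicated(called_genes$gene_id), , drop = FALSE]
  g <- g[order(g$chrom, g$start, g$stop, g$gene_id), , drop = FALSE]

  out <- list()
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, , drop = FALSE]
    k <- nrow(gc)
    if (k < N_min) next
    ok <- (gc$start[-1] - gc$stop[-k]) <= max_gap
    bounds <- c(0L, which(!ok), k)      # maximal runs between broken gaps
    for (j in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[j] + 1L):bounds[j + 1L]
      if (length(idx) < N_min) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        span_start = gc$start[idx[1]],
        span_stop = max(gc$stop[idx]),
        size = length(idx),
        members = I(list(gc$gene_id[idx])),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      span_start = integer(0), span_stop = integer(0),
                      size = integer(0), members = I(list()),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- cbind(cluster_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Null distribution of cluster counts by stratified resampling
#'
#' Draws, `n_perm` times, a random gene set with the same per-chromosome
#' composition as the true called set — sampling without replacement
#' within each chromosome from the full gene pool — and records the
#' number of physical clusters found at the same `L_kb`/`N_min` setting.
#'
#' @param all_genes Full gene pool (gene table).
#' @param stratify Named integer vector: how many genes to draw per
#'   chromosome (typically `table(chrom)` of the called set).
#' @param L_kb,N_min Cluster parameters, as in
#'   [find_physical_clusters()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Integer vector of `n_perm` null cluster counts.
#' @export
simulate_null_clusters <- function(all_genes, stratify, L_kb = 3,
                                   N_min = 3L, n_perm = 10000L, seed = 1L) {
  if (L_kb <= 0) stopf("'L_kb' must be positive")
  max_gap <- L_kb * 1000
  stratify <- stratify[stratify > 0]
  chroms <- names(stratify)
  pool <- lapply(setNames(chroms, chroms), function(ch) {
    gc <- all_genes[all_genes$chrom == ch, , drop = FALSE]
    gc <- gc[order(gc$start, gc$stop, gc$gene_id), , drop = FALSE]
    list(start = gc$start, stop = gc$stop, n = nrow(gc))
  })
  for (ch in chroms) {
    if (stratify[[ch]] > pool[[ch]]$n) {
      stopf("sampling error: stratum %s asks for %d of %d genes",
            ch, stratify[[ch]], pool[[ch]]$n)
    }
  }
  local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      total <- 0L
      for (ch in chroms) {
        p <- pool[[ch]]
        k <- stratify[[ch]]
        idx <- sort.int(sample.int(p$n, k))
        total <- total + count_runs(p$start[idx], p$stop[idx],
                                    max_gap, N_min)
      }
      total
    }, integer(1))
  })
}

#' Empirical p-value of an observed cluster count
#'
#' p = (number of null counts >= observed count) / (number of
#' permutations). When no null draw reaches the observed count the
#' p-value is below the resolution of the permutation test and is
#' reported as a bound, p < 1/n_perm (e.g. "p < 1e-04" at 10000
#' permutations); the stored `p_value` is then 1/n_perm and
#' `below_resolution` is set.
#'
#' @param C_true Observed cluster count.
#' @param null_counts Integer vector of null cluster counts.
#' @return List: `p_value` in (0, 1], `below_resolution`, `n_perm`,
#'   `label` (printable form).
#' @export
cluster_significance <- function(C_true, null_counts) {
  if (!length(null_counts)) stopf("'null_counts' must be non-empty")
  n_perm <- length(null_counts)
  hits <- sum(null_counts >= C_true)
  if (hits == 0L) {
    list(p_value = 1 / n_perm, below_resolution = TRUE, n_perm = n_perm,
         label = sprintf("p < %g", 1 / n_perm))
  } else {
    list(p_value = hits / n_perm, below_resolution = FALSE, n_perm = n_perm,
         label = sprintf("p = %g", hits / n_perm))
  }
}

#' Full physical-cluster permutation test
#'
#' Finds clusters in the called set, builds the chromosome-stratified
#' null with [simulate_null_clusters()], and reports the empirical
#' p-value.
#'
#' @param called_genes Gene table of the called set.
#' @param all_genes Gene pool for the null (default: the annotation the
#'   called set came from; pass the full annotation).
#' @param L_kb,N_min,n_perm,seed See [simulate_null_clusters()].
#' @return List of class `cluster_test`: `clusters`, `C_true`,
#'   `clustered_genes`, `null_counts`, `p_value`, `below_resolution`,
#'   `label`, plus the parameters.
#' @export
cluster_test <- function(called_genes, all_genes, L_kb = 3, N_min = 3L,
                         n_perm = 10000L, seed = 1L) {
  clusters <- find_physical_clusters(called_genes, L_kb = L_kb, N_min = N_min)
  C_true <- nrow(clusters)
  stratify <- table(called_genes$chrom[!duplicated(called_genes$gene_id)])
  null_counts <- simulate_null_clusters(all_genes, stratify, L_kb = L_kb,
                                        N_min = N_min, n_perm = n_perm,
                                        seed = seed)
  sig <- cluster_significance(C_true, null_counts)
  structure(c(list(clusters = clusters, C_true = C_true,
                   clustered_genes = sum(clusters$size),
                   null_counts = null_counts),
              sig,
              list(L_kb = L_kb, N_min = N_min)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("physical-cluster test (L = %g kb, N >= %d, %d permutations)\n",
              x$L_kb, x$N_min, x$n_perm))
  cat(sprintf("  C_true = %d clusters (%d genes); null mean %.2f; %s\n",
              x$C_true, x$clustered_genes, mean(x$null_counts), x$label))
  invisible(x)
}

#' Scan maximum-gap settings L
#'
#' Runs the full permutation test at each L in `L_list` (1–5 kb by
#' default) and tabulates the observed cluster count, clustered-gene
#' total, null summary and p-value per setting. Each L uses a seed
#' deterministically derived from `seed` and its position in `L_list`,
#' so a scan reproduces single-L runs exactly.
#'
#' @param called_genes,all_genes,N_min,n_perm,seed As in
#'   [cluster_test()].
#' @param L_list Numeric vector of L settings in kilobases.
#' @return List: `summary` (data frame with one row per L) and
#'   `results` (list of `cluster_test` objects, named by L).
#' @export
scan_L_settings <- function(called_genes, all_genes,
                            L_list = c(1, 2, 3, 4, 5), N_min = 3L,
                            n_perm = 10000L, seed = 1L) {
  if (!length(L_list) || any(L_list <= 0)) {
    stopf("'L_list' must be non-empty and positive")
  }
  results <- lapply(seq_along(L_list), function(i) {
    cluster_test(called_genes, all_genes, L_kb = L_list[i], N_min = N_min,
                 n_perm = n_perm, seed = derive_seed(seed, i))
  })
  names(results) <- as.character(L_list)
  summary <- data.frame(
    L_kb = L_list,
    C_true = vapply(results, `[[`, integer(1), "C_true"),
    clustered_genes = vapply(results, function(r)
      as.integer(r$clustered_genes), integer(1)),
    null_mean = vapply(results, function(r) mean(r$null_counts), numeric(1)),
    null_max = vapply(results, function(r) max(r$null_counts), numeric(1)),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    below_resolution = vapply(results, `[[`, logical(1), "below_resolution")
  )
  rownames(summary) <- NULL
  list(summary = summary, results = results)
}
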