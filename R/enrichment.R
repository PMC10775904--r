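#' Spike-in anchored median-of-ratios scale factors
#'
#' Library size factors in the style of median-of-ratios normalization,
#' computed on the anchor rows only — by default the scaling spike-ins,
#' which are added to every sample in fixed amounts and therefore absorb
#' technical variation without being distorted by biological enrichment.
#' Each anchor row is divided by its row-wise geometric mean (rows with a
#' zero in any library are dropped), the per-library median of those
#' ratios is taken, and factors are rescaled to geometric mean 1.
#' Normalized count = raw count / factor.
#'
#' @param cm A [count_matrix()].
#' @param anchor `"scaling-spikeins"` (default) or `"all-genes"`.
#' @return Named numeric vector of positive factors, one per library,
#'   with geometric mean 1; class `scale_factors`.
#' @export
compute_scale_factors <- function(cm, anchor = c("scaling-spikeins",
                                                 "all-genes")) {
  anchor <- match.arg(anchor)
  rows <- if (anchor == "scaling-spikeins") {
    which(cm$rows$is_spikein & cm$rows$spikein_class %in% "scaling")
  } else {
    which(!cm$rows$is_spikein)
  }
  if (!length(rows)) stopf("normalization error: no anchor rows (%s)", anchor)
  m <- cm$counts[rows, , drop = FALSE]
  keep <- rowSums(m == 0) == 0
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) {
    stopf("normalization error: every anchor row has a zero in some library")
  }
  logm <- log(m)
  log_ratio <- logm - rowMeans(logm)           # row-wise geometric mean
  f <- exp(apply(log_ratio, 2, median))
  f <- f / geometric_mean(f)
  structure(setNames(f, colnames(cm$counts)), class = "scale_factors",
            anchor = anchor, n_anchor_rows = nrow(m))
}

#' Normalize a count matrix by scale factors
#'
#' @param cm A [count_matrix()].
#' @param factors A `scale_factors` vector from [compute_scale_factors()].
#' @return Numeric matrix of normalized counts (raw / factor).
#' @export
normalize_counts <- function(cm, factors) {
  if (!identical(names(factors), colnames(cm$counts))) {
    stopf("scale factors do not match the libraries of this count matrix")
  }
  sweep(cm$counts, 2, unclass(factors), "/")
}

#' Per-gene, per-stage fold enrichment
#'
#' For every row and stage, the mean of normalized counts over the
#' enrichment replicates is divided by the mean over the input
#' replicates, after adding a pseudocount to both: FC =
#' (mean enrichment + pseudocount) / (mean input + pseudocount). With the
#' default pseudocount of 1 normalized count, genes absent from both
#' fractions get FC = 1 rather than a spurious signal.
#'
#' @param cm A [count_matrix()].
#' @param factors Scale factors from [compute_scale_factors()].
#' @param pseudocount Non-negative pseudocount (normalized counts).
#' @return Data frame (the enrichment table): `gene_id`, `stage`,
#'   `mean_input_norm`, `mean_enrich_norm`, `fold_enrichment`,
#'   `is_spikein`, `spikein_class`; one row per gene per stage.
#' @export
compute_fold_enrichment <- function(cm, factors = compute_scale_factors(cm),
                                    pseudocount = 1) {
  if (pseudocount < 0) stopf("'pseudocount' must be non-negative")
  norm <- normalize_counts(cm, factors)
  stages <- unique(cm$libraries$stage)
  out <- vector("list", length(stages))
  for (k in seq_along(stages)) {
    st <- stages[k]
    in_cols <- cm$libraries$stage == st & cm$libraries$fraction == "input"
    en_cols <- cm$libraries$stage == st & cm$libraries$fraction == "enrichment"
    if (!any(in_cols) || !any(en_cols)) {
      stopf("pairing error: stage '%s' lacks input or enrichment libraries", st)
    }
    mi <- rowMeans(norm[, in_cols, drop = FALSE])
    me <- rowMeans(norm[, en_cols, drop = FALSE])
    out[[k]] <- data.frame(
      gene_id = cm$rows$gene_id,
      stage = st,
      mean_input_norm = mi,
      mean_enrich_norm = me,
      fold_enrichment = (me + pseudocount) / (mi + pseudocount),
      is_spikein = cm$rows$is_spikein,
      spikein_class = cm$rows$spikein_class,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call NAD-RNAs at a fold-enrichment cutoff with tiered lists
#'
#' A gene is called NAD-capped at a stage when its fold enrichment is at
#' least `cutoff` (inclusive) and its mean normalized input count passes
#' the detection filter `min_input`, which prevents calls driven purely
#' by pseudocounts on undetected genes. Called genes are additionally
#' tiered at fold enrichment at and higher than 4, 6 and 8; the tier
#' lists are nested by construction. Spike-in rows are never called.
#'
#' @param tab Enrichment table from [compute_fold_enrichment()].
#' @param cutoff Fold-enrichment cutoff (>= 1); default 2.
#' @param min_input Detection filter on mean normalized input counts.
#' @param tiers Tier cutoffs for the nested lists.
#' @return List of class `nad_calls`: `table` (the enrichment table with
#'   `is_called` and `tier` columns; `tier` is the highest tier cutoff
#'   reached, NA for uncalled rows), `called` (per-stage character
#'   vectors of called gene ids), `tier_lists` (per stage, a list of
#'   gene-id vectors named by tier cutoff).
#' @export
call_nad_rnas <- function(tab, cutoff = 2, min_input = 10,
                          tiers = c(2, 4, 6, 8)) {
  if (cutoff < 1) stopf("'cutoff' must be at least 1")
  tiers <- sort(unique(c(cutoff, tiers[tiers >= cutoff])))
  gene <- !tab$is_spikein
  called <- gene & tab$fold_enrichment >= cutoff &
    tab$mean_input_norm >= min_input
  tier <- rep(NA_real_, nrow(tab))
  for (t in tiers) tier[called & tab$fold_enrichment >= t] <- t
  tab$is_called <- called
  tab$tier <- tier
  stages <- unique(tab$stage)
  called_by_stage <- lapply(setNames(stages, stages), function(st) {
    tab$gene_id[tab$stage == st & tab$is_called]
  })
  tier_lists <- lapply(setNames(stages, stages), function(st) {
    lapply(setNames(tiers, tiers), function(t) {
      tab$gene_id[tab$stage == st & tab$is_called &
                    tab$fold_enrichment >= t]
    })
  })
  structure(list(table = tab, called = called_by_stage,
                 tier_lists = tier_lists, cutoff = cutoff,
                 min_input = min_input),
            class = "nad_calls")
}

#' @export
print.nad_calls <- function(x, ...) {
  cat(sprintf("NAD-RNA calls (FC >= %g, mean input >= %g):\n",
              x$cutoff, x$min_input))
  for (st in names(x$called)) {
    cat(sprintf("  %s: %d genes\n", st, length(x$called[[st]])))
  }
  invisible(x)
}

#' Assess sensitivity and specificity spike-in controls
#'
#' Reports the fold enrichment of each spike-in class per stage and
#' pooled over stages, with pass/fail flags evaluated on the pooled
#' value: the specificity spike-in (100% m7G-capped) must stay below
#' 2-fold, the sensitivity spike-in (partly NAD-capped) must reach at
#' least 2-fold.
#'
#' @param tab Enrichment table from [compute_fold_enrichment()]; must
#'   contain sensitivity and specificity spike-in rows.
#' @param cutoff Fold-enrichment cutoff separating pass from fail.
#' @return List with `report` (data frame: `spikein_class`, `stage`,
#'   `fold_enrichment`; stage `"all"` pools replicate means over stages),
#'   `sensitivity_pass`, `specificity_pass`.
#' @export
assess_spikein_controls <- function(tab, cutoff = 2) {
  sp <- tab[tab$is_spikein & tab$spikein_class %in%
              c("sensitivity", "specificity"), , drop = FALSE]
  for (cl in c("sensitivity", "specificity")) {
    if (!any(sp$spikein_class == cl)) {
      stopf("control error: %s spike-in absent", cl)
    }
  }
  per_stage <- sp[, c("spikein_class", "stage", "fold_enrichment")]
  pooled <- stats::aggregate(
    cbind(mean_input_norm, mean_enrich_norm) ~ spikein_class,
    data = sp, FUN = mean)
  pooled$stage <- "all"
  pooled$fold_enrichment <-
    (pooled$mean_enrich_norm + 1) / (pooled$mean_input_norm + 1)
  report <- rbind(per_stage[, c("spikein_class", "stage", "fold_enrichment")],
                  pooled[, c("spikein_class", "stage", "fold_enrichment")])
  fc_all <- setNames(pooled$fold_enrichment, pooled$spikein_class)
  list(report = report,
       sensitivity_fc = unname(fc_all["sensitivity"]),
       specificity_fc = unname(fc_all["specificity"]),
       sensitivity_pass = fc_all["sensitivity"] >= cutoff,
       specificity_pass = fc_all["specificity"] < cutoff)
}

#' Sequencing-saturation curve by binomial subsampling
#'
#' Randomly thins one library to a series of depth fractions and counts,
#' at each fraction, the genes detected with strictly more than
#' `threshold` reads, averaged over `n_draws` independent subsamples.
#' A plateau indicates that sequencing saturation has been reached.
#'
#' @param counts Integer vector of one library's counts.
#' @param fractions Depth fractions in (0, 1].
#' @param threshold Detection threshold; a gene counts as detected when
#'   its subsampled count is strictly greater than this (default 10).
#' @param n_draws Subsamples per fraction.
#' @param seed Integer seed.
#' @return Data frame: `fraction`, `mean_detected`, `sd_detected`.
#' @export
saturation_curve <- function(counts, fractions = seq(0.1, 1, by = 0.1),
                             threshold = 10L, n_draws = 10L, seed = 1L) {
  if (sum(counts) <= 0) stopf("library total must be positive")
  if (any(fractions <= 0 | fractions > 1)) {
    stopf("fractions must lie in (0, 1]")
  }
  counts <- as.integer(counts)
  local_seed(seed, {
    res <- lapply(fractions, function(f) {
      det <- vapply(seq_len(n_draws), function(i) {
        sub <- if (f == 1) counts else rbinom(length(counts), counts, f)
        sum(sub > threshold)
      }, numeric(1))
      data.frame(fraction = f, mean_detected = mean(det),
                 sd_detected = sd(det))
    })
    do.call(rbind, res)
  })
}
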