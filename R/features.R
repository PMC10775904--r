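#' Enrichment deciles versus gene length
#'
#' Ranks called genes by fold enrichment, splits them into 10
#' equal-frequency bins (decile 1 = lowest enrichment; ties broken by
#' gene id; when the count is not a multiple of 10 the remainder is
#' spread over the lowest deciles), and reports per-decile medians. A
#' decreasing median length across deciles indicates that shorter genes
#' carry stronger NAD capping.
#'
#' @param called Data frame with columns `gene_id`, `fold_enrichment`,
#'   `gene_length`; at least 10 rows.
#' @return Data frame: `decile`, `n`, `median_length`, `median_fc`.
#' @export
enrichment_deciles <- function(called) {
  n <- nrow(called)
  if (n < 10L) stopf("at least 10 called genes are required")
  ord <- order(called$fold_enrichment, called$gene_id)
  sizes <- rep(n %/% 10L, 10L)
  rem <- n %% 10L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  decile <- rep(seq_len(10L), times = sizes)
  x <- called[ord, , drop = FALSE]
  out <- data.frame(
    decile = seq_len(10L),
    n = sizes,
    median_length = vapply(split(x$gene_length, decile), median, numeric(1)),
    median_fc = vapply(split(x$fold_enrichment, decile), median, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' Compare UTR lengths between two gene groups
#'
#' Welch two-sample t test (two-tailed) between, typically, the UTR
#' lengths of NAD-capped genes and of expressed genes capped only by
#' m7G. Genes with zero annotated UTR should be excluded upstream
#' (length 0 is treated as missing annotation, not as a short UTR).
#'
#' @param group_a,group_b Numeric vectors of UTR lengths (bp); each
#'   needs >= 2 values and positive variance.
#' @return List: `mean_a`, `mean_b`, `t` (sign = sign(mean_a - mean_b)),
#'   `p` (two-tailed), `df`.
#' @export
compare_utr_lengths <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stopf("statistics error: both groups need at least 2 values")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(mean_a = mean(group_a), mean_b = mean(group_b),
                  t = 0, p = 1, df = length(group_a) + length(group_b) - 2))
    }
    stopf("statistics error: both groups are constant")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(mean_a = unname(ht$estimate[1]), mean_b = unname(ht$estimate[2]),
       t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Per-gene correlation between expression and NAD capping
#'
#' For each gene, the Pearson correlation between its expression profile
#' (log2 normalized input means per stage) and its capping profile (log2
#' fold enrichment per stage) across stages, with a two-tailed p-value
#' from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' Genes whose profile is constant in either matrix have no defined
#' correlation and are flagged (`sign_class` `"undefined"`) and excluded
#' from significance counts.
#'
#' @param expr,cap Numeric genes-by-stages matrices with matching row
#'   and column names; at least 3 stages.
#' @param alpha Significance threshold on the two-tailed p (default
#'   0.05).
#' @return Data frame: `gene_id`, `r`, `p`, `n`, `sign_class`
#'   (`"negative-significant"`, `"positive-significant"`, `"ns"`,
#'   `"undefined"`).
#' @export
expression_capping_correlation <- function(expr, cap, alpha = 0.05) {
  expr <- as.matrix(expr)
  cap <- as.matrix(cap)
  if (!identical(dimnames(expr), dimnames(cap))) {
    stopf("'expr' and 'cap' must have identical gene and stage names")
  }
  n <- ncol(expr)
  if (n < 3L) stopf("at least 3 stages are required")
  res <- lapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    y <- cap[i, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(data.frame(gene_id = rownames(expr)[i], r = NA_real_,
                        p = NA_real_, n = n, sign_class = "undefined",
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    cls <- if (p < alpha) {
      if (r < 0) "negative-significant" else "positive-significant"
    } else "ns"
    data.frame(gene_id = rownames(expr)[i], r = r, p = p, n = n,
               sign_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tabulate called genes by biotype or chromosome
#'
#' Exact counts of called genes per category and stage; categories
#' present in the annotation but without calls are reported with count
#' 0.
#'
#' @param called_by_stage Named list (stage -> character vector of
#'   called gene ids).
#' @param annotation Gene table covering every called gene.
#' @param field `"biotype"` or `"chrom"`.
#' @return Data frame: `stage`, `category`, `count`.
#' @export
tabulate_calls <- function(called_by_stage, annotation,
                           field = c("biotype", "chrom")) {
  field <- match.arg(field)
  categories <- sort(unique(annotation[[field]]))
  out <- list()
  for (st in names(called_by_stage)) {
    ids <- called_by_stage[[st]]
    missing <- setdiff(ids, annotation$gene_id)
    if (length(missing)) {
      stopf("called gene absent from annotation: %s", missing[1])
    }
    cat_of <- annotation[[field]][match(ids, annotation$gene_id)]
    counts <- table(factor(cat_of, levels = categories))
    out[[st]] <- data.frame(stage = st, category = categories,
                            count = as.integer(counts),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
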