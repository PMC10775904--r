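# Hand-computed median-of-ratios oracle used against the implementation.
oracle_scale_factors <- function(anchor_counts) {
  keep <- apply(anchor_counts, 1, function(r) all(r > 0))
  m <- anchor_counts[keep, , drop = FALSE]
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  f <- apply(m / gm, 2, median)
  f / exp(mean(log(f)))
}

test_that("identical libraries get unit scale factors", {
  counts <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
                   dimnames = list(letters[1:3], c("L1", "L2")))
  cm <- make_cm(counts, n_scaling = 3)
  f <- compute_scale_factors(cm)
  expect_equal(as.numeric(f), c(1, 1))
})

test_that("a doubled library splits factors as (1/sqrt(2), sqrt(2))", {
  base <- c(10L, 25L, 40L, 80L)
  counts <- cbind(L1 = base, L2 = 2L * base)
  rownames(counts) <- letters[1:4]
  cm <- make_cm(counts, n_scaling = 0)
  # anchor on all genes since every row carries the same distortion
  f <- compute_scale_factors(cm, anchor = "all-genes")
  expect_equal(as.numeric(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  norm <- normalize_counts(cm, f)
  expect_equal(norm[, 1], norm[, 2], tolerance = 1e-12)
})

test_that("factors match the brute-force median-of-ratios oracle", {
  withr::with_seed(42, {
    for (i in 1:5) {
      anchors <- matrix(sample(5:500, 20L), 5, 4)
      genes <- matrix(sample(0:100, 12L), 3, 4)
      cm <- make_cm(rbind(genes, anchors))
      cm$rows$is_spikein[4:8] <- TRUE
      cm$rows$spikein_class[4:8] <- "scaling"
      f <- compute_scale_factors(cm)
      expect_equal(as.numeric(f), unname(oracle_scale_factors(anchors)),
                   tolerance = 1e-12)
    }
  })
})

test_that("all-zero anchor rows are dropped; no usable anchors is an error", {
  counts <- rbind(c(5L, 7L), c(0L, 3L))
  rownames(counts) <- c("a", "b")
  cm <- make_cm(counts)
  cm$rows$is_spikein[] <- TRUE
  cm$rows$spikein_class[] <- "scaling"
  f <- compute_scale_factors(cm)
  expect_equal(attr(f, "n_anchor_rows"), 1L)
  cm$counts[1, 1] <- 0L
  expect_error(compute_scale_factors(cm), "normalization error")
})

test_that("fold enrichment follows the pseudocount formula", {
  counts <- cbind(L1 = c(50L, 0L, 30L), L2 = c(100L, 0L, 30L))
  rownames(counts) <- c("a", "b", "c")
  cm <- make_cm(counts, n_scaling = 3)
  tab <- compute_fold_enrichment(cm, pseudocount = 1)
  tab <- tab[!tab$is_spikein, ]
  expect_equal(tab$fold_enrichment[tab$gene_id == "g001"], 101 / 51)
  expect_equal(tab$fold_enrichment[tab$gene_id == "g002"], 1)  # 0/0 guard
  tab0 <- compute_fold_enrichment(cm, pseudocount = 0)
  expect_equal(tab0$fold_enrichment[tab0$gene_id == "g003"], 1)
})

test_that("calling respects cutoff, detection filter and tier nesting", {
  tab <- data.frame(
    gene_id = sprintf("g%d", 1:6), stage = "s1",
    mean_input_norm = c(50, 50, 50, 5, 50, 50),
    mean_enrich_norm = c(50, 250, 450, 50, 100, 40),
    fold_enrichment = c(1, 4.0, 8.5, 9, 2.0, 0.8),
    is_spikein = FALSE, spikein_class = NA_character_,
    stringsAsFactors = FALSE
  )
  calls <- call_nad_rnas(tab, cutoff = 2, min_input = 10)
  expect_setequal(calls$called$s1, c("g2", "g3", "g5"))  # g4 fails filter
  tl <- calls$tier_lists$s1
  expect_true("g2" %in% tl[["4"]])          # inclusive: FC = 4.0 is in tier 4
  expect_false("g2" %in% tl[["6"]])
  expect_true("g3" %in% tl[["8"]])
  expect_true(all(tl[["8"]] %in% tl[["6"]]) &&
                all(tl[["6"]] %in% tl[["4"]]) &&
                all(tl[["4"]] %in% tl[["2"]]))
  expect_error(call_nad_rnas(tab, cutoff = 0.5), "at least 1")
})

test_that("calls recover planted truth with a confusion-matrix oracle", {
  st <- simulate_study(7, n_genes = 200, base_rate = 0.2, gain = 8)
  tab <- compute_fold_enrichment(st$cm)
  calls <- call_nad_rnas(tab)
  called <- calls$called$embryo
  # brute-force confusion matrix from the truth table
  pos <- st$truth$gene_id[st$truth$is_nad]
  neg <- st$truth$gene_id[!st$truth$is_nad]
  tp <- length(intersect(called, pos))
  fp <- length(intersect(called, neg))
  expect_equal(tp + fp, length(called))
  expect_gt(tp / length(pos), 0.9)
  expect_lt(fp / max(1, length(called)), 0.1)
})

test_that("normalization makes fold changes invariant to library scaling", {
  st <- simulate_study(9, n_genes = 80, depth = 2e4)
  # exact invariance without a pseudocount: the rescaled library factor
  # absorbs the constant completely
  tab1 <- compute_fold_enrichment(st$cm, pseudocount = 0)
  cm2 <- st$cm
  cm2$counts[, 3] <- cm2$counts[, 3] * 3L
  tab2 <- compute_fold_enrichment(cm2, pseudocount = 0)
  expect_equal(tab2$fold_enrichment, tab1$fold_enrichment, tolerance = 1e-9)
  # with the default pseudocount the distortion stays below 1%
  d1 <- compute_fold_enrichment(st$cm)
  d2 <- compute_fold_enrichment(cm2)
  expect_lt(max(abs(d2$fold_enrichment / d1$fold_enrichment - 1)), 0.01)
})

test_that("spike-in control assessment reports classes and flags", {
  st <- simulate_study(13, n_genes = 100)
  tab <- compute_fold_enrichment(st$cm)
  ctrl <- assess_spikein_controls(tab)
  expect_true(ctrl$sensitivity_pass)   # 5% NAD at efficiency 600 -> FC ~ 31
  expect_true(ctrl$specificity_pass)   # 0% NAD -> FC ~ 1
  expect_gt(ctrl$sensitivity_fc, 10)
  expect_lt(ctrl$specificity_fc, 2)
  expect_setequal(unique(ctrl$report$stage),
                  c("embryo", "larva", "pupa", "adult", "all"))
  no_sens <- tab[!(tab$spikein_class %in% "sensitivity"), ]
  expect_error(assess_spikein_controls(no_sens), "control error")
})

test_that("saturation subsampling is exact at fraction 1 and strict at the threshold", {
  counts <- c(rep(100L, 5), rep(11L, 3), rep(10L, 4), rep(2L, 8))
  sat <- saturation_curve(counts, fractions = 1, threshold = 10,
                          n_draws = 3, seed = 1)
  expect_equal(sat$mean_detected, 8)   # counts of exactly 10 are NOT detected
  expect_equal(sat$sd_detected, 0)
  expect_error(saturation_curve(counts, fractions = c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(saturation_curve(integer(5)), "positive")
})

test_that("mean detected genes is monotone in the subsampling fraction", {
  withr::with_seed(5, counts <- as.integer(rnbinom(400, mu = 40, size = 2)))
  sat <- saturation_curve(counts, fractions = c(0.2, 0.8), threshold = 10,
                          n_draws = 50, seed = 3)
  expect_lte(sat$mean_detected[1], sat$mean_detected[2])
})
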