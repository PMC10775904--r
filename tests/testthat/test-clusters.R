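test_that("adjacent gap is start-of-downstream minus stop-of-upstream", {
  a <- list(chrom = "2L", start = 1, stop = 1000)
  expect_equal(adjacent_gap(a, list(chrom = "2L", start = 2001, stop = 3000)),
               1001L)
  expect_equal(adjacent_gap(a, list(chrom = "2L", start = 500, stop = 2000)),
               -500L)   # overlap
  expect_equal(adjacent_gap(a, list(chrom = "2L", start = 1001, stop = 1500)),
               1L)      # abutting
  expect_error(adjacent_gap(a, list(chrom = "3R", start = 2001, stop = 3000)),
               "different chromosomes")
  expect_error(adjacent_gap(list(chrom = "2L", start = 5000, stop = 6000), a),
               "upstream")
})

test_that("the cluster rule joins runs of >= 3 genes with gaps <= L", {
  g <- make_genes(c(1, 2001, 4001), c(1000, 3000, 5000))
  cl <- find_physical_clusters(g, L_kb = 3, N_min = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3)
  expect_equal(cl$members[[1]], g$gene_id)
  expect_equal(cl$span_start, 1L)
  expect_equal(cl$span_stop, 5000L)
  # two genes never form a cluster, however close
  g2 <- make_genes(c(1, 1001), c(1000, 2000))
  expect_equal(nrow(find_physical_clusters(g2, L_kb = 3)), 0)
  expect_error(find_physical_clusters(g, L_kb = 0), "positive")
  expect_error(find_physical_clusters(g, L_kb = 3, N_min = 0), "at least 1")
})

test_that("a gap of exactly L kilobases joins; one base more splits", {
  g <- make_genes(c(1, 4001, 8001), c(1000, 5000, 9000))
  # gaps are 3001 and 3001: L = 3 kb excludes, L = 3.001 joins
  expect_equal(nrow(find_physical_clusters(g, L_kb = 3)), 0)
  expect_equal(nrow(find_physical_clusters(g, L_kb = 3.001)), 1)
  g3 <- make_genes(c(1, 4000, 7999), c(1000, 4999, 8999))
  # gaps exactly 3000: inclusive rule joins at L = 3
  expect_equal(nrow(find_physical_clusters(g3, L_kb = 3)), 1)
})

test_that("overlapping and nested genes always satisfy the gap rule", {
  g <- make_genes(c(1, 500, 600), c(1000, 2000, 700))
  cl <- find_physical_clusters(g, L_kb = 1, N_min = 3)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3)
})

test_that("greedy maximal runs equal the exhaustive oracle on random instances", {
  for (s in 1:100) {
    g <- random_instance(n_genes = sample(5:50, 1), n_chrom = 3, seed = s)
    L <- sample(c(1, 2, 3, 5), 1)
    got <- find_physical_clusters(g, L_kb = L, N_min = 3)
    got_members <- unclass(got$members)
    got_members <- got_members[order(vapply(got_members, paste, "",
                                            collapse = ","))]
    expect_identical(unname(got_members), oracle_clusters(g, L, 3),
                     label = sprintf("instance seed %d", s))
  }
})

test_that("null sampling is degenerate when the stratum is the whole pool", {
  g <- random_instance(30, n_chrom = 2, seed = 4)
  strat <- table(g$chrom)
  nc <- simulate_null_clusters(g, strat, L_kb = 3, n_perm = 50, seed = 1)
  expect_equal(length(unique(nc)), 1L)
  expect_equal(nc[1], nrow(find_physical_clusters(g, L_kb = 3)))
})

test_that("fewer selected genes than N_min gives an all-zero null", {
  g <- random_instance(20, n_chrom = 1, seed = 6)
  nc <- simulate_null_clusters(g, c(chr1 = 2), L_kb = 5, n_perm = 100,
                               seed = 2)
  expect_true(all(nc == 0))
})

test_that("oversized strata raise a sampling error", {
  g <- random_instance(10, n_chrom = 1, seed = 8)
  expect_error(simulate_null_clusters(g, c(chr1 = 99), L_kb = 3),
               "sampling error")
})

test_that("every permutation reproduces the per-chromosome composition", {
  # chromosome A: 6 tightly packed genes (any 3 form a cluster);
  # chromosome B: genes megabases apart (2 drawn, can never cluster).
  a <- make_genes(seq(1, by = 700, length.out = 6),
                  seq(500, by = 700, length.out = 6), chrom = "A",
                  ids = sprintf("a%d", 1:6))
  b <- make_genes(seq(1, by = 2e6, length.out = 5),
                  seq(1000, by = 2e6, length.out = 5), chrom = "B",
                  ids = sprintf("b%d", 1:5))
  g <- rbind(a, b)
  nc <- simulate_null_clusters(g, c(A = 3, B = 2), L_kb = 3,
                               n_perm = 200, seed = 3)
  # exactly one cluster (from A's stratum) in every single draw
  expect_true(all(nc == 1))
})

test_that("permutation estimate matches the exactly enumerated null", {
  # 6 equally spaced genes: adjacent gap 901 <= 1 kb, skipping a gene
  # gives 1901 > 1 kb, so a cluster needs 3 consecutive genes.
  g <- make_genes(seq(1, by = 1000, length.out = 6),
                  seq(100, by = 1000, length.out = 6), chrom = "X")
  subsets <- combn(6, 3)
  exact <- mean(apply(subsets, 2, function(idx) {
    nrow(find_physical_clusters(g[idx, ], L_kb = 1, N_min = 3)) >= 1
  }))
  expect_equal(exact, 4 / 20)   # the 4 consecutive triples
  nc <- simulate_null_clusters(g, c(X = 3), L_kb = 1, n_perm = 10000,
                               seed = 11)
  est <- mean(nc >= 1)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(est - exact), 3 * se)
})

test_that("the empirical p-value follows the plain counting rule", {
  expect_equal(cluster_significance(7, 0:9)$p_value, 3 / 10)
  expect_false(cluster_significance(7, 0:9)$below_resolution)
  p0 <- cluster_significance(0, 0:9)
  expect_equal(p0$p_value, 1)
  below <- cluster_significance(50, rep(0:3, 2500))
  expect_true(below$below_resolution)
  expect_equal(below$p_value, 1 / 10000)
  expect_match(below$label, "<")
  expect_error(cluster_significance(1, integer(0)), "non-empty")
})

test_that("the L scan matches single-L runs and its tabulated summary", {
  g <- random_instance(40, n_chrom = 2, seed = 21)
  called <- g[seq(1, 40, by = 2), ]
  scan <- scan_L_settings(called, g, L_list = c(1, 3), n_perm = 200,
                          seed = 77)
  for (i in 1:2) {
    single <- cluster_test(called, g, L_kb = c(1, 3)[i], n_perm = 200,
                           seed = nadrna:::derive_seed(77, i))
    expect_equal(scan$results[[i]]$C_true, single$C_true)
    expect_identical(scan$results[[i]]$null_counts, single$null_counts)
    expect_equal(scan$summary$p_value[i], single$p_value)
  }
})

test_that("toy scan: gaps of 1500 bp cluster at L >= 2 but not at L = 1", {
  g <- make_genes(c(1, 2501, 5001, 7501), c(1000, 3500, 6000, 8500))
  scan <- scan_L_settings(g, g, L_list = 1:5, n_perm = 50, seed = 1)
  expect_equal(scan$summary$C_true, c(0L, 1L, 1L, 1L, 1L))
})

test_that("an empty called set yields zero clusters and p = 1 at all L", {
  g <- random_instance(20, n_chrom = 1, seed = 31)
  scan <- scan_L_settings(g[0, ], g, L_list = 1:3, n_perm = 50, seed = 5)
  expect_true(all(scan$summary$C_true == 0))
  expect_true(all(scan$summary$p_value == 1))
})

test_that("total clustered genes is non-decreasing in L", {
  for (s in 1:10) {
    g <- random_instance(50, n_chrom = 2, seed = 100 + s)
    called <- g[sample(50, 30), ]
    sizes <- vapply(1:5, function(L)
      sum(find_physical_clusters(called, L_kb = L)$size), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})
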