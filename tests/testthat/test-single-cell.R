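# Single-cell scoring, Beta-weight correction, clustering, experiments.

test_that("fragment bias averages the two end scores", {
  g <- sim_genome(500, seed = 71, name = "c")
  tab <- sim_truth_bias(4, "naive_random", sd = 1, seed = 72)
  fr <- tibble::tibble(chrom = "c", start = 100L, end = 260L,
                       strand = NA_character_, barcode = "BC1", count = 1L)
  fb <- fragment_bias(fr, g, tab, method = "five_prime")
  reg <- tibble::tibble(chrom = "c", start = 50L, end = 450L)
  pb <- position_bias(g, reg, tab, method = "five_prime")
  expect_equal(fb$bias,
               (pb$bias_plus[pb$pos == 100] + pb$bias_minus[pb$pos == 259]) / 2)
  # dimeric default agrees with the dimeric position bias at both ends
  fbd <- fragment_bias(fr, g, tab)
  pbd <- position_bias(g, reg, tab, method = "selma_dimeric")
  expect_equal(fbd$bias,
               (pbd$bias_plus[pbd$pos == 100] + pbd$bias_minus[pbd$pos == 259]) / 2)
  # flat table -> the flat value
  flat <- tab; flat$score <- rep(0.3, nrow(flat))
  expect_equal(fragment_bias(fr, g, flat)$bias, 0.3)
})

test_that("cell and peak bias scores are medians over their groups", {
  fr <- tibble::tibble(chrom = "c",
                       start = c(10L, 30L, 50L, 110L, 130L),
                       end = c(40L, 70L, 90L, 150L, 170L),
                       barcode = c("A", "A", "A", "B", "B"),
                       bias = c(1, 5, 2, 3, 7))
  cbs <- cell_bias_score(fr)
  expect_equal(cbs$cbs[cbs$barcode == "A"], 2)  # odd count: middle order stat
  expect_equal(cbs$cbs[cbs$barcode == "B"], 5)
  peaks <- tibble::tibble(chrom = "c", start = c(0L, 100L), end = c(100L, 200L))
  pk <- peak_bias_score(peaks, fr)   # midpoints 25, 50, 70, 130, 150
  expect_equal(pk$pbs, c(2, 5))
  expect_identical(pk$n_fragments, c(3L, 2L))
  # duplicated fragments leave the median unchanged
  pk2 <- peak_bias_score(peaks, dplyr::bind_rows(fr, fr))
  expect_equal(pk2$pbs, pk$pbs)
  # empty peak flagged as NA
  pk3 <- peak_bias_score(tibble::tibble(chrom = "c", start = 900L, end = 950L), fr)
  expect_true(is.na(pk3$pbs))
})

test_that("read-count filters drop the documented units", {
  m <- Matrix::Matrix(0, 3, 3, sparse = TRUE)
  m[1, ] <- c(5000, 6000, 3999)  # peak sums: row1 over after col filter?
  m[2, ] <- c(4000, 4000, 2000)
  m[3, ] <- c(1000, 5, 4)
  colnames(m) <- c("c1", "c2", "c3"); rownames(m) <- c("p1", "p2", "p3")
  # cell totals: 10000, 10005, 6003 -> c3 dropped (9,999-style shortfall)
  out <- filter_units(m, min_cell_reads = 10000, min_peak_reads = 10,
                      max_peak_reads = 20000)
  expect_identical(colnames(out), c("c1", "c2"))
  expect_identical(rownames(out), c("p1", "p2", "p3"))
  # peak with 4001 reads removed at the default ceiling
  m2 <- Matrix::Matrix(matrix(c(2001, 2000, 10, 10), 2, 2, byrow = TRUE), sparse = TRUE)
  rownames(m2) <- c("hot", "ok"); colnames(m2) <- c("c1", "c2")
  out2 <- filter_units(m2, min_cell_reads = 0)
  expect_identical(rownames(out2), "ok")
  expect_identical(unname(attr(out2, "removed")["peaks"]), 1L)
  # all-pass matrix is untouched
  out3 <- filter_units(m2, min_cell_reads = 0, max_peak_reads = 5000)
  expect_equal(as.matrix(out3), as.matrix(m2))
})

test_that("the Beta weight satisfies its closed form and constraints", {
  expect_equal(beta_weight(0), 0)
  expect_equal(beta_weight(1), 0)
  expect_equal(beta_weight(1 / 3), 16 / 9)
  x <- seq(0, 1, 0.001)
  expect_equal(beta_weight(x), 12 * x * (1 - x)^2)
  q <- integrate(beta_weight, 0, 1, abs.tol = 1e-10)
  expect_lt(abs(q$value - 1), 1e-9)
  expect_error(beta_weight(1.2))
})

test_that("matrix correction conserves totals and fixes the all-equal case", {
  set.seed(73)
  m <- Matrix::rsparsematrix(50, 20, density = 0.3,
                             rand.x = function(n) rpois(n, 5) + 1)
  pbs <- rnorm(50)
  mc <- correct_matrix(m, pbs)
  expect_lt(abs(sum(mc) - sum(m)) / sum(m), 1e-9)
  # equal PBS -> identity
  mc2 <- correct_matrix(m, rep(0.7, 50))
  expect_equal(as.matrix(mc2), as.matrix(m), tolerance = 1e-12)
  # relative downweighting follows W(x_top) / W(x_mode)
  x <- (rank(pbs) - 0.5) / 50
  ratio_obs <- Matrix::rowSums(mc)[which.max(pbs)] / Matrix::rowSums(m)[which.max(pbs)]
  ratio_mode <- Matrix::rowSums(mc)[which.min(abs(x - 1/3))] /
    Matrix::rowSums(m)[which.min(abs(x - 1/3))]
  expect_equal(ratio_obs / ratio_mode,
               beta_weight(x[which.max(pbs)]) / beta_weight(x[which.min(abs(x - 1/3))]),
               tolerance = 1e-9)
  expect_error(correct_matrix(m, c(NA, pbs[-1])), "undefined")
})

test_that("stochastic rounding preserves integers and expectations", {
  m <- Matrix::Matrix(matrix(c(2, 0.5, 0, 1.25), 2, 2), sparse = TRUE)
  r1 <- synthesize_integer_counts(m, seed = 1)
  expect_true(all(r1@x == floor(r1@x)))
  expect_equal(as.matrix(r1)[1, 1], 2)  # integer entries never change
  draws <- vapply(1:400, function(s) as.matrix(synthesize_integer_counts(m, seed = s))[2, 1],
                  numeric(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(400))
  expect_identical(as.matrix(synthesize_integer_counts(m, seed = 9)),
                   as.matrix(synthesize_integer_counts(m, seed = 9)))
})

test_that("clustering is deterministic, permutation-equivariant and exact on easy data", {
  sc <- sim_sc(n_peaks = 120, cells_per_type = 30, seed = 74)
  sig <- sc$counts[!sc$peaks$biased, ]
  l1 <- cluster_cells(sig, 3, seed = 5)
  l2 <- cluster_cells(sig, 3, seed = 5)
  expect_identical(l1, l2)
  expect_equal(adjusted_rand_index(l1, sc$labels$type), 1)
  perm <- sample(ncol(sig))
  lp <- cluster_cells(sig[, perm], 3, seed = 5)
  expect_equal(adjusted_rand_index(lp, l1[perm]), 1)
})

test_that("ARI matches brute-force pair counting on toys", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), b), 0)
  expect_error(adjusted_rand_index(a, b[-1]), "length")
})

test_that("vectorized per-peak ANOVA agrees with lm and controls type I error", {
  set.seed(75)
  m <- Matrix::Matrix(matrix(rpois(300 * 24, 5), 300, 24), sparse = TRUE)
  grp <- rep(1:3, each = 8)
  prof <- anova_contribution_profile(m, grp, pbs = rnorm(300))
  expect_lt(abs(sum(prof$n_qualifying) / 300 - 0.05), 0.035)
  av <- selma:::.row_anova(m, grp)
  or <- oracle_anova_f(as.numeric(m[17, ]), grp)
  expect_equal(av$f[17], unname(or["f"]), tolerance = 1e-10)
  expect_equal(av$p_value[17], unname(or["p"]), tolerance = 1e-10)
})

test_that("group effects concentrated in low-PBS peaks give a decaying profile", {
  sc <- sim_sc(seed = 76)
  fr <- fragment_bias(sc$fragments, sc$genome, sc$truth)
  pk <- peak_bias_score(sc$peaks, fr)
  prof <- anova_contribution_profile(sc$counts, sc$labels$type, pk$pbs)
  ok <- !is.na(prof$median_f)
  lo <- prof$median_f[ok & prof$x < 0.5]
  hi <- prof$median_f[ok & prof$x >= 0.6]
  expect_gt(median(lo), median(hi))
})

test_that("CBS separates populations with different bias exposure", {
  sc <- sim_sc(n_types = 2, cells_per_type = 50, exposure = c(0.25, 4),
               truth_sd = 0.8, seed = 77)
  fr <- fragment_bias(sc$fragments, sc$genome, sc$truth)
  cb <- dplyr::inner_join(cell_bias_score(fr), sc$labels, by = "barcode")
  hi <- cb$cbs[cb$type == 2]; lo <- cb$cbs[cb$type == 1]
  expect_lt(rank_sum_test(hi, lo)$p_value, 0.01)
  auc <- mean(outer(hi, lo, ">") + 0.5 * outer(hi, lo, "=="))
  expect_gt(auc, 0.9)
})

test_that("peak-removal relative ranks favor PBS-guided retention", {
  sc <- sim_sc(n_peaks = 150, cells_per_type = 30, seed = 78)
  fr <- fragment_bias(sc$fragments, sc$genome, sc$truth)
  pk <- peak_bias_score(sc$peaks, fr)
  res <- peak_removal_experiment(sc$counts, pk$pbs, sc$labels$type, 3,
                                 retain_percents = c(55, 65, 75, 85),
                                 n_random = 12, seed = 3, n_components = 20)
  expect_identical(nrow(res), 4L)
  expect_gt(median(res$rel_rank_retained), median(res$rel_rank_all))
  res2 <- peak_removal_experiment(sc$counts, pk$pbs, sc$labels$type, 3,
                                  retain_percents = c(55, 65, 75, 85),
                                  n_random = 12, seed = 3, n_components = 20)
  expect_identical(res, res2)
})
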