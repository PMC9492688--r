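# Footprint bias scores, aggregate profiles, occupancy inference metrics.

make_flat_bias <- function(n, value = 0) {
  tibble::tibble(region_id = 1L, chrom = "c", pos = 0:(n - 1),
                 bias_plus = value, bias_minus = value)
}

test_that("FBS is zero under flat bias and recovers a constructed spike", {
  fp <- tibble::tibble(chrom = "c", start = 10L, end = 40L)
  expect_equal(footprint_bias_score(fp, make_flat_bias(60))$fbs, 0)
  # +2 at the 6 spike-set positions on both strands, 0 elsewhere -> FBS = 2
  bias <- make_flat_bias(60)
  spikes <- c(17 + (-1:1), 32 + (-1:1))
  bias$bias_plus[bias$pos %in% spikes] <- 2
  bias$bias_minus[bias$pos %in% spikes] <- 2
  res <- footprint_bias_score(fp, bias)
  expect_equal(res$spike_bias, 2)
  expect_equal(res$center_bias, 0)
  expect_equal(res$fbs, 2)
  expect_error(footprint_bias_score(tibble::tibble(chrom = "c", start = 0L, end = 16L),
                                    bias), "longer than 16")
})

test_that("FBS matches the brute-force recomputation on a noisy 30-bp toy", {
  set.seed(51)
  bias <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:49,
                         bias_plus = rnorm(50), bias_minus = rnorm(50))
  fp <- tibble::tibble(chrom = "c", start = 10L, end = 40L)
  res <- footprint_bias_score(fp, bias)
  or <- oracle_fbs(10, 40, bias$bias_plus, bias$bias_minus, bias$pos)
  expect_equal(res$fbs, or)
})

test_that("planted spike amplitude is recovered and the flat case is exact", {
  sf <- sim_footprints(n = 800, spike_amp = 1.2, noise_sd = 0.3, seed = 52)
  fb <- footprint_bias_score(sf$footprints, sf$bias)
  expect_lt(abs(mean(fb$fbs) / 1.2 - 1), 0.05)
  sf0 <- sim_footprints(n = 30, spike_amp = 0, noise_sd = 0, seed = 53)
  expect_equal(footprint_bias_score(sf0$footprints, sf0$bias)$fbs, rep(0, 30))
})

test_that("shuffled FBS centers at zero and is reproducible", {
  sf <- sim_footprints(n = 600, spike_amp = 1, seed = 54)
  tab <- sim_truth_bias(6, "naive_random", sd = 1, seed = 55)
  s1 <- shuffled_fbs(sf$footprints, tab, seed = 56)
  s2 <- shuffled_fbs(sf$footprints, tab, seed = 56)
  expect_identical(s1$fbs, s2$fbs)
  expect_lt(abs(mean(s1$fbs)), 3 * sd(s1$fbs) / sqrt(nrow(s1)))
})

test_that("aggregate profiles are exact for constant and duplicated input", {
  fp <- tibble::tibble(chrom = "c", start = c(10L, 10L), end = c(40L, 40L))
  agg <- aggregate_profile(fp, make_flat_bias(120, 1.5), flank = 10)
  expect_true(all(abs(agg$plus - 1.5) < 1e-12))
  one <- aggregate_profile(fp[1, ], make_flat_bias(120, 1.5), flank = 10)
  expect_equal(agg$plus, one$plus)
})

test_that("aggregate profile peaks at the spike anchors for planted spikes", {
  sf <- sim_footprints(n = 300, spike_amp = 1.5, noise_sd = 0.2, seed = 57)
  agg <- aggregate_profile(sf$footprints, sf$bias, flank = 20)
  nb <- nrow(agg)
  spike_bins <- c(20, 21, 22, nb - 21, nb - 20, nb - 19)  # anchors +/- 1
  expect_true(which.max(agg$plus) %in% spike_bins)
  expect_true(which.max(agg$minus) %in% spike_bins)
})

test_that("raw footprint score evaluates its formula and is monotone", {
  expect_equal(raw_footprint_score(5, 5, 5), 0)
  expect_equal(raw_footprint_score(0, 7, 7), 2 * log(8))
  sc <- raw_footprint_score(0:10, 7, 7)
  expect_true(all(diff(sc) < 0))
  expect_error(raw_footprint_score(-1, 1, 1))
})

test_that("occupancy inference separates separable data and not noise", {
  set.seed(58)
  d <- tibble::tibble(x = c(rnorm(100, 0), rnorm(100, 6)),
                      bound = rep(0:1, each = 100))
  p <- infer_occupancy(d, features = "x", seed = 1)
  pm <- partial_metrics(p, d$bound)
  expect_equal(pm$value[pm$measure == "auroc" & pm$at == 1], 1)
  d2 <- tibble::tibble(x = rnorm(400), bound = rbinom(400, 1, 0.5))
  p2 <- infer_occupancy(d2, features = "x", seed = 1)
  auc2 <- partial_metrics(p2, d2$bound)$value[1]
  expect_lt(abs(auc2 - 0.5), 0.12)
  expect_error(infer_occupancy(tibble::tibble(x = 1:4, bound = 1), seed = 1),
               "both occupancy classes")
})

test_that("partial metrics match trapezoid oracles and a reference full AUC", {
  set.seed(59)
  probs <- runif(200)
  labels <- rbinom(200, 1, plogis(4 * (probs - 0.4)))
  pm <- partial_metrics(probs, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE)))
  expect_equal(pm$value[pm$measure == "auroc" & pm$at == 1], ref,
               tolerance = 1e-9)
  # 6-point toy against the explicit trapezoid oracle
  pr6 <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lb6 <- c(1, 0, 1, 1, 0, 0)
  pm6 <- partial_metrics(pr6, lb6)
  pts <- .rank_points_oracle(pr6, lb6)
  for (cc in c(1, 0.1, 0.01)) {
    expect_equal(pm6$value[pm6$measure == "auroc" & pm6$at == cc],
                 oracle_partial_area(c(0, pts$fpr), c(0, pts$tpr), cc),
                 info = paste("auroc at", cc))
    expect_equal(pm6$value[pm6$measure == "auprc" & pm6$at == cc],
                 oracle_partial_area(c(0, pts$recall),
                                     c(pts$precision[1], pts$precision), cc),
                 info = paste("auprc at", cc))
  }
  # perfect and reversed rankings
  perf <- partial_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(all(perf$value == 1))
  rev6 <- partial_metrics(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(rev6$value[rev6$measure == "auroc" & rev6$at == 1], 0)
})

test_that("rank score evaluates closed forms and is monotone in each rank", {
  expect_equal(rank_score(rep(1, 6), 3), log(4))
  expect_equal(rank_score(rep(3, 6), 3), -log(3 / 4))
  base <- rank_score(c(1, 2, 1, 3, 2, 1), 4)
  worse <- rank_score(c(1, 2, 1, 4, 2, 1), 4)
  expect_lt(worse, base)
  expect_error(rank_score(c(0, 1, 1, 1, 1, 1), 3))
})

test_that("adding an informative FBS feature beats a permuted-bias feature", {
  wins <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 300
    reads <- rnorm(n); fscore <- rnorm(n); fbs <- rnorm(n)
    bound <- rbinom(n, 1, plogis(reads + fscore - 1.3 * fbs))
    d <- tibble::tibble(bound, reads, fscore, fbs, fbs_perm = sample(fbs))
    p_fbs <- infer_occupancy(d, features = c("reads", "fscore", "fbs"), seed = s)
    p_perm <- infer_occupancy(d, features = c("reads", "fscore", "fbs_perm"), seed = s)
    m_fbs <- partial_metrics(p_fbs, bound)$value
    m_perm <- partial_metrics(p_perm, bound)$value
    r_fbs <- vapply(1:6, function(i) rank(-c(m_fbs[i], m_perm[i]))[1], numeric(1))
    r_perm <- vapply(1:6, function(i) rank(-c(m_fbs[i], m_perm[i]))[2], numeric(1))
    rank_score(r_fbs, 2) > rank_score(r_perm, 2)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("one-sided rank-sum utility detects a located shift", {
  set.seed(61)
  res <- rank_sum_test(rnorm(80, 1), rnorm(80, 0))
  expect_lt(res$p_value, 0.01)
})
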