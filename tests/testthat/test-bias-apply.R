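# Position-bias conventions, bias-expected profiles, obs/exp correlation.

test_that("five_prime position bias equals direct k-mer lookups", {
  g <- sim_genome(300, seed = 21, name = "c")
  tab <- sim_truth_bias(4, "naive_random", sd = 1, seed = 22)
  reg <- tibble::tibble(chrom = "c", start = 50L, end = 120L)
  pb <- position_bias(g, reg, tab, method = "five_prime")
  scores <- setNames(tab$score, tab$kmer)
  for (i in c(50L, 80L, 119L)) {
    kp <- oracle_cleavage_kmer(g$seq[["c"]], i, "+", 4)
    km <- oracle_cleavage_kmer(g$seq[["c"]], i, "-", 4)
    expect_equal(pb$bias_plus[pb$pos == i], unname(scores[kp]))
    expect_equal(pb$bias_minus[pb$pos == i], unname(scores[km]))
  }
})

test_that("a selma_fit scorer agrees with its materialized table", {
  g <- sim_genome(400, seed = 23, name = "c")
  truth <- sim_truth_bias(6, "simplex_structured", sd = 0.5, seed = 24)
  reg <- tibble::tibble(chrom = "c", start = 100L, end = 200L)
  pb_fit <- position_bias(g, reg, truth, method = "five_prime")
  pb_tab <- position_bias(g, reg, selma_bias_table(truth), method = "five_prime")
  expect_equal(pb_fit$bias_plus, pb_tab$bias_plus, tolerance = 1e-12)
  expect_equal(pb_fit$bias_minus, pb_tab$bias_minus, tolerance = 1e-12)
})

test_that("dimeric combination averages the two coupled log scores", {
  g <- sim_genome(300, seed = 25, name = "c")
  tab <- sim_truth_bias(4, "naive_random", sd = 1, seed = 26)
  reg <- tibble::tibble(chrom = "c", start = 50L, end = 250L)
  fp <- position_bias(g, reg, tab, method = "five_prime")
  di <- position_bias(g, reg, tab, method = "selma_dimeric")
  i <- 100L
  expect_equal(di$bias_plus[di$pos == i],
               (fp$bias_plus[fp$pos == i] + fp$bias_minus[fp$pos == i + 9]) / 2)
  expect_equal(di$bias_minus[di$pos == i],
               (fp$bias_minus[fp$pos == i] + fp$bias_plus[fp$pos == i - 9]) / 2)
  # flat table -> flat combination; the printed example: 2 and 0 average to 1
  flat <- tab; flat$score <- rep(0.7, nrow(flat))
  df <- position_bias(g, reg, flat, method = "selma_dimeric")
  expect_true(all(abs(df$bias_plus - 0.7) < 1e-12, na.rm = TRUE))
  expect_equal((2 + 0) / 2, 1)
})

test_that("shifted method references the plus table on both strands", {
  g <- sim_genome(300, seed = 27, name = "c")
  tab <- sim_truth_bias(4, "naive_random", sd = 1, seed = 28)
  reg <- tibble::tibble(chrom = "c", start = 50L, end = 250L)
  fp <- position_bias(g, reg, tab, method = "five_prime")
  sh <- position_bias(g, reg, tab, method = "shifted", shift = 5)
  i <- 120L
  expect_equal(sh$bias_plus[sh$pos == i], fp$bias_plus[fp$pos == i + 5])
  expect_equal(sh$bias_minus[sh$pos == i], fp$bias_plus[fp$pos == i - 5])
})

test_that("masked lookup restricts scoring to informative mask positions", {
  g <- genome(c(c = "ACGTACGTACGTACGTACGT"))
  reg <- tibble::tibble(chrom = "c", start = 0L, end = 20L)
  ev <- tibble::tibble(chrom = "c", cut = c(5L, 9L), strand = c("+", "-"),
                       barcode = NA_character_, count = 1L)
  mask <- "NNCX"
  bg <- masked_background_counts(g, reg, mask)
  # brute force: informative offsets are -2, -1 relative to the cut
  seqs <- g$seq[["c"]]
  fwd <- sapply(3:20, function(i) substr(seqs, i - 2, i - 1))
  rcs <- oracle_revcomp(seqs)
  rev <- sapply(3:20, function(i) substr(rcs, i - 2, i - 1))
  or <- table(c(fwd, rev))
  expect_equal(bg$count, as.numeric(or[bg$kmer]))
  nc <- masked_cleavage_counts(g, ev, reg, mask)
  # plus cut at 5: bases at 3,4 = "TA"; minus cut at 9: rc-strand context
  expect_true("TA" %in% nc$kmer)
  tab <- naive_bias(nc, bg, pseudocount = 0.5, min_background = 1, k = 2)
  pb <- position_bias(g, reg, tab, method = "masked", mask = mask)
  sc <- setNames(tab$score, tab$kmer)
  expect_equal(pb$bias_plus[pb$pos == 5], unname(sc["TA"]))
  expect_error(position_bias(g, reg, tab, method = "masked", mask = "NNXX"),
               "exactly one C")
})

test_that("expected profile matches hand and brute-force evaluation", {
  obs <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:5,
                        plus = c(0, 3, 0, 3, 0, 0), minus = 0)
  bias <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:5,
                         bias_plus = c(0, 0, 1, 0, 0, 0), bias_minus = 0)
  ex <- expected_profile(obs, bias, w = 6)
  expect_equal(ex$exp_plus, c(NA, NA, NA, 6 / 7, NA, NA))
  # randomized case against the brute-force oracle
  set.seed(29)
  n <- 80
  obs2 <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:(n - 1),
                         plus = rpois(n, 2), minus = rpois(n, 2))
  bias2 <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:(n - 1),
                          bias_plus = rnorm(n, 0, 0.5), bias_minus = rnorm(n, 0, 0.5))
  ex2 <- expected_profile(obs2, bias2, w = 10)
  expect_equal(ex2$exp_plus, oracle_expected(obs2$plus, bias2$bias_plus, 10))
  expect_equal(ex2$exp_minus, oracle_expected(obs2$minus, bias2$bias_minus, 10))
  # the literal per-position form
  exl <- expected_profile(obs2, bias2, w = 10, per_position = TRUE)
  i <- 41
  y <- 2^bias2$bias_plus[i] / sum(2^bias2$bias_plus[(i - 5):(i + 4)])
  expect_equal(exl$exp_plus[i], obs2$plus[i] * y)
})

test_that("uniform bias reduces the expected profile to a moving average", {
  set.seed(30)
  n <- 200
  obs <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:(n - 1),
                        plus = rpois(n, 3), minus = rpois(n, 1))
  bias <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:(n - 1),
                         bias_plus = 2, bias_minus = -1)
  ex <- expected_profile(obs, bias, w = 50)
  i <- 100
  expect_equal(ex$exp_plus[i + 1], mean(obs$plus[(i - 25):(i + 24) + 1]))
  expect_equal(ex$exp_minus[i + 1], mean(obs$minus[(i - 25):(i + 24) + 1]))
  # window weights normalize exactly at any fixed center
  y <- 2^bias$bias_plus[(i - 25):(i + 24) + 1]
  expect_equal(sum(y / sum(y)), 1)
})

test_that("obs/exp correlation behaves at the identity and null limits", {
  set.seed(31)
  obs <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:999,
                        plus = rpois(1000, 3), minus = rpois(1000, 3))
  ident <- tibble::tibble(region_id = 1L, chrom = "c", pos = 0:999,
                          exp_plus = obs$plus, exp_minus = obs$minus)
  expect_equal(obs_exp_correlation(obs, ident), 1)
  shuf <- ident
  shuf$exp_plus <- sample(shuf$exp_plus)
  shuf$exp_minus <- sample(shuf$exp_minus)
  expect_lt(abs(obs_exp_correlation(obs, shuf)), 0.07)
})

test_that("bias-method ranking holds on simulated dimeric data", {
  ranks_ok <- vapply(1:3, function(s) {
    g <- sim_genome(120000, seed = 40 + s)
    reg <- sim_regions(g, 30, 1000, seed = 41 + s)
    truth <- sim_truth_bias(6, "simplex_structured", sd = 0.6, seed = 42 + s)
    fr <- sim_atac_dimeric(g, reg, truth, 60000, seed = 43 + s)
    ev <- extract_cleavages(fr)
    obs <- pileup(ev, reg)
    tab <- naive_bias(count_cleavage_kmers(g, ev, reg, 6),
                      count_background_kmers(g, reg, 6), min_background = 1)
    fit <- fit_selma(tab)
    r_of <- function(method, scorer) {
      pb <- position_bias(g, reg, scorer, method = method)
      obs_exp_correlation(obs, expected_profile(obs, pb))
    }
    r_di <- r_of("selma_dimeric", fit)
    r_fp <- r_of("five_prime", fit)
    r_pm <- r_of("selma_dimeric", permute_bias_table(selma_bias_table(fit), seed = 44 + s))
    (r_di >= r_fp) && (r_fp >= r_pm)
  }, logical(1))
  expect_true(all(ranks_ok))
})
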