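# Single-cell ATAC-seq bias scoring (per-fragment, per-cell, per-peak),
# Beta-weight correction of peak-by-cell matrices, clustering, and the two
# diagnostic experiments (peak-removal relative ranks, per-percentile ANOVA
# contribution).

#' Per-fragment bias scores
#'
#' The bias of a paired fragment is the mean of the bias scores of its two
#' cleavage ends (the 5' end at `start` on +, the 3' end at `end - 1` on -),
#' each scored under the given convention (default: the dimeric-combined
#' score, see [position_bias()]).
#'
#' @param fragments Fragment tibble with `chrom`, `start`, `end` (paired).
#' @param genome A `selma_genome`.
#' @param scorer Bias table or `selma_fit`.
#' @param method `"selma_dimeric"` (default) or `"five_prime"`.
#' @param offset Dimer span (default 9).
#' @return The fragment tibble with a `bias` column (`NA` when both end
#'   windows are invalid; single valid ends score alone).
#' @export
fragment_bias <- function(fragments, genome, scorer,
                          method = c("selma_dimeric", "five_prime"),
                          offset = 9L) {
  method <- match.arg(method)
  if (any(is.na(fragments$end))) rlang::abort("fragment bias needs paired fragments")
  k <- .scorer_k(scorer)
  out <- rep(NA_real_, nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    sel <- which(fragments$chrom == ch)
    sc <- .strand_scores(genome, ch, scorer, k)
    n <- nchar(genome$seq[[ch]])
    circ <- genome$circular[[ch]]
    at <- function(x, i) {
      if (circ) x[(i %% n) + 1L]
      else ifelse(i >= 0L & i < n, x[pmax(i, 0L) + 1L], NA_real_)
    }
    i5 <- fragments$start[sel]
    i3 <- fragments$end[sel] - 1L
    if (method == "five_prime") {
      e5 <- at(sc$plus, i5)
      e3 <- at(sc$minus, i3)
    } else {
      e5 <- (at(sc$plus, i5) + at(sc$minus, i5 + offset)) / 2
      e3 <- (at(sc$minus, i3) + at(sc$plus, i3 - offset)) / 2
    }
    out[sel] <- rowMeans(cbind(e5, e3), na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  fragments$bias <- out
  fragments
}

#' Cell bias score (CBS)
#'
#' Median fragment bias per cell barcode.
#'
#' @param fragments Fragment tibble with `barcode` and `bias` columns (see
#'   [fragment_bias()]).
#' @return Tibble `(barcode, cbs, n_fragments)`.
#' @export
cell_bias_score <- function(fragments) {
  fragments |>
    dplyr::filter(!is.na(.data$bias), !is.na(.data$barcode)) |>
    dplyr::group_by(barcode = .data$barcode) |>
    dplyr::summarise(cbs = stats::median(.data$bias),
                     n_fragments = dplyr::n(), .groups = "drop")
}

#' Peak bias score (PBS)
#'
#' Median fragment bias per peak, over the fragments assigned to the peak.
#' Default assignment places a fragment in the peak containing its midpoint;
#' `"any_overlap"` and `"both_ends"` are available as alternatives.
#'
#' @param peaks Region tibble.
#' @param fragments Fragment tibble with a `bias` column.
#' @param assign Fragment-to-peak rule.
#' @return The peak tibble with `pbs` and `n_fragments` appended (`NA`/0 for
#'   peaks with no scoreable fragment).
#' @export
peak_bias_score <- function(peaks, fragments,
                            assign = c("midpoint", "any_overlap", "both_ends")) {
  assign <- match.arg(assign)
  fr <- fragments[!is.na(fragments$bias), , drop = FALSE]
  peaks$.row <- seq_len(nrow(peaks))
  acc_bias <- vector("list", nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    fch <- fr[fr$chrom == ch, , drop = FALSE]
    if (!nrow(fch) || !nrow(pk)) next
    q <- switch(assign,
      midpoint = {
        mid <- (fch$start + fch$end) %/% 2L
        IRanges::IRanges(mid + 1L, mid + 1L)
      },
      any_overlap = IRanges::IRanges(fch$start + 1L, fch$end),
      both_ends = IRanges::IRanges(fch$start + 1L, fch$end)
    )
    s <- IRanges::IRanges(pk$start + 1L, pk$end)
    hits <- IRanges::findOverlaps(q, s,
      type = if (assign == "both_ends") "within" else "any")
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (u in unique(sh)) {
      row <- pk$.row[u]
      acc_bias[[row]] <- c(acc_bias[[row]], fch$bias[qh[sh == u]])
    }
  }
  peaks$pbs <- vapply(acc_bias, function(v) if (length(v)) stats::median(v) else NA_real_,
                      numeric(1L))
  peaks$n_fragments <- vapply(acc_bias, length, integer(1L))
  peaks$.row <- NULL
  peaks
}

#' Filter cells and peaks by read count
#'
#' Retains cells with at least `min_cell_reads` total counts and peaks with
#' totals inside `[min_peak_reads, max_peak_reads]` (sparsely covered peaks
#' are uninformative; extreme totals flag artifacts).
#'
#' @param counts Peaks-by-cells matrix (sparse or dense) or a `selma_pcm`.
#' @param min_cell_reads Minimum reads per retained cell (default 10000).
#' @param min_peak_reads Minimum reads per retained peak (default 10).
#' @param max_peak_reads Maximum reads per retained peak (default 4000).
#' @return Filtered object of the input type, with attribute `"removed"`
#'   (named vector: cells and peaks dropped).
#' @export
filter_units <- function(counts, min_cell_reads = 10000, min_peak_reads = 10,
                         max_peak_reads = 4000) {
  pcm <- inherits(counts, "selma_pcm")
  m <- if (pcm) counts$counts else counts
  keep_cell <- Matrix::colSums(m) >= min_cell_reads
  m2 <- m[, keep_cell, drop = FALSE]
  rs <- Matrix::rowSums(m2)
  keep_peak <- rs >= min_peak_reads & rs <= max_peak_reads
  if (!any(keep_peak) || !any(keep_cell)) rlang::abort("filtering removed everything")
  m2 <- m2[keep_peak, , drop = FALSE]
  removed <- c(cells = sum(!keep_cell), peaks = sum(!keep_peak))
  if (pcm) {
    out <- structure(list(counts = m2,
                          peaks = counts$peaks[keep_peak, , drop = FALSE]),
                     class = "selma_pcm")
  } else {
    out <- m2
  }
  attr(out, "removed") <- removed
  out
}

#' Beta peak-weight function
#'
#' `W(x) = x^(a-1) (1-x)^(b-1) / B(a, b)`; with the default shape
#' `a = 2, b = 3` this is `W(x) = 12 x (1-x)^2`: zero at both ends,
#' integrating to 1, with mode at `x = 1/3`.  `x` is the PBS percentile of
#' a peak, so the most extreme high-bias peaks (and the rare no-bias
#' extreme) are downweighted relative to typical peaks.
#'
#' @param x Percentile(s) in `[0, 1]`.
#' @param alpha,beta Shape parameters (> 1).
#' @return `W(x)`.
#' @examples
#' beta_weight(1/3)  # 16/9
#' @export
beta_weight <- function(x, alpha = 2, beta = 3) {
  if (any(x < 0 | x > 1)) rlang::abort("`x` must lie in [0, 1]")
  stats::dbeta(x, alpha, beta)
}

#' Beta-weight bias correction of a peak-by-cell matrix
#'
#' Each peak's row is multiplied by `W(x)` where `x` is the peak's PBS
#' percentile (ascending rank, average ties, mapped to `(rank - 0.5)/n` so
#' `x` never hits 0 or 1), then the whole matrix is rescaled so its total
#' count equals the raw total.  With all-equal PBS the correction is the
#' identity.
#'
#' @param counts Peaks-by-cells matrix (sparse or dense) or `selma_pcm`.
#' @param pbs Per-peak bias scores, aligned with the rows; must be defined
#'   for every retained peak.
#' @param alpha,beta Weight shape (default 2, 3).
#' @return Corrected matrix of the input type (entries are non-integer;
#'   see [synthesize_integer_counts()]).
#' @export
correct_matrix <- function(counts, pbs, alpha = 2, beta = 3) {
  pcm <- inherits(counts, "selma_pcm")
  m <- if (pcm) counts$counts else counts
  if (length(pbs) != nrow(m)) rlang::abort("`pbs` must have one value per peak row")
  if (any(is.na(pbs))) rlang::abort("`pbs` contains undefined values; filter those peaks first")
  x <- (rank(pbs, ties.method = "average") - 0.5) / length(pbs)
  w <- beta_weight(x, alpha, beta)
  total <- sum(m)
  m2 <- Matrix::Diagonal(x = w) %*% m
  m2 <- m2 * (total / sum(m2))
  m2 <- methods::as(m2, "CsparseMatrix")
  dimnames(m2) <- dimnames(m)
  if (pcm) structure(list(counts = m2, peaks = counts$peaks), class = "selma_pcm") else m2
}

#' Stochastically round a corrected matrix to integers
#'
#' Each entry `v` becomes `floor(v) + Bernoulli(v - floor(v))`, preserving
#' the expectation entry-wise (needed by tools that require integer read
#' counts).
#'
#' @param counts Corrected matrix (sparse or dense) or `selma_pcm`.
#' @param seed Integer seed.
#' @return Integer-valued matrix of the input type.
#' @export
synthesize_integer_counts <- function(counts, seed) {
  pcm <- inherits(counts, "selma_pcm")
  m <- if (pcm) counts$counts else counts
  m <- methods::as(m, "CsparseMatrix")
  v <- m@x
  .with_seed(seed, {
    m@x <- floor(v) + stats::rbinom(length(v), 1L, v - floor(v))
  })
  m <- Matrix::drop0(m)
  if (pcm) structure(list(counts = m, peaks = counts$peaks), class = "selma_pcm") else m
}

#' PCA + k-means cell clustering
#'
#' The naive clustering pipeline used for evaluation: per-cell depth
#' normalization (to the median depth), `log1p`, PCA keeping
#' `n_components` PCs, then k-means with multiple restarts.  Deterministic
#' given `seed`.
#'
#' @param counts Peaks-by-cells matrix or `selma_pcm`.
#' @param n_clusters Number of clusters (use the known number of types).
#' @param n_components PCs kept (default 60, capped at the data rank).
#' @param seed Integer seed.
#' @param nstart k-means restarts (default 10).
#' @return Integer cluster labels named by cell barcode.
#' @export
cluster_cells <- function(counts, n_clusters, n_components = 60L, seed = 1L,
                          nstart = 10L) {
  m <- if (inherits(counts, "selma_pcm")) counts$counts else counts
  if (ncol(m) < n_clusters) rlang::abort("fewer cells than clusters")
  depth <- Matrix::colSums(m)
  depth[depth == 0] <- 1
  norm <- m %*% Matrix::Diagonal(x = stats::median(depth) / depth)
  xm <- log1p(as.matrix(Matrix::t(norm)))
  npc <- min(n_components, ncol(xm), nrow(xm) - 1L)
  pcs <- stats::prcomp(xm, center = TRUE, scale. = FALSE, rank. = npc)$x
  km <- .with_seed(seed, stats::kmeans(pcs, centers = n_clusters,
                                       nstart = nstart, iter.max = 100L))
  stats::setNames(km$cluster, colnames(m))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings (permutation model);
#' 1 for identical partitions, ~0 for unrelated ones.
#'
#' @param labels,truth Equal-length label vectors.
#' @return ARI.
#' @export
adjusted_rand_index <- function(labels, truth) {
  if (length(labels) != length(truth)) rlang::abort("label vectors differ in length")
  mclust::adjustedRandIndex(labels, truth)
}

#' Peak-removal relative-rank experiment
#'
#' For each retention percentage, cells are clustered on (a) the peaks with
#' the lowest PBS and (b) `n_random` random peak subsets of the same size;
#' the relative rank of a clustering is the number of random-subset ARIs
#' below its ARI.  High relative ranks for the PBS-retained subsets mean
#' that removing high-bias peaks helps beyond removing random peaks.
#'
#' @param counts Peaks-by-cells matrix or `selma_pcm`.
#' @param pbs Per-peak bias scores (row-aligned).
#' @param truth Reference cell labels.
#' @param n_clusters Clusters for k-means.
#' @param retain_percents Percentages of peaks retained (default 50..99).
#' @param n_random Random subsets per percentage (default 100).
#' @param seed Integer seed.
#' @param n_components,nstart Passed to [cluster_cells()].
#' @return Tibble with per-percentage ARIs and relative ranks for the
#'   PBS-retained and the all-peaks clusterings.
#' @export
peak_removal_experiment <- function(counts, pbs, truth, n_clusters,
                                    retain_percents = 50:99, n_random = 100L,
                                    seed = 1L, n_components = 60L, nstart = 2L) {
  m <- if (inherits(counts, "selma_pcm")) counts$counts else counts
  np <- nrow(m)
  ord <- order(pbs)  # ascending: lowest bias first
  ari_all <- adjusted_rand_index(
    cluster_cells(m, n_clusters, n_components, seed = seed, nstart = nstart), truth)
  purrr::map_dfr(seq_along(retain_percents), function(i) {
    pct <- retain_percents[i]
    size <- max(n_clusters, floor(np * pct / 100))
    keep <- ord[seq_len(size)]
    ari_keep <- adjusted_rand_index(
      cluster_cells(m[keep, , drop = FALSE], n_clusters, n_components,
                    seed = seed + i, nstart = nstart), truth)
    rand_aris <- vapply(seq_len(n_random), function(r) {
      sub <- .with_seed(seed * 1000L + i * 101L + r, sample.int(np, size))
      adjusted_rand_index(
        cluster_cells(m[sub, , drop = FALSE], n_clusters, n_components,
                      seed = seed + i, nstart = nstart), truth)
    }, numeric(1L))
    tibble::tibble(
      retain_percent = pct, n_peaks = size,
      ari_retained = ari_keep, ari_all = ari_all,
      rel_rank_retained = sum(rand_aris < ari_keep),
      rel_rank_all = sum(rand_aris < ari_all)
    )
  })
}

# vectorized one-way ANOVA across columns of a peaks x cells matrix
.row_anova <- function(m, groups) {
  groups <- as.factor(groups)
  G <- stats::model.matrix(~ 0 + groups)
  ng <- colSums(G)
  n <- ncol(m)
  kg <- length(ng)
  gs <- as.matrix(m %*% G)                 # group sums per peak
  tot <- Matrix::rowSums(m)
  ssb <- rowSums(sweep(gs^2, 2L, ng, "/")) - tot^2 / n
  sst <- Matrix::rowSums(m * m) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (kg - 1)) / (ssw / (n - kg))
  p <- stats::pf(f, kg - 1, n - kg, lower.tail = FALSE)
  tibble::tibble(f = f, p_value = p)
}

#' Per-percentile ANOVA contribution profile
#'
#' One-way ANOVA of each peak's counts across the reference cell groups;
#' within each PBS percentile, the median F statistic of the peaks with
#' p < `alpha` summarizes how much that percentile contributes to
#' separating the cell types.  A profile that decays at high percentiles is
#' the empirical motivation for downweighting high-PBS peaks.
#'
#' @param counts Peaks-by-cells matrix or `selma_pcm`.
#' @param truth Reference cell labels (>= 2 groups).
#' @param pbs Per-peak bias scores (row-aligned).
#' @param alpha ANOVA p-value cutoff for a peak to qualify (default 0.05).
#' @return Tibble `(percentile, x, n_peaks, n_qualifying, median_f)`;
#'   `median_f` is `NA` for percentiles with no qualifying peak.
#' @export
anova_contribution_profile <- function(counts, truth, pbs, alpha = 0.05) {
  m <- if (inherits(counts, "selma_pcm")) counts$counts else counts
  if (length(unique(truth)) < 2L) rlang::abort("need >= 2 cell groups")
  av <- .row_anova(m, truth)
  pct <- pmin(floor((rank(pbs, ties.method = "average") - 0.5) / length(pbs) * 100), 99L)
  tibble::tibble(peak = seq_len(nrow(m)), percentile = pct,
                 f = av$f, p_value = av$p_value) |>
    dplyr::group_by(percentile = .data$percentile) |>
    dplyr::summarise(
      n_peaks = dplyr::n(),
      n_qualifying = sum(.data$p_value < alpha, na.rm = TRUE),
      median_f = {
        q <- !is.na(.data$p_value) & .data$p_value < alpha
        if (any(q)) stats::median(.data$f[q]) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(x = .data$percentile / 100, .after = "percentile")
}
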