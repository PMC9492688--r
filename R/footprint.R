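# Footprint bias scores, aggregate footprint profiles, the raw footprint
# score, and evaluation of TF-occupancy inference (partial AUROC/AUPRC and
# the integrated rank score).
#
# DNaseI footprints carry two recurrent bias "spikes" 7 bp inside each
# footprint boundary; a footprint whose apparent protection pattern is
# explained by those spikes rather than by TF binding has a high footprint
# bias score (FBS).

# fast per-chrom position lookup into a profile-like tibble
.pos_lookup <- function(profile, cols) {
  by_chrom <- split(profile[, c("pos", cols)], profile$chrom)
  by_chrom <- lapply(by_chrom, function(d) d[!duplicated(d$pos), , drop = FALSE])
  function(chrom, positions) {
    d <- by_chrom[[chrom]]
    if (is.null(d)) {
      out <- matrix(NA_real_, length(positions), length(cols))
      colnames(out) <- cols
      return(out)
    }
    idx <- match(positions, d$pos)
    as.matrix(d[idx, cols, drop = FALSE])
  }
}

# spike coordinates of a footprint [start, end): 7 bp inside each boundary
.spikes <- function(start, end) {
  list(left = start + 7L, right = end - 8L)
}

.fbs_core <- function(footprints, get_bias) {
  n <- nrow(footprints)
  # expand every footprint to its positions once; one bulk lookup per chrom
  lens <- footprints$end - footprints$start
  fid <- rep(seq_len(n), lens)
  pos <- unlist(purrr::map2(footprints$start, footprints$end - 1L, seq),
                use.names = FALSE)
  sL <- footprints$start + 7L; sR <- footprints$end - 8L
  is_spike <- abs(pos - sL[fid]) <= 1L | abs(pos - sR[fid]) <= 1L
  vals <- matrix(NA_real_, length(pos), 2L)
  for (ch in unique(footprints$chrom)) {
    sel <- footprints$chrom[fid] == ch
    vals[sel, ] <- get_bias(ch, pos[sel])
  }
  both <- c(vals[, 1L], vals[, 2L])
  fid2 <- c(fid, fid)
  spike2 <- c(is_spike, is_spike)
  b <- vapply(split(both[spike2], fid2[spike2]),
              function(v) mean(v, na.rm = TRUE), numeric(1L))
  cc <- vapply(split(both[!spike2], fid2[!spike2]),
               function(v) stats::median(v, na.rm = TRUE), numeric(1L))
  out <- footprints
  out$spike_bias <- unname(b[as.character(seq_len(n))])
  out$center_bias <- unname(cc[as.character(seq_len(n))])
  out$fbs <- out$spike_bias - out$center_bias
  out
}

#' Footprint bias score (FBS)
#'
#' For each footprint: `b` is the mean bias over the spike set (positions
#' within 1 bp of each spike, both strands pooled), `c` the median bias over
#' the remaining footprint positions (both strands), and `FBS = b - c`.
#' Spikes sit 7 bp inside the left and right footprint boundaries.
#'
#' @param footprints Region tibble; every footprint must be longer than
#'   16 bp so the spike sets are interior.
#' @param bias Position bias tibble from [position_bias()] covering the
#'   footprint positions.
#' @return The footprint tibble with columns `spike_bias`, `center_bias`,
#'   `fbs` appended.
#' @export
footprint_bias_score <- function(footprints, bias) {
  if (any(footprints$end - footprints$start <= 16L)) {
    rlang::abort("footprints must be longer than 16 bp for interior spike sets")
  }
  lk <- .pos_lookup(bias, c("bias_plus", "bias_minus"))
  out <- .fbs_core(footprints, lk)
  if (any(is.nan(out$fbs))) {
    rlang::abort("bias is undefined over an entire footprint")
  }
  out
}

#' FBS under a randomly re-assigned bias table
#'
#' Null control: each (position, strand) in each footprint is scored by a
#' draw (with replacement) from the bias table's score multiset, destroying
#' any sequence association while preserving the score distribution; the
#' FBS is then computed as usual.
#'
#' @inheritParams footprint_bias_score
#' @param table A bias table supplying the score multiset.
#' @param seed Integer seed.
#' @return As [footprint_bias_score()].
#' @export
shuffled_fbs <- function(footprints, table, seed) {
  scores <- table$score[is.finite(table$score)]
  .with_seed(seed, {
    get_bias <- function(chrom, positions) {
      matrix(sample(scores, 2L * length(positions), replace = TRUE),
             ncol = 2L)
    }
    .fbs_core(footprints, get_bias)
  })
}

#' Aggregate length-normalized footprint profile
#'
#' Averages a per-position signal (cleavage counts or bias scores) across
#' footprints of different lengths in a common frame: `flank` positions
#' anchored outside/at the left spike, the inter-spike center scaled to
#' `center_bins` bins, and the mirrored right side.  Offsets are labeled
#' relative to the spikes (0 at each spike).
#'
#' @param footprints Region tibble (each longer than 16 bp).
#' @param signal A [pileup()] profile (`plus`/`minus`) or a
#'   [position_bias()] tibble (`bias_plus`/`bias_minus`).
#' @param flank Positions shown left/right of each spike (default 50).
#' @param center_bins Number of bins for the inter-spike center (default 4).
#' @return Tibble with `bin` (ordered frame coordinate label), `segment`
#'   (`left`, `center`, `right`), `plus`, `minus` (mean signal across
#'   footprints).
#' @export
aggregate_profile <- function(footprints, signal, flank = 50L, center_bins = 4L) {
  if (any(footprints$end - footprints$start <= 16L)) {
    rlang::abort("footprints must be longer than 16 bp")
  }
  cols <- if ("bias_plus" %in% names(signal)) c("bias_plus", "bias_minus") else c("plus", "minus")
  lk <- .pos_lookup(signal, cols)
  nb <- 2L * (flank + 1L) + center_bins
  acc_p <- matrix(NA_real_, nrow(footprints), nb)
  acc_m <- matrix(NA_real_, nrow(footprints), nb)
  for (j in seq_len(nrow(footprints))) {
    sp <- .spikes(footprints$start[j], footprints$end[j])
    left_pos <- (sp$left - flank):sp$left
    right_pos <- sp$right:(sp$right + flank)
    lv <- lk(footprints$chrom[j], left_pos)
    rv <- lk(footprints$chrom[j], right_pos)
    ctr <- (sp$left + 1L):(sp$right - 1L)
    cv <- lk(footprints$chrom[j], ctr)
    bin_of <- ceiling(seq_along(ctr) / length(ctr) * center_bins)
    cp <- tapply(cv[, 1L], bin_of, mean, na.rm = TRUE)
    cm <- tapply(cv[, 2L], bin_of, mean, na.rm = TRUE)
    acc_p[j, ] <- c(lv[, 1L], cp[as.character(seq_len(center_bins))], rv[, 1L])
    acc_m[j, ] <- c(lv[, 2L], cm[as.character(seq_len(center_bins))], rv[, 2L])
  }
  tibble::tibble(
    bin = seq_len(nb),
    segment = c(rep("left", flank + 1L), rep("center", center_bins),
                rep("right", flank + 1L)),
    offset = c(-(flank:0), rep(NA_integer_, center_bins), 0:flank),
    plus = colMeans(acc_p, na.rm = TRUE),
    minus = colMeans(acc_m, na.rm = TRUE)
  )
}

#' Raw footprint score
#'
#' `-(ln((n_C + 1)/(n_R + 1)) + ln((n_C + 1)/(n_L + 1)))`: depletion of
#' cleavages in the motif region relative to its equal-length flanks.
#' Vectorized.
#'
#' @param n_c,n_l,n_r Cleavage counts in the center, left flank, right flank.
#' @return Numeric score (higher = stronger protection).
#' @examples
#' raw_footprint_score(0, 7, 7)  # 2 * log(8)
#' @export
raw_footprint_score <- function(n_c, n_l, n_r) {
  if (any(c(n_c, n_l, n_r) < 0)) rlang::abort("counts must be >= 0")
  -(log((n_c + 1) / (n_r + 1)) + log((n_c + 1) / (n_l + 1)))
}

#' Out-of-fold TF-occupancy probabilities from logistic regression
#'
#' Fits a binary logistic model of site occupancy on the given features with
#' stratified k-fold cross-validation (features standardized on each
#' training fold) and returns the out-of-fold predicted probabilities, so
#' downstream metrics are honest.
#'
#' @param data Tibble of one row per candidate site.
#' @param label_col Name of the 0/1 occupancy column.
#' @param features Character vector of feature column names (default: all
#'   numeric columns except the label).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return Numeric vector of predicted occupancy probabilities, input order.
#' @export
infer_occupancy <- function(data, label_col = "bound", features = NULL,
                            folds = 5L, seed = 1L) {
  y <- data[[label_col]]
  if (is.null(y)) rlang::abort(sprintf("no column `%s`", label_col))
  if (length(unique(y)) < 2L) rlang::abort("both occupancy classes must be present")
  features <- features %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1L))], label_col)
  X <- as.matrix(data[, features, drop = FALSE])
  if (any(!is.finite(X))) rlang::abort("features must be finite")
  n <- length(y)
  fold <- integer(n)
  .with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  probs <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sd_, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sd_, "/")
    df <- data.frame(y = y[tr], Xtr)
    m <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
    probs[te] <- suppressWarnings(
      stats::predict(m, newdata = data.frame(Xte), type = "response"))
  }
  probs
}

# ROC points (FPR, TPR) and PR points (recall, precision) with ties grouped
.rank_points <- function(probs, labels) {
  o <- order(probs, decreasing = TRUE)
  p <- probs[o]; l <- labels[o]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(l); N <- sum(1 - l)
  list(tpr = tp[last] / P, fpr = fp[last] / N,
       recall = tp[last] / P, precision = tp[last] / (tp[last] + fp[last]))
}

# trapezoid area under piecewise-linear curve through (x, y), cut at x = c,
# normalized by c
.partial_trapezoid <- function(x, y, c) {
  keep <- x <= c + 1e-12
  xs <- x[keep]; ys <- y[keep]
  if (!length(xs) || max(xs) < c - 1e-12) {
    # interpolate the curve at c
    i <- which(x > c)[1L]
    if (!is.na(i)) {
      x0 <- if (i > 1L) x[i - 1L] else 0
      y0 <- if (i > 1L) y[i - 1L] else 0
      frac <- (c - x0) / (x[i] - x0)
      xs <- c(xs, c); ys <- c(ys, y0 + frac * (y[i] - y0))
    }
  }
  if (length(xs) < 2L) return(if (length(xs) == 1L) ys[1L] * xs[1L] / c / 1 else 0)
  sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2) / c
}

#' Partial AUROC / AUPRC
#'
#' Area under the ROC curve restricted to false-positive rate in `[0, c]`
#' and area under the precision-recall curve restricted to recall in
#' `[0, c]`, each normalized by `c` so a perfect ranking scores 1, for
#' `c` in 1, 0.1, 0.01.  Curves are piecewise linear through the tie-grouped
#' ranking points (trapezoid rule); the ROC curve starts at (0, 0), the PR
#' curve starts at recall 0 with the first point's precision.
#'
#' @param probs Predicted scores.
#' @param labels 0/1 truth labels (both classes present).
#' @return Tibble with columns `measure` (`auroc`/`auprc`), `at` (1, 0.1,
#'   0.01) and `value`.
#' @export
partial_metrics <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) rlang::abort("both classes must be present")
  pts <- .rank_points(probs, labels)
  cuts <- c(1, 0.1, 0.01)
  roc_x <- c(0, pts$fpr); roc_y <- c(0, pts$tpr)
  pr_x <- c(0, pts$recall); pr_y <- c(pts$precision[1L], pts$precision)
  tibble::tibble(
    measure = rep(c("auroc", "auprc"), each = 3L),
    at = rep(cuts, 2L),
    value = c(vapply(cuts, function(cc) .partial_trapezoid(roc_x, roc_y, cc), numeric(1L)),
              vapply(cuts, function(cc) .partial_trapezoid(pr_x, pr_y, cc), numeric(1L)))
  )
}

#' Integrated rank score across performance measures
#'
#' Models are ranked (1 = best, average ranks for ties) on each of the six
#' partial AUROC/AUPRC measures; a model's score is
#' `S = (1/6) * sum_i -ln(r_i / (N + 1))` with `N` the number of models.
#' Higher is better; strictly decreasing in every rank.
#'
#' @param ranks Numeric vector of the model's six ranks.
#' @param n_models Total number of models `N`.
#' @return The rank score `S`.
#' @examples
#' rank_score(rep(1, 6), 3)  # log(4)
#' @export
rank_score <- function(ranks, n_models) {
  if (any(ranks < 1 | ranks > n_models)) {
    rlang::abort("ranks must lie in [1, n_models]")
  }
  mean(-log(ranks / (n_models + 1)))
}

#' One-sided two-group rank-sum comparison
#'
#' Convenience wrapper used to compare FBS distributions between footprint
#' groups (e.g. TF-binding hotspot vs desert footprints).
#'
#' @param x,y Numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()] (default: `x`
#'   stochastically greater than `y`).
#' @return Tibble with `statistic` and `p_value`.
#' @export
rank_sum_test <- function(x, y, alternative = "greater") {
  ht <- stats::wilcox.test(x, y, alternative = alternative, exact = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}
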