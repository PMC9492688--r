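# Per-position strand bias under several estimation conventions, the
# bias-expected cleavage profile, and observed/expected agreement.

# Per-contig strand score arrays (length n, 0-based position -> R index + 1).
# scorer is either a bias table / score vector (exact k-mer lookup) or a
# selma_fit (positional evaluation; no 4^k table needed).
# s_minus uses the rule: the minus-strand context at cut i equals the
# plus-strand context on the reverse-complement contig at position n - 1 - i.
.strand_scores <- function(genome, chrom, scorer, k) {
  n <- nchar(genome$seq[[chrom]])
  circ <- genome$circular[[chrom]]
  half <- k %/% 2L
  if (inherits(scorer, "selma_fit")) {
    ints <- .seq_ints(genome$seq[[chrom]])
    rc_ints <- rev(3L - ints)
    if (circ) {
      fwd_ws <- .fit_window_scores(scorer, c(ints, ints[seq_len(k - 1L)]))
      rc_ws <- .fit_window_scores(scorer, c(rc_ints, rc_ints[seq_len(k - 1L)]))
    } else {
      fwd_ws <- .fit_window_scores(scorer, ints)
      rc_ws <- .fit_window_scores(scorer, rc_ints)
    }
    lookup <- function(ws, w0) {
      out <- rep(NA_real_, n)
      if (circ) {
        out <- ws[(w0 %% n) + 1L]
      } else {
        ok <- w0 >= 0L & w0 <= n - k
        out[ok] <- ws[w0[ok] + 1L]
      }
      out
    }
    i <- 0:(n - 1L)
    list(plus = lookup(fwd_ws, i - half),
         minus = lookup(rc_ws, n - 1L - i - half))
  } else {
    vec <- if (is.numeric(scorer)) scorer else .table_score_vec(scorer)
    codes <- .contig_codes(genome, chrom, k)
    i <- 0:(n - 1L)
    get <- function(w0) {
      out <- rep(NA_integer_, n)
      if (circ) {
        out <- codes[(w0 %% n) + 1L]
      } else {
        ok <- w0 >= 0L & w0 <= n - k
        out[ok] <- codes[w0[ok] + 1L]
      }
      out
    }
    pc <- get(i - half)
    mc <- get(i - half + 1L)
    ok <- !is.na(mc)
    mc[ok] <- .revcomp_codes(mc[ok], k)
    sp <- rep(NA_real_, n); sm <- rep(NA_real_, n)
    sp[!is.na(pc)] <- vec[pc[!is.na(pc)] + 1L]
    sm[ok] <- vec[mc[ok] + 1L]
    list(plus = sp, minus = sm)
  }
}

.scorer_k <- function(scorer, k = NULL) {
  if (inherits(scorer, "selma_fit")) return(scorer$k)
  kk <- attr(scorer, "k")
  if (!is.null(kk)) return(kk)
  if (!is.null(k)) return(k)
  rlang::abort("cannot infer k from the bias scorer; pass `k`")
}

#' Per-position strand bias scores over regions
#'
#' Assigns a log2 bias score to every (position, strand) in the regions,
#' under one of four conventions:
#'
#' * `"five_prime"`: the score of the k-mer at the cut on its own strand.
#' * `"selma_dimeric"`: dimeric transposition couples the cut at `i` (+) with
#'   a partner cut at `i + offset` (-).  The combined score is the geometric
#'   mean of the two propensity ratios, i.e. the arithmetic mean of the two
#'   log2 scores: `a'+_i = (a+_i + a-_{i+offset}) / 2`,
#'   `a'-_i = (a-_i + a+_{i-offset}) / 2` (default `offset = 9`).
#' * `"shifted"`: cut coordinates shifted by `shift` before lookup,
#'   `a'+_i = a+_{i+shift}` and `a'-_i = a+_{i-shift}` — note both strands
#'   reference the plus-strand score, reproducing the published convention
#'   verbatim (the strand asymmetry is intentional here, not a bug).
#' * `"masked"`: gapped-context lookup; `mask` is a string over `{X, N, C}`
#'   with exactly one `C` marking the cut position, `N` marking informative
#'   bases and `X` ignored bases.  The scorer must be trained on the same
#'   mask (see [masked_background_counts()]).
#'
#' @param genome A `selma_genome`.
#' @param regions Region tibble.
#' @param scorer A bias table or a `selma_fit` (fits are evaluated
#'   positionally, so large `k` never materializes a `4^k` table).
#' @param method One of `"five_prime"`, `"selma_dimeric"`, `"shifted"`,
#'   `"masked"`.
#' @param offset Dimer span for `"selma_dimeric"` (default 9).
#' @param shift Coordinate shift for `"shifted"` (default 5).
#' @param mask Mask string for `"masked"`.
#' @param k k-mer size override when the scorer is a bare score vector.
#' @return Long tibble `(region_id, chrom, pos, bias_plus, bias_minus)` in
#'   the same frame as [pileup()]; `NA` where a window is invalid.
#' @export
position_bias <- function(genome, regions,
                          scorer,
                          method = c("five_prime", "selma_dimeric", "shifted", "masked"),
                          offset = 9L, shift = 5L, mask = NULL, k = NULL) {
  method <- match.arg(method)
  validate_regions(regions, genome)
  rframe <- .region_frame(regions)
  if (method == "masked") {
    if (is.null(mask)) rlang::abort("masked method needs `mask`")
    return(.position_bias_masked(genome, rframe, scorer, mask))
  }
  k <- .scorer_k(scorer, k)
  out_p <- vector("list", nrow(rframe)); out_m <- vector("list", nrow(rframe))
  for (ch in unique(rframe$chrom)) {
    sc <- .strand_scores(genome, ch, scorer, k)
    n <- nchar(genome$seq[[ch]])
    circ <- genome$circular[[ch]]
    at <- function(x, i) {   # positional lookup honoring contig topology
      if (circ) x[(i %% n) + 1L]
      else ifelse(i >= 0L & i < n, x[pmax(i, 0L) + 1L], NA_real_)
    }
    for (ri in which(rframe$chrom == ch)) {
      i <- rframe$start[ri]:(rframe$end[ri] - 1L)
      bp <- switch(method,
        five_prime = at(sc$plus, i),
        selma_dimeric = (at(sc$plus, i) + at(sc$minus, i + offset)) / 2,
        shifted = at(sc$plus, i + shift)
      )
      bm <- switch(method,
        five_prime = at(sc$minus, i),
        selma_dimeric = (at(sc$minus, i) + at(sc$plus, i - offset)) / 2,
        shifted = at(sc$plus, i - shift)
      )
      out_p[[ri]] <- bp; out_m[[ri]] <- bm
    }
  }
  out <- tibble::tibble(
    region_id = rep(rframe$region_id, rframe$width),
    chrom = rep(rframe$chrom, rframe$width),
    pos = unlist(purrr::map2(rframe$start, rframe$end - 1L, seq), use.names = FALSE),
    bias_plus = unlist(out_p, use.names = FALSE),
    bias_minus = unlist(out_m, use.names = FALSE)
  )
  attr(out, "method") <- method
  out
}

# ---- gapped-mask (informative-position) contexts -------------------------

.parse_mask <- function(mask) {
  ch <- strsplit(mask, "")[[1L]]
  if (any(!ch %in% c("X", "N", "C"))) rlang::abort("mask may only contain X, N, C")
  cut <- which(ch == "C")
  if (length(cut) != 1L) rlang::abort("mask must contain exactly one C")
  list(offsets = which(ch == "N") - cut, m = sum(ch == "N"))
}

# gapped context codes at every position of an integer sequence
.masked_codes <- function(ints, offsets) {
  n <- length(ints)
  lo <- min(c(offsets, 0L)); hi <- max(c(offsets, 0L))
  first <- 1L - lo; last <- n - hi        # valid cut positions (R index)
  if (last < first) return(list(codes = integer(0), first = first, last = last))
  idx <- first:last
  codes <- integer(length(idx))
  for (d in offsets) codes <- codes * 4L + ints[idx + d]
  list(codes = codes, first = first, last = last)
}

# per-contig gapped scores for both strands (plus rule on rc contig = minus)
.masked_strand_scores <- function(genome, chrom, vec, mask) {
  pm <- .parse_mask(mask)
  n <- nchar(genome$seq[[chrom]])
  ints <- .seq_ints(genome$seq[[chrom]])
  rc_ints <- rev(3L - ints)
  score_of <- function(ii) {
    mc <- .masked_codes(ii, pm$offsets)
    out <- rep(NA_real_, n)
    if (length(mc$codes)) {
      ok <- !is.na(mc$codes)
      vals <- rep(NA_real_, length(mc$codes))
      vals[ok] <- vec[mc$codes[ok] + 1L]
      out[mc$first:mc$last] <- vals
    }
    out
  }
  sp <- score_of(ints)
  sm_rc <- score_of(rc_ints)
  list(plus = sp, minus = sm_rc[n - (0:(n - 1L))])  # minus[i] = rc score at n-1-i
}

.position_bias_masked <- function(genome, rframe, scorer, mask) {
  pm <- .parse_mask(mask)
  vec <- if (is.numeric(scorer)) scorer else .table_score_vec(scorer)
  if (length(vec) != 4^pm$m) {
    rlang::abort("scorer was not trained on this mask (size mismatch)")
  }
  out_p <- vector("list", nrow(rframe)); out_m <- vector("list", nrow(rframe))
  for (ch in unique(rframe$chrom)) {
    sc <- .masked_strand_scores(genome, ch, vec, mask)
    for (ri in which(rframe$chrom == ch)) {
      i <- rframe$start[ri]:(rframe$end[ri] - 1L)
      out_p[[ri]] <- sc$plus[i + 1L]
      out_m[[ri]] <- sc$minus[i + 1L]
    }
  }
  out <- tibble::tibble(
    region_id = rep(rframe$region_id, rframe$width),
    chrom = rep(rframe$chrom, rframe$width),
    pos = unlist(purrr::map2(rframe$start, rframe$end - 1L, seq), use.names = FALSE),
    bias_plus = unlist(out_p, use.names = FALSE),
    bias_minus = unlist(out_m, use.names = FALSE)
  )
  attr(out, "method") <- "masked"
  out
}

#' Gapped-context counts for mask-trained bias tables
#'
#' Background and cleavage counts over the informative (`N`) positions of a
#' gapped mask, the analogues of [count_background_kmers()] and
#' [count_cleavage_kmers()] for the gapped model.  The resulting counts feed
#' [naive_bias()] (with `k` = number of informative positions) to train a
#' mask-specific table for [position_bias()]'s `"masked"` method.
#'
#' @inheritParams count_background_kmers
#' @param mask Mask string over `{X, N, C}` with exactly one `C`.
#' @return Tibble `(kmer, count)` with the full count vector as attribute
#'   `"vec"`; "k-mers" here are the concatenated informative bases.
#' @export
masked_background_counts <- function(genome, regions, mask) {
  pm <- .parse_mask(mask)
  validate_regions(regions, genome)
  vec <- numeric(4^pm$m)
  for (i in seq_len(nrow(regions))) {
    sub <- substr(genome$seq[[regions$chrom[i]]], regions$start[i] + 1L, regions$end[i])
    ints <- .seq_ints(sub)
    for (ii in list(ints, rev(3L - ints))) {
      mc <- .masked_codes(ii, pm$offsets)
      cc <- mc$codes[!is.na(mc$codes)]
      if (length(cc)) vec <- vec + tabulate(cc + 1L, nbins = 4^pm$m)
    }
  }
  .counts_to_tbl(vec, pm$m)
}

#' @rdname masked_background_counts
#' @param events Event tibble.
#' @export
masked_cleavage_counts <- function(genome, events, regions, mask) {
  pm <- .parse_mask(mask)
  validate_regions(regions, genome)
  ev <- events[.events_in_regions(events, regions), , drop = FALSE]
  vec <- numeric(4^pm$m)
  for (ch in unique(ev$chrom)) {
    n <- nchar(genome$seq[[ch]])
    ints <- .seq_ints(genome$seq[[ch]])
    rc_ints <- rev(3L - ints)
    sel <- ev[ev$chrom == ch, , drop = FALSE]
    code_at <- function(ii, cuts) {
      mc <- .masked_codes(ii, pm$offsets)
      out <- rep(NA_integer_, length(cuts))
      ok <- cuts + 1L >= mc$first & cuts + 1L <= mc$last
      out[ok] <- mc$codes[cuts[ok] + 1L - mc$first + 1L]
      out
    }
    plus <- sel$strand == "+"
    codes <- rep(NA_integer_, nrow(sel))
    codes[plus] <- code_at(ints, sel$cut[plus])
    codes[!plus] <- code_at(rc_ints, n - 1L - sel$cut[!plus])
    ok <- !is.na(codes)
    if (any(ok)) {
      t1 <- rowsum(as.numeric(sel$count[ok]), codes[ok])
      vec[as.integer(rownames(t1)) + 1L] <- vec[as.integer(rownames(t1)) + 1L] + t1[, 1L]
    }
  }
  .counts_to_tbl(vec, pm$m)
}

# ---- expected profile -----------------------------------------------------

# rolling w-window sums over a flat per-region vector; window for position
# with region offset o is [o - w/2, o + w/2 - 1]; NA outside regions' full
# windows or when the window contains NA input
.roll_sum <- function(x, w, lens) {
  half <- w %/% 2L
  nax <- is.na(x)
  x0 <- ifelse(nax, 0, x)
  cs <- cumsum(x0)
  csna <- cumsum(as.numeric(nax))
  n <- length(x)
  out <- rep(NA_real_, n)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  for (r in seq_along(lens)) {
    if (lens[r] < w) next
    o <- seq.int(starts[r] + half, ends[r] - half + 1L)  # centers with full windows
    lo <- o - half; hi <- o + half - 1L
    s <- cs[hi] - c(0, cs)[lo]
    bad <- (csna[hi] - c(0, csna)[lo]) > 0
    s[bad] <- NA_real_
    out[o] <- s
  }
  out
}

#' Bias-expected cleavage profile
#'
#' For each position `i` and strand, the observed cleavages in the `w`-bp
#' window centered on `i` are redistributed according to the sequence bias:
#' `y_i = 2^{a_i} / sum_{j in window} 2^{a_j}` and the expected count is
#' `T_i * y_i` with `T_i` the window's observed total.  Setting
#' `per_position = TRUE` instead multiplies the position's own observed
#' count by `y_i` (the literal printed form of the estimator; it correlates
#' with the observation by construction, so the default window-total form is
#' what the observed/expected comparison should use).
#'
#' @param observed Strand profile from [pileup()].
#' @param bias Position bias from [position_bias()] on the same regions.
#' @param w Window width in bp (even, default 50; window is
#'   `[i - w/2, i + w/2 - 1]`).
#' @param per_position Use the literal per-position form (default `FALSE`).
#' @return Tibble in the profile frame with columns `exp_plus`, `exp_minus`
#'   (`NA` where the window leaves the region or bias is undefined).
#' @export
expected_profile <- function(observed, bias, w = 50L, per_position = FALSE) {
  if (w %% 2L != 0L) rlang::abort("`w` must be even")
  if (nrow(observed) != nrow(bias) ||
      !all(observed$region_id == bias$region_id) ||
      !all(observed$pos == bias$pos)) {
    rlang::abort("`observed` and `bias` must share the same region frame")
  }
  lens <- rle(observed$region_id)$lengths
  if (any(lens < w)) {
    # windows never fit in these regions; they simply yield all-NA positions
    if (all(lens < w)) rlang::abort("window `w` larger than every region")
  }
  one_strand <- function(counts, a) {
    p2 <- 2^a
    denom <- .roll_sum(p2, w, lens)
    y <- p2 / denom
    tot <- if (per_position) counts else .roll_sum(counts, w, lens)
    tot * y
  }
  out <- observed[, c("region_id", "chrom", "pos")]
  out$exp_plus <- one_strand(observed$plus, bias$bias_plus)
  out$exp_minus <- one_strand(observed$minus, bias$bias_minus)
  attr(out, "w") <- w
  out
}

#' Observed/expected profile correlation
#'
#' Pearson correlation between observed and bias-expected cleavage counts
#' over all defined in-region positions, both strands pooled.  Higher values
#' mean the bias model explains more of the fine structure of the cleavage
#' profile.
#'
#' @param observed Strand profile from [pileup()].
#' @param expected Expected profile from [expected_profile()].
#' @return A single Pearson r (`NA` when degenerate).
#' @export
obs_exp_correlation <- function(observed, expected) {
  if (nrow(observed) != nrow(expected)) {
    rlang::abort("profiles must share the same region frame")
  }
  .pearson(c(observed$plus, observed$minus),
           c(expected$exp_plus, expected$exp_minus))
}
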