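# Naive k-mer bias estimation: count k-mers at cleavage sites against
# background k-mer occurrences over a region set, then take the log2 ratio.
#
# Window conventions (0-based, half-open), for a cut at position i:
#   plus strand:  forward sequence of [i - k/2, i + k/2)
#   minus strand: reverse complement of [i - k/2 + 1, i + k/2 + 1)
# so the k-mer is centered on the cut as seen by the enzyme on its own
# strand.  Windows leaving a linear contig or containing N yield no k-mer;
# circular contigs (mtDNA) wrap around the origin.

# forward k-mer codes at every window start of a contig; circular contigs
# give one window per position (wrap-around), linear ones n - k + 1
.contig_codes <- function(genome, chrom, k) {
  seq <- genome$seq[[chrom]]
  if (is.null(seq)) rlang::abort(sprintf("contig %s not in genome", chrom))
  ints <- .seq_ints(seq)
  if (genome$circular[[chrom]]) {
    .kmer_codes(c(ints, ints[seq_len(k - 1L)]), k)
  } else {
    .kmer_codes(ints, k)
  }
}

# per-event k-mer codes (strand-resolved); NA where the window is invalid
.event_codes <- function(genome, events, k) {
  k <- .check_even_k(k)
  half <- k %/% 2L
  out <- rep(NA_integer_, nrow(events))
  for (ch in unique(events$chrom)) {
    sel <- which(events$chrom == ch)
    n <- nchar(genome$seq[[ch]])
    circ <- genome$circular[[ch]]
    codes <- .contig_codes(genome, ch, k)
    cut <- events$cut[sel]
    plus <- events$strand[sel] == "+"
    w <- integer(length(sel))
    w[plus] <- cut[plus] - half
    w[!plus] <- cut[!plus] - half + 1L
    if (circ) {
      w <- w %% n
      code <- codes[w + 1L]
    } else {
      ok <- w >= 0L & w <= n - k
      code <- rep(NA_integer_, length(sel))
      code[ok] <- codes[w[ok] + 1L]
    }
    if (any(!plus, na.rm = TRUE)) {
      mi <- which(!plus & !is.na(code))
      code[mi] <- .revcomp_codes(code[mi], k)
    }
    out[sel] <- code
  }
  out
}

#' k-mer at a cleavage site
#'
#' Vectorized over events.  For a plus-strand cut at 0-based position `i` the
#' k-mer is the forward sequence of `[i - k/2, i + k/2)`; for a minus-strand
#' cut it is the reverse complement of `[i - k/2 + 1, i + k/2 + 1)`.
#'
#' @param genome A `selma_genome`.
#' @param events Event tibble (`chrom`, `cut`, `strand`).
#' @param k Even k-mer size, 4..14.
#' @return Character vector of k-mers, `NA` where the window leaves a linear
#'   contig or contains `N`.
#' @examples
#' g <- genome(c(chr1 = "AACCGGTT"))
#' ev <- tibble::tibble(chrom = "chr1", cut = 4L, strand = c("+", "-"))
#' cleavage_kmer(g, ev, k = 4)  # "CCGG", "ACCG"
#' @export
cleavage_kmer <- function(genome, events, k) {
  codes <- .event_codes(genome, events, k)
  out <- rep(NA_character_, length(codes))
  ok <- !is.na(codes)
  out[ok] <- .codes_to_kmers(codes[ok], k)
  out
}

# which events fall inside >= 1 region (logical)
.events_in_regions <- function(events, regions) {
  keep <- logical(nrow(events))
  for (ch in unique(regions$chrom)) {
    rg <- regions[regions$chrom == ch, , drop = FALSE]
    sel <- which(events$chrom == ch)
    if (!length(sel)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(events$cut[sel] + 1L, events$cut[sel] + 1L),
      IRanges::IRanges(rg$start + 1L, rg$end)
    )
    keep[sel] <- ov
  }
  keep
}

# full code-indexed count vector (length 4^k) -> compact tibble with attr
.counts_to_tbl <- function(vec, k) {
  nz <- which(vec > 0)
  out <- tibble::tibble(kmer = .codes_to_kmers(nz - 1L, k),
                        count = vec[nz])
  attr(out, "k") <- k
  attr(out, "vec") <- vec
  out
}

#' Count background k-mer occurrences over regions
#'
#' Every k-length window lying fully inside a region contributes one count to
#' its forward k-mer and one to the reverse complement (cleavage k-mers are
#' read off both strands, so the background must be, too).  Windows with `N`
#' are skipped.  A region spanning a whole circular contig contributes
#' wrap-around windows, giving total mass `2L` instead of `2(L - k + 1)`.
#'
#' @param genome A `selma_genome`.
#' @param regions Region tibble.
#' @param k Even k-mer size.
#' @return Tibble `(kmer, count)` of nonzero counts; the full code-indexed
#'   count vector rides along as attribute `"vec"` for the fitting pipeline.
#' @export
count_background_kmers <- function(genome, regions, k) {
  k <- .check_even_k(k)
  validate_regions(regions, genome)
  vec <- numeric(4^k)
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    n <- nchar(genome$seq[[ch]])
    circ <- genome$circular[[ch]]
    whole <- regions$start[i] == 0L && regions$end[i] == n
    if (circ && whole) {
      ints <- .seq_ints(genome$seq[[ch]])
      fwd <- .kmer_codes(c(ints, ints[seq_len(k - 1L)]), k)
    } else {
      sub <- substr(genome$seq[[ch]], regions$start[i] + 1L, regions$end[i])
      fwd <- .kmer_codes(.seq_ints(sub), k)
    }
    fwd <- fwd[!is.na(fwd)]
    if (!length(fwd)) next
    rc <- .revcomp_codes(fwd, k)
    tt <- tabulate(fwd + 1L, nbins = 4^k) + tabulate(rc + 1L, nbins = 4^k)
    vec <- vec + tt
  }
  .counts_to_tbl(vec, k)
}

#' Count cleavage-associated k-mers
#'
#' Each event inside a region whose k-mer window is valid contributes its
#' `count` to that k-mer.  Events outside all regions, or with windows
#' leaving a linear contig or containing `N`, are ignored.
#'
#' @inheritParams count_background_kmers
#' @param events Event tibble from [extract_cleavages()].
#' @return Tibble `(kmer, count)` with attribute `"vec"` as in
#'   [count_background_kmers()].
#' @export
count_cleavage_kmers <- function(genome, events, regions, k) {
  k <- .check_even_k(k)
  validate_regions(regions, genome)
  ev <- events[.events_in_regions(events, regions), , drop = FALSE]
  vec <- numeric(4^k)
  if (nrow(ev)) {
    codes <- .event_codes(genome, ev, k)
    ok <- !is.na(codes)
    if (any(ok)) {
      t1 <- rowsum(as.numeric(ev$count[ok]), codes[ok])
      vec[as.integer(rownames(t1)) + 1L] <- t1[, 1L]
    }
  }
  .counts_to_tbl(vec, k)
}

# accept either the tibble form (with "vec" attribute) or a bare full vector
.as_count_vec <- function(x, k) {
  if (is.numeric(x)) {
    if (length(x) != 4^k) rlang::abort("count vector has wrong length for k")
    return(x)
  }
  v <- attr(x, "vec")
  if (!is.null(v)) return(v)
  vec <- numeric(4^k)
  codes <- .kmers_to_codes(x$kmer, k)
  vec[codes + 1L] <- x$count
  vec
}

#' Naive k-mer bias scores
#'
#' `score_j = log2((N_j + pseudocount) / M_j)` for every k-mer whose
#' background occurrence `M_j` reaches `min_background`; k-mers below the
#' threshold are omitted from the table.  The ratio is stored on the log2
#' scale, which is the scale the bias-expected profile exponentiates.
#'
#' @param n_cleavage Cleavage k-mer counts ([count_cleavage_kmers()] output
#'   or a full `4^k` vector).
#' @param n_background Background k-mer counts ([count_background_kmers()]).
#' @param pseudocount Added to the cleavage count only (default 1).
#' @param min_background Minimum background occurrences for a score to be
#'   reported (default 5).
#' @param k k-mer size; taken from the inputs when omitted.
#' @param background_kind Label: `"peaks"`, `"mappable"`, or `"mtDNA"`.
#' @return A bias table tibble with `provenance = "naive"`.
#' @export
naive_bias <- function(n_cleavage, n_background, pseudocount = 1,
                       min_background = 5L, k = NULL,
                       background_kind = "peaks") {
  k <- k %||% attr(n_background, "k") %||% attr(n_cleavage, "k")
  if (is.null(k)) rlang::abort("supply `k` when passing bare count vectors")
  N <- .as_count_vec(n_cleavage, k)
  M <- .as_count_vec(n_background, k)
  keep <- which(M >= min_background)
  if (!length(keep)) rlang::abort("no k-mer reaches `min_background` occurrences")
  out <- new_bias_table(
    kmer = .codes_to_kmers(keep - 1L, k),
    score = log2((N[keep] + pseudocount) / M[keep]),
    n_cleavage = N[keep],
    n_background = M[keep],
    k = k, provenance = "naive", background_kind = background_kind
  )
  out
}

#' Expand peak summits to fixed-flank accessible regions
#'
#' @param summits Region tibble of width-1 summit records.
#' @param flank Bases added on each side (default 200, giving 400-bp
#'   regions).
#' @param genome Optional `selma_genome` used to clip at contig ends.
#' @return Region tibble of `[summit - flank, summit + flank)` intervals,
#'   clipped at position 0 and at contig length when a genome is given.
#' @export
expand_summits <- function(summits, flank = 200L, genome = NULL) {
  if (any(summits$end - summits$start != 1L)) {
    rlang::abort("summit records must have width 1")
  }
  flank <- as.integer(flank)
  out <- summits
  out$start <- pmax(summits$start - flank, 0L)
  out$end <- summits$start + flank
  if (!is.null(genome)) {
    len <- contig_lengths(genome)
    out$end <- pmin(out$end, len[out$chrom])
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}
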