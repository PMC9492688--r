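# Seeded simulators producing every input with known ground truth:
# genomes, truth bias (tables or simplex-structured), monomeric
# DNaseI-style cleavages, dimeric Tn5-style fragments, mtDNA-like circular
# contigs, footprints with planted bias spikes, and peak-by-cell matrices
# with planted bias structure.  Everything is fully determined by `seed`.

#' Simulate a random genome
#'
#' @param length Contig length in bp.
#' @param gc GC fraction (i.i.d. bases).
#' @param seed Integer seed.
#' @param circular Flag the contig circular (no N is ever generated).
#' @param name Contig name.
#' @return A `selma_genome` with one contig.
#' @export
sim_genome <- function(length, gc = 0.5, seed = 1L, circular = FALSE,
                       name = "chr1") {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- .with_seed(seed, paste(sample(.BASES, length, replace = TRUE, prob = p),
                                collapse = ""))
  genome(stats::setNames(seq, name), circular = if (circular) name else character())
}

#' Simulate a set of disjoint accessible regions
#'
#' Samples `n` non-overlapping fixed-width regions on a contig, emulating
#' the small accessible fraction (peaks) over which cleavage analysis runs;
#' regions closer than 20 bp to a previous one are dropped, so slightly
#' fewer than `n` regions can result.
#'
#' @param genome A `selma_genome`.
#' @param n Number of regions requested.
#' @param width Region width in bp.
#' @param seed Integer seed.
#' @param chrom Contig (default: first).
#' @return Region tibble sorted by start.
#' @export
sim_regions <- function(genome, n, width, seed = 1L, chrom = NULL) {
  chrom <- chrom %||% names(genome$seq)[1L]
  len <- nchar(genome$seq[[chrom]])
  if (len < width + 100L) rlang::abort("contig too short for the requested width")
  .with_seed(seed, {
    starts <- sort(sample.int(len - width - 1L, n))
    keep <- c(TRUE, diff(starts) > width + 20L)
    tibble::tibble(chrom = chrom, start = starts[keep],
                   end = starts[keep] + width)
  })
}

#' Simulate an mtDNA-like circular contig
#'
#' A circular, N-free contig named `chrM` at the human mitochondrial genome
#' size by default.
#'
#' @param length Contig length (default 16569).
#' @param gc GC fraction (default 0.45, mtDNA-like).
#' @param seed Integer seed.
#' @return A `selma_genome`.
#' @export
sim_mtdna <- function(length = 16569L, gc = 0.45, seed = 1L) {
  sim_genome(length, gc = gc, seed = seed, circular = TRUE, name = "chrM")
}

#' Simulate a ground-truth bias
#'
#' Two structures:
#' * `"simplex_structured"`: random coefficients on the simplex features,
#'   rescaled so the log2 score sd over random k-mers matches `sd`.  The
#'   truth is then exactly representable by the model (the working
#'   assumption behind simplex bias estimation), and is returned as a
#'   `selma_fit` so any `k` can be evaluated positionally.
#' * `"naive_random"`: i.i.d. normal log2 scores for all `4^k` k-mers
#'   (limited to `k <= 10`), returned as a bias table.  This truth has no
#'   low-order sequence structure, which is exactly what makes it useful as
#'   a worst case for the model.
#'
#' @param k Even k-mer size.
#' @param structure `"simplex_structured"` or `"naive_random"`.
#' @param sd Target log2 score standard deviation (default 0.5).
#' @param seed Integer seed.
#' @return A `selma_fit` or a bias table, usable wherever a scorer is.
#' @export
sim_truth_bias <- function(k, structure = c("simplex_structured", "naive_random"),
                           sd = 0.5, seed = 1L) {
  structure <- match.arg(structure)
  k <- .check_even_k(k)
  if (structure == "naive_random") {
    if (k > 10L) rlang::abort("naive_random truth is limited to k <= 10")
    scores <- .with_seed(seed, stats::rnorm(4^k, 0, sd))
    codes <- seq_len(4^k) - 1L
    return(new_bias_table(.codes_to_kmers(codes, k), scores,
                          rep(NA_real_, 4^k), rep(NA_real_, 4^k),
                          k = k, provenance = "truth", background_kind = "simulated"))
  }
  p <- param_count(k)
  .with_seed(seed, {
    a <- stats::rnorm(p, 0, 1)
    a[1L] <- 0
    fit <- base::structure(list(coefficients = stats::setNames(a, .simplex_colnames(k)),
                                k = k, n_train = 0L, weighting = "truth"),
                           class = "selma_fit")
    probe <- sample.int(4^k, min(4^k, 100000L), replace = TRUE) - 1L
    s <- stats::sd(.fit_scores_for_codes(fit, probe))
    fit$coefficients[-1L] <- fit$coefficients[-1L] * (sd / s)
    fit$sigma <- 0
    fit$r_squared <- 1
    fit
  })
}

# draw (flat index, strand) pairs proportional to 2^bias over a region frame
.sample_cut_sites <- function(bias, n) {
  w <- c(2^bias$bias_plus, 2^bias$bias_minus)
  w[is.na(w)] <- 0
  if (all(w == 0)) rlang::abort("no valid positions to sample cleavages from")
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  m <- nrow(bias)
  strand <- ifelse(idx > m, "-", "+")
  flat <- ifelse(idx > m, idx - m, idx)
  list(flat = flat, strand = strand)
}

#' Simulate monomeric (DNaseI-style) cleavage reads
#'
#' Single-end cleavage events drawn within the regions with probability
#' proportional to `2^(truth score)` of each (position, strand)'s k-mer;
#' exactly `n_events` events are produced.
#'
#' @param genome A `selma_genome`.
#' @param regions Region tibble.
#' @param truth Scorer (bias table or `selma_fit`).
#' @param n_events Number of cleavage events.
#' @param seed Integer seed.
#' @return Single-end fragment tibble (`end` is `NA`; `strand` set).
#' @export
sim_dnase <- function(genome, regions, truth, n_events, seed = 1L) {
  bias <- position_bias(genome, regions, truth, method = "five_prime")
  .with_seed(seed, {
    cut <- .sample_cut_sites(bias, n_events)
    tibble::tibble(
      chrom = bias$chrom[cut$flat],
      start = bias$pos[cut$flat],
      end = NA_integer_,
      strand = cut$strand,
      barcode = NA_character_,
      count = 1L
    ) |> dplyr::arrange(.data$chrom, .data$start)
  })
}

#' Simulate dimeric (Tn5-style) paired fragments
#'
#' Each transposition event inserts at plus-position `i` with probability
#' proportional to `2^(a+_i) * 2^(a-_{i+offset})` (the product of its two
#' cut k-mer propensities) and cuts both strands: `+` at `i` and `-` at
#' `i + offset`.  Insertions are sampled per region, sorted, and paired
#' consecutively, so one insertion terminates two adjacent fragments — the
#' geometry that produces the `offset`-bp plus/minus cross-correlation
#' signature even for a flat truth.
#'
#' @inheritParams sim_dnase
#' @param n_fragments Approximate number of fragments (the consecutive
#'   pairing yields one fragment less per region than insertions).
#' @param offset Dimer span (default 9).
#' @return Paired fragment tibble.
#' @export
sim_atac_dimeric <- function(genome, regions, truth, n_fragments, offset = 9L,
                             seed = 1L) {
  bias <- position_bias(genome, regions, truth, method = "selma_dimeric",
                        offset = offset)
  w <- 2^(2 * bias$bias_plus)   # == 2^{a+_i} * 2^{a-_{i+offset}}
  w[is.na(w)] <- 0
  rids <- unique(bias$region_id)
  mass <- vapply(rids, function(r) sum(w[bias$region_id == r]), numeric(1L))
  if (all(mass == 0)) rlang::abort("no valid insertion positions")
  .with_seed(seed, {
    n_ins <- stats::rmultinom(1L, n_fragments + length(rids), mass)[, 1L]
    frags <- purrr::map_dfr(seq_along(rids), function(ri) {
      sel <- which(bias$region_id == rids[ri])
      if (n_ins[ri] < 2L || mass[ri] == 0) return(NULL)
      ins <- sort(sample(bias$pos[sel], n_ins[ri], replace = TRUE, prob = w[sel]))
      tibble::tibble(
        chrom = bias$chrom[sel[1L]],
        start = ins[-length(ins)],
        end = ins[-1L] + offset + 1L
      )
    })
    if (nrow(frags) > n_fragments) frags <- frags[seq_len(n_fragments), , drop = FALSE]
    frags$strand <- NA_character_
    frags$barcode <- NA_character_
    frags$count <- 1L
    dplyr::arrange(frags, .data$chrom, .data$start)
  })
}

#' Simulate footprints with planted bias spikes
#'
#' Builds a one-contig genome of `n` open regions, each holding one
#' footprint with `flank` bp of open chromatin on either side.  Cleavage
#' rates are `depth_per_bp` per strand outside footprints, reduced by the
#' `protection` factor inside, and multiplied by `2^spike_amp` at the spike
#' positions (7 bp inside each boundary, +/- 1 bp).  The planted
#' position-bias profile (value `spike_amp` at spike-set positions, 0
#' elsewhere, plus optional Gaussian noise) is returned alongside, so
#' footprint bias scores can be checked against the planted amplitude.
#'
#' @param n Number of footprints.
#' @param length_range Footprint length range (inclusive, default 25..50).
#' @param flank Open flank per side (default 50).
#' @param protection Multiplicative cleavage reduction inside the footprint
#'   (default 0.3).
#' @param spike_amp Planted spike amplitude, log2 units (default 1).
#' @param noise_sd Gaussian noise sd added to the planted bias (default 0).
#' @param depth_per_bp Expected cleavages per open position per strand
#'   (default 2).
#' @param seed Integer seed.
#' @return List with `genome`, `regions` (open regions), `footprints`,
#'   `events` (cleavage events with counts), `bias` (planted position-bias
#'   tibble), `spike_amp`.
#' @export
sim_footprints <- function(n = 100L, length_range = c(25L, 50L), flank = 50L,
                           protection = 0.3, spike_amp = 1, noise_sd = 0,
                           depth_per_bp = 2, seed = 1L) {
  .with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    gap <- 10L
    widths <- lens + 2L * flank
    starts <- cumsum(c(0L, utils::head(widths + gap, -1L)))
    total <- sum(widths) + gap * n
    g <- genome(stats::setNames(paste(sample(.BASES, total, replace = TRUE),
                                      collapse = ""), "chr1"))
    regions <- tibble::tibble(chrom = "chr1", start = starts, end = starts + widths)
    fps <- tibble::tibble(chrom = "chr1", start = starts + flank,
                          end = starts + flank + lens)
    rframe <- .region_frame(regions)
    npos <- sum(rframe$width)
    pos <- unlist(purrr::map2(rframe$start, rframe$end - 1L, seq), use.names = FALSE)
    rid <- rep(rframe$region_id, rframe$width)
    inside <- pos >= fps$start[rid] & pos < fps$end[rid]
    spike <- abs(pos - (fps$start[rid] + 7L)) <= 1L |
      abs(pos - (fps$end[rid] - 8L)) <= 1L
    planted <- ifelse(spike, spike_amp, 0)
    bias <- tibble::tibble(
      region_id = rid, chrom = "chr1", pos = pos,
      bias_plus = planted + stats::rnorm(npos, 0, noise_sd),
      bias_minus = planted + stats::rnorm(npos, 0, noise_sd)
    )
    rate <- depth_per_bp * ifelse(inside, protection, 1) * 2^planted
    cp <- stats::rpois(npos, rate)
    cm <- stats::rpois(npos, rate)
    keep <- cp > 0 | cm > 0
    events <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1", cut = pos[cp > 0], strand = "+",
                     barcode = NA_character_, count = cp[cp > 0]),
      tibble::tibble(chrom = "chr1", cut = pos[cm > 0], strand = "-",
                     barcode = NA_character_, count = cm[cm > 0])
    ) |> dplyr::arrange(.data$cut)
    list(genome = g, regions = regions, footprints = fps, events = events,
         bias = bias, spike_amp = spike_amp)
  })
}

#' Simulate a single-cell ATAC experiment with planted bias structure
#'
#' Cell types are distinguishable only through "signal" peaks (each signal
#' peak is preferentially accessible in one type).  A fraction of peaks are
#' "biased" peaks: their sequence is tiled from high-truth-score k-mers (so
#' their estimated peak bias score is high) and their counts carry
#' bias-driven noise shared across types — per-cell lognormal factors on
#' blocks of biased peaks — which confounds clustering.  Fragments with
#' cell barcodes are generated inside peaks with probability proportional
#' to the dimeric insertion propensity, so CBS/PBS estimation closes the
#' loop against the planted truth.
#'
#' @param n_types Number of cell types (default 3).
#' @param cells_per_type Cells per type (default 60).
#' @param n_peaks Total peaks (default 200).
#' @param frac_biased Fraction of biased peaks (default 0.4).
#' @param peak_width Peak width in bp (default 400).
#' @param k Truth k-mer size (default 6).
#' @param truth_sd Truth score sd (default 0.5).
#' @param depth_mean Mean fragments per cell (default 500).
#' @param signal_fold Accessibility fold of a signal peak in its preferred
#'   type (default 2.5).
#' @param bias_noise_sd sd of the per-cell log-normal block factors on
#'   biased peaks (default 1.5).
#' @param n_noise_blocks Number of biased-peak blocks sharing a per-cell
#'   factor (default 8).
#' @param exposure Optional per-type multiplier on biased-peak rates
#'   (length `n_types`); unequal values make CBS differ across types.
#' @param seed Integer seed.
#' @return List with `genome`, `peaks` (with `biased` flag), `counts`
#'   (sparse peaks x cells), `fragments` (barcoded), `labels`
#'   (barcode, type), `truth` (bias table), `config`.
#' @export
sim_sc <- function(n_types = 3L, cells_per_type = 60L, n_peaks = 200L,
                   frac_biased = 0.4, peak_width = 400L, k = 6L,
                   truth_sd = 0.5, depth_mean = 500, signal_fold = 2.5,
                   bias_noise_sd = 1.5, n_noise_blocks = 8L,
                   exposure = NULL, seed = 1L) {
  truth <- sim_truth_bias(k, "naive_random", sd = truth_sd, seed = seed + 7L)
  tvec <- .table_score_vec(truth)
  n_cells <- n_types * cells_per_type
  n_biased <- round(n_peaks * frac_biased)
  .with_seed(seed, {
    biased <- c(rep(TRUE, n_biased), rep(FALSE, n_peaks - n_biased))
    biased <- sample(biased)
    # biased peaks: tile sequence from k-mers drawn with prob ~ 2^(8*score),
    # concentrating composition in the top of the truth table
    hot_p <- 2^(8 * tvec); hot_p <- hot_p / sum(hot_p)
    mk_seq <- function(is_biased) {
      if (is_biased) {
        nk <- ceiling(peak_width / k)
        codes <- sample.int(4^k, nk, replace = TRUE, prob = hot_p) - 1L
        substr(paste(.codes_to_kmers(codes, k), collapse = ""), 1L, peak_width)
      } else {
        paste(sample(.BASES, peak_width, replace = TRUE), collapse = "")
      }
    }
    gap <- strrep("N", 20L)
    peak_seqs <- vapply(biased, mk_seq, character(1L))
    g <- genome(c(chr1 = paste(peak_seqs, collapse = gap)))
    starts <- (seq_len(n_peaks) - 1L) * (peak_width + 20L)
    peaks <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + peak_width,
                            name = sprintf("peak%04d", seq_len(n_peaks)),
                            biased = biased)
    # expected rates
    base_rate <- stats::rlnorm(n_peaks, 0, 0.3)
    pref_type <- sample.int(n_types, n_peaks, replace = TRUE)
    depth_f <- stats::rlnorm(n_cells, 0, 0.3)
    type_of <- rep(seq_len(n_types), each = cells_per_type)
    block_of <- sample.int(n_noise_blocks, n_peaks, replace = TRUE)
    block_f <- matrix(stats::rlnorm(n_noise_blocks * n_cells, 0, bias_noise_sd),
                      n_noise_blocks, n_cells)
    expo <- exposure %||% rep(1, n_types)
    lam <- matrix(base_rate, n_peaks, n_cells)
    for (cc in seq_len(n_cells)) {
      f <- ifelse(biased,
                  block_f[block_of, cc] * expo[type_of[cc]],
                  ifelse(pref_type == type_of[cc], signal_fold, 1))
      lam[, cc] <- lam[, cc] * f * depth_f[cc]
    }
    lam <- lam * (depth_mean * n_cells / sum(lam))
    counts <- matrix(stats::rpois(length(lam), lam), n_peaks, n_cells)
    barcodes <- sprintf("BC%04d", seq_len(n_cells))
    dimnames(counts) <- list(peaks$name, barcodes)
    # fragments: positions within the peak ~ dimeric insertion propensity
    pb <- position_bias(g, peaks[, c("chrom", "start", "end")], truth,
                        method = "selma_dimeric")
    frags <- vector("list", n_peaks)
    for (p in seq_len(n_peaks)) {
      tot <- sum(counts[p, ])
      if (tot == 0L) next
      sel <- which(pb$region_id == p)
      wp <- 2^(2 * pb$bias_plus[sel]); wp[is.na(wp)] <- 0
      wp[pb$pos[sel] > peaks$end[p] - 30L] <- 0   # room for the fragment body
      if (all(wp == 0)) wp <- as.numeric(pb$pos[sel] <= peaks$end[p] - 30L)
      st <- sample(pb$pos[sel], tot, replace = TRUE, prob = wp)
      len <- pmax(20L, pmin(round(stats::rnorm(tot, 150, 20)),
                            peaks$end[p] - st - 1L))
      frags[[p]] <- tibble::tibble(
        chrom = "chr1", start = st, end = st + len,
        strand = NA_character_,
        barcode = rep(barcodes, counts[p, ]),
        count = 1L
      )
    }
    fragments <- dplyr::bind_rows(frags) |> dplyr::arrange(.data$start)
    list(
      genome = g, peaks = peaks,
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      fragments = fragments,
      labels = tibble::tibble(barcode = barcodes, type = type_of),
      truth = truth,
      config = list(n_types = n_types, cells_per_type = cells_per_type,
                    n_peaks = n_peaks, frac_biased = frac_biased,
                    peak_width = peak_width, k = k, seed = seed)
    )
  })
}
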