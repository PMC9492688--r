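# Readers and writers for the external formats the package touches.
# All interval coordinates are 0-based half-open (BED-native) everywhere in
# the package; translation to the 1-based inclusive windows used in k-mer
# extraction happens only inside the k-mer layer.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file (gzip allowed; multi-line records allowed).
#' @param circular_contigs Character vector of contig names to flag as
#'   circular (e.g. `"chrM"`); k-mer windows on circular contigs wrap around
#'   the origin.
#' @return A `selma_genome`: list with `seq` (named uppercase character
#'   vector) and `circular` (named logical).  Alphabet is restricted to
#'   `A,C,G,T,N`; `U` is mapped to `T`; anything else is an error.  Circular
#'   contigs must be N-free.
#' @export
read_genome <- function(path, circular_contigs = character()) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) rlang::abort("FASTA contains no records")
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    rlang::abort(sprintf("contig %s contains non-IUPAC characters (only A,C,G,T,N,U supported)",
                         nm[which(bad)[1L]]))
  }
  if (any(nchar(seqs) == 0L)) rlang::abort("empty FASTA record")
  missing <- setdiff(circular_contigs, nm)
  if (length(missing)) {
    rlang::abort(paste0("circular contigs not in FASTA: ", paste(missing, collapse = ", ")))
  }
  genome(seqs, circular = circular_contigs)
}

#' Construct a genome object from in-memory sequences
#'
#' @param seqs Named character vector of uppercase contig sequences.
#' @param circular Names of circular contigs.
#' @return A `selma_genome`.
#' @export
genome <- function(seqs, circular = character()) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    rlang::abort("contigs must be named")
  }
  circ <- stats::setNames(names(seqs) %in% circular, names(seqs))
  if (any(circ & grepl("N", seqs, fixed = TRUE))) {
    rlang::abort("circular contigs must not contain N")
  }
  structure(list(seq = seqs, circular = circ), class = "selma_genome")
}

#' @export
print.selma_genome <- function(x, ...) {
  cat(sprintf("genome with %d contig(s):\n", length(x$seq)))
  for (nm in names(x$seq)) {
    cat(sprintf("  %s: %d bp%s\n", nm, nchar(x$seq[[nm]]),
                if (x$circular[[nm]]) " (circular)" else ""))
  }
  invisible(x)
}

contig_lengths <- function(genome) {
  stats::setNames(nchar(genome$seq), names(genome$seq))
}

#' Read genomic intervals from BED
#'
#' Coordinates are kept 0-based half-open, exactly as in the file; output is
#' sorted by (contig, start).
#'
#' @param path Tab-separated BED file (gzip allowed), no header.
#' @param min_cols Minimum number of columns required (3 or 6).
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path, min_cols = 3L) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < min_cols) {
    rlang::abort(sprintf("BED has %d columns, need >= %d", ncol(raw), min_cols))
  }
  out <- tibble::tibble(
    chrom = as.character(raw[[1L]]),
    start = as.integer(raw[[2L]]),
    end = as.integer(raw[[3L]])
  )
  if (ncol(raw) >= 4L) out$name <- as.character(raw[[4L]])
  if (ncol(raw) >= 5L) out$score <- as.numeric(raw[[5L]])
  if (ncol(raw) >= 6L) out$strand <- as.character(raw[[6L]])
  validate_regions(out)
  dplyr::arrange(out, .data$chrom, .data$start)
}

validate_regions <- function(regions, genome = NULL) {
  if (any(regions$start < 0L)) rlang::abort("negative start coordinate in regions")
  if (any(regions$start >= regions$end)) {
    i <- which(regions$start >= regions$end)[1L]
    rlang::abort(sprintf("region with start >= end: %s:%d-%d",
                         regions$chrom[i], regions$start[i], regions$end[i]))
  }
  if (!is.null(genome)) {
    len <- contig_lengths(genome)
    unknown <- setdiff(unique(regions$chrom), names(len))
    if (length(unknown)) {
      rlang::abort(paste0("regions on contigs absent from genome: ",
                          paste(unknown, collapse = ", ")))
    }
    over <- regions$end > len[regions$chrom]
    if (any(over)) {
      i <- which(over)[1L]
      rlang::abort(sprintf("region exceeds contig length: %s:%d-%d",
                           regions$chrom[i], regions$start[i], regions$end[i]))
    }
  }
  invisible(regions)
}

#' Write intervals as BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional further
#'   BED columns (`name`, `score`, `strand`, extras appended in order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(regions))
  extra <- setdiff(names(regions), cols)
  readr::write_tsv(regions[, c(cols, extra)], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read aligned fragments / reads
#'
#' Two dialects:
#' * `"plain"`: BED-like `(chrom, start, end[, strand][, barcode])`;
#'   coordinates pass through unchanged.  Single-end records may leave `end`
#'   as `NA` but must then carry a strand.
#' * `"tenx_shifted"`: the 10x `fragments.tsv` 5-column dialect
#'   `(chrom, start, end, barcode, count)`.  Those files store
#'   transposition centers shifted by +4/-5 from the cleavage sites, so the
#'   reader undoes the shift: `start - 4`, `end + 5`.  A worked example:
#'   a stored row `(chr1, 104, 195)` becomes the fragment `(chr1, 100, 200)`,
#'   whose cleavage events are `+` at 100 and `-` at 199.  Rows whose shift
#'   would produce a negative start are dropped (count reported via message).
#'   Duplicate `(chrom, start, end, barcode)` rows are collapsed, summing the
#'   count column.
#'
#' @param path Tab-separated file (gzip allowed), no header.
#' @param dialect `"plain"` or `"tenx_shifted"`.
#' @param barcode_column For `"plain"`: optional 1-based column index holding
#'   the cell barcode.
#' @param dedup For `"plain"`: collapse identical `(chrom, start, end,
#'   barcode)` records to one (upstream pipelines usually deduplicate
#'   already, so the default is `FALSE`).
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `barcode`,
#'   `count`.
#' @export
read_fragments <- function(path, dialect = c("plain", "tenx_shifted"),
                           barcode_column = NULL, dedup = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (dialect == "tenx_shifted") {
    if (ncol(raw) < 5L) rlang::abort("tenx_shifted dialect needs 5 columns")
    out <- tibble::tibble(
      chrom = as.character(raw[[1L]]),
      start = as.integer(raw[[2L]]) - 4L,
      end = as.integer(raw[[3L]]) + 5L,
      strand = NA_character_,
      barcode = as.character(raw[[4L]]),
      count = as.integer(raw[[5L]])
    )
    neg <- out$start < 0L
    if (any(neg)) {
      message(sprintf("read_fragments: dropped %d row(s) whose shift-back gave a negative start",
                      sum(neg)))
      out <- out[!neg, , drop = FALSE]
    }
    out <- out |>
      dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand, .data$barcode) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  } else {
    if (ncol(raw) < 3L) rlang::abort("plain fragment file needs >= 3 columns")
    out <- tibble::tibble(
      chrom = as.character(raw[[1L]]),
      start = as.integer(raw[[2L]]),
      end = suppressWarnings(as.integer(raw[[3L]]))
    )
    strand_col <- which(vapply(raw, function(col) all(col %in% c("+", "-"), na.rm = TRUE) &&
                                 is.character(col) && any(!is.na(col)), logical(1L)))
    out$strand <- if (length(strand_col)) as.character(raw[[strand_col[1L]]]) else NA_character_
    out$barcode <- if (!is.null(barcode_column)) as.character(raw[[barcode_column]]) else NA_character_
    out$count <- 1L
    if (dedup) {
      out <- out |>
        dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                        .data$barcode, .keep_all = TRUE)
    }
  }
  bad <- !is.na(out$end) & out$start >= out$end
  if (any(bad)) {
    i <- which(bad)[1L]
    rlang::abort(sprintf("malformed fragment (start >= end): %s:%d-%d",
                         out$chrom[i], out$start[i], out$end[i]))
  }
  single <- is.na(out$end)
  if (any(single & is.na(out$strand))) {
    rlang::abort("single-end records (missing end) must carry a strand")
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write fragments as a plain BED-like TSV
#'
#' @param fragments Fragment tibble (as from [read_fragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments, path, col_names = FALSE, progress = FALSE, na = ".")
  invisible(path)
}

#' Read / write a k-mer bias table
#'
#' TSV with header `kmer, score, n_cleavage, n_background, provenance, k`;
#' scores survive a write/read round trip at full double precision.
#'
#' @param path TSV path (gzip allowed).
#' @return A bias table tibble.
#' @export
read_bias_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(kmer = "c", score = "c",
                                                 n_cleavage = "d", n_background = "d",
                                                 provenance = "c", k = "i"))
  # base strtod is correctly rounded, so 17-digit decimals round-trip bitwise
  raw$score <- as.numeric(raw$score)
  need <- c("kmer", "score", "n_cleavage", "n_background", "provenance", "k")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    rlang::abort(paste0("bias table file missing columns: ", paste(miss, collapse = ", ")))
  }
  k <- unique(raw$k)
  if (length(k) != 1L) rlang::abort("bias table file mixes k values")
  if (any(nchar(raw$kmer) != k)) rlang::abort("k-mer length differs from the k column")
  out <- new_bias_table(raw$kmer, raw$score, raw$n_cleavage, raw$n_background,
                        k = k, provenance = unique(raw$provenance)[1L],
                        background_kind = attr(raw, "background_kind") %||% "unknown")
  validate_bias_table(out)
  out
}

#' @rdname read_bias_table
#' @param table Bias table to write.
#' @export
write_bias_table <- function(table, path) {
  validate_bias_table(table)
  out <- tibble::as_tibble(table)[, c("kmer", "score", "n_cleavage", "n_background")]
  # serialize doubles at 17 significant digits so scores round-trip bitwise
  out$score <- sprintf("%.17g", out$score)
  out$provenance <- attr(table, "provenance") %||% "naive"
  out$k <- attr(table, "k") %||% nchar(table$kmer[1L])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a peak-by-cell count matrix
#'
#' MatrixMarket coordinate file plus a peak BED and a barcode list (one
#' barcode per line).  Rows are peaks, columns are cells.
#'
#' @param mtx Path to the MatrixMarket file.
#' @param peaks Path to the peak BED (row labels, in matrix row order).
#' @param barcodes Path to the barcode list (column labels).
#' @return A list of class `selma_pcm`: `counts` (sparse `dgCMatrix` with
#'   dimnames), `peaks` (region tibble in row order).
#' @export
read_peak_cell_matrix <- function(mtx, peaks, barcodes) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  pk <- read_bed_unsorted(peaks)
  bc <- readr::read_lines(barcodes, progress = FALSE)
  if (nrow(pk) != nrow(m)) {
    rlang::abort(sprintf("matrix has %d rows but %d peaks given", nrow(m), nrow(pk)))
  }
  if (length(bc) != ncol(m)) {
    rlang::abort(sprintf("matrix has %d columns but %d barcodes given", ncol(m), length(bc)))
  }
  if (any(m@x < 0)) rlang::abort("negative counts in matrix")
  pk$name <- if ("name" %in% names(pk)) pk$name else
    paste0(pk$chrom, ":", pk$start, "-", pk$end)
  dimnames(m) <- list(pk$name, bc)
  structure(list(counts = m, peaks = pk), class = "selma_pcm")
}

# BED reader preserving file order (matrix row labels must not be re-sorted)
read_bed_unsorted <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  out <- tibble::tibble(chrom = as.character(raw[[1L]]),
                        start = as.integer(raw[[2L]]),
                        end = as.integer(raw[[3L]]))
  if (ncol(raw) >= 4L) out$name <- as.character(raw[[4L]])
  validate_regions(out)
  out
}

#' @rdname read_peak_cell_matrix
#' @param pcm A `selma_pcm` object.
#' @param prefix Output prefix; writes `<prefix>.mtx`, `<prefix>.peaks.bed`,
#'   `<prefix>.barcodes.txt`.
#' @export
write_peak_cell_matrix <- function(pcm, prefix) {
  Matrix::writeMM(pcm$counts, paste0(prefix, ".mtx"))
  write_bed(pcm$peaks, paste0(prefix, ".peaks.bed"))
  readr::write_lines(colnames(pcm$counts), paste0(prefix, ".barcodes.txt"))
  invisible(prefix)
}

#' @export
print.selma_pcm <- function(x, ...) {
  cat(sprintf("peak-by-cell matrix: %d peaks x %d cells, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}
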