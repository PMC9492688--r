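# Integer k-mer machinery shared across the package.
#
# Bases map to integers A=0, C=1, G=2, T=3 (N and anything else -> NA).  A
# k-mer is identified by its lexicographic code: the first base is the most
# significant base-4 digit, so code("AC") = 0*4 + 1 = 1.  Codes stay below
# 2^31 for k <= 15, so plain R integers are safe for the supported k <= 14.

.BASES <- c("A", "C", "G", "T")

.base_lookup <- local({
  lk <- rep(NA_integer_, 256L)
  lk[utf8ToInt("A") + 1L] <- 0L
  lk[utf8ToInt("C") + 1L] <- 1L
  lk[utf8ToInt("G") + 1L] <- 2L
  lk[utf8ToInt("T") + 1L] <- 3L
  lk
})

# character string (one contig) -> integer vector of base codes, NA for N
.seq_ints <- function(seq) {
  .base_lookup[utf8ToInt(seq) + 1L]
}

.ints_to_seq <- function(ints) {
  out <- rep("N", length(ints))
  ok <- !is.na(ints)
  out[ok] <- .BASES[ints[ok] + 1L]
  paste(out, collapse = "")
}

# Rolling k-mer codes: element i is the code of the window starting at
# 0-based offset i-1 (R index i), i = 1 .. length(ints) - k + 1.
# Windows touching an NA base get code NA.
.kmer_codes <- function(ints, k) {
  n <- length(ints)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  codes <- integer(m)
  for (j in seq_len(k)) {
    codes <- codes * 4L + ints[j:(m + j - 1L)]
  }
  codes
}

# Reverse-complement of k-mer codes, computed digit-wise (no 4^k table).
.revcomp_codes <- function(codes, k) {
  rc <- integer(length(codes))
  rc[is.na(codes)] <- NA_integer_
  tmp <- codes
  for (j in seq_len(k)) {
    d <- tmp %% 4L
    rc <- rc * 4L + (3L - d)
    tmp <- tmp %/% 4L
  }
  rc
}

# codes -> k-mer strings, vectorized (used when tables are materialized)
.codes_to_kmers <- function(codes, k) {
  n <- length(codes)
  if (n == 0L) return(character(0))
  cols <- vector("list", k)
  tmp <- codes
  for (j in k:1) {
    cols[[j]] <- .BASES[(tmp %% 4L) + 1L]
    tmp <- tmp %/% 4L
  }
  do.call(paste0, cols)
}

# k-mer strings -> codes (NA when a string contains a non-ACGT base)
.kmers_to_codes <- function(kmers, k) {
  if (length(kmers) == 0L) return(integer(0))
  ints <- .base_lookup[utf8ToInt(paste(kmers, collapse = "")) + 1L]
  mat <- matrix(ints, nrow = k)
  codes <- integer(length(kmers))
  for (j in seq_len(k)) {
    codes <- codes * 4L + mat[j, ]
  }
  codes
}

.revcomp_seq <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.check_even_k <- function(k, min = 4L, max = 14L) {
  if (length(k) != 1L || is.na(k) || k %% 2L != 0L || k < min || k > max) {
    rlang::abort(sprintf("`k` must be a single even integer in [%d, %d], got %s",
                         min, max, paste(k, collapse = ",")))
  }
  as.integer(k)
}
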