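# Simplex encoding of k-mers and the linear bias model fitted on top of
# naive k-mer scores.
#
# Each nucleotide is one of the four tetrahedral vertices of the 0-centered
# cube of side 2; a dinucleotide is the row-major flattening of the outer
# product of its two base vectors.  A k-mer is encoded as
# [intercept | k mononucleotide blocks of 3 | k-1 dinucleotide blocks of 9],
# p(k) = 12k - 8 features, every entry in {-1, +1}.

ENC_MONO <- rbind(
  A = c( 1, -1, -1),
  C = c(-1,  1, -1),
  G = c(-1, -1,  1),
  T = c( 1,  1,  1)
)

# 16 x 9, rows ordered AA, AC, AG, AT, CA, ... (first base most significant)
ENC_DI <- local({
  m <- matrix(0, 16L, 9L)
  for (b1 in 0:3) {
    for (b2 in 0:3) {
      m[b1 * 4L + b2 + 1L, ] <- as.vector(t(outer(ENC_MONO[b1 + 1L, ],
                                                  ENC_MONO[b2 + 1L, ])))
    }
  }
  b <- c("A", "C", "G", "T")
  rownames(m) <- as.vector(t(outer(b, b, paste0)))
  m
})

#' Simplex encoding of a single nucleotide
#'
#' Maps a base to its 3-dimensional simplex vector: the four bases sit at
#' four tetrahedral vertices of the cube `[-1, 1]^3`, so the encodings are
#' mutually orthogonal, of equal norm, and sum to zero.
#'
#' @param base Single character, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return Numeric vector of length 3 with entries in `{-1, 1}`.
#' @examples
#' encode_base("A")  # c(1, -1, -1)
#' @export
encode_base <- function(base) {
  if (!is.character(base) || length(base) != 1L || !base %in% .BASES) {
    rlang::abort("`base` must be one of \"A\", \"C\", \"G\", \"T\"")
  }
  unname(ENC_MONO[base, ])
}

#' Simplex encoding of a dinucleotide
#'
#' The interaction term for two adjacent bases: the row-major flattening of
#' the outer product of the two base encodings.  The 16 dinucleotide vectors
#' are again mutually orthogonal with equal norm.
#'
#' @param base1,base2 Single characters in `{A, C, G, T}`.
#' @return Numeric vector of length 9 with entries in `{-1, 1}`.
#' @examples
#' encode_dinucleotide("A", "T")
#' @export
encode_dinucleotide <- function(base1, base2) {
  v1 <- encode_base(base1)
  v2 <- encode_base(base2)
  as.vector(t(outer(v1, v2)))
}

#' Number of parameters of the simplex k-mer model
#'
#' One intercept, `k` mononucleotide blocks of 3 and `k - 1` dinucleotide
#' blocks of 9: `p(k) = 1 + 3k + 9(k - 1) = 12k - 8`.  Compare with the
#' `4^k` free parameters of a naive k-mer table.
#'
#' @param k k-mer size (integer `>= 2`).
#' @return Integer parameter count.
#' @examples
#' param_count(6)   # 64
#' param_count(10)  # 112
#' @export
param_count <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 2L) {
    rlang::abort("`k` must be a single integer >= 2")
  }
  as.integer(12L * k - 8L)
}

#' Simplex feature vector of a k-mer
#'
#' @param kmer A single k-mer string over `{A, C, G, T}`.
#' @return Named numeric vector of length `12k - 8` with entries in
#'   `{-1, 1}`; layout `[intercept | mono_1..mono_k | di_1..di_{k-1}]`.
#' @examples
#' length(encode_kmer("ACGTACGTAC"))  # 112
#' @export
encode_kmer <- function(kmer) {
  if (!is.character(kmer) || length(kmer) != 1L) {
    rlang::abort("`kmer` must be a single string")
  }
  k <- nchar(kmer)
  if (k < 2L) rlang::abort("k-mer must have length >= 2")
  code <- .kmers_to_codes(kmer, k)
  if (is.na(code)) rlang::abort(sprintf("invalid base in k-mer \"%s\"", kmer))
  drop(.simplex_design(code, k))
}

.simplex_colnames <- function(k) {
  c("intercept",
    paste0("mono", rep(seq_len(k), each = 3L), "_", rep(1:3, k)),
    paste0("di", rep(seq_len(k - 1L), each = 9L), "_", rep(1:9, k - 1L)))
}

# design matrix rows for a vector of k-mer codes; n x (12k - 8)
.simplex_design <- function(codes, k) {
  n <- length(codes)
  p <- 12L * k - 8L
  digits <- matrix(0L, n, k)
  tmp <- codes
  for (j in k:1) {
    digits[, j] <- tmp %% 4L
    tmp <- tmp %/% 4L
  }
  X <- matrix(1, n, p)
  for (j in seq_len(k)) {
    X[, (2L + 3L * (j - 1L)):(1L + 3L * j)] <- ENC_MONO[digits[, j] + 1L, , drop = FALSE]
  }
  off <- 1L + 3L * k
  for (j in seq_len(k - 1L)) {
    di <- digits[, j] * 4L + digits[, j + 1L]
    X[, (off + 9L * (j - 1L) + 1L):(off + 9L * j)] <- ENC_DI[di + 1L, , drop = FALSE]
  }
  colnames(X) <- .simplex_colnames(k)
  X
}

#' Fit the simplex linear model to a naive k-mer bias table
#'
#' Ordinary (optionally background-count weighted) least squares of the naive
#' log2 bias scores on the simplex encodings of their k-mers.  The fitted
#' value for a k-mer is its model bias score; because the model has only
#' `12k - 8` parameters it extrapolates to all `4^k` k-mers, including those
#' never observed in training.
#'
#' The normal equations are accumulated in chunks (the +/-1 design is very
#' well conditioned), so tables with millions of rows fit in modest memory.
#'
#' @param naive A naive bias table from [naive_bias()] (tibble with columns
#'   `kmer`, `score`, `n_background`).
#' @param weighting `"none"` (default) for OLS, or `"background"` to weight
#'   each k-mer by its background occurrence count (noisier scores from rare
#'   k-mers get less influence).
#' @return An object of class `selma_fit` with elements `coefficients`, `k`,
#'   `n_train`, `sigma`, `r_squared`.  Use [predict()][predict.selma_fit],
#'   [selma_bias_table()], [tidy()][tidy.selma_fit] and
#'   [glance()][glance.selma_fit] on it.
#' @export
fit_selma <- function(naive, weighting = c("none", "background")) {
  weighting <- match.arg(weighting)
  k <- attr(naive, "k")
  if (is.null(k)) {
    kl <- unique(nchar(naive$kmer))
    if (length(kl) != 1L) rlang::abort("mixed k-mer lengths in `naive`")
    k <- as.integer(kl)
  }
  p <- param_count(k)
  keep <- is.finite(naive$score)
  codes <- .kmers_to_codes(naive$kmer[keep], k)
  y <- naive$score[keep]
  w <- if (weighting == "background") as.numeric(naive$n_background[keep]) else NULL
  n <- length(y)
  if (n < p) {
    rlang::abort(sprintf("need at least %d k-mers with defined scores to fit k = %d (got %d)",
                         p, k, n))
  }
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  chunk <- 200000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    X <- .simplex_design(codes[s:e], k)
    if (is.null(w)) {
      XtX <- XtX + crossprod(X)
      Xty <- Xty + crossprod(X, y[s:e])
    } else {
      Xw <- X * w[s:e]
      XtX <- XtX + crossprod(X, Xw)
      Xty <- Xty + crossprod(Xw, y[s:e])
    }
  }
  qd <- qr(XtX)
  if (qd$rank < p) {
    bad <- .simplex_colnames(k)[qd$pivot[(qd$rank + 1L):p]]
    blocks <- unique(sub("_[0-9]+$", "", bad))
    rlang::abort(paste0("rank-deficient simplex design; unidentifiable blocks: ",
                        paste(blocks, collapse = ", ")))
  }
  a <- drop(solve(qd, Xty))
  names(a) <- .simplex_colnames(k)
  fit <- structure(
    list(coefficients = a, k = k, n_train = n, weighting = weighting),
    class = "selma_fit"
  )
  fitted <- .fit_scores_for_codes(fit, codes)
  res <- y - fitted
  fit$sigma <- sqrt(sum(res^2) / max(n - p, 1L))
  fit$r_squared <- if (stats::var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else NA_real_
  fit
}

# Per-position contribution tables: mono 4 x k, di 16 x (k-1).
.fit_contribs <- function(fit) {
  k <- fit$k
  a <- fit$coefficients
  monoC <- matrix(0, 4L, k)
  for (j in seq_len(k)) {
    monoC[, j] <- ENC_MONO %*% a[(2L + 3L * (j - 1L)):(1L + 3L * j)]
  }
  off <- 1L + 3L * k
  diC <- matrix(0, 16L, k - 1L)
  for (j in seq_len(k - 1L)) {
    diC[, j] <- ENC_DI %*% a[(off + 9L * (j - 1L) + 1L):(off + 9L * j)]
  }
  list(intercept = unname(a[1L]), mono = monoC, di = diC)
}

# model scores for a vector of k-mer codes (NA in -> NA out)
.fit_scores_for_codes <- function(fit, codes) {
  k <- fit$k
  ct <- .fit_contribs(fit)
  out <- rep(ct$intercept, length(codes))
  digits <- matrix(0L, length(codes), k)
  tmp <- codes
  for (j in k:1) {
    digits[, j] <- tmp %% 4L
    tmp <- tmp %/% 4L
  }
  for (j in seq_len(k)) {
    out <- out + ct$mono[digits[, j] + 1L, j]
  }
  for (j in seq_len(k - 1L)) {
    out <- out + ct$di[digits[, j] * 4L + digits[, j + 1L] + 1L, j]
  }
  out[is.na(codes)] <- NA_real_
  out
}

# model scores for every window start of a base-integer sequence
# (fast path used by position_bias and the simulators; avoids 4^k tables)
.fit_window_scores <- function(fit, ints) {
  k <- fit$k
  n <- length(ints)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  ct <- .fit_contribs(fit)
  out <- rep(ct$intercept, m)
  for (j in seq_len(k)) {
    out <- out + ct$mono[ints[j:(m + j - 1L)] + 1L, j]
  }
  for (j in seq_len(k - 1L)) {
    di <- ints[j:(m + j - 1L)] * 4L + ints[(j + 1L):(m + j)]
    out <- out + ct$di[di + 1L, j]
  }
  out
}

#' @export
print.selma_fit <- function(x, ...) {
  cat(sprintf("Simplex k-mer bias fit (k = %d, p = %d)\n", x$k, param_count(x$k)))
  cat(sprintf("  trained on %d k-mers (%s weighting)\n", x$n_train, x$weighting))
  cat(sprintf("  residual sd %.4g, R^2 %.4g\n", x$sigma, x$r_squared))
  invisible(x)
}

#' Model bias scores for new k-mers
#'
#' @param object A `selma_fit`.
#' @param kmers Character vector of k-mers (length-`k` strings).
#' @param ... Unused.
#' @return Numeric vector of fitted log2 bias scores.
#' @export
predict.selma_fit <- function(object, kmers, ...) {
  codes <- .kmers_to_codes(kmers, object$k)
  .fit_scores_for_codes(object, codes)
}

#' @export
coef.selma_fit <- function(object, ...) object$coefficients

#' Tidy a simplex bias fit
#'
#' One row per coefficient, with its block (`intercept`, `mono`, `di`) and
#' the k-mer position the block describes.
#'
#' @param x A `selma_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `block`, `position`, `estimate`.
#' @export
tidy.selma_fit <- function(x, ...) {
  term <- names(x$coefficients)
  block <- sub("[0-9].*$", "", term)
  pos <- suppressWarnings(as.integer(sub("_[0-9]+$", "", sub("^[a-z]+", "", term))))
  tibble::tibble(term = term, block = block, position = pos,
                 estimate = unname(x$coefficients))
}

#' One-line summary of a simplex bias fit
#'
#' @param x A `selma_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `p`, `n_train`, `sigma`, `r_squared`.
#' @export
glance.selma_fit <- function(x, ...) {
  tibble::tibble(k = x$k, p = param_count(x$k), n_train = x$n_train,
                 sigma = x$sigma, r_squared = x$r_squared)
}

#' Generic tidy / glance (broom-style)
#' @param x Object to summarize.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Materialize the full model bias table
#'
#' Evaluates the fitted model on all `4^k` k-mers.  Intended for `k <= 10`
#' (about one million rows); for larger `k` use [predict.selma_fit()] or the
#' profile functions, which evaluate the model positionally.
#'
#' @param fit A `selma_fit`.
#' @param provenance Provenance label stored on the table.
#' @return A bias table tibble (see [naive_bias()]) covering every k-mer.
#' @export
selma_bias_table <- function(fit, provenance = "selma") {
  k <- fit$k
  ncodes <- 4^k
  if (ncodes > 2^24) {
    rlang::abort("full table materialization is limited to k <= 12; use predict()")
  }
  codes <- seq_len(ncodes) - 1L
  scores <- .fit_scores_for_codes(fit, codes)
  new_bias_table(
    kmer = .codes_to_kmers(codes, k),
    score = scores,
    n_cleavage = rep(NA_real_, ncodes),
    n_background = rep(NA_real_, ncodes),
    k = k, provenance = provenance
  )
}

#' Randomly permute a bias table ("simulated enzyme" control)
#'
#' Reassigns the score column across k-mers uniformly at random, preserving
#' the score multiset.  Used as a null control: positional structure of the
#' genome is kept while any real sequence-bias association is destroyed.
#'
#' @param table A bias table.
#' @param seed Integer seed; same seed gives the same permutation.
#' @return A bias table with `provenance = "permuted"`.
#' @export
permute_bias_table <- function(table, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  idx <- .with_seed(seed, sample.int(nrow(table)))
  out <- table
  out$score <- table$score[idx]
  attr(out, "provenance") <- "permuted"
  out
}
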