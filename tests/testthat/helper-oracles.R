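# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's internal code paths: string
# manipulation, dense enumeration, svd pseudoinverse, pair counting.

oracle_base_enc <- list(
  A = c(1, -1, -1), C = c(-1, 1, -1), G = c(-1, -1, 1), T = c(1, 1, 1)
)

# encode a k-mer string from first principles (row-major outer products)
oracle_encode <- function(kmer) {
  b <- strsplit(kmer, "")[[1]]
  mono <- unlist(lapply(b, function(x) oracle_base_enc[[x]]))
  di <- unlist(lapply(seq_len(length(b) - 1), function(i) {
    as.vector(t(outer(oracle_base_enc[[b[i]]], oracle_base_enc[[b[i + 1]]])))
  }))
  c(1, mono, di)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# enumerate both-strand k-mer occurrences over a region's sequence
oracle_background <- function(seq, k) {
  n <- nchar(seq)
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("N", w)) out <- c(out, w, oracle_revcomp(w))
  }
  table(out)
}

# cleavage k-mer by direct window arithmetic (0-based cut, 1-based substr)
oracle_cleavage_kmer <- function(seq, cut, strand, k) {
  if (strand == "+") {
    s <- cut - k / 2 + 1
    if (s < 1 || s + k - 1 > nchar(seq)) return(NA_character_)
    w <- substr(seq, s, s + k - 1)
  } else {
    s <- cut - k / 2 + 2
    if (s < 1 || s + k - 1 > nchar(seq)) return(NA_character_)
    w <- oracle_revcomp(substr(seq, s, s + k - 1))
  }
  if (grepl("N", w)) NA_character_ else w
}

# least squares via svd pseudoinverse on a dense design
oracle_lstsq <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-10
  drop(sv$v[, keep] %*% ((t(sv$u[, keep]) %*% y) / sv$d[keep]))
}

# expected profile by direct evaluation of the window redistribution
oracle_expected <- function(counts, a, w) {
  n <- length(counts)
  half <- w / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - half; hi <- i + half - 1
    if (lo < 1 || hi > n) next
    win <- lo:hi
    out[i] <- sum(counts[win]) * 2^a[i] / sum(2^a[win])
  }
  out
}

# FBS by literal recomputation from per-position bias arrays (0-based coords)
oracle_fbs <- function(start, end, bias_plus, bias_minus, pos) {
  sL <- start + 7; sR <- end - 8
  spike <- unique(c(sL + (-1:1), sR + (-1:1)))
  rest <- setdiff(start:(end - 1), spike)
  b <- mean(c(bias_plus[match(spike, pos)], bias_minus[match(spike, pos)]))
  cc <- median(c(bias_plus[match(rest, pos)], bias_minus[match(rest, pos)]))
  b - cc
}

# ranking points for ROC/PR curves by explicit threshold sweep
.rank_points_oracle <- function(probs, labels) {
  th <- sort(unique(probs), decreasing = TRUE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- fpr <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- probs >= th[i]
    tpr[i] <- sum(labels[sel] == 1) / P
    fpr[i] <- sum(labels[sel] == 0) / N
    prec[i] <- mean(labels[sel] == 1)
  }
  list(tpr = tpr, fpr = fpr, recall = tpr, precision = prec)
}

# trapezoid partial areas from an explicit curve point list
oracle_partial_area <- function(x, y, cut) {
  # piecewise-linear curve through the ordered points (x, y), vertical
  # segments allowed; integrate segment by segment over [0, cut] / cut
  area <- 0
  for (i in seq_len(length(x) - 1)) {
    x1 <- x[i]; x2 <- x[i + 1]; y1 <- y[i]; y2 <- y[i + 1]
    if (x1 >= cut) break
    if (x2 > cut) {  # clip the crossing segment at cut
      y2 <- y1 + (y2 - y1) * (cut - x1) / (x2 - x1)
      x2 <- cut
    }
    area <- area + (x2 - x1) * (y1 + y2) / 2
  }
  area / cut
}

# ARI by direct pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  tot <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - exp_idx) / (max_idx - exp_idx)
}

# one-way ANOVA F via lm on a single response vector
oracle_anova_f <- function(y, g) {
  av <- stats::anova(stats::lm(y ~ factor(g)))
  c(f = av$`F value`[1], p = av$`Pr(>F)`[1])
}
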