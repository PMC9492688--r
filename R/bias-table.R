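# The k-mer bias table container: a tibble with one row per k-mer and
# attributes k / provenance / background_kind.  Scores are log2 of the
# (pseudocounted) cleavage/background ratio; NA marks k-mers whose
# background occurrence fell below the reporting threshold.

new_bias_table <- function(kmer, score, n_cleavage, n_background,
                           k, provenance = "naive", background_kind = "peaks") {
  out <- tibble::tibble(
    kmer = kmer,
    score = as.numeric(score),
    n_cleavage = as.numeric(n_cleavage),
    n_background = as.numeric(n_background)
  )
  attr(out, "k") <- as.integer(k)
  attr(out, "provenance") <- provenance
  attr(out, "background_kind") <- background_kind
  class(out) <- c("selma_bias", class(out))
  out
}

validate_bias_table <- function(table) {
  need <- c("kmer", "score", "n_cleavage", "n_background")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    rlang::abort(paste0("bias table is missing columns: ", paste(miss, collapse = ", ")))
  }
  kl <- unique(nchar(table$kmer))
  if (length(kl) != 1L) {
    rlang::abort("bias table mixes k-mer lengths")
  }
  if (anyDuplicated(table$kmer)) {
    dup <- table$kmer[duplicated(table$kmer)][1L]
    rlang::abort(sprintf("duplicate k-mer in bias table: \"%s\"", dup))
  }
  if (any(!grepl("^[ACGT]+$", table$kmer))) {
    rlang::abort("bias table k-mers must be over {A,C,G,T}")
  }
  invisible(table)
}

#' @export
print.selma_bias <- function(x, ...) {
  cat(sprintf("k-mer bias table: k = %s, provenance = %s, background = %s\n",
              attr(x, "k"), attr(x, "provenance"), attr(x, "background_kind")))
  cat(sprintf("  %d k-mers, %d with defined scores\n",
              nrow(x), sum(is.finite(x$score))))
  NextMethod()
}

# numeric vector of length 4^k indexed by k-mer code + 1 (NA where undefined)
.table_score_vec <- function(table) {
  k <- attr(table, "k") %||% unique(nchar(table$kmer))
  vec <- rep(NA_real_, 4^k)
  codes <- .kmers_to_codes(table$kmer, k)
  vec[codes + 1L] <- table$score
  vec
}

#' Median-center the scores of a bias table
#'
#' Subtracts the median of the defined scores, the convention used when
#' comparing tables estimated from different samples (only relative
#' propensities are identifiable).  Idempotent.
#'
#' @param table A bias table.
#' @return The table with centered scores.
#' @export
center_scores <- function(table) {
  if (!nrow(table)) rlang::abort("empty bias table")
  med <- stats::median(table$score, na.rm = TRUE)
  table$score <- table$score - med
  table
}

`%||%` <- function(a, b) if (is.null(a)) b else a
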