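#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor cov rbinom rlnorm rnorm rpois runif sd wilcox.test
#' @importFrom utils head read.delim write.table
NULL

# Internal: validate a scalar fraction in [lo, hi].
check_fraction <- function(x, name, lo = 0, hi = 1, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < lo || x > hi || (strict_lo && x <= lo)) {
    abort(sprintf("`%s` must be a single number in %s%s, %s]",
                  name, if (strict_lo) "(" else "[", format(lo), format(hi)))
  }
  invisible(x)
}

# Internal: derive a reproducible child seed from a parent seed and a tag.
# Keeps results well under .Machine$integer.max.
derive_seed <- function(seed, tag) {
  offset <- sum(utf8ToInt(as.character(tag))) %% 1000L
  (as.integer(seed) %% 2000000L) * 1000L + offset
}

# Internal: population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Internal: numerically stable log(sum(exp(x))) over rows of a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Library-size normalize and log-transform a count matrix
#'
#' Divides each cell (column) by its total count, multiplies by a fixed scale
#' factor, and applies `log1p`. This is the transformation used throughout the
#' pipeline before any Gaussian statistic (differential expression,
#' conditional mutual information, embedding features, classifier input) is
#' computed, since those estimators are invalid on raw counts.
#'
#' @param counts A genes x cells numeric matrix of nonnegative counts.
#' @param scale_factor Per-cell target library size after normalization.
#' @return A matrix of the same shape, `log1p(count / libsize * scale_factor)`.
#'   All-zero cells are left at zero.
#' @export
tm_normalize_counts <- function(counts, scale_factor = 1e4) {
  stopifnot(is.matrix(counts) || inherits(counts, "Matrix"))
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  libs[libs == 0] <- 1
  log1p(sweep(counts, 2L, libs, "/") * scale_factor)
}
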