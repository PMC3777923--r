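# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent (C collation) ordering; used wherever the canonical
# pair order "lexicographic by gene_id" matters.
radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) x[radix_order(x)]

# Squared Euclidean cross-distance matrix between the rows of A (q x m) and
# the rows of B (n x m) via the crossprod expansion; clamps the tiny negative
# values that cancellation produces.
cross_dist_sq <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[is.nan(d2)] <- Inf  # Inf - Inf from a non-finite coordinate
  d2[d2 < 0] <- 0
  d2
}

# log(sum(exp(x))) without overflow; -Inf for an empty or all -Inf input.
log_sum_exp <- function(x) {
  m <- suppressWarnings(max(x))
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_pplink <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
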