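# Stage 1: real-valued phylogenetic profiles and the non-zero filter.
#
# A gene's phylogenetic profile is the vector of R-values across the n
# reference organisms: the best bit score against each organism (S-value,
# trimmed to 0 below 50) divided by the gene's self-alignment score, then
# column-normalized so the non-zero entries of each organism average 1.
# Pair similarity is the inner product of two normalized profiles, and a
# pair is only considered reliable if both profiles carry at least nz
# non-zero entries.

#' Construct a profile matrix
#'
#' @param values Numeric genes x organisms matrix of R-values (rownames gene
#'   ids, colnames organism ids), all entries >= 0.
#' @param normalized Has per-organism column normalization been applied?
#' @return An object of class `profile_matrix` with fields `values`,
#'   `gene_ids`, `organism_ids`, `normalized`.
#' @export
profile_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pplink("profile matrix needs gene rownames and organism colnames")
  if (any(values < 0)) stop_pplink("R-values must be >= 0")
  structure(list(values = values,
                 gene_ids = rownames(values),
                 organism_ids = colnames(values),
                 normalized = isTRUE(normalized)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d genes x %d organisms (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "column-normalized" else "raw R-values"))
  invisible(x)
}

#' Trim a bit score at the homology-noise threshold
#'
#' Non-homologous sequences have an appreciable chance of aligning with a
#' bit score up to about 50, so S-values below 50 are set to zero.
#'
#' @param S Numeric vector of bit scores (>= 0).
#' @param threshold Trim threshold (default 50; strict "lower than").
#' @return `S` with entries `< threshold` replaced by 0.
#' @export
trim_score <- function(S, threshold = 50) {
  if (any(S < 0)) stop_pplink("bit scores must be >= 0")
  ifelse(S < threshold, 0, S)
}

#' Normalize a bit score by the self-alignment score
#'
#' R = S_ab / S_aa, clamped to at most 1: a cross-organism score exceeding
#' the self-score is pathological and would break the documented [0, 1]
#' pre-normalization range (clamping is reported with a warning).
#'
#' @param S_ab Trimmed bit score(s) of gene a against organism b.
#' @param S_aa Self-alignment score(s) of gene a (> 0).
#' @return Numeric R-value(s) in [0, 1].
#' @export
r_value <- function(S_ab, S_aa) {
  if (any(!is.finite(S_aa)) || any(S_aa <= 0))
    stop_pplink("self score S_aa must be finite and > 0")
  if (any(S_ab < 0)) stop_pplink("S_ab must be >= 0")
  r <- S_ab / S_aa
  if (any(r > 1)) {
    warning(sprintf("%d R-value(s) > 1 clamped to 1", sum(r > 1)),
            call. = FALSE)
    r <- pmin(r, 1)
  }
  r
}

#' Build the raw profile matrix from a hit table
#'
#' Entry (g, b) is `r_value(trim_score(S_gb), S_gg)`; a missing hit
#' contributes 0. The query organism must not appear in the reference
#' collection: a profile column for the query itself would be degenerate
#' (every gene hits itself), so overlapping ids are refused unless
#' explicitly overridden.
#'
#' @param hits A [hit_table()].
#' @param genes Ordered gene ids (default: sorted names of the self scores).
#' @param organisms Ordered reference organism ids (default: sorted organisms
#'   present in `hits`).
#' @param query_organism Optional id of the query organism, checked against
#'   `organisms`.
#' @param allow_query_in_references Override the overlap refusal.
#' @return A raw (un-normalized) [profile_matrix()].
#' @export
build_profile_matrix <- function(hits, genes = NULL, organisms = NULL,
                                 query_organism = NULL,
                                 allow_query_in_references = FALSE) {
  stopifnot(inherits(hits, "hit_table"))
  genes <- genes %||% radix_sort(names(hits$self_scores))
  organisms <- organisms %||% radix_sort(unique(hits$scores$organism))
  if (!is.null(query_organism) && query_organism %in% organisms &&
      !allow_query_in_references)
    stop_pplink("query organism '%s' is in the reference collection",
                query_organism)
  missing_self <- setdiff(genes, names(hits$self_scores))
  if (length(missing_self))
    stop_pplink("missing self score for gene(s): %s",
                paste(missing_self, collapse = ", "))

  V <- matrix(0, nrow = length(genes), ncol = length(organisms),
              dimnames = list(genes, organisms))
  sc <- hits$scores[hits$scores$gene_id %in% genes &
                      hits$scores$organism %in% organisms, , drop = FALSE]
  if (nrow(sc)) {
    V[cbind(match(sc$gene_id, genes), match(sc$organism, organisms))] <-
      r_value(trim_score(sc$score), hits$self_scores[sc$gene_id])
  }
  profile_matrix(V, normalized = FALSE)
}

#' Column-normalize a profile matrix
#'
#' Within each reference organism, every non-zero R-value is divided by the
#' mean of that column's non-zero R-values (zero entries and all-zero
#' columns are untouched). This prevents the pair similarity from being
#' dominated by a few large R-values from phylogenetically close organisms.
#' Applying it twice is an error.
#'
#' @param matrix_ A raw [profile_matrix()].
#' @return The normalized `profile_matrix` (each column's non-zero mean is 1).
#' @export
normalize_columns <- function(matrix_) {
  stopifnot(inherits(matrix_, "profile_matrix"))
  if (matrix_$normalized)
    stop_pplink("profile matrix is already column-normalized")
  V <- matrix_$values
  for (b in seq_len(ncol(V))) {
    nz <- V[, b] > 0
    if (any(nz)) V[nz, b] <- V[nz, b] / mean(V[nz, b])
  }
  profile_matrix(V, normalized = TRUE)
}

#' Inner-product similarity of two profiles
#'
#' @param p_i,p_j Numeric R-value vectors of equal length (rows of the same
#'   normalized profile matrix).
#' @return `sum(p_i * p_j)` (symmetric, non-negative).
#' @export
profile_similarity <- function(p_i, p_j) {
  if (length(p_i) != length(p_j))
    stop_pplink("profile length mismatch (%d vs %d)", length(p_i),
                length(p_j))
  sum(p_i * p_j)
}

#' Non-zero reliability filter
#'
#' A similarity resting on too few organisms is unreliable: the pair passes
#' only if *both* profiles have at least `nz` non-zero entries (`nz = 0`
#' passes everything; `nz = 1` rejects only all-zero profiles).
#'
#' @param p_i,p_j Profile vectors.
#' @param nz Non-negative integer threshold.
#' @return TRUE iff both profiles have `>= nz` non-zero elements.
#' @export
nonzero_filter <- function(p_i, p_j, nz) {
  if (nz < 0) stop_pplink("nz must be >= 0")
  sum(p_i != 0) >= nz && sum(p_j != 0) >= nz
}

#' Run stage 1 over a pair set
#'
#' Applies the non-zero filter first; the similarity of a pair failing it is
#' not computed (`NA`, "no prediction"). A pair survives stage 1 iff it
#' passes the filter and its similarity strictly exceeds `sim_threshold`
#' (default 0: only zero-similarity pairs are dropped).
#'
#' @param matrix_ A column-normalized [profile_matrix()].
#' @param pairs Pair data frame (`gene_a`, `gene_b`, optional `related`).
#' @param nz Non-zero filter threshold.
#' @param sim_threshold Similarity threshold (strict).
#' @return `pairs` with added columns `similarity`, `passed_nz`,
#'   `passed_similarity`.
#' @export
stage_one <- function(matrix_, pairs, nz = 1L, sim_threshold = 0) {
  stopifnot(inherits(matrix_, "profile_matrix"))
  if (!matrix_$normalized)
    stop_pplink("stage_one requires a column-normalized profile matrix")
  V <- matrix_$values
  absent <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(V))
  if (length(absent))
    stop_pplink("gene(s) absent from profile matrix: %s",
                paste(absent, collapse = ", "))
  ia <- match(pairs$gene_a, rownames(V))
  ib <- match(pairs$gene_b, rownames(V))
  nz_count <- rowSums(V != 0)
  passed_nz <- nz_count[ia] >= nz & nz_count[ib] >= nz
  similarity <- rep(NA_real_, nrow(pairs))
  if (any(passed_nz))
    similarity[passed_nz] <- rowSums(V[ia[passed_nz], , drop = FALSE] *
                                       V[ib[passed_nz], , drop = FALSE])
  pairs$similarity <- similarity
  pairs$passed_nz <- unname(passed_nz)
  pairs$passed_similarity <- pairs$passed_nz & !is.na(similarity) &
    similarity > sim_threshold
  pairs
}
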