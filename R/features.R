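# Conjoint-triad sequence encoding.
#
# Residues are collapsed into 7 physicochemical groups (dipole strength and
# side-chain volume), a sliding window of three consecutive group symbols is
# counted into a 343-dimensional occurrence vector, and a pair of proteins
# is the 686-dimensional concatenation of the two vectors in canonical
# (lexicographic gene-id) order.

# Table of the seven amino-acid groups.
AA_GROUPS <- list(
  `1` = c("A", "G", "V"),
  `2` = c("I", "L", "F", "P"),
  `3` = c("Y", "M", "T", "S"),
  `4` = c("H", "N", "Q", "W"),
  `5` = c("R", "K"),
  `6` = c("D", "E"),
  `7` = c("C")
)

.aa_group_lookup <- local({
  v <- integer(0)
  for (g in names(AA_GROUPS)) v[AA_GROUPS[[g]]] <- as.integer(g)
  v
})

#' Physicochemical group of a residue
#'
#' @param residue Character vector of single amino-acid letters (the 20
#'   standard residues, uppercase).
#' @return Integer group number(s) in 1..7.
#' @export
group_of <- function(residue) {
  g <- .aa_group_lookup[residue]
  if (anyNA(g))
    stop_pplink("non-standard residue(s): %s",
                paste(unique(residue[is.na(g)]), collapse = ", "))
  unname(g)
}

#' Index of a triad of groups
#'
#' Base-7 positional code with the first residue most significant; a
#' bijection between group triples and 0..342. Any consistent bijection
#' works as long as training and prediction share it.
#'
#' @param g1,g2,g3 Integer group numbers in 1..7 (vectorized).
#' @return Integer triad index in 0..342.
#' @export
triad_index <- function(g1, g2, g3) {
  if (any(c(g1, g2, g3) < 1L) || any(c(g1, g2, g3) > 7L))
    stop_pplink("group numbers must be in 1..7")
  (g1 - 1L) * 49L + (g2 - 1L) * 7L + (g3 - 1L)
}

#' Decode a triad index back to its group triple
#' @param index Integer in 0..342.
#' @return Integer matrix with columns `g1`, `g2`, `g3`.
#' @export
triad_groups <- function(index) {
  if (any(index < 0L) || any(index > 342L))
    stop_pplink("triad index must be in 0..342")
  cbind(g1 = index %/% 49L + 1L,
        g2 = (index %% 49L) %/% 7L + 1L,
        g3 = index %% 7L + 1L)
}

#' Conjoint-triad occurrence vector of a protein sequence
#'
#' Slides a width-3 window (step 1) over the group sequence and counts each
#' triad type: a length-L sequence contributes `max(L - 2, 0)` counts.
#'
#' @param protein_seq A single protein sequence over the standard residues.
#' @param scale `"counts"` (raw occurrences, the default) or `"minmax"`
#'   (counts rescaled to `(o - min(o)) / max(o)`, an optional normalization
#'   for experimentation).
#' @return Numeric vector of length 343 (named by the group triple).
#' @export
occurrence_vector <- function(protein_seq, scale = c("counts", "minmax")) {
  scale <- match.arg(scale)
  stopifnot(length(protein_seq) == 1L)
  g <- group_of(strsplit(protein_seq, "", fixed = TRUE)[[1L]])
  L <- length(g)
  o <- integer(343L)
  if (L >= 3L) {
    idx <- triad_index(g[1:(L - 2L)], g[2:(L - 1L)], g[3:L])
    o <- tabulate(idx + 1L, nbins = 343L)
  }
  tg <- triad_groups(0:342)
  names(o) <- paste0(tg[, 1L], tg[, 2L], tg[, 3L])
  if (scale == "minmax" && max(o) > 0) o <- (o - min(o)) / max(o)
  o
}

#' Occurrence vectors for a whole set of gene records
#' @param records A [gene_records()] tibble.
#' @inheritParams occurrence_vector
#' @return Numeric genes x 343 matrix, rownames gene ids.
#' @export
occurrence_matrix <- function(records, scale = c("counts", "minmax")) {
  scale <- match.arg(scale)
  M <- t(vapply(records$protein_seq,
                function(s) occurrence_vector(s, scale = scale),
                numeric(343L), USE.NAMES = FALSE))
  rownames(M) <- records$gene_id
  M
}

#' Encode a protein pair as a 686-dimensional feature vector
#'
#' Concatenates the two occurrence vectors in canonical pair order
#' (lexicographic by gene id), so `encode_pair(a, b)` and
#' `encode_pair(b, a)` are identical.
#'
#' @param rec_a,rec_b Single gene records (1-row tibbles or lists with
#'   `gene_id` and `protein_seq`).
#' @inheritParams occurrence_vector
#' @return Numeric vector of length 686.
#' @export
encode_pair <- function(rec_a, rec_b, scale = c("counts", "minmax")) {
  scale <- match.arg(scale)
  ids <- c(rec_a$gene_id, rec_b$gene_id)
  seqs <- c(rec_a$protein_seq, rec_b$protein_seq)
  ord <- radix_order(ids)
  c(occurrence_vector(seqs[ord[1L]], scale = scale),
    occurrence_vector(seqs[ord[2L]], scale = scale))
}

#' Feature matrix for a set of pairs
#'
#' Computes each gene's occurrence vector once and assembles the pair rows
#' by indexing, which is what makes whole-pipeline runs affordable.
#'
#' @param records Gene records covering every gene named in `pairs`.
#' @param pairs Pair data frame (`gene_a`, `gene_b` in canonical order).
#' @inheritParams occurrence_vector
#' @return Numeric pairs x 686 matrix (first 343 columns belong to
#'   `gene_a`).
#' @export
pair_features <- function(records, pairs, scale = c("counts", "minmax")) {
  scale <- match.arg(scale)
  M <- occurrence_matrix(records, scale = scale)
  absent <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(M))
  if (length(absent))
    stop_pplink("gene(s) without records: %s", paste(absent, collapse = ", "))
  swap <- pairs$gene_a > pairs$gene_b  # enforce canonical orientation
  a <- ifelse(swap, pairs$gene_b, pairs$gene_a)
  b <- ifelse(swap, pairs$gene_a, pairs$gene_b)
  cbind(M[a, , drop = FALSE], M[b, , drop = FALSE])
}
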