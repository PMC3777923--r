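# File formats, dataset filters and pair labeling.
#
# The pipeline consumes protein FASTA files, BLAST tabular (outfmt-6 style)
# hit files and a two-column gene -> pathway membership table. Everything is
# parsed into plain data structures: gene records are a tibble with a
# list-column of pathway ids, hit tables are a best-hit-reduced score table
# plus a named vector of self-alignment scores.

#' Construct a table of gene records
#'
#' A gene record holds the protein sequence of one gene together with its
#' (optional) nucleotide gene length and the set of pathways it participates
#' in. Records are the common currency between the I/O, feature-encoding and
#' pipeline layers.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param protein_seq Character vector of protein sequences (uppercased).
#' @param nt_length Integer vector of nucleotide gene lengths, or `NA` when
#'   unknown (a proxy of `3 * (protein length + 1)` is substituted by
#'   [filter_genes()]).
#' @param pathways List of character vectors, one set of pathway ids per gene.
#' @return A tibble with columns `gene_id`, `protein_seq`, `nt_length` and
#'   list-column `pathways`.
#' @export
gene_records <- function(gene_id, protein_seq, nt_length = NA_integer_,
                         pathways = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop_pplink("duplicate gene ids: %s",
                paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(!nzchar(gene_id))) stop_pplink("empty gene id")
  n <- length(gene_id)
  pathways <- pathways %||% rep(list(character(0)), n)
  tibble::tibble(
    gene_id = gene_id,
    protein_seq = toupper(as.character(protein_seq)),
    nt_length = as.integer(rep_len(nt_length, n)),
    pathways = pathways
  )
}

#' Read a protein FASTA file
#'
#' The record identifier is the first whitespace-delimited token of the
#' header; multi-line sequence bodies are concatenated and uppercased; record
#' order is preserved. A sequence line appearing before any header is a parse
#' error reported with its line number.
#'
#' @param path Path to a FASTA file.
#' @return A [gene_records()] tibble (pathways empty, `nt_length` `NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_pplink("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(gene_records(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop_pplink("malformed FASTA in %s: sequence before header at line %d",
                path, nonblank[1L])
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  gene_records(ids, as.character(seqs))
}

#' Write gene records to a protein FASTA file
#' @param records A [gene_records()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$protein_seq)
  names(set) <- records$gene_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct a hit table
#'
#' @param scores Data frame with columns `gene_id`, `organism`, `score`
#'   (best BLAST bit score of the gene against all ORFs of the organism).
#' @param self_scores Named numeric vector of self-alignment bit scores
#'   \eqn{S_{aa}}, names are gene ids.
#' @return An object of class `hit_table`.
#' @export
hit_table <- function(scores, self_scores) {
  scores <- as.data.frame(scores)[, c("gene_id", "organism", "score")]
  if (anyDuplicated(scores[, c("gene_id", "organism")]))
    stop_pplink("hit table not reduced: duplicate (gene, organism) entries")
  if (any(scores$score < 0)) stop_pplink("negative bit score")
  if (any(!is.finite(self_scores)) || any(self_scores <= 0))
    stop_pplink("self scores must be finite and > 0")
  missing_self <- setdiff(unique(scores$gene_id), names(self_scores))
  if (length(missing_self))
    stop_pplink("missing self score for gene(s): %s",
                paste(missing_self, collapse = ", "))
  structure(list(scores = scores, self_scores = self_scores),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d best-hit entries, %d genes, %d organisms\n",
              nrow(x$scores), length(x$self_scores),
              length(unique(x$scores$organism))))
  invisible(x)
}

#' Read BLAST tabular output into a hit table
#'
#' Parses an outfmt-6-style tab-separated file and keeps, for every
#' (query gene, reference organism), the maximum bit score over all hits.
#' Rows whose query and subject ids are identical are self-alignments and
#' populate the self-score slot; every other subject id must be mapped to a
#' reference organism by `subject_to_org`. Column positions are configurable
#' because custom BLAST output layouts abound.
#'
#' @param path Path to the tabular file.
#' @param subject_to_org Named character vector mapping subject sequence ids
#'   to reference organism ids.
#' @param qseqid_col,sseqid_col,bitscore_col 1-based column positions
#'   (defaults: standard outfmt 6, bitscore in column 12).
#' @param self_path Optional path to a two-column TSV (gene_id, self bit
#'   score) supplying self-alignment scores; in-file `qseqid == sseqid` hits
#'   take precedence.
#' @return A [hit_table()].
#' @export
read_blast_tabular <- function(path, subject_to_org,
                               qseqid_col = 1L, sseqid_col = 2L,
                               bitscore_col = 12L, self_path = NULL) {
  if (!file.exists(path)) stop_pplink("no such file: %s", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  need <- max(qseqid_col, sseqid_col, bitscore_col)
  if (nrow(tab) && ncol(tab) < need)
    stop_pplink("%s has %d columns; need at least %d", path, ncol(tab), need)

  self_scores <- numeric(0)
  if (!is.null(self_path)) {
    st <- utils::read.delim(self_path, header = FALSE,
                            colClasses = c("character", "numeric"))
    self_scores <- stats::setNames(st[[2L]], st[[1L]])
  }

  if (nrow(tab) == 0L)
    return(hit_table(data.frame(gene_id = character(0),
                                organism = character(0),
                                score = numeric(0)),
                     self_scores))

  q <- tab[[qseqid_col]]
  s <- tab[[sseqid_col]]
  b <- suppressWarnings(as.numeric(tab[[bitscore_col]]))
  if (anyNA(b))
    stop_pplink("non-numeric bitscore at line %d of %s", which(is.na(b))[1L],
                path)

  is_self <- q == s
  if (any(is_self)) {
    infile_self <- tapply(b[is_self], q[is_self], max)
    self_scores[names(infile_self)] <- infile_self  # in-file wins
  }

  q <- q[!is_self]; s <- s[!is_self]; b <- b[!is_self]
  unmapped <- setdiff(unique(s), names(subject_to_org))
  if (length(unmapped))
    stop_pplink("subject id(s) with no organism mapping: %s",
                paste(unmapped, collapse = ", "))
  org <- unname(subject_to_org[s])

  if (length(q)) {
    key <- paste(q, org, sep = "\r")
    best <- tapply(b, key, max)
    parts <- strsplit(names(best), "\r", fixed = TRUE)
    scores <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                         organism = vapply(parts, `[`, "", 2L),
                         score = as.numeric(best))
  } else {
    scores <- data.frame(gene_id = character(0), organism = character(0),
                         score = numeric(0))
  }
  hit_table(scores, self_scores)
}

#' Read a subject -> organism mapping TSV
#' @param path Two-column TSV: subject id, organism id.
#' @return Named character vector.
#' @export
read_subject_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2L) stop_pplink("subject map must have 2 columns")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read a gene -> pathway membership table
#'
#' KEGG-style two-column TSV (gene_id, pathway_id); repeated gene rows union
#' their pathways, duplicate rows are idempotent.
#'
#' @param path Path to the TSV.
#' @return Named list: gene id -> character vector of pathway ids.
#' @export
read_pathway_membership <- function(path) {
  if (!file.exists(path)) stop_pplink("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop_pplink("membership row with %d columns at line %d of %s",
                lengths(fields)[bad[1L]], bad[1L], path)
  gene <- vapply(fields, `[`, "", 1L)
  pw <- vapply(fields, `[`, "", 2L)
  lapply(split(pw, gene), function(x) unique(x))
}

#' Attach pathway memberships to gene records
#' @param records A [gene_records()] tibble.
#' @param membership Named list as returned by [read_pathway_membership()].
#' @return The records with the `pathways` column filled (genes absent from
#'   `membership` get the empty set).
#' @export
attach_pathways <- function(records, membership) {
  records$pathways <- lapply(records$gene_id, function(g) {
    membership[[g]] %||% character(0)
  })
  records
}

#' Apply the dataset filters
#'
#' Keeps genes whose nucleotide sequence is strictly longer than `min_nt`,
#' whose protein sequence contains only the 20 proteinogenic residues, and
#' that participate in at least one pathway. When `nt_length` is absent,
#' `3 * (protein length + 1)` (coding length plus stop codon) is used as a
#' proxy and the substitution is reported via `message()`.
#'
#' @param records A [gene_records()] tibble.
#' @param min_nt Length threshold in nucleotides (strict; default 150).
#' @param require_pathway Drop genes with an empty pathway set (default TRUE).
#' @return The filtered tibble. Idempotent.
#' @export
filter_genes <- function(records, min_nt = 150L, require_pathway = TRUE) {
  if (nrow(records) == 0L) return(records)
  nt <- records$nt_length
  if (anyNA(nt)) {
    message(sprintf("filter_genes: nt_length absent for %d gene(s); using 3*(protein length + 1)",
                    sum(is.na(nt))))
    nt[is.na(nt)] <- 3L * (nchar(records$protein_seq[is.na(nt)]) + 1L)
  }
  ok_len <- nt > min_nt
  ok_aa <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", records$protein_seq)
  ok_pw <- if (require_pathway) lengths(records$pathways) > 0L else TRUE
  records[ok_len & ok_aa & ok_pw, , drop = FALSE]
}

#' Enumerate all unordered gene pairs with relatedness labels
#'
#' Two genes are *related* iff their pathway sets intersect; all
#' \eqn{\binom{G}{2}} pairs over the `G` records are enumerated with
#' `gene_a < gene_b` under C-locale lexicographic order (the canonical pair
#' order used throughout the package).
#'
#' @param records A [gene_records()] tibble with pathway sets attached.
#' @return Data frame with columns `gene_a`, `gene_b`, `related` (logical).
#' @export
derive_pair_labels <- function(records) {
  ids <- records$gene_id
  if (anyDuplicated(ids)) stop_pplink("duplicate gene ids")
  G <- length(ids)
  if (G < 2L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      related = logical(0)))
  ord <- radix_order(ids)
  ids <- ids[ord]
  pathways <- records$pathways[ord]

  # shared-pathway counts via the gene x pathway incidence matrix
  pw_ids <- unique(unlist(pathways, use.names = FALSE))
  if (length(pw_ids)) {
    inc <- matrix(0, nrow = G, ncol = length(pw_ids),
                  dimnames = list(NULL, pw_ids))
    for (i in seq_len(G)) inc[i, pathways[[i]]] <- 1
    shared <- tcrossprod(inc)
  } else {
    shared <- matrix(0, G, G)
  }

  ia <- rep.int(seq_len(G - 1L), times = (G - 1L):1L)
  ib <- sequence((G - 1L):1L) + ia
  data.frame(gene_a = ids[ia], gene_b = ids[ib],
             related = shared[cbind(ia, ib)] > 0)
}

#' Write / read a profile matrix as TSV
#'
#' Plain tab-separated text: an optional `# normalized: true|false` comment
#' line, a header row of organism ids, then one row per gene (first column
#' the gene id). Round-trips values to better than 1e-12.
#'
#' @param matrix_ A [profile_matrix()].
#' @param path Output path.
#' @return `path` invisibly (write); a `profile_matrix` (read).
#' @export
write_profile_matrix <- function(matrix_, path) {
  stopifnot(inherits(matrix_, "profile_matrix"))
  v <- matrix_$values
  header <- paste(c("gene_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], formatC(v[i, ], digits = 17, format = "g")),
          collapse = "\t")
  }, "")
  writeLines(c(sprintf("# normalized: %s", tolower(matrix_$normalized)),
               header, rows), path)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  if (!file.exists(path)) stop_pplink("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  normalized <- FALSE
  if (length(lines) && startsWith(lines[1L], "#")) {
    normalized <- grepl("true", lines[1L], fixed = TRUE)
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop_pplink("empty profile matrix file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1L]))
    stop_pplink("ragged row at line %d of %s", which(ncols != ncols[1L])[1L],
                path)
  organisms <- fields[[1L]][-1L]
  body <- fields[-1L]
  genes <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]),
                   numeric(length(organisms))))
  if (length(organisms) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(genes, organisms)
  profile_matrix(vals, normalized = normalized)
}
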