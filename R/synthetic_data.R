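# Seeded synthetic data bundles.
#
# Emulates the structure the two-stage method assumes: pathways define
# clades of reference organisms in which their member genes are present
# (co-evolution signal for stage 1) and biased distributions over the seven
# residue groups (compositional signal for stage 2). A per-pathway
# coherence factor couples the two signals — strongly conserved functional
# modules are conserved both in their presence pattern and in their
# sequence composition — which is the agreement between stages that the
# two-stage design exploits. All randomness flows from the single config
# seed.

#' Synthetic bundle configuration
#'
#' @param n_pathways Number of pathways (functional modules).
#' @param genes_per_pathway Genes per pathway, per organism (pathways are
#'   disjoint: each gene belongs to exactly one).
#' @param n_reference_organisms Size of the reference collection.
#' @param clade_fraction Probability that a reference organism belongs to a
#'   pathway's clade.
#' @param presence_noise Baseline per-cell presence flip probability
#'   (modulated per pathway by the coherence factor, mean preserved).
#' @param selfscore_range Range (low, high) of self-alignment bit scores.
#' @param hit_ratio_shape Beta shape parameters of the `S_ab / S_aa` ratio
#'   for present genes, rescaled to the interval `(50 / S_aa, 1]` so every
#'   present cell survives the trim rule.
#' @param subthreshold_rate Probability that an absent cell gets a spurious
#'   score uniform in (0, 50) — exercising the trim rule.
#' @param group_bias_strength Dirichlet concentration of the per-pathway
#'   distributions over the 7 residue groups (smaller = spikier = stronger
#'   compositional signal).
#' @param seq_length_range Protein length range (residues), uniform.
#' @param coherence_shape Beta shape parameters of the per-pathway
#'   coherence factor coupling presence noise and compositional bias.
#' @param disjoint_clades If TRUE, reference organisms are partitioned
#'   round-robin among pathways (clades never overlap), the regime in which
#'   a noiseless bundle gives cross-pathway similarity exactly 0. Default
#'   FALSE: independent random clades.
#' @param seed Integer seed fixing all downstream randomness.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_pathways = 8L, genes_per_pathway = 12L,
                         n_reference_organisms = 40L,
                         clade_fraction = 0.35, presence_noise = 0.08,
                         selfscore_range = c(200, 600),
                         hit_ratio_shape = c(5, 2),
                         subthreshold_rate = 0.05,
                         group_bias_strength = 0.5,
                         seq_length_range = c(80L, 300L),
                         coherence_shape = c(2, 2),
                         disjoint_clades = FALSE,
                         seed = 42L) {
  stopifnot(n_pathways >= 1, genes_per_pathway >= 2,
            n_reference_organisms >= 1,
            clade_fraction >= 0, clade_fraction <= 1,
            presence_noise >= 0, presence_noise <= 0.5,
            subthreshold_rate >= 0, subthreshold_rate <= 1,
            group_bias_strength > 0,
            selfscore_range[1] > 50, diff(selfscore_range) >= 0,
            seq_length_range[1] >= 3, diff(seq_length_range) >= 0)
  structure(list(
    n_pathways = as.integer(n_pathways),
    genes_per_pathway = as.integer(genes_per_pathway),
    n_reference_organisms = as.integer(n_reference_organisms),
    clade_fraction = clade_fraction, presence_noise = presence_noise,
    selfscore_range = selfscore_range, hit_ratio_shape = hit_ratio_shape,
    subthreshold_rate = subthreshold_rate,
    group_bias_strength = group_bias_strength,
    seq_length_range = as.integer(seq_length_range),
    coherence_shape = coherence_shape,
    disjoint_clades = isTRUE(disjoint_clades),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d pathways x %d genes, %d reference organisms, seed %d\n",
    x$n_pathways, x$genes_per_pathway, x$n_reference_organisms, x$seed))
  invisible(x)
}

.pathway_ids <- function(config) sprintf("pw%02d", seq_len(config$n_pathways))
.organism_ids <- function(config)
  sprintf("org%03d", seq_len(config$n_reference_organisms))

# Pathway-level structure shared by the two organisms of a bundle:
# clades, coherence factors, group distributions. Consumes the RNG stream.
.pathway_structure <- function(config) {
  P <- config$n_pathways
  O <- config$n_reference_organisms
  coherence <- stats::rbeta(P, config$coherence_shape[1],
                            config$coherence_shape[2])
  if (config$disjoint_clades) {
    clades <- matrix(FALSE, P, O)
    clades[cbind((seq_len(O) - 1L) %% P + 1L, seq_len(O))] <- TRUE
  } else {
    clades <- matrix(stats::runif(P * O) < config$clade_fraction, P, O)
  }
  dimnames(clades) <- list(.pathway_ids(config), .organism_ids(config))
  conc <- config$group_bias_strength * (1.5 - coherence)
  group_probs <- t(vapply(conc, function(a) {
    g <- stats::rgamma(7L, shape = a)
    g / sum(g)
  }, numeric(7L)))
  rownames(group_probs) <- .pathway_ids(config)
  list(clades = clades, coherence = coherence, group_probs = group_probs)
}

#' Generate the presence/absence structure
#'
#' Each pathway gets a clade of reference organisms; each gene inherits its
#' pathway's presence row with independent per-cell flips whose rate is the
#' configured `presence_noise` scaled by `2 * (1 - coherence)` for its
#' pathway (so pathway coherence preserves the mean rate). Consumes the
#' current RNG stream; seed with [withr::with_seed()] or use
#' [generate_bundle()], which seeds everything from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param prefix Gene-id prefix (one letter; ids look like `Q0001`).
#' @param structure_ Optional pathway structure to reuse (internal; lets
#'   the two organisms of a bundle share clades and group distributions).
#' @return List with `pathway_presence` (pathways x organisms logical),
#'   `gene_presence` (genes x organisms logical), `assignments` (named
#'   character vector gene -> pathway), `coherence`, `group_probs`.
#' @export
generate_presence <- function(config, prefix = "Q", structure_ = NULL) {
  st <- structure_ %||% .pathway_structure(config)
  P <- config$n_pathways
  G <- P * config$genes_per_pathway
  gene_ids <- sprintf("%s%04d", prefix, seq_len(G))
  pw <- rep(.pathway_ids(config), each = config$genes_per_pathway)
  assignments <- stats::setNames(pw, gene_ids)
  flip_rate <- config$presence_noise * 2 *
    (1 - st$coherence[match(pw, .pathway_ids(config))])
  flip_rate <- pmin(pmax(flip_rate, 0), 1)
  base <- st$clades[pw, , drop = FALSE]
  flips <- matrix(stats::runif(length(base)), nrow = G) <
    matrix(flip_rate, nrow = G, ncol = ncol(base))
  gene_presence <- xor(base, flips)
  dimnames(gene_presence) <- list(gene_ids, colnames(st$clades))
  list(pathway_presence = st$clades, gene_presence = gene_presence,
       assignments = assignments, coherence = st$coherence,
       group_probs = st$group_probs)
}

#' Generate a hit table from a presence matrix
#'
#' Self scores are uniform in `selfscore_range`; a present (gene, organism)
#' cell gets `S_ab = S_aa * ratio` with the ratio Beta-distributed on
#' `(50 / S_aa, 1]` (always surviving the trim at 50); an absent cell is 0,
#' or with probability `subthreshold_rate` a spurious score uniform in
#' (0, 50) that the trim rule removes. Consumes the current RNG stream.
#'
#' @param presence Genes x organisms logical matrix
#'   (`gene_presence` from [generate_presence()]).
#' @param config A [synth_config()].
#' @return A [hit_table()].
#' @export
generate_hit_table <- function(presence, config) {
  genes <- rownames(presence)
  orgs <- colnames(presence)
  G <- length(genes)
  self_scores <- stats::setNames(
    stats::runif(G, config$selfscore_range[1], config$selfscore_range[2]),
    genes)
  rows <- vector("list", G)
  for (i in seq_len(G)) {
    s_aa <- self_scores[i]
    present <- presence[i, ]
    score <- numeric(length(orgs))
    if (any(present)) {
      lo <- 50 / s_aa
      ratio <- lo + stats::rbeta(sum(present), config$hit_ratio_shape[1],
                                 config$hit_ratio_shape[2]) * (1 - lo)
      ratio <- pmax(ratio, lo * (1 + 1e-9))  # strictly above the trim
      score[present] <- s_aa * ratio
    }
    if (any(!present) && config$subthreshold_rate > 0) {
      spurious <- !present &
        stats::runif(length(orgs)) < config$subthreshold_rate
      score[spurious] <- stats::runif(sum(spurious), 0, 50)
    }
    keep <- score > 0
    rows[[i]] <- data.frame(gene_id = genes[i], organism = orgs[keep],
                            score = score[keep])
  }
  hit_table(do.call(rbind, rows), self_scores)
}

.residues_by_group <- function() AA_GROUPS

#' Generate group-biased protein sequences
#'
#' Each gene's residues are drawn position-by-position: a group from its
#' pathway's distribution over the 7 groups, then a residue uniformly
#' within the group. Lengths are uniform in `seq_length_range`; the
#' emitted `nt_length` is `3 * (length + 1)` (coding length plus stop
#' codon). Consumes the current RNG stream.
#'
#' @param assignments Named character vector gene -> pathway.
#' @param config A [synth_config()].
#' @param group_probs Pathways x 7 matrix of group probabilities
#'   (from [generate_presence()]).
#' @return A [gene_records()] tibble with singleton pathway sets.
#' @export
generate_sequences <- function(assignments, config, group_probs) {
  genes <- names(assignments)
  span <- config$seq_length_range[2] - config$seq_length_range[1] + 1L
  lens <- config$seq_length_range[1] +
    sample.int(span, length(genes), replace = TRUE) - 1L
  groups <- .residues_by_group()
  seqs <- vapply(seq_along(genes), function(i) {
    p <- group_probs[assignments[i], ]
    g <- sample.int(7L, lens[i], replace = TRUE, prob = p)
    paste(vapply(g, function(k) {
      members <- groups[[k]]
      members[sample.int(length(members), 1L)]
    }, ""), collapse = "")
  }, "")
  gene_records(genes, seqs, nt_length = 3L * (lens + 1L),
               pathways = as.list(unname(assignments)))
}

#' Generate a complete synthetic bundle
#'
#' Two organisms (query and training) are generated from the same pathway
#' structure — shared clades, coherence and group distributions — but with
#' independent gene-level draws, mirroring cross-organism training without
#' leaking identical sequences. Optionally writes the bundle to disk in
#' exactly the formats the I/O layer reads (FASTA, BLAST-tabular-shaped
#' TSV, membership TSV, subject-map TSV) plus a JSON manifest recording
#' the configuration.
#'
#' @param config A [synth_config()]; `config$seed` fixes everything.
#' @param dir Optional output directory.
#' @return A bundle: list with `query` and `training` (each holding
#'   `records`, `hits`, `presence`, `assignments`), `pathway_presence`,
#'   `coherence`, `group_probs` and `config`.
#' @export
generate_bundle <- function(config = synth_config(), dir = NULL) {
  bundle <- withr::with_seed(config$seed, {
    st <- .pathway_structure(config)
    make_org <- function(prefix) {
      pres <- generate_presence(config, prefix = prefix, structure_ = st)
      hits <- generate_hit_table(pres$gene_presence, config)
      records <- generate_sequences(pres$assignments, config,
                                    pres$group_probs)
      list(records = records, hits = hits,
           presence = pres$gene_presence, assignments = pres$assignments)
    }
    list(query = make_org("Q"), training = make_org("T"),
         pathway_presence = st$clades, coherence = st$coherence,
         group_probs = st$group_probs, config = config)
  })
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

# 12-column outfmt-6-shaped rows; subject ids "<org>|orfNNNN" so the
# subject map is recoverable, plus qseqid == sseqid self rows.
.write_hits_tsv <- function(hits, path) {
  sc <- hits$scores
  subj <- sprintf("%s|orf%04d", sc$organism, seq_len(nrow(sc)))
  filler <- function(n) cbind(pident = rep("90.0", n), length = "100",
                              mismatch = "5", gapopen = "0", qstart = "1",
                              qend = "100", sstart = "1", send = "100",
                              evalue = "1e-30")
  body <- cbind(q = sc$gene_id, s = subj, filler(nrow(sc)),
                bit = formatC(sc$score, digits = 17, format = "g"))
  selfs <- cbind(q = names(hits$self_scores), s = names(hits$self_scores),
                 filler(length(hits$self_scores)),
                 bit = formatC(hits$self_scores, digits = 17, format = "g"))
  utils::write.table(rbind(body, selfs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  data.frame(subject = subj, organism = sc$organism)
}

#' Write a bundle to disk
#' @param bundle A bundle from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  for (org in c("query", "training")) {
    d <- file.path(dir, org)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    part <- bundle[[org]]
    write_fasta(part$records, file.path(d, "proteins.fasta"))
    smap <- .write_hits_tsv(part$hits, file.path(d, "hits.tsv"))
    utils::write.table(smap, file.path(d, "subject_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    mem <- data.frame(gene = rep(part$records$gene_id,
                                 lengths(part$records$pathways)),
                      pathway = unlist(part$records$pathways))
    utils::write.table(mem, file.path(d, "membership.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(format = "pplink-bundle", version = 1L,
                   config = unclass(bundle$config),
                   organisms = c("query", "training"),
                   files = c("proteins.fasta", "hits.tsv",
                             "subject_map.tsv", "membership.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a bundle written by [write_bundle()]
#'
#' Re-reads every file through the package's own parsers ([read_fasta()],
#' [read_blast_tabular()], [read_pathway_membership()]); `nt_length` is
#' reconstructed as `3 * (protein length + 1)`, which is exactly what the
#' generator emits.
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return A bundle (without the generator-internal presence matrices).
#' @export
load_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "pplink-bundle"))
    stop_pplink("%s does not contain a pplink bundle", dir)
  read_org <- function(org) {
    d <- file.path(dir, org)
    records <- read_fasta(file.path(d, "proteins.fasta"))
    records$nt_length <- 3L * (nchar(records$protein_seq) + 1L)
    records <- attach_pathways(
      records, read_pathway_membership(file.path(d, "membership.tsv")))
    smap <- read_subject_map(file.path(d, "subject_map.tsv"))
    hits <- read_blast_tabular(file.path(d, "hits.tsv"), smap)
    list(records = records, hits = hits)
  }
  cfg <- do.call(synth_config, as.list(manifest$config))
  list(query = read_org("query"), training = read_org("training"),
       config = cfg)
}
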