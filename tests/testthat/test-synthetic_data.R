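test_that("presence generation: clade inheritance, noise, determinism", {
  cfg <- tiny_config(seed = 83L)

  # noiseless: every gene row equals its pathway's clade row
  cfg0 <- tiny_config(seed = 83L, presence_noise = 0)
  pres <- withr::with_seed(cfg0$seed, generate_presence(cfg0))
  for (g in rownames(pres$gene_presence)) {
    expect_identical(unname(pres$gene_presence[g, ]),
                     unname(pres$pathway_presence[pres$assignments[[g]], ]))
  }

  # clade_fraction = 1 -> all-present matrix
  cfg1 <- tiny_config(seed = 83L, clade_fraction = 1, presence_noise = 0)
  pres1 <- withr::with_seed(cfg1$seed, generate_presence(cfg1))
  expect_true(all(pres1$gene_presence))

  # fixed seed -> identical matrices; structure dimensions are right
  a <- withr::with_seed(cfg$seed, generate_presence(cfg))
  b <- withr::with_seed(cfg$seed, generate_presence(cfg))
  expect_identical(a$gene_presence, b$gene_presence)
  expect_equal(dim(a$pathway_presence),
               c(cfg$n_pathways, cfg$n_reference_organisms))
  expect_equal(nrow(a$gene_presence),
               cfg$n_pathways * cfg$genes_per_pathway)

  # disjoint mode partitions the organisms among pathways
  cfgd <- tiny_config(seed = 83L, disjoint_clades = TRUE)
  presd <- withr::with_seed(cfgd$seed, generate_presence(cfgd))
  expect_true(all(colSums(presd$pathway_presence) == 1L))
})

test_that("hit tables respect the trim-rule support constraints", {
  cfg <- tiny_config(seed = 89L, subthreshold_rate = 0)
  out <- withr::with_seed(cfg$seed, {
    pres <- generate_presence(cfg)
    list(pres = pres, hits = generate_hit_table(pres$gene_presence, cfg))
  })
  hits <- out$hits
  pres <- out$pres$gene_presence
  expect_s3_class(hits, "hit_table")
  # with subthreshold_rate = 0 every entry comes from a present cell
  idx <- cbind(match(hits$scores$gene_id, rownames(pres)),
               match(hits$scores$organism, colnames(pres)))
  expect_true(all(pres[idx]))
  # every absent cell scores 0 (is simply missing from the table)
  expect_equal(nrow(hits$scores), sum(pres))
  # present-cell scores all survive the trim: strictly above 50
  expect_true(all(hits$scores$score > 50))
  # R-values stay in (0, 1]
  r <- hits$scores$score / hits$self_scores[hits$scores$gene_id]
  expect_true(all(r > 0 & r <= 1))

  # spurious scores never survive the trim
  cfg2 <- tiny_config(seed = 89L, subthreshold_rate = 0.5)
  hits2 <- withr::with_seed(cfg2$seed, {
    pres2 <- generate_presence(cfg2)
    generate_hit_table(pres2$gene_presence, cfg2)
  })
  spurious <- hits2$scores$score < 50
  expect_gt(sum(spurious), 0)
  expect_true(all(trim_score(hits2$scores$score[spurious]) == 0))
})

test_that("generated sequences are proteinogenic, length-bounded and group-biased", {
  cfg <- tiny_config(seed = 97L, group_bias_strength = 0.05)
  recs <- withr::with_seed(cfg$seed, {
    pres <- generate_presence(cfg)
    generate_sequences(pres$assignments, cfg, pres$group_probs)
  })
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", recs$protein_seq)))
  lens <- nchar(recs$protein_seq)
  expect_true(all(lens >= cfg$seq_length_range[1] &
                    lens <= cfg$seq_length_range[2]))
  expect_equal(recs$nt_length, 3L * (lens + 1L))
  expect_identical(filter_genes(recs)$gene_id, recs$gene_id)  # all survive

  # strong concentration: same-pathway group compositions are close,
  # cross-pathway compositions differ
  comp <- t(vapply(recs$protein_seq, function(s) {
    tabulate(group_of(strsplit(s, "")[[1]]), 7) / nchar(s)
  }, numeric(7)))
  pw <- unlist(recs$pathways)
  within <- sapply(split(seq_len(nrow(comp)), pw), function(ix)
    mean(dist(comp[ix, ])))
  expect_lt(mean(within), mean(dist(comp[!duplicated(pw), ])))
})

test_that("bundles are seed-reproducible, seed-sensitive and byte-stable on disk", {
  cfg <- tiny_config(seed = 101L)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$query$records, b2$query$records)
  expect_identical(b1$query$hits$scores, b2$query$hits$scores)
  expect_identical(b1$training$records, b2$training$records)

  b3 <- generate_bundle(tiny_config(seed = 102L))
  expect_false(identical(b1$query$hits$scores, b3$query$hits$scores))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  f1 <- file.path(d1, "query", "proteins.fasta")
  f2 <- file.path(d2, "query", "proteins.fasta")
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
})

test_that("query and training organisms share pathway structure but not genes", {
  b <- generate_bundle(tiny_config(seed = 103L))
  expect_length(intersect(b$query$records$gene_id,
                          b$training$records$gene_id), 0L)
  expect_setequal(unique(unlist(b$query$records$pathways)),
                  unique(unlist(b$training$records$pathways)))
  expect_false(any(b$query$records$protein_seq %in%
                     b$training$records$protein_seq))
})

test_that("written bundles reload end-to-end through the package's own parsers", {
  b <- generate_bundle(tiny_config(seed = 107L))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- load_bundle(dir)

  expect_equal(back$query$records$gene_id, b$query$records$gene_id)
  expect_equal(back$query$records$protein_seq, b$query$records$protein_seq)
  expect_equal(back$query$records$nt_length, b$query$records$nt_length)
  expect_equal(lapply(back$query$records$pathways, sort),
               lapply(b$query$records$pathways, sort))
  expect_equal(back$config$seed, b$config$seed)

  # hit tables survive the TSV round trip to write precision
  o1 <- with(b$query$hits$scores, order(gene_id, organism))
  o2 <- with(back$query$hits$scores, order(gene_id, organism))
  expect_equal(back$query$hits$scores[o2, "score"],
               b$query$hits$scores[o1, "score"], tolerance = 1e-12)
  expect_equal(back$query$hits$self_scores[names(b$query$hits$self_scores)],
               b$query$hits$self_scores, tolerance = 1e-12)

  # and the reloaded bundle drives stage 1 identically
  s_mem <- run_pred_first(b)
  s_disk <- run_pred_first(back)
  expect_equal(s_disk, s_mem, tolerance = 1e-9)
})

test_that("positive-pair fraction matches the pathway combinatorics", {
  cfg <- tiny_config(seed = 109L)
  b <- generate_bundle(cfg)
  pairs <- derive_pair_labels(b$query$records)
  G <- cfg$n_pathways * cfg$genes_per_pathway
  expected <- cfg$n_pathways * choose(cfg$genes_per_pathway, 2) / choose(G, 2)
  expect_equal(mean(pairs$related), expected)  # exact: disjoint pathways
})

test_that("more presence noise degrades stage-1 ranking, in expectation over seeds", {
  prec_at <- function(noise, seed) {
    b <- generate_bundle(tiny_config(seed = seed, presence_noise = noise))
    ranked <- run_pred_first(b)
    precision_at_k(ranked, min(50L, nrow(ranked)))
  }
  seeds <- 201:220
  lo <- vapply(seeds, function(s) prec_at(0.02, s), numeric(1))
  hi <- vapply(seeds, function(s) prec_at(0.30, s), numeric(1))
  expect_gt(mean(lo), mean(hi))
})
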