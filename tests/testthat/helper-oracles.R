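# Independent oracles and small fixtures shared across tests. The oracles
# are deliberately naive (plain loops, no shared code with the package) so
# they can arbitrate the vectorized implementations.

# Brute-force stage 1: per-pair loops over profile vectors.
oracle_stage_one <- function(values, pairs, nz, sim_threshold) {
  out <- pairs
  out$similarity <- NA_real_
  out$passed_nz <- FALSE
  out$passed_similarity <- FALSE
  for (r in seq_len(nrow(pairs))) {
    p <- values[pairs$gene_a[r], ]
    q <- values[pairs$gene_b[r], ]
    cnt_p <- 0; cnt_q <- 0
    for (v in p) if (v != 0) cnt_p <- cnt_p + 1
    for (v in q) if (v != 0) cnt_q <- cnt_q + 1
    if (cnt_p >= nz && cnt_q >= nz) {
      out$passed_nz[r] <- TRUE
      s <- 0
      for (b in seq_along(p)) s <- s + p[b] * q[b]
      out$similarity[r] <- s
      out$passed_similarity[r] <- s > sim_threshold
    }
  }
  out
}

# Double-loop Gaussian KDE with externally supplied per-sample bandwidths.
oracle_kde <- function(train, sigma, v) {
  m <- ncol(train)
  total <- 0
  for (i in seq_len(nrow(train))) {
    d2 <- sum((v - train[i, ])^2)
    total <- total + (2 * pi)^(-m / 2) * sigma[i]^(-m) *
      exp(-d2 / (2 * sigma[i]^2))
  }
  total / nrow(train)
}

# Brute-force recall-precision AUC: explicit curve points + trapezoids.
oracle_auc <- function(labels, r, P = sum(labels)) {
  xs <- 0; ys <- NULL
  tp <- 0
  for (k in seq_along(labels)) {
    if (labels[k]) {
      tp <- tp + 1
      xs <- c(xs, tp / P)
      ys <- c(ys, tp / k)
    }
  }
  if (is.null(ys)) return(0)
  ys <- c(ys[1], ys)
  if (r < max(xs)) {
    yr <- approx(xs, ys, xout = r)$y
    keep <- xs <= r
    xs <- c(xs[keep], r); ys <- c(ys[keep], yr)
  }
  area <- 0
  for (i in seq_len(length(xs) - 1))
    area <- area + (xs[i + 1] - xs[i]) * (ys[i] + ys[i + 1]) / 2
  area
}

# A tiny, fast bundle for unit tests (full default bundles are reserved for
# the end-to-end acceptance checks).
tiny_config <- function(seed = 7L, ...) {
  synth_config(n_pathways = 4L, genes_per_pathway = 6L,
               n_reference_organisms = 20L,
               seq_length_range = c(60L, 120L), seed = seed, ...)
}

random_records <- function(n, len = 30L, seed = 1L) {
  withr::with_seed(seed, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    gene_records(sprintf("g%03d", seq_len(n)),
                 vapply(seq_len(n), function(i)
                   paste(sample(aas, len, replace = TRUE), collapse = ""),
                   ""))
  })
}
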