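# Pipeline orchestration and evaluation.
#
# Three experimental protocols over a data bundle (query organism +
# training organism):
#   Pred_both  — stage-1 survivors re-ranked by the RVKDE score,
#   Pred_1st   — stage-1 survivors ranked by profile similarity itself,
#   Pred_2nd   — the RVKDE alone, on random nz-passing samples whose class
#                composition matches the stage-1 survivors (averaged over
#                repeats).
# Metrics: precision at k, AUC in the recall-precision plane up to a target
# recall, and the adjusted AUC (ratio to a perfect predictor).

# Deterministic ranking: descending score, ties by pair id (C locale).
rank_predictions <- function(df) {
  df[radix_order(-df$score, df$gene_a, df$gene_b), , drop = FALSE]
}

#' Prepare normalized query profiles from a bundle
#' @param bundle A data bundle (see [generate_bundle()] / [load_bundle()]).
#' @return A column-normalized [profile_matrix()] over the filtered query
#'   genes.
#' @export
build_query_profiles <- function(bundle) {
  recs <- filter_genes(bundle$query$records)
  normalize_columns(build_profile_matrix(bundle$query$hits,
                                         genes = radix_sort(recs$gene_id)))
}

#' Train the stage-2 RVKDE on the training organism
#'
#' Labels all pairs of the (filtered) training-organism genes by pathway
#' co-membership, encodes them as 686-dimensional conjoint-triad vectors
#' and fits the two class densities.
#'
#' @param bundle A data bundle.
#' @param params An [rvkde_params()].
#' @return A fitted [rvkde_fit()] model.
#' @export
train_linkage_model <- function(bundle, params = pair_rvkde_params()) {
  recs <- filter_genes(bundle$training$records)
  pairs <- derive_pair_labels(recs)
  X <- pair_features(recs, pairs)
  rvkde_fit(X[pairs$related, , drop = FALSE],
            X[!pairs$related, , drop = FALSE], params)
}

.stage_one_for_bundle <- function(bundle, nz, sim_threshold) {
  recs <- filter_genes(bundle$query$records)
  pm <- build_query_profiles(bundle)
  pairs <- derive_pair_labels(recs)
  list(records = recs,
       s1 = stage_one(pm, pairs, nz = nz, sim_threshold = sim_threshold))
}

#' Run the full two-stage predictor (Pred_both)
#'
#' Stage-1 survivors (non-zero filter, then similarity strictly above the
#' threshold) are scored by the trained RVKDE and ranked by score; pairs
#' filtered out at stage 1 are absent from the output (no prediction).
#'
#' @param bundle A data bundle.
#' @param nz Non-zero filter threshold (default 1: only all-zero profiles
#'   are rejected).
#' @param sim_threshold Similarity threshold (strict; default 0).
#' @param params RVKDE parameters used when `model` is not supplied.
#' @param model Optional pre-trained [rvkde_fit()] model (reuse across
#'   protocols to avoid refitting).
#' @return Ranked data frame `gene_a`, `gene_b`, `score`, `related`
#'   (descending score, ties by pair id).
#' @export
run_pred_both <- function(bundle, nz = 1L, sim_threshold = 0,
                          params = pair_rvkde_params(), model = NULL) {
  st <- .stage_one_for_bundle(bundle, nz, sim_threshold)
  surv <- st$s1[st$s1$passed_similarity, , drop = FALSE]
  model <- model %||% train_linkage_model(bundle, params)
  if (nrow(surv) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), related = logical(0)))
  X <- pair_features(st$records, surv)
  out <- data.frame(gene_a = surv$gene_a, gene_b = surv$gene_b,
                    score = predict(model, X, type = "score"),
                    related = surv$related)
  rank_predictions(out)
}

#' Run stage 1 as an individual predictor (Pred_1st)
#'
#' Identical survivor set to [run_pred_both()], but ranked by the profile
#' similarity itself.
#'
#' @inheritParams run_pred_both
#' @return Ranked data frame as in [run_pred_both()] (`score` is the
#'   similarity).
#' @export
run_pred_first <- function(bundle, nz = 1L, sim_threshold = 0) {
  st <- .stage_one_for_bundle(bundle, nz, sim_threshold)
  surv <- st$s1[st$s1$passed_similarity, , drop = FALSE]
  out <- data.frame(gene_a = surv$gene_a, gene_b = surv$gene_b,
                    score = surv$similarity, related = surv$related)
  rank_predictions(out)
}

#' Run stage 2 as an individual predictor (Pred_2nd)
#'
#' Per repeat, a seeded stratified random sample is drawn from the pairs
#' that pass the non-zero filter, with positive and negative counts matched
#' to the stage-1 survivors; the sample is scored by the RVKDE and ranked,
#' and the precision-at-k curves are averaged pointwise over repeats.
#'
#' @inheritParams run_pred_both
#' @param repeats Number of random samples to average (default 10).
#' @param seed Integer seed for the sampling.
#' @return Data frame `k`, `precision` (the averaged curve), with the
#'   per-repeat precision matrix in `attr(, "per_repeat")` and the matched
#'   quota in `attr(, "quota")`.
#' @export
run_pred_second <- function(bundle, nz = 1L, repeats = 10L, seed = 1L,
                            sim_threshold = 0, params = pair_rvkde_params(),
                            model = NULL) {
  st <- .stage_one_for_bundle(bundle, nz, sim_threshold)
  s1 <- st$s1
  quota_pos <- sum(s1$passed_similarity & s1$related)
  quota_neg <- sum(s1$passed_similarity & !s1$related)
  eligible <- s1[s1$passed_nz, , drop = FALSE]
  pos_idx <- which(eligible$related)
  neg_idx <- which(!eligible$related)
  if (quota_pos > length(pos_idx) || quota_neg > length(neg_idx))
    stop_pplink("quota (%d pos, %d neg) exceeds nz-passing pairs (%d, %d)",
                quota_pos, quota_neg, length(pos_idx), length(neg_idx))
  n_k <- quota_pos + quota_neg
  if (n_k == 0L)
    return(structure(data.frame(k = integer(0), precision = numeric(0)),
                     quota = c(pos = 0L, neg = 0L)))

  model <- model %||% train_linkage_model(bundle, params)
  # score every eligible pair once; repeats only re-sample rows
  scores <- predict(model, pair_features(st$records, eligible),
                    type = "score")

  per_repeat <- withr::with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      take <- c(pos_idx[sample.int(length(pos_idx), quota_pos)],
                neg_idx[sample.int(length(neg_idx), quota_neg)])
      ranked <- rank_predictions(
        data.frame(gene_a = eligible$gene_a[take],
                   gene_b = eligible$gene_b[take],
                   score = scores[take], related = eligible$related[take]))
      cumsum(ranked$related) / seq_len(n_k)
    }, numeric(n_k))
  })
  per_repeat <- matrix(per_repeat, nrow = n_k)
  structure(data.frame(k = seq_len(n_k),
                       precision = rowMeans(per_repeat)),
            per_repeat = per_repeat,
            quota = c(pos = quota_pos, neg = quota_neg))
}

#' Precision among the top k predictions
#'
#' @param ranked Ranked predictions ([run_pred_both()] output) or an
#'   averaged curve ([run_pred_second()] output).
#' @param k Rank cutoff, `1 <= k <= nrow(ranked)`.
#' @return Fraction of true related pairs among the top `k` (or the
#'   averaged precision at `k` for a curve).
#' @export
precision_at_k <- function(ranked, k) {
  if (k < 1L || k > nrow(ranked))
    stop_pplink("k = %d out of range 1..%d", k, nrow(ranked))
  if (!is.null(ranked$precision)) return(ranked$precision[ranked$k == k])
  mean(ranked$related[seq_len(k)])
}

#' Area under the recall-precision curve up to a target recall
#'
#' The curve is sampled at every rank where a positive is retrieved
#' (recall `i/P`, precision `i/rank`), anchored at recall 0 with the first
#' precision value, integrated by the trapezoid rule and linearly
#' interpolated to end exactly at `r`. A perfect ranking gives exactly `r`.
#'
#' @param ranked Ranked predictions with a logical `related` column.
#' @param r Target recall in (0, 1].
#' @param n_positives Recall denominator `P` (default: positives present in
#'   `ranked`; pass the study-wide positive count when the ranking covers
#'   only a filtered subset).
#' @return The AUC (0 if no positive is retrieved).
#' @export
auc_at_recall <- function(ranked, r, n_positives = sum(ranked$related)) {
  if (r <= 0 || r > 1) stop_pplink("target recall must be in (0, 1]")
  if (n_positives < 1) stop_pplink("no positives: recall undefined")
  pos_rank <- which(ranked$related)
  if (length(pos_rank) == 0L) return(0)
  rec <- seq_along(pos_rank) / n_positives
  prec <- seq_along(pos_rank) / pos_rank
  x <- c(0, rec)
  y <- c(prec[1L], prec)
  if (r < max(x)) {
    keep <- x <= r
    y_r <- stats::approx(x, y, xout = r)$y
    x <- c(x[keep], r)
    y <- c(y[keep], y_r)
  }
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Adjusted AUC: ratio to a perfect predictor
#'
#' A perfect predictor has precision 1 up to any recall, so its AUC at
#' recall `r` is `r`; the adjusted AUC is `auc / r`.
#'
#' @param auc AUC value from [auc_at_recall()].
#' @param r The recall it was computed at (> 0).
#' @return `auc / r` (1 for a perfect ranking).
#' @export
adjusted_auc <- function(auc, r) {
  if (r <= 0) stop_pplink("recall must be > 0")
  auc / r
}

#' Write ranked predictions to TSV
#' @param ranked Ranked predictions data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
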