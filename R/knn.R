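# Training-free zero-shot k-NN classifier.
#
# For a test phosphosite: find the k most similar training (site, kinase)
# pairs in phosphosite embedding space, majority-vote the light-kinase label
# (falling back to the nearest neighbour's label when no label strictly wins
# the plurality), then score every dark kinase by the cosine similarity of
# its embedding to the predicted light kinase's embedding.

#' k-NN classifier configuration
#'
#' @param k neighbourhood size (>= 1; odd values recommended).
#' @param site_metric similarity in phosphosite space: `"cosine"` (default)
#'   or `"euclidean"` (negated distance).
#' @return a `knn_config` list.
#' @export
knn_config <- function(k = 3L, site_metric = c("cosine", "euclidean")) {
  site_metric <- match.arg(site_metric)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  structure(list(k = k, site_metric = site_metric), class = "knn_config")
}

row_normalize <- function(m, what = "vector") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    abort(sprintf("zero-norm %s encountered; cosine similarity undefined.", what))
  }
  m / nrm
}

# similarity of one query row against all rows of M (both unnormalized)
site_similarities <- function(query, M, metric) {
  if (metric == "cosine") {
    q <- query / sqrt(sum(query^2))
    if (!all(is.finite(q))) abort("zero-norm site vector; cosine undefined.")
    as.numeric(row_normalize(M, "training site vector") %*% q)
  } else {
    -sqrt(colSums((t(M) - query)^2))
  }
}

# vote over the k nearest training pairs; returns the predicted light kinase
vote_light_kinase <- function(sims, train_labels, k) {
  ord <- order(-sims)                    # stable: distance ties keep pair order
  top <- ord[seq_len(k)]
  labs <- train_labels[top]
  cnt <- table(labs)
  best <- names(cnt)[cnt == max(cnt)]
  if (length(best) == 1L) best else labs[1L]   # no strict plurality -> 1-NN label
}

#' Zero-shot k-NN scores for a single phosphosite
#'
#' @param site_vec embedding vector of the test phosphosite.
#' @param train_pairs training association pairs (`site_id`, `kinase_id`);
#'   each pair is one neighbour, so a multilabel site contributes one
#'   neighbour per kinase label.
#' @param site_store [embedding_store()] covering the training sites.
#' @param kinase_store [embedding_store()] covering light and dark kinases.
#' @param dark_ids the zero-shot (dark) kinases to score; must be disjoint
#'   from the training kinases.
#' @param config a [knn_config()].
#' @return named numeric vector of cosine scores over `dark_ids`, in
#'   `[-1, 1]`.
#' @export
knn_scores <- function(site_vec, train_pairs, site_store, kinase_store,
                       dark_ids, config = knn_config()) {
  if (inherits(train_pairs, "phospho_dataset")) train_pairs <- train_pairs$pairs
  n_pairs <- nrow(train_pairs)
  if (config$k > n_pairs) {
    abort(sprintf("k (%d) exceeds the number of training pairs (%d).",
                  config$k, n_pairs))
  }
  overlap <- intersect(dark_ids, unique(train_pairs$kinase_id))
  if (length(overlap)) {
    abort(sprintf("dark kinases overlap the training kinases: %s",
                  paste(head(overlap, 5), collapse = ", ")))
  }
  M <- store_vectors(site_store, train_pairs$site_id)
  sims <- site_similarities(site_vec, M, config$site_metric)
  light <- vote_light_kinase(sims, train_pairs$kinase_id, config$k)
  lv <- as.numeric(store_vectors(kinase_store, light))
  lv <- lv / sqrt(sum(lv^2))
  D <- row_normalize(store_vectors(kinase_store, dark_ids), "kinase embedding")
  setNames(as.numeric(D %*% lv), dark_ids)
}

#' Batched zero-shot k-NN prediction
#'
#' Applies [knn_scores()] to every test site, sharing the similarity
#' computation. Deterministic given its inputs.
#'
#' @param test_site_ids identifiers of the test phosphosites (resolved in
#'   `site_store`).
#' @inheritParams knn_scores
#' @return numeric score matrix, `length(test_site_ids)` x
#'   `length(dark_ids)`, with dimnames.
#' @export
knn_predict_all <- function(test_site_ids, train_pairs, site_store,
                            kinase_store, dark_ids, config = knn_config()) {
  if (inherits(train_pairs, "phospho_dataset")) train_pairs <- train_pairs$pairs
  n_pairs <- nrow(train_pairs)
  if (config$k > n_pairs) {
    abort(sprintf("k (%d) exceeds the number of training pairs (%d).",
                  config$k, n_pairs))
  }
  overlap <- intersect(dark_ids, unique(train_pairs$kinase_id))
  if (length(overlap)) {
    abort(sprintf("dark kinases overlap the training kinases: %s",
                  paste(head(overlap, 5), collapse = ", ")))
  }
  M <- store_vectors(site_store, train_pairs$site_id)
  Q <- store_vectors(site_store, test_site_ids)
  if (config$site_metric == "cosine") {
    S <- row_normalize(Q, "test site vector") %*%
      t(row_normalize(M, "training site vector"))
  } else {
    sq <- outer(rowSums(Q^2), rep(1, n_pairs)) +
      outer(rep(1, nrow(Q)), rowSums(M^2)) - 2 * Q %*% t(M)
    S <- -sqrt(pmax(sq, 0))
  }
  lights <- vapply(seq_len(nrow(S)), function(i) {
    vote_light_kinase(S[i, ], train_pairs$kinase_id, config$k)
  }, character(1))
  LK <- row_normalize(store_vectors(kinase_store, lights), "kinase embedding")
  D <- row_normalize(store_vectors(kinase_store, dark_ids), "kinase embedding")
  out <- LK %*% t(D)
  dimnames(out) <- list(test_site_ids, dark_ids)
  out
}

#' Select k by validation macro AP
#'
#' @param reports tibble with columns `k` and `macro_ap` (one row per
#'   candidate), e.g. assembled from validation [evaluate_scores()] runs.
#' @return the `k` with maximal validation macro AP; ties resolve to the
#'   smallest k.
#' @export
select_k <- function(reports) {
  stopifnot(all(c("k", "macro_ap") %in% names(reports)), nrow(reports) >= 1L)
  reports <- arrange(reports, .data$k)
  reports$k[which.max(reports$macro_ap)]
}
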