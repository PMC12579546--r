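# Multilabel zero-shot ranking metrics.
#
# Scores live in a sites x kinases matrix (dimnames required). Ground truth
# is the association pair list. AP is non-interpolated: the mean, over the
# positives, of precision at each positive's rank, with descending stable
# sort (ties keep input order).

#' Non-interpolated average precision
#'
#' Sorts items by decreasing score (stable: ties keep input order) and
#' averages the precision at each positive's rank. `-Inf` scores are legal
#' and rank below all finite scores.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector of the same length; `TRUE` marks a
#'   positive.
#' @return AP in `[0, 1]`, or `NA_real_` when there is no positive
#'   (undefined; callers exclude such classes).
#' @export
#' @examples
#' average_precision(c(3, 2, 1), c(TRUE, FALSE, FALSE))  # 1
#' average_precision(c(3, 2, 1), c(FALSE, FALSE, TRUE))  # 1/3
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch.")
  if (!any(labels)) return(NA_real_)
  ord <- order(-scores)            # radix sort, stable for ties
  lab <- labels[ord]
  ranks <- which(lab)
  prec <- cumsum(lab)[ranks] / ranks
  mean(prec)
}

# pairs -> logical label matrix aligned with a score matrix
label_matrix <- function(score_matrix, pairs) {
  if (inherits(pairs, "phospho_dataset")) pairs <- pairs$pairs
  sites <- rownames(score_matrix)
  kin <- colnames(score_matrix)
  if (is.null(sites) || is.null(kin)) {
    abort("score matrix must carry site rownames and kinase colnames.")
  }
  L <- matrix(FALSE, nrow(score_matrix), ncol(score_matrix),
              dimnames = dimnames(score_matrix))
  keep <- pairs$site_id %in% sites & pairs$kinase_id %in% kin
  p <- pairs[keep, ]
  L[cbind(match(p$site_id, sites), match(p$kinase_id, kin))] <- TRUE
  L
}

#' Macro average precision over kinase classes
#'
#' For each kinase (column), ranks all test sites by that kinase's scores;
#' positives are the sites associated with the kinase. The macro AP is the
#' unweighted mean over kinases. Kinases with no positive site are excluded
#' with a warning.
#'
#' @param score_matrix numeric matrix, sites x kinases, with dimnames.
#' @param pairs association pair tibble (`site_id`, `kinase_id`) or a
#'   `phospho_dataset`.
#' @return list with `macro_ap` (scalar) and `per_kinase` (tibble
#'   `kinase_id`, `ap`, `n_positive`).
#' @export
macro_ap <- function(score_matrix, pairs) {
  L <- label_matrix(score_matrix, pairs)
  ap <- vapply(seq_len(ncol(score_matrix)), function(j) {
    average_precision(score_matrix[, j], L[, j])
  }, numeric(1))
  per <- tibble(kinase_id = colnames(score_matrix), ap = ap,
                n_positive = colSums(L))
  if (anyNA(ap)) {
    warn(sprintf("excluding %d kinase(s) with no positive site from macro AP.",
                 sum(is.na(ap))))
  }
  list(macro_ap = mean(ap, na.rm = TRUE), per_kinase = per)
}

#' Phosphosite-level average precision
#'
#' For each site (row), ranks the evaluated kinases by score; positives are
#' the site's true kinases. Returns the mean over sites; sites with no true
#' kinase among the evaluated set are excluded with a warning.
#'
#' @inheritParams macro_ap
#' @return list with `phosphosite_ap` and `per_site` tibble.
#' @export
phosphosite_ap <- function(score_matrix, pairs) {
  L <- label_matrix(score_matrix, pairs)
  ap <- vapply(seq_len(nrow(score_matrix)), function(i) {
    average_precision(score_matrix[i, ], L[i, ])
  }, numeric(1))
  per <- tibble(site_id = rownames(score_matrix), ap = ap,
                n_positive = rowSums(L))
  if (anyNA(ap)) {
    warn(sprintf("excluding %d site(s) with no evaluable positive from phosphosite AP.",
                 sum(is.na(ap))))
  }
  list(phosphosite_ap = mean(ap, na.rm = TRUE), per_site = per)
}

#' Macro AP after aggregating kinases into families or groups
#'
#' Kinase columns are collapsed into class columns via `agg` (`"max"`:
#' a site's class score is the best score among member kinases; `"sum"`
#' available as an alternative). A site is positive for a class iff any of
#' its true kinases maps to the class. Macro AP is then computed over
#' classes.
#'
#' @inheritParams macro_ap
#' @param mapping named character vector kinase_id -> class label, total over
#'   the evaluated kinases.
#' @param agg aggregation operator, `"max"` (default) or `"sum"`.
#' @return list with `aggregated_ap` and `per_class` tibble.
#' @export
aggregated_ap <- function(score_matrix, pairs, mapping, agg = c("max", "sum")) {
  agg <- match.arg(agg)
  kin <- colnames(score_matrix)
  miss <- setdiff(kin, names(mapping))
  if (length(miss)) {
    abort(sprintf("mapping missing for kinase(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  cls <- mapping[kin]
  classes <- unique(unname(cls))
  agg_fun <- if (agg == "max") {
    function(m) apply(m, 1, max)
  } else {
    function(m) rowSums(m)
  }
  S <- vapply(classes, function(cl) {
    agg_fun(score_matrix[, cls == cl, drop = FALSE])
  }, numeric(nrow(score_matrix)))
  S <- matrix(S, nrow = nrow(score_matrix),
              dimnames = list(rownames(score_matrix), classes))
  if (inherits(pairs, "phospho_dataset")) pairs <- pairs$pairs
  cls_pairs <- pairs |>
    filter(.data$kinase_id %in% kin) |>
    mutate(kinase_id = unname(mapping[.data$kinase_id])) |>
    distinct()
  res <- macro_ap(S, cls_pairs)
  list(aggregated_ap = res$macro_ap,
       per_class = rename(res$per_kinase, class = "kinase_id"))
}

#' Macro AP restricted to the true kinase group(s)
#'
#' Simulates perfect group-level prediction: for every site, the scores of
#' kinases outside the union of its true kinases' groups are set to `-Inf`
#' (they rank strictly below all finite scores), then the ordinary macro AP
#' over kinases is computed.
#'
#' @inheritParams macro_ap
#' @param groups named character vector kinase_id -> group, total over the
#'   evaluated kinases.
#' @return list with `masked_group_ap` and `per_kinase` tibble.
#' @export
masked_group_ap <- function(score_matrix, pairs, groups) {
  kin <- colnames(score_matrix)
  miss <- setdiff(kin, names(groups))
  if (length(miss)) {
    abort(sprintf("group unknown for kinase(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  L <- label_matrix(score_matrix, pairs)
  g <- groups[kin]
  masked <- score_matrix
  for (i in seq_len(nrow(masked))) {
    allowed <- unique(g[L[i, ]])
    masked[i, !(g %in% allowed)] <- -Inf
  }
  res <- macro_ap(masked, pairs)
  list(masked_group_ap = res$macro_ap, per_kinase = res$per_kinase)
}

#' hit@k accuracy
#'
#' Fraction of sites whose top-k ranked kinases (descending score, stable
#' ties) contain at least one true kinase.
#'
#' @inheritParams macro_ap
#' @param k integer vector of cutoffs.
#' @return tibble with `k` and `hit_rate`.
#' @export
hit_at_k <- function(score_matrix, pairs, k = c(1L, 3L, 5L, 10L)) {
  L <- label_matrix(score_matrix, pairs)
  k <- sort(unique(as.integer(k)))
  if (any(k < 1L)) abort("`k` must be >= 1.")
  hits <- matrix(FALSE, nrow(score_matrix), length(k))
  for (i in seq_len(nrow(score_matrix))) {
    ord <- order(-score_matrix[i, ])
    lab <- L[i, ord]
    hits[i, ] <- vapply(k, function(kk) any(lab[seq_len(min(kk, length(lab)))]),
                        logical(1))
  }
  tibble(k = k, hit_rate = colMeans(hits))
}

#' Monte-Carlo random-ranking baseline for macro AP
#'
#' Repeatedly assigns every site an independent uniform-random ranking of the
#' kinases, computes the macro AP, and averages over runs. This is the
#' reference level any informative classifier must beat.
#'
#' @param pairs association pair tibble restricted to the evaluated sites and
#'   kinases.
#' @param site_ids,kinase_ids the evaluated sites and kinases.
#' @param n_runs number of random rankings per site (default 1000).
#' @param seed RNG seed.
#' @return list with `mean_ap`, `sd_ap`, and the per-run vector `runs`.
#' @export
random_baseline_ap <- function(pairs, site_ids, kinase_ids,
                               n_runs = 1000L, seed = 1L) {
  if (n_runs < 1L) abort("`n_runs` must be >= 1.")
  n_s <- length(site_ids); n_k <- length(kinase_ids)
  runs <- local_seed(seed, {
    vapply(seq_len(n_runs), function(r) {
      S <- matrix(runif(n_s * n_k), n_s, n_k,
                  dimnames = list(site_ids, kinase_ids))
      suppressWarnings(macro_ap(S, pairs)$macro_ap)
    }, numeric(1))
  })
  list(mean_ap = mean(runs), sd_ap = if (n_runs > 1L) sd(runs) else NA_real_,
       runs = runs)
}

#' Read / write a score matrix as TSV
#'
#' Site rows x kinase columns, with a leading `site_id` column.
#'
#' @param path TSV path.
#' @return `read_score_matrix()` returns a numeric matrix with dimnames.
#' @export
read_score_matrix <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(site_id = "c", .default = "d"))
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb$site_id
  m
}

#' @rdname read_score_matrix
#' @param score_matrix numeric matrix with dimnames.
#' @export
write_score_matrix <- function(score_matrix, path) {
  tb <- dplyr::bind_cols(tibble(site_id = rownames(score_matrix)),
                         as_tibble(score_matrix, .name_repair = "minimal"))
  readr::write_tsv(tb, path)
  invisible(path)
}
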