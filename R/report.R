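# EvalReport: one object bundling every ranking metric for a score matrix.

#' Evaluate a score matrix with the full metric suite
#'
#' Computes per-kinase and macro AP, phosphosite AP, family- and
#' group-aggregated AP, masked-group AP and hit@k for a sites x kinases
#' score matrix against an association pair list.
#'
#' @param score_matrix numeric matrix, sites x kinases, with dimnames.
#' @param pairs association pairs (`site_id`, `kinase_id`) or a
#'   `phospho_dataset`.
#' @param kinases kinase tibble (or `phospho_dataset`) supplying `family` and
#'   `group`; when `NULL`, family/group/masked metrics are skipped.
#' @param k cutoffs for hit@k.
#' @param agg aggregation operator for family/group AP (`"max"` or `"sum"`).
#' @return an `eval_report` object.
#' @export
evaluate_scores <- function(score_matrix, pairs, kinases = NULL,
                            k = c(1L, 3L, 5L, 10L), agg = "max") {
  if (inherits(pairs, "phospho_dataset")) {
    if (is.null(kinases)) kinases <- pairs$kinases
    pairs <- pairs$pairs
  }
  if (inherits(kinases, "phospho_dataset")) kinases <- kinases$kinases
  mac <- macro_ap(score_matrix, pairs)
  pho <- phosphosite_ap(score_matrix, pairs)
  hit <- hit_at_k(score_matrix, pairs, k = k)
  fam <- grp <- msk <- NULL
  if (!is.null(kinases)) {
    kin <- colnames(score_matrix)
    rows <- match(kin, kinases$kinase_id)
    if (anyNA(rows)) abort("score matrix kinases missing from kinase table.")
    fam_map <- setNames(kinases$family[rows], kin)
    grp_map <- setNames(kinases$group[rows], kin)
    fam <- aggregated_ap(score_matrix, pairs, fam_map, agg = agg)
    grp <- aggregated_ap(score_matrix, pairs, grp_map, agg = agg)
    msk <- masked_group_ap(score_matrix, pairs, grp_map)
  }
  structure(list(
    macro_ap = mac$macro_ap, per_kinase_ap = mac$per_kinase,
    phosphosite_ap = pho$phosphosite_ap, per_site_ap = pho$per_site,
    family_ap = if (is.null(fam)) NA_real_ else fam$aggregated_ap,
    group_ap = if (is.null(grp)) NA_real_ else grp$aggregated_ap,
    masked_group_ap = if (is.null(msk)) NA_real_ else msk$masked_group_ap,
    hit_at_k = hit,
    n_sites = nrow(score_matrix), n_kinases = ncol(score_matrix)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d sites x %d kinases\n", x$n_sites, x$n_kinases))
  cat(sprintf("  macro AP:        %.4f\n", x$macro_ap))
  cat(sprintf("  phosphosite AP:  %.4f\n", x$phosphosite_ap))
  if (!is.na(x$family_ap)) cat(sprintf("  family AP:       %.4f\n", x$family_ap))
  if (!is.na(x$group_ap)) cat(sprintf("  group AP:        %.4f\n", x$group_ap))
  if (!is.na(x$masked_group_ap)) {
    cat(sprintf("  masked-group AP: %.4f\n", x$masked_group_ap))
  }
  for (i in seq_len(nrow(x$hit_at_k))) {
    cat(sprintf("  hit@%-2d:          %.4f\n", x$hit_at_k$k[i], x$hit_at_k$hit_rate[i]))
  }
  invisible(x)
}

#' @describeIn evaluate_scores per-kinase AP tibble.
#' @param x an `eval_report`.
#' @param ... unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_kinase_ap

#' @describeIn evaluate_scores one-row tibble of the summary metrics.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  out <- tibble(macro_ap = x$macro_ap, phosphosite_ap = x$phosphosite_ap,
                family_ap = x$family_ap, group_ap = x$group_ap,
                masked_group_ap = x$masked_group_ap,
                n_sites = x$n_sites, n_kinases = x$n_kinases)
  for (i in seq_len(nrow(x$hit_at_k))) {
    out[[paste0("hit_at_", x$hit_at_k$k[i])]] <- x$hit_at_k$hit_rate[i]
  }
  out
}

#' @describeIn evaluate_scores bar chart of per-kinase AP, worst to best.
#' @param object an `eval_report`.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- object$per_kinase_ap |>
    filter(!is.na(.data$ap)) |>
    arrange(.data$ap) |>
    mutate(kinase_id = factor(.data$kinase_id, levels = .data$kinase_id))
  ggplot(d, aes(x = .data$kinase_id, y = .data$ap)) +
    geom_col() +
    labs(x = NULL, y = "average precision",
         title = sprintf("per-kinase AP (macro AP = %.3f)", object$macro_ap)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Serialize / load an evaluation report
#'
#' JSON for the summary plus per-kinase APs; a flat TSV of per-kinase APs is
#' written alongside when `tsv = TRUE`.
#'
#' @param report an `eval_report`.
#' @param path output `.json` path.
#' @param tsv also write `<path>.per_kinase.tsv`.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, tsv = TRUE) {
  obj <- list(
    macro_ap = report$macro_ap, phosphosite_ap = report$phosphosite_ap,
    family_ap = report$family_ap, group_ap = report$group_ap,
    masked_group_ap = report$masked_group_ap,
    hit_at_k = setNames(as.list(report$hit_at_k$hit_rate),
                        paste0("hit_at_", report$hit_at_k$k)),
    n_sites = report$n_sites, n_kinases = report$n_kinases,
    per_kinase_ap = setNames(as.list(report$per_kinase_ap$ap),
                             report$per_kinase_ap$kinase_id))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  if (tsv) {
    readr::write_tsv(report$per_kinase_ap, paste0(path, ".per_kinase.tsv"))
  }
  invisible(path)
}
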