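# Zero-shot benchmark split generation.
#
# Kinases (classes), not sites, are split: train/validation/test kinase sets
# are disjoint, every held-out kinase has enough association pairs for a
# stable AP estimate, high-identity kinases are co-assigned, and test kinases
# are drawn per kinase group so each group is represented where possible.
# A site may legitimately appear in several splits with different kinase
# labels; the zero-shot contract concerns the kinase sets only.

#' Split configuration
#'
#' @param test_min minimum association pairs for a kinase to be eligible for
#'   the test set (kinases below this are train-only). Default 15.
#' @param val_min minimum pairs for validation eligibility. Default 10.
#' @param identity_threshold pairwise-identity threshold above which kinases
#'   are co-assigned. Default 0.90.
#' @param target_fractions train/validation/test target fractions over
#'   association pairs; must sum to 1. Default `c(0.80, 0.10, 0.10)`.
#' @param seed integer seed controlling every random choice.
#' @param scoring alignment scoring, see [alignment_scoring()].
#' @return a `split_config` list.
#' @export
split_config <- function(test_min = 15L, val_min = 10L,
                         identity_threshold = 0.90,
                         target_fractions = c(0.80, 0.10, 0.10),
                         seed = 1L, scoring = alignment_scoring()) {
  if (abs(sum(target_fractions) - 1) > 1e-8) {
    abort("`target_fractions` must sum to 1.")
  }
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("`identity_threshold` must be in (0, 1].")
  }
  structure(list(test_min = as.integer(test_min), val_min = as.integer(val_min),
                 identity_threshold = identity_threshold,
                 target_fractions = target_fractions,
                 seed = as.integer(seed), scoring = scoring),
            class = "split_config")
}

# evaluate `code` under `seed` without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# One hold-out stage: choose a held kinase set from `pool` (character ids).
# Eligibility requires >= min_pairs associations; identity clusters restricted
# to the pool are co-assigned; multi-member eligible clusters are flipped
# wholly to the held side with probability p_flip; then a stratified per-group
# draw tops up until `target_pairs` is reached. Groups with >= 3 eligible
# kinases are always given at least one held kinase. Consumes RNG state.
hold_out_stage <- function(pool, counts, id_sub, threshold, min_pairs,
                           target_pairs, p_flip) {
  counts <- counts[match(pool, counts$kinase_id), ]
  eligible <- counts$kinase_id[counts$n_pairs >= min_pairs]
  if (!length(eligible)) return(character(0))

  cl <- cluster_by_identity(tibble(kinase_id = pool, domain_sequence = ""),
                            threshold = threshold, id_matrix = id_sub)
  members <- split(cl$kinase_id, cl$cluster)
  npairs <- setNames(counts$n_pairs, counts$kinase_id)
  grp <- setNames(counts$group, counts$kinase_id)

  held <- character(0)
  singles <- character(0)   # eligible singleton-cluster kinases, free to draw
  for (mem in members) {
    if (any(npairs[mem] < min_pairs)) next   # forced to train
    if (length(mem) > 1L) {
      if (runif(1) < p_flip) held <- c(held, mem)
    } else {
      singles <- c(singles, mem)
    }
  }
  held_pairs <- sum(npairs[held])

  # group order: descending eligible pair mass, ties by name for determinism
  gmass <- tapply(npairs[singles], grp[singles], sum)
  gsize <- table(grp[singles])
  groups <- names(sort(gmass, decreasing = TRUE))
  groups <- groups[order(-gmass[groups], groups)]

  cand <- split(singles, grp[singles])
  draw_one <- function(g) {
    pool_g <- cand[[g]]
    pick <- pool_g[sample.int(length(pool_g), 1L)]
    cand[[g]] <<- setdiff(pool_g, pick)
    held <<- c(held, pick)
    held_pairs <<- held_pairs + npairs[[pick]]
    pick
  }

  # guarantee pass: any group with >= 3 eligible candidates contributes one
  for (g in groups) {
    has_held <- any(grp[held] == g)
    if (!has_held && !is.na(gsize[g]) && gsize[g] >= 3L) draw_one(g)
  }
  # top-up rounds until the pair target is reached
  while (held_pairs < target_pairs) {
    open <- groups[vapply(groups, function(g) length(cand[[g]]) > 0L, logical(1))]
    if (!length(open)) break
    for (g in open) {
      if (held_pairs >= target_pairs) break
      draw_one(g)
    }
  }
  held
}

#' Generate a zero-shot benchmark split
#'
#' Partitions the kinases of a dataset into disjoint train/validation/test
#' sets and materializes the corresponding association pair lists. The
#' procedure: (1) kinases with fewer than `test_min` pairs are train-only;
#' (2) kinases are clustered at `identity_threshold` sequence identity;
#' clusters containing a train-only member are forced to train, remaining
#' multi-member clusters are flipped wholly to train or test; (3) test
#' kinases are drawn per kinase group (stratified, seeded) until the test
#' pair count reaches the target fraction; (4) the same procedure with
#' `val_min` picks validation kinases from the remaining train kinases;
#' (5) each split receives all pairs of its kinases.
#'
#' Deterministic given `dataset` and `config$seed`.
#'
#' @param dataset a [phospho_dataset()].
#' @param config a [split_config()].
#' @param id_matrix optional precomputed [identity_matrix()]; computed from
#'   the kinase table when `NULL`.
#' @return a `benchmark_split` object.
#' @export
make_split <- function(dataset, config = split_config(), id_matrix = NULL) {
  stopifnot(inherits(dataset, "phospho_dataset"))
  counts <- kinase_pair_counts(dataset)
  total <- nrow(dataset$pairs)
  if (!any(counts$n_pairs >= config$test_min)) {
    abort(sprintf(
      "infeasible split: no kinase has >= test_min (%d) association pairs, so no group can contribute a test kinase.",
      config$test_min))
  }
  if (is.null(id_matrix)) {
    id_matrix <- identity_matrix(dataset$kinases, config$scoring)
  }
  all_ids <- dataset$kinases$kinase_id
  fr <- config$target_fractions

  res <- local_seed(config$seed, {
    test_ids <- hold_out_stage(all_ids, counts, id_matrix,
                               config$identity_threshold, config$test_min,
                               target_pairs = fr[3] * total, p_flip = fr[3])
    remain <- setdiff(all_ids, test_ids)
    val_ids <- hold_out_stage(remain, counts,
                              id_matrix[remain, remain, drop = FALSE],
                              config$identity_threshold, config$val_min,
                              target_pairs = fr[2] * total,
                              p_flip = fr[2] / (fr[1] + fr[2]))
    list(test = test_ids, val = val_ids)
  })
  if (!length(res$test)) {
    abort("infeasible split: stratified draw produced an empty test kinase set.")
  }
  train_ids <- setdiff(all_ids, c(res$test, res$val))

  take <- function(ids) dataset$pairs[dataset$pairs$kinase_id %in% ids, ]
  structure(list(
    train_kinases = train_ids, val_kinases = sort(res$val),
    test_kinases = sort(res$test),
    train_pairs = take(train_ids), val_pairs = take(res$val),
    test_pairs = take(res$test),
    config = config, seed = config$seed),
    class = "benchmark_split")
}

#' @export
print.benchmark_split <- function(x, ...) {
  n <- vapply(list(x$train_pairs, x$val_pairs, x$test_pairs), nrow, integer(1))
  cat(sprintf(
    "<benchmark_split> seed %d\n  train: %d kinases / %d pairs\n  val:   %d kinases / %d pairs\n  test:  %d kinases / %d pairs\n",
    x$seed, length(x$train_kinases), n[1], length(x$val_kinases), n[2],
    length(x$test_kinases), n[3]))
  invisible(x)
}

#' @describeIn make_split tidy summary: one row per kinase with its split
#'   assignment and pair count.
#' @param x a `benchmark_split`.
#' @param ... unused.
#' @method tidy benchmark_split
#' @export
tidy.benchmark_split <- function(x, ...) {
  assign_tbl <- bind_rows(
    tibble(kinase_id = x$train_kinases, split = "train"),
    tibble(kinase_id = x$val_kinases, split = "validation"),
    tibble(kinase_id = x$test_kinases, split = "test"))
  pairs <- bind_rows(x$train_pairs, x$val_pairs, x$test_pairs)
  assign_tbl |>
    left_join(count(pairs, .data$kinase_id, name = "n_pairs"), by = "kinase_id") |>
    mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L))
}

#' @describeIn make_split one-row summary with kinase and pair counts and
#'   achieved pair fractions.
#' @method glance benchmark_split
#' @export
glance.benchmark_split <- function(x, ...) {
  n <- vapply(list(x$train_pairs, x$val_pairs, x$test_pairs), nrow, integer(1))
  tibble(n_train_kinases = length(x$train_kinases),
         n_val_kinases = length(x$val_kinases),
         n_test_kinases = length(x$test_kinases),
         n_train_pairs = n[1], n_val_pairs = n[2], n_test_pairs = n[3],
         frac_train = n[1] / sum(n), frac_val = n[2] / sum(n),
         frac_test = n[3] / sum(n), seed = x$seed)
}

#' Audit a benchmark split against the zero-shot contract
#'
#' Checks an arbitrary (possibly externally supplied) split against a
#' dataset: pairwise disjointness of the kinase sets, resolution of all
#' references, membership of every pair's kinase in its split, per-kinase
#' minimum pair counts for validation/test kinases, and absence of
#' cross-split kinase pairs at or above the identity threshold.
#'
#' @param dataset a [phospho_dataset()].
#' @param split a `benchmark_split` (or a list with the same fields).
#' @param config a [split_config()] supplying the thresholds.
#' @param id_matrix optional precomputed identity matrix.
#' @return tibble of violations with columns `rule`, `kinase_id`, `detail`;
#'   zero rows iff the split satisfies the contract.
#' @export
validate_split <- function(dataset, split, config = split_config(),
                           id_matrix = NULL) {
  stopifnot(inherits(dataset, "phospho_dataset"))
  v <- list()
  note <- function(rule, kin, detail) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, kinase_id = kin, detail = detail)
  }
  sets <- list(train = split$train_kinases, validation = split$val_kinases,
               test = split$test_kinases)
  combos <- utils::combn(names(sets), 2, simplify = FALSE)
  for (cmb in combos) {
    ov <- intersect(sets[[cmb[1]]], sets[[cmb[2]]])
    for (k in ov) note("disjointness", k, paste(cmb, collapse = "/"))
  }
  unknown <- setdiff(unlist(sets, use.names = FALSE), dataset$kinases$kinase_id)
  for (k in unknown) note("unresolved_kinase", k, "not in dataset")

  pair_sets <- list(train = split$train_pairs, validation = split$val_pairs,
                    test = split$test_pairs)
  for (nm in names(pair_sets)) {
    stray <- setdiff(unique(pair_sets[[nm]]$kinase_id), sets[[nm]])
    for (k in stray) note("pair_membership", k, paste0("pair kinase not in ", nm, " set"))
  }
  mins <- c(validation = config$val_min, test = config$test_min)
  for (nm in names(mins)) {
    cnt <- table(factor(pair_sets[[nm]]$kinase_id, levels = sets[[nm]]))
    low <- names(cnt)[cnt < mins[[nm]]]
    for (k in low) {
      note("min_pairs", k, sprintf("%s kinase has %d < %d pairs", nm, cnt[[k]], mins[[nm]]))
    }
  }
  # identity leakage across splits
  resolved <- lapply(sets, intersect, y = dataset$kinases$kinase_id)
  if (is.null(id_matrix)) {
    id_matrix <- identity_matrix(dataset$kinases, config$scoring)
  }
  for (cmb in combos) {
    a <- resolved[[cmb[1]]]; b <- resolved[[cmb[2]]]
    if (!length(a) || !length(b)) next
    sub <- id_matrix[a, b, drop = FALSE]
    hits <- which(sub >= config$identity_threshold, arr.ind = TRUE)
    if (nrow(hits)) {
      for (r in seq_len(nrow(hits))) {
        note("identity_leakage", a[hits[r, 1]],
             sprintf("%.3f identity to %s (%s/%s)", sub[hits[r, 1], hits[r, 2]],
                     b[hits[r, 2]], cmb[1], cmb[2]))
      }
    }
  }
  if (length(v)) bind_rows(v) else tibble(rule = character(0),
                                          kinase_id = character(0),
                                          detail = character(0))
}

#' Write a benchmark split to disk
#'
#' Emits `train_pairs.tsv`, `val_pairs.tsv`, `test_pairs.tsv` and a
#' `split_manifest.yaml` recording the seed, configuration, kinase
#' assignments and per-group counts.
#'
#' @param split a `benchmark_split`.
#' @param dir output directory.
#' @param dataset optional dataset used to record per-group counts.
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir, dataset = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(split$train_pairs, file.path(dir, "train_pairs.tsv"))
  readr::write_tsv(split$val_pairs, file.path(dir, "val_pairs.tsv"))
  readr::write_tsv(split$test_pairs, file.path(dir, "test_pairs.tsv"))
  manifest <- list(
    seed = split$seed,
    config = list(test_min = split$config$test_min,
                  val_min = split$config$val_min,
                  identity_threshold = split$config$identity_threshold,
                  target_fractions = as.numeric(split$config$target_fractions),
                  scoring = split$config$scoring),
    kinases = list(train = as.list(split$train_kinases),
                   validation = as.list(split$val_kinases),
                   test = as.list(split$test_kinases)))
  if (!is.null(dataset)) {
    grp <- setNames(dataset$kinases$group, dataset$kinases$kinase_id)
    manifest$group_counts <- lapply(
      list(train = split$train_kinases, validation = split$val_kinases,
           test = split$test_kinases),
      function(ids) as.list(table(grp[ids])))
  }
  yaml::write_yaml(manifest, file.path(dir, "split_manifest.yaml"))
  invisible(dir)
}
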