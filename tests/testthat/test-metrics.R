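test_that("average precision matches hand-derived cases", {
  expect_equal(average_precision(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(average_precision(c(3, 2, 1), c(FALSE, FALSE, TRUE)), 1 / 3)
  expect_equal(average_precision(c(0.1, 0.9, 0.5), c(TRUE, TRUE, TRUE)), 1)
  expect_true(is.na(average_precision(c(1, 2), c(FALSE, FALSE))))
  # stable tie order: earlier input wins the shared rank
  expect_equal(average_precision(c(1, 1), c(TRUE, FALSE)), 1)
  expect_equal(average_precision(c(1, 1), c(FALSE, TRUE)), 1 / 2)
})

test_that("AP is invariant under strictly monotone transforms of scores", {
  set.seed(61)
  for (rep in 1:20) {
    s <- runif(10)
    l <- runif(10) < 0.4
    if (!any(l)) l[1] <- TRUE
    expect_equal(average_precision(s, l), average_precision(exp(3 * s), l),
                 tolerance = 1e-12)
    expect_equal(average_precision(s, l), average_precision(rank(s) * 10, l),
                 tolerance = 1e-12)
  }
})

test_that("macro and phosphosite AP average over the right axis", {
  S <- matrix(c(0.9, 0.1, 0.5,
                0.2, 0.8, 0.6), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("k1", "k2")))
  pairs <- tibble::tibble(site_id = c("s1", "s2", "s3"),
                          kinase_id = c("k1", "k2", "k2"))
  res <- macro_ap(S, pairs)
  expect_equal(res$macro_ap,
               mean(c(bf_average_precision(S[, 1], c(TRUE, FALSE, FALSE)),
                      bf_average_precision(S[, 2], c(FALSE, TRUE, TRUE)))),
               tolerance = 1e-12)
  # perfect matrix -> macro 1; two kinases with APs .2/.4 -> macro .3 analogue
  P <- matrix(c(1, 0, 0, 0, 1, 1), 3, 2, dimnames = dimnames(S))
  expect_equal(macro_ap(P, pairs)$macro_ap, 1)
  expect_equal(phosphosite_ap(P, pairs)$phosphosite_ap, 1)
  # single site with one true kinase of 4 ranked 2nd -> AP 0.5
  S1 <- matrix(c(0.9, 0.7, 0.3, 0.1), 1, 4,
               dimnames = list("s1", paste0("k", 1:4)))
  p1 <- tibble::tibble(site_id = "s1", kinase_id = "k2")
  expect_equal(phosphosite_ap(S1, p1)$phosphosite_ap, 0.5)
  # kinase with no positives is excluded with a warning
  pairs_partial <- pairs[pairs$kinase_id == "k1", ]
  expect_warning(m <- macro_ap(S, pairs_partial), "excluding")
  expect_equal(m$macro_ap, m$per_kinase$ap[1])
})

test_that("aggregated AP collapses to macro AP for singleton classes", {
  set.seed(62)
  S <- random_score_matrix(4, 3)
  L <- random_label_matrix(4, 3)
  pairs <- labels_to_pairs(L, rownames(S), colnames(S))
  singleton <- setNames(colnames(S), colnames(S))
  expect_equal(aggregated_ap(S, pairs, singleton)$aggregated_ap,
               macro_ap(S, pairs)$macro_ap, tolerance = 1e-12)
  onecls <- setNames(rep("all", 3), colnames(S))
  expect_equal(aggregated_ap(S, pairs, onecls)$aggregated_ap, 1)
})

test_that("masked-group AP is vacuous for one group and perfect for singletons", {
  set.seed(63)
  S <- random_score_matrix(5, 4)
  L <- random_label_matrix(5, 4)
  pairs <- labels_to_pairs(L, rownames(S), colnames(S))
  one_group <- setNames(rep("g", 4), colnames(S))
  expect_equal(masked_group_ap(S, pairs, one_group)$masked_group_ap,
               macro_ap(S, pairs)$macro_ap, tolerance = 1e-12)
  singleton_groups <- setNames(colnames(S), colnames(S))
  expect_equal(masked_group_ap(S, pairs, singleton_groups)$masked_group_ap, 1)
})

test_that("masking that removes only negatives never lowers macro AP", {
  set.seed(64)
  for (rep in 1:15) {
    S <- random_score_matrix(5, 4, ties = rep %% 2 == 0)
    L <- random_label_matrix(5, 4)
    pairs <- labels_to_pairs(L, rownames(S), colnames(S))
    groups <- setNames(sample(c("g1", "g2"), 4, TRUE), colnames(S))
    expect_gte(masked_group_ap(S, pairs, groups)$masked_group_ap,
               macro_ap(S, pairs)$macro_ap - 1e-12)
  }
})

test_that("hit@k counts top-k intersections and is non-decreasing in k", {
  S <- matrix(c(0.9, 0.2,
                0.5, 0.8,
                0.1, 0.5), 2, 3,
              dimnames = list(c("s1", "s2"), c("k1", "k2", "k3")))
  # s1: true kinase at rank 1; s2: true kinase at rank 3
  pairs <- tibble::tibble(site_id = c("s1", "s2"), kinase_id = c("k1", "k1"))
  h <- hit_at_k(S, pairs, k = c(1, 2, 3))
  expect_equal(h$hit_rate, c(0.5, 0.5, 1.0))
  expect_true(all(diff(h$hit_rate) >= 0))
  expect_equal(hit_at_k(S, pairs, k = 5)$hit_rate, 1)  # k >= n_kinases
})

test_that("all metrics match the brute-force oracle on exhaustive small shapes", {
  set.seed(65)
  for (n_s in 1:5) for (n_k in 1:4) for (rep in 1:3) {
    S <- random_score_matrix(n_s, n_k, ties = rep == 3)
    L <- random_label_matrix(n_s, n_k)
    pairs <- labels_to_pairs(L, rownames(S), colnames(S))
    groups <- setNames(sample(c("gA", "gB"), n_k, TRUE), colnames(S))
    expect_equal(suppressWarnings(macro_ap(S, pairs)$macro_ap),
                 bf_macro_ap(S, L), tolerance = 1e-12)
    expect_equal(suppressWarnings(phosphosite_ap(S, pairs)$phosphosite_ap),
                 bf_phosphosite_ap(S, L), tolerance = 1e-12)
    expect_equal(aggregated_ap(S, pairs, groups)$aggregated_ap,
                 bf_aggregated_ap(S, L, groups), tolerance = 1e-12)
    expect_equal(aggregated_ap(S, pairs, groups, agg = "sum")$aggregated_ap,
                 bf_aggregated_ap(S, L, groups, agg = "sum"), tolerance = 1e-12)
    expect_equal(masked_group_ap(S, pairs, groups)$masked_group_ap,
                 bf_masked_group_ap(S, L, groups), tolerance = 1e-12)
    for (k in 1:n_k) {
      expect_equal(hit_at_k(S, pairs, k)$hit_rate, bf_hit_at_k(S, L, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("the random baseline converges to the exhaustive-permutation expectation", {
  # one kinase, 4 sites of which 2 positive: enumerate all 4! rankings
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  perms <- all_perms(4)
  exp_ap <- mean(vapply(perms, function(p) {
    bf_average_precision(order(p), labels)    # scores = permutation ranks
  }, numeric(1)))
  pairs <- tibble::tibble(site_id = c("s1", "s2"), kinase_id = "k1")
  rb <- random_baseline_ap(pairs, paste0("s", 1:4), "k1",
                           n_runs = 3000, seed = 2)
  expect_equal(rb$mean_ap, exp_ap, tolerance = 0.02)
  # all sites positive for the single kinase -> exactly 1 in every run
  pairs_all <- tibble::tibble(site_id = paste0("s", 1:4), kinase_id = "k1")
  rb1 <- random_baseline_ap(pairs_all, paste0("s", 1:4), "k1",
                            n_runs = 5, seed = 3)
  expect_equal(rb1$mean_ap, 1)
  expect_equal(rb1$sd_ap, 0)
})

test_that("evaluate_scores bundles every metric with tidy/glance access", {
  bench <- generate_benchmark(synthetic_spec(seed = 8, sigma_site = 0))
  sc <- zero_shot_scenario(bench, seed = 8)
  S <- knn_predict_all(sc$test_sites, sc$train_pairs, bench$site_store,
                       bench$kinase_store, sc$dark_ids, knn_config(k = 1))
  rep <- evaluate_scores(S, sc$test_pairs, kinases = bench$dataset)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$macro_ap, mean(rep$per_kinase_ap$ap), tolerance = 1e-12)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("macro_ap", "masked_group_ap", "hit_at_5") %in% names(g)))
  expect_identical(nrow(tidy(rep)), length(sc$dark_ids))
  expect_true(all(tidy(rep)$ap >= 0 & tidy(rep)$ap <= 1))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  # serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$macro_ap, rep$macro_ap, tolerance = 1e-12)
})
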