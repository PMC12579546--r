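# Synthetic kinome benchmark generator.
#
# Emulates the statistical structure the pipeline has to cope with -- a
# long-tailed sites-per-kinase distribution straddling the test-eligibility
# threshold, near-duplicate kinase sequences that must be co-assigned,
# kinase-group structure in both sequence and embedding space, multilabel
# sites -- without attempting to imitate phosphosite motif biology. Site and
# kinase embeddings share one space (as when one protein language model
# embeds both sides); a linear-map variant stresses the bilinear model
# beyond what nearest-neighbour transfer can exploit.

#' Synthetic benchmark specification
#'
#' Defaults describe a kinome of 4 groups x 12 kinases with unit-norm
#' orthogonal group centres, within-group embedding spread 0.15, site noise
#' 0.5 (so the zero-shot task is informative but far from saturated, as the
#' real task is), log-normal sites-per-kinase counts (median 15, so kinases
#' fall on both sides of the test-eligibility threshold), 10% cloned kinases
#' at >= 90% sequence identity and 10% multilabel sites.
#'
#' @param n_groups number of kinase groups (embedding centres are mutually
#'   orthogonal; requires `dim >= n_groups`).
#' @param kinases_per_group kinases per group.
#' @param families_per_group sequence families nested in each group.
#' @param dim embedding dimension.
#' @param sites_meanlog,sites_sdlog,sites_min,sites_max log-normal
#'   sites-per-kinase distribution (rounded, clamped).
#' @param sigma_within within-group kinase embedding spread.
#' @param sigma_site site embedding noise around the kinase embedding.
#' @param clone_fraction fraction of kinases duplicated as a high-identity
#'   clone (4% of residues substituted, guaranteeing >= 90% identity).
#' @param multilabel_rate fraction of sites given a second, same-group
#'   kinase label.
#' @param seq_length kinase domain length.
#' @param mutation_rate_group per-residue substitution rate from group
#'   ancestor to family ancestor.
#' @param mutation_rate_kinase per-residue substitution rate from family
#'   ancestor to kinase.
#' @param linear_map relate site space to kinase space by a random rotation
#'   instead of the identity.
#' @param seed RNG seed; the generated benchmark is fully determined by the
#'   spec including the seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_groups = 4L, kinases_per_group = 12L,
                           families_per_group = 3L, dim = 16L,
                           sites_meanlog = log(15), sites_sdlog = 1,
                           sites_min = 2L, sites_max = 120L,
                           sigma_within = 0.15, sigma_site = 0.5,
                           clone_fraction = 0.1, multilabel_rate = 0.1,
                           seq_length = 100L, mutation_rate_group = 0.35,
                           mutation_rate_kinase = 0.12, linear_map = FALSE,
                           seed = 1L) {
  spec <- list(n_groups = as.integer(n_groups),
               kinases_per_group = as.integer(kinases_per_group),
               families_per_group = as.integer(families_per_group),
               dim = as.integer(dim), sites_meanlog = sites_meanlog,
               sites_sdlog = sites_sdlog, sites_min = as.integer(sites_min),
               sites_max = as.integer(sites_max),
               sigma_within = sigma_within, sigma_site = sigma_site,
               clone_fraction = clone_fraction,
               multilabel_rate = multilabel_rate,
               seq_length = as.integer(seq_length),
               mutation_rate_group = mutation_rate_group,
               mutation_rate_kinase = mutation_rate_kinase,
               linear_map = isTRUE(linear_map), seed = as.integer(seed))
  if (spec$dim < 2L) abort("`dim` must be >= 2.")
  if (spec$dim < spec$n_groups) abort("`dim` must be >= `n_groups`.")
  fracs <- c(spec$clone_fraction, spec$multilabel_rate)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must be in [0, 1].")
  if (spec$clone_fraction > 0 && spec$kinases_per_group < 1L) {
    abort("clone_fraction > 0 requires at least one kinase per group.")
  }
  if (any(c(spec$sigma_within, spec$sigma_site) < 0)) {
    abort("noise levels must be non-negative.")
  }
  if (spec$sites_min < 1L) abort("sites-per-kinase support must be >= 1.")
  structure(spec, class = "synthetic_spec")
}

random_seq <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# substitute each position independently with `rate`, uniform over the 19
# alternative residues (no indels: identity stays analytically controllable)
mutate_seq <- function(seq, rate) {
  ch <- seq_chars(seq)
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(c) sample(setdiff(AA20, c), 1L), character(1))
  paste(ch, collapse = "")
}

# substitute exactly k distinct positions
mutate_k_positions <- function(seq, k) {
  ch <- seq_chars(seq)
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(c) sample(setdiff(AA20, c), 1L), character(1))
  paste(ch, collapse = "")
}

random_window <- function(flank = 7L) {
  res <- sample(c("S", "T", "Y"), 1L)
  paste0(paste(sample(AA20, flank, TRUE), collapse = ""), res,
         paste(sample(AA20, flank, TRUE), collapse = ""))
}

#' Generate a synthetic benchmark
#'
#' Builds a complete, self-consistent benchmark from a [synthetic_spec()]:
#' a kinase table (sequences with group/family structure and clones), a
#' phosphosite table with 15-mer windows, an association pair list, and
#' site/kinase embedding stores with controlled group geometry. Fully
#' deterministic given the spec.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_benchmark`: list with `dataset`
#'   ([phospho_dataset()]), `site_store`, `kinase_store`
#'   ([embedding_store()]s), `clones` (tibble `clone_id`, `parent_id`), and
#'   `spec`.
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    # --- kinases: sequences with group/family structure -------------------
    kin <- list()
    for (g in seq_len(spec$n_groups)) {
      g_anc <- random_seq(spec$seq_length)
      fam_anc <- lapply(seq_len(spec$families_per_group), function(f) {
        mutate_seq(g_anc, spec$mutation_rate_group)
      })
      for (j in seq_len(spec$kinases_per_group)) {
        f <- ((j - 1L) %% spec$families_per_group) + 1L
        kin[[length(kin) + 1L]] <- tibble(
          kinase_id = sprintf("KIN_g%d_%02d", g, j),
          domain_sequence = mutate_seq(fam_anc[[f]], spec$mutation_rate_kinase),
          group = sprintf("Group%d", g),
          family = sprintf("Fam%d.%d", g, f))
      }
    }
    kinases <- bind_rows(kin)
    # EC annotations: group-level base class, occasional second class, some
    # kinases unannotated
    u <- runif(nrow(kinases))
    kinases$ec_classes <- lapply(seq_len(nrow(kinases)), function(i) {
      g <- match(kinases$group[i], unique(kinases$group))
      if (u[i] < 0.7) sprintf("2.7.11.%d", g)
      else if (u[i] < 0.9) c(sprintf("2.7.11.%d", g), sprintf("2.7.12.%d", g))
      else character(0)
    })

    # clones: near-duplicates that must be co-assigned by the splitter
    n_clones <- round(spec$clone_fraction * nrow(kinases))
    clones <- tibble(clone_id = character(0), parent_id = character(0))
    if (n_clones > 0L) {
      parents <- sample(kinases$kinase_id, n_clones)
      k_sub <- max(1L, ceiling(0.04 * spec$seq_length))
      for (p in parents) {
        row <- kinases[kinases$kinase_id == p, ]
        kinases <- bind_rows(kinases, mutate(row,
          kinase_id = paste0(p, "c"),
          domain_sequence = mutate_k_positions(row$domain_sequence, k_sub)))
        clones <- bind_rows(clones, tibble(clone_id = paste0(p, "c"),
                                           parent_id = p))
      }
    }

    # --- embeddings: orthonormal group centres ----------------------------
    centres <- qr.Q(qr(matrix(rnorm(spec$dim * spec$n_groups), spec$dim)))
    g_idx <- match(kinases$group, unique(kinases$group))
    K <- t(vapply(seq_len(nrow(kinases)), function(i) {
      centres[, g_idx[i]] + rnorm(spec$dim, sd = spec$sigma_within)
    }, numeric(spec$dim)))
    rownames(K) <- kinases$kinase_id
    site_map <- if (spec$linear_map) {
      qr.Q(qr(matrix(rnorm(spec$dim^2), spec$dim)))
    } else {
      diag(spec$dim)
    }

    # --- sites and pairs --------------------------------------------------
    n_sites_per <- pmin(pmax(round(stats::rlnorm(nrow(kinases),
                                                 spec$sites_meanlog,
                                                 spec$sites_sdlog)),
                             spec$sites_min), spec$sites_max)
    n_total <- sum(n_sites_per)
    kin_of_site <- rep(kinases$kinase_id, n_sites_per)
    grp_of_site <- rep(kinases$group, n_sites_per)
    within_idx <- unlist(lapply(n_sites_per, seq_len), use.names = FALSE)
    substrate <- sprintf("SUB_%s_%d", kin_of_site, within_idx)
    position <- sample(8:2000, n_total, replace = TRUE)
    flank_chars <- function() {
      apply(matrix(sample(AA20, n_total * 7L, TRUE), n_total), 1, paste,
            collapse = "")
    }
    residue <- sample(c("S", "T", "Y"), n_total, replace = TRUE)
    window <- paste0(flank_chars(), residue, flank_chars())
    sid <- make_site_id(substrate, position)
    sites <- tibble(site_id = sid, substrate_id = substrate,
                    position = position, residue = residue, window = window)
    S <- K[kin_of_site, , drop = FALSE] %*% t(site_map) +
      matrix(rnorm(n_total * spec$dim, sd = spec$sigma_site), n_total)
    rownames(S) <- sid

    grp_members <- split(kinases$kinase_id, kinases$group)
    multi <- which(runif(n_total) < spec$multilabel_rate &
                     lengths(grp_members[grp_of_site]) > 1L)
    second <- vapply(multi, function(i) {
      sample(setdiff(grp_members[[grp_of_site[i]]], kin_of_site[i]), 1L)
    }, character(1))
    pairs <- bind_rows(
      tibble(site_id = sid, kinase_id = unname(kin_of_site)),
      tibble(site_id = unname(sid[multi]), kinase_id = unname(second)))

    structure(list(
      dataset = phospho_dataset(kinases, sites, pairs),
      site_store = embedding_store(S),
      kinase_store = embedding_store(K),
      clones = clones, spec = spec),
      class = "synthetic_benchmark")
  })
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("<synthetic_benchmark> seed %d, sigma_site %.3g\n",
              x$spec$seed, x$spec$sigma_site))
  print(x$dataset)
  invisible(x)
}

#' Write a synthetic benchmark in the standard exchange formats
#'
#' Emits the dataset TSVs ([write_dataset()]) plus `site_embeddings.tsv` and
#' `kinase_embeddings.tsv` ([write_embedding_store()]), making synthetic and
#' real data interchangeable downstream.
#'
#' @param benchmark a `synthetic_benchmark`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  write_dataset(benchmark$dataset, dir)
  write_embedding_store(benchmark$site_store, file.path(dir, "site_embeddings.tsv"))
  write_embedding_store(benchmark$kinase_store, file.path(dir, "kinase_embeddings.tsv"))
  invisible(dir)
}

#' Carve a controlled zero-shot scenario out of a synthetic benchmark
#'
#' Selects one dark (test) kinase and one validation kinase per group --
#' uniformly among kinases with at least `min_sites` sites that are not
#' involved in a clone pair (clones are left in training so the scenario
#' never leaks near-duplicates) -- and materializes the train/validation/test
#' pair lists. Used by the parameter-recovery harness; [make_split()] is the
#' production splitter.
#'
#' @param benchmark a `synthetic_benchmark`.
#' @param min_sites minimum sites for a kinase to be picked as dark or
#'   validation.
#' @param seed seed for the per-group draws.
#' @return list with `dark_ids`, `val_ids`, `train_pairs`, `val_pairs`,
#'   `test_pairs`, `test_sites`, `val_sites`.
#' @export
zero_shot_scenario <- function(benchmark, min_sites = 5L, seed = 1L) {
  ds <- benchmark$dataset
  counts <- kinase_pair_counts(ds)
  cloned <- union(benchmark$clones$clone_id, benchmark$clones$parent_id)
  eligible <- counts |>
    filter(.data$n_pairs >= min_sites, !(.data$kinase_id %in% cloned))
  picks <- local_seed(seed, {
    lapply(split(eligible$kinase_id, eligible$group), function(ids) {
      if (length(ids) < 2L) {
        abort("a group lacks two eligible kinases for the zero-shot scenario.")
      }
      sample(ids, 2L)
    })
  })
  dark_ids <- sort(vapply(picks, `[`, character(1), 1L))
  val_ids <- sort(vapply(picks, `[`, character(1), 2L))
  train_kin <- setdiff(ds$kinases$kinase_id, c(dark_ids, val_ids))
  take <- function(ids) ds$pairs[ds$pairs$kinase_id %in% ids, ]
  test_pairs <- take(dark_ids); val_pairs <- take(val_ids)
  list(dark_ids = dark_ids, val_ids = val_ids,
       train_pairs = take(train_kin), val_pairs = val_pairs,
       test_pairs = test_pairs,
       test_sites = unique(test_pairs$site_id),
       val_sites = unique(val_pairs$site_id))
}

#' Parameter-recovery curve over site-noise levels
#'
#' For each site-noise level and generator seed, generates a benchmark,
#' carves a zero-shot scenario, runs the chosen classifier, and records the
#' test macro AP. Averaged over seeds the curve is non-increasing in the
#' noise level and approaches the random baseline as noise swamps the group
#' separation.
#'
#' @param sigma_grid site-noise levels to sweep.
#' @param classifier `"knn"` or `"bzsm"`.
#' @param seeds generator seeds.
#' @param spec base [synthetic_spec()]; `sigma_site` and `seed` are
#'   overridden per cell.
#' @param knn_k neighbourhood size for the k-NN classifier.
#' @param bzsm_epochs,bzsm_lr fit budget for the bilinear classifier.
#' @return tibble with `classifier`, `sigma_site`, `seed`, `macro_ap`.
#' @export
recovery_report <- function(sigma_grid = c(0, 0.5, 2, 8),
                            classifier = c("knn", "bzsm"), seeds = 1:5,
                            spec = synthetic_spec(), knn_k = 1L,
                            bzsm_epochs = 60L, bzsm_lr = 0.02) {
  classifier <- match.arg(classifier)
  grid <- tidyr::expand_grid(sigma_site = sigma_grid, seed = seeds)
  grid$macro_ap <- purrr::pmap_dbl(grid, function(sigma_site, seed) {
    sp <- spec
    sp$sigma_site <- sigma_site
    sp$seed <- seed
    bench <- generate_benchmark(sp)
    sc <- zero_shot_scenario(bench, seed = seed)
    S <- if (classifier == "knn") {
      knn_predict_all(sc$test_sites, sc$train_pairs, bench$site_store,
                      bench$kinase_store, sc$dark_ids,
                      knn_config(k = knn_k))
    } else {
      cfg <- bzsm_config(learning_rate = bzsm_lr, epochs = bzsm_epochs,
                         seed = seed)
      fit <- bzsm_train(sc$train_pairs, bench$site_store, bench$kinase_store,
                        cfg, val_pairs = sc$val_pairs, val_kinases = sc$val_ids)
      predict(fit, sc$test_sites, sc$dark_ids, bench$site_store,
              bench$kinase_store)
    }
    suppressWarnings(macro_ap(S, sc$test_pairs)$macro_ap)
  })
  grid$classifier <- classifier
  grid[, c("classifier", "sigma_site", "seed", "macro_ap")]
}
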