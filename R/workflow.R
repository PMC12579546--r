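# Configuration-driven workflow: one structured config describes a full run
# (dataset -> split -> encode -> fit/predict -> evaluate). CLI flags map
# onto config keys; a run manifest records the config hash and seeds so any
# run is reproducible from its manifest.

#' Assemble a run configuration
#'
#' A run configuration is a named list with sections `dataset`, `split`,
#' `encoder`, `model` and `eval`, plus top-level `out_dir` and `seed`.
#' Either build it in R or load it from YAML with `run_config(path = ...)`;
#' explicit arguments override file values.
#'
#' Defaults describe a fully synthetic run: generate a benchmark
#' ([generate_benchmark()]), split it ([make_split()]), use the generated
#' embedding stores, run the k-NN classifier with `k` selected on the
#' validation kinases, and evaluate with the full metric suite.
#'
#' @param path optional YAML file.
#' @param ... named overrides merged over the file/defaults (nested lists
#'   are merged shallowly per section).
#' @return a `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    out_dir = "darkzsl_run",
    seed = 1L,
    dataset = list(source = "synthetic"),    # or kinases/sites/pairs paths
    split = list(test_min = 15L, val_min = 10L, identity_threshold = 0.90,
                 target_fractions = c(0.80, 0.10, 0.10)),
    encoder = list(source = "stores",        # "stores" | baseline encoding name
                   site_path = NULL, kinase_path = NULL,
                   use_family = FALSE, use_group = FALSE, use_ec = FALSE),
    model = list(type = "knn", k = c(3L, 5L, 7L),
                 learning_rate = 0.01, weight_decay = 1e-4,
                 optimizer = "adam", schedule = "exponential",
                 epochs = 100L, batch_size = 64L, restarts = 3L),
    eval = list(hit_k = c(1L, 3L, 5L, 10L), agg = "max"))
  cfg <- defaults
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "run_config")
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

wf_log <- function(stage, fmt, ...) {
  message(sprintf("[darkzsl:%s] %s", stage, sprintf(fmt, ...)))
}

# resolve the dataset + embedding stores a config describes
load_run_inputs <- function(config) {
  ds_cfg <- config$dataset
  if (identical(ds_cfg$source, "synthetic")) {
    spec_args <- ds_cfg[setdiff(names(ds_cfg), "source")]
    spec_args$seed <- spec_args$seed %||% config$seed
    bench <- do.call(synthetic_spec, spec_args) |> generate_benchmark()
    dataset <- bench$dataset
    stores <- list(site = bench$site_store, kinase = bench$kinase_store)
  } else {
    dataset <- read_dataset(ds_cfg$kinases, ds_cfg$sites, ds_cfg$pairs,
                            fasta_path = ds_cfg$fasta)
    stores <- NULL
  }
  enc <- config$encoder
  if (identical(enc$source, "stores")) {
    if (!is.null(enc$site_path)) {
      stores <- list(site = read_embedding_store(enc$site_path),
                     kinase = read_embedding_store(enc$kinase_path))
    }
    if (is.null(stores)) abort("encoder source 'stores' needs site/kinase paths.")
    if (any(c(enc$use_family, enc$use_group, enc$use_ec))) {
      stores$kinase <- augment_store(stores$kinase, dataset,
                                     use_family = isTRUE(enc$use_family),
                                     use_group = isTRUE(enc$use_group),
                                     use_ec = isTRUE(enc$use_ec))
    }
  } else {
    trig <- if (!is.null(enc$trigram_path)) read_trigram_table(enc$trigram_path)
    stores <- list(
      site = encode_sites(dataset, encoding = enc$source, trigram_table = trig),
      kinase = encode_kinases(dataset, encoding = enc$source,
                              trigram_table = trig,
                              use_family = isTRUE(enc$use_family),
                              use_group = isTRUE(enc$use_group),
                              use_ec = isTRUE(enc$use_ec)))
  }
  list(dataset = dataset, site_store = stores$site, kinase_store = stores$kinase)
}

config_split <- function(config) {
  s <- config$split
  split_config(test_min = s$test_min, val_min = s$val_min,
               identity_threshold = s$identity_threshold,
               target_fractions = unlist(s$target_fractions),
               seed = config$seed)
}

#' Generate and write a benchmark split from a run configuration
#'
#' Loads (or generates) the configured dataset, runs [make_split()], audits
#' it with [validate_split()], and writes the pair lists plus manifest under
#' `<out_dir>/splits/`.
#'
#' @param config a [run_config()].
#' @return the `benchmark_split`, invisibly.
#' @export
cmd_split <- function(config = run_config()) {
  inputs <- load_run_inputs(config)
  scfg <- config_split(config)
  idm <- identity_matrix(inputs$dataset, scfg$scoring)
  split <- make_split(inputs$dataset, scfg, id_matrix = idm)
  viol <- validate_split(inputs$dataset, split, scfg, id_matrix = idm)
  if (nrow(viol)) {
    abort(sprintf("generated split violates its own contract (%d violations).",
                  nrow(viol)))
  }
  dir <- file.path(config$out_dir, "splits")
  write_split(split, dir, dataset = inputs$dataset)
  g <- glance(split)
  wf_log("split", "train/val/test pairs: %d/%d/%d (fractions %.2f/%.2f/%.2f)",
         g$n_train_pairs, g$n_val_pairs, g$n_test_pairs,
         g$frac_train, g$frac_val, g$frac_test)
  invisible(split)
}

#' Evaluate a score matrix from a run configuration
#'
#' Reads a score matrix and pair list, runs [evaluate_scores()], and writes
#' the report under `<out_dir>/reports/`.
#'
#' @param config a [run_config()] whose `eval` section carries `scores`
#'   (TSV score matrix path) and `pairs` (TSV pair list path); a
#'   `dataset$kinases` path enables family/group metrics.
#' @return the `eval_report`, invisibly.
#' @export
cmd_evaluate <- function(config) {
  S <- read_score_matrix(config$eval$scores)
  pairs <- readr::read_tsv(config$eval$pairs,
                           col_types = readr::cols(.default = "c"))
  kinases <- NULL
  if (!is.null(config$dataset$kinases)) {
    kinases <- readr::read_tsv(config$dataset$kinases,
                               col_types = readr::cols(.default = "c"))
    kinases$ec_classes <- split_ec(kinases$ec %||% rep("", nrow(kinases)))
  }
  miss <- setdiff(unique(pairs$site_id), rownames(S))
  if (length(miss)) {
    abort(sprintf("score matrix lacks rows for %d labelled site(s).",
                  length(miss)))
  }
  report <- evaluate_scores(S, pairs, kinases = kinases,
                            k = unlist(config$eval$hit_k),
                            agg = config$eval$agg %||% "max")
  dir <- file.path(config$out_dir, "reports")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_eval_report(report, file.path(dir, "eval_report.json"))
  wf_log("evaluate", "macro AP %.4f over %d sites x %d kinases",
         report$macro_ap, report$n_sites, report$n_kinases)
  invisible(report)
}

#' Run the full pipeline from a configuration
#'
#' Executes dataset loading/generation, split generation, encoding, model
#' fitting/prediction and evaluation, writing every intermediate artifact
#' under `out_dir` (`splits/`, `encodings/`, `models/`, `scores/`,
#' `reports/`) plus a `run_manifest.yaml` recording the config hash, seed
#' and package version. Reproducible: the same config and seed yield
#' identical outputs (single-threaded).
#'
#' @param config a [run_config()].
#' @return list with `split`, `report` (test-set `eval_report`), `model`
#'   (fitted `bzsm` or selected `knn_config`), and for multi-restart
#'   bilinear runs `restarts` (the [bzsm_restarts()] summary).
#' @export
cmd_run <- function(config = run_config()) {
  out <- config$out_dir
  for (d in c("splits", "encodings", "models", "scores", "reports")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  inputs <- load_run_inputs(config)
  wf_log("load", "%d kinases, %d sites, %d pairs",
         nrow(inputs$dataset$kinases), nrow(inputs$dataset$sites),
         nrow(inputs$dataset$pairs))

  scfg <- config_split(config)
  idm <- identity_matrix(inputs$dataset, scfg$scoring)
  split <- make_split(inputs$dataset, scfg, id_matrix = idm)
  viol <- validate_split(inputs$dataset, split, scfg, id_matrix = idm)
  if (nrow(viol)) abort("generated split failed validation.")
  write_split(split, file.path(out, "splits"), dataset = inputs$dataset)

  write_embedding_store(inputs$site_store,
                        file.path(out, "encodings", "site_embeddings.tsv"))
  write_embedding_store(inputs$kinase_store,
                        file.path(out, "encodings", "kinase_embeddings.tsv"))

  test_sites <- unique(split$test_pairs$site_id)
  val_sites <- unique(split$val_pairs$site_id)
  model_cfg <- config$model
  restarts_summary <- NULL

  if (identical(model_cfg$type, "knn")) {
    ks <- as.integer(unlist(model_cfg$k))
    if (length(ks) > 1L) {
      val_aps <- vapply(ks, function(k) {
        S <- knn_predict_all(val_sites, split$train_pairs, inputs$site_store,
                             inputs$kinase_store, split$val_kinases,
                             knn_config(k = k))
        suppressWarnings(macro_ap(S, split$val_pairs)$macro_ap)
      }, numeric(1))
      k_best <- select_k(tibble(k = ks, macro_ap = val_aps))
      wf_log("knn", "selected k = %d by validation macro AP", k_best)
    } else {
      k_best <- ks
    }
    model <- knn_config(k = k_best,
                        site_metric = model_cfg$site_metric %||% "cosine")
    S <- knn_predict_all(test_sites, split$train_pairs, inputs$site_store,
                         inputs$kinase_store, split$test_kinases, model)
  } else if (identical(model_cfg$type, "bzsm")) {
    bcfg <- bzsm_config(
      learning_rate = model_cfg$learning_rate, optimizer = model_cfg$optimizer,
      schedule = model_cfg$schedule, weight_decay = model_cfg$weight_decay,
      epochs = model_cfg$epochs, batch_size = model_cfg$batch_size,
      restarts = model_cfg$restarts %||% 3L, seed = config$seed)
    n_restarts <- bcfg$restarts
    if (n_restarts > 1L) {
      restarts_summary <- bzsm_restarts(
        bcfg, split$train_pairs, inputs$site_store, inputs$kinase_store,
        split$val_pairs, split$val_kinases, split$test_pairs,
        split$test_kinases, n = n_restarts)
      model <- restarts_summary$models[[1L]]
      wf_log("bzsm", "test macro AP %s over %d restarts",
             restarts_summary$label, n_restarts)
    } else {
      model <- bzsm_train(split$train_pairs, inputs$site_store,
                          inputs$kinase_store, bcfg,
                          val_pairs = split$val_pairs,
                          val_kinases = split$val_kinases)
    }
    saveRDS(model[c("W", "d", "m", "train_kinases", "best_epoch")],
            file.path(out, "models", "bzsm_model.rds"))
    readr::write_tsv(model$log, file.path(out, "models", "training_log.tsv"))
    S <- predict(model, test_sites, split$test_kinases, inputs$site_store,
                 inputs$kinase_store)
  } else {
    abort(sprintf("unknown model type '%s'.", model_cfg$type))
  }

  write_score_matrix(S, file.path(out, "scores", "test_scores.tsv"))
  report <- evaluate_scores(S, split$test_pairs, kinases = inputs$dataset,
                            k = unlist(config$eval$hit_k),
                            agg = config$eval$agg %||% "max")
  write_eval_report(report, file.path(out, "reports", "eval_report.json"))
  wf_log("report", "test macro AP %.4f, masked-group AP %.4f",
         report$macro_ap, report$masked_group_ap)

  manifest <- list(
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("darkzsl")),
    model_type = model_cfg$type,
    n_train_pairs = nrow(split$train_pairs),
    n_val_pairs = nrow(split$val_pairs),
    n_test_pairs = nrow(split$test_pairs),
    test_macro_ap = report$macro_ap)
  if (!is.null(restarts_summary)) {
    manifest$restart_mean_ap <- restarts_summary$mean_ap
    manifest$restart_sd_ap <- restarts_summary$sd_ap
  }
  yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))

  invisible(list(split = split, report = report, model = model,
                 restarts = restarts_summary))
}
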