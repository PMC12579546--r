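# Small in-code fixtures shared across tests.

tiny_kinases <- function() {
  tibble::tibble(
    kinase_id = c("KIN1", "KIN2"),
    domain_sequence = c("MKLVDERTACGHIKLM", "MKLVDERSACGHPKLM"),
    group = c("CMGC", "CMGC"),
    family = c("CDK", "MAPK"),
    ec_classes = list("2.7.11.22", character(0)))
}

tiny_sites <- function() {
  tibble::tibble(
    site_id = c("SUBA_9", "SUBA_20", "SUBB_4"),
    substrate_id = c("SUBA", "SUBA", "SUBB"),
    position = c(9L, 20L, 4L),
    residue = c("S", "T", "Y"),
    window = c("ACDEFGHSIKLMNPQ", "RSTVWYATDEFGHIK", "____AGHYKLMNPQR"))
}

tiny_pairs <- function() {
  tibble::tibble(
    site_id = c("SUBA_9", "SUBA_20", "SUBB_4", "SUBA_9"),
    kinase_id = c("KIN1", "KIN1", "KIN2", "KIN2"))
}

tiny_dataset <- function() {
  phospho_dataset(tiny_kinases(), tiny_sites(), tiny_pairs())
}

# named score matrix with random entries (optionally with ties)
random_score_matrix <- function(n_sites, n_kinases, ties = FALSE) {
  v <- if (ties) {
    sample(seq(0, 1, by = 0.25), n_sites * n_kinases, replace = TRUE)
  } else {
    runif(n_sites * n_kinases)
  }
  matrix(v, n_sites, n_kinases,
         dimnames = list(paste0("s", seq_len(n_sites)),
                         paste0("k", seq_len(n_kinases))))
}

# random label matrix guaranteeing every kinase and site has >= 1 positive
random_label_matrix <- function(n_sites, n_kinases) {
  L <- matrix(runif(n_sites * n_kinases) < 0.4, n_sites, n_kinases)
  for (j in seq_len(n_kinases)) if (!any(L[, j])) L[sample(n_sites, 1L), j] <- TRUE
  for (i in seq_len(n_sites)) if (!any(L[i, ])) L[i, sample(n_kinases, 1L)] <- TRUE
  L
}

labels_to_pairs <- function(L, site_ids, kinase_ids) {
  idx <- which(L, arr.ind = TRUE)
  tibble::tibble(site_id = site_ids[idx[, 1]], kinase_id = kinase_ids[idx[, 2]])
}
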