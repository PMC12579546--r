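# Baseline sequence encodings for phosphosite windows and kinase domains.
#
# Fixed-length 15-mer windows use concatenated per-position blocks; variable
# length kinase domains use position-averaged (pooled) blocks. Pad positions
# contribute zero rows to BLOSUM62/NLF blocks and are excluded from pooled
# one-hot frequencies only insofar as the pad symbol has its own column.

seq_chars <- function(seq) strsplit(seq, "")[[1]]

#' One-hot encode a sequence
#'
#' With `pooled = FALSE` (fixed-length windows) returns the concatenation of
#' per-position indicator vectors, length `nchar(seq) * length(alphabet)`.
#' With `pooled = TRUE` (variable-length domains) returns the
#' position-averaged indicator vector of length `length(alphabet)`; its
#' entries are symbol frequencies and sum to 1.
#'
#' @param seq amino-acid string.
#' @param alphabet symbol set; defaults to the 22-symbol window alphabet when
#'   `pooled = FALSE` and the 21-symbol domain alphabet when `pooled = TRUE`.
#' @param pooled average over positions instead of concatenating.
#' @param pad_char pad character admitted in windows.
#' @return numeric vector.
#' @export
one_hot_encode <- function(seq, alphabet = NULL, pooled = FALSE, pad_char = "_") {
  if (!nzchar(seq)) abort("`seq` must be non-empty.")
  if (is.null(alphabet)) {
    alphabet <- if (pooled) aa_alphabet() else aa_alphabet(pad_char = pad_char)
  }
  ch <- seq_chars(seq)
  idx <- match(ch, alphabet)
  if (anyNA(idx)) {
    abort(sprintf("character(s) outside alphabet: %s",
                  paste(unique(ch[is.na(idx)]), collapse = ", ")))
  }
  m <- matrix(0, nrow = length(ch), ncol = length(alphabet))
  m[cbind(seq_along(ch), idx)] <- 1
  if (pooled) colMeans(m) else as.vector(t(m))
}

blosum62_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      full <- get_sub_matrix("BLOSUM62")
      cache <<- full[c(AA20, "X"), AA20]
    }
    cache
  }
})

#' BLOSUM62 encode a sequence
#'
#' Each residue is represented by its BLOSUM62 substitution-score row
#' (restricted to the 20 canonical residue columns; `X` uses its own row);
#' pad characters contribute zero rows. Rows are concatenated for windows or
#' position-averaged for domains.
#'
#' @inheritParams one_hot_encode
#' @return numeric vector of length `20 * nchar(seq)` (`pooled = FALSE`) or
#'   20 (`pooled = TRUE`).
#' @export
blosum62_encode <- function(seq, pooled = FALSE, pad_char = "_") {
  encode_by_table(seq, blosum62_rows(), pooled = pooled, pad_char = pad_char)
}

# shared row-lookup encoder: `table` is residues x dims, pads -> zero rows
encode_by_table <- function(seq, table, pooled, pad_char) {
  if (!nzchar(seq)) abort("`seq` must be non-empty.")
  ch <- seq_chars(seq)
  rows <- matrix(0, nrow = length(ch), ncol = ncol(table))
  is_pad <- ch == pad_char
  idx <- match(ch[!is_pad], rownames(table))
  if (anyNA(idx)) {
    abort(sprintf("character(s) outside alphabet: %s",
                  paste(unique(ch[!is_pad][is.na(idx)]), collapse = ", ")))
  }
  rows[!is_pad, ] <- table[idx, , drop = FALSE]
  if (pooled) colMeans(rows) else as.vector(t(rows))
}

nlf_env <- new.env(parent = emptyenv())

#' The packaged NLF residue descriptor table
#'
#' An 18-dimension-per-residue physicochemical descriptor table in the style
#' of the non-linear Fisher-transform (NLF) amino-acid encoding. The table
#' shipped with this package (`inst/extdata/nlf_synthetic.tsv`) is a
#' *synthetic stand-in*: it is derived from the spectral decomposition of the
#' BLOSUM62 substitution matrix (18 leading eigencomponents per residue, the
#' ambiguity code `X` mapped to the zero vector) rather than from the
#' original published transform, and is packaged so the encoder surface and
#' its tests are fully reproducible offline. Supply `path` to use a genuine
#' NLF table with the same layout (residue + 18 value columns).
#'
#' @param path optional TSV path overriding the packaged table.
#' @return numeric matrix, residues as rownames, 18 columns.
#' @export
nlf_table <- function(path = NULL) {
  if (!is.null(path)) {
    tb <- readr::read_tsv(path, col_types = readr::cols(residue = "c", .default = "d"))
    m <- as.matrix(tb[, -1])
    rownames(m) <- tb$residue
    return(m)
  }
  if (is.null(nlf_env$table)) {
    p <- system.file("extdata", "nlf_synthetic.tsv", package = "darkzsl")
    if (!nzchar(p)) abort("packaged NLF table not found; reinstall darkzsl or pass `path`.")
    nlf_env$table <- nlf_table(p)
  }
  nlf_env$table
}

#' NLF encode a sequence
#'
#' Per-residue 18-dimensional NLF descriptor rows, concatenated for windows
#' or position-averaged for domains; pad characters contribute zero rows.
#' See [nlf_table()] for the provenance of the packaged coefficient table.
#'
#' @inheritParams one_hot_encode
#' @param table NLF coefficient matrix from [nlf_table()].
#' @return numeric vector.
#' @export
nlf_encode <- function(seq, pooled = FALSE, pad_char = "_", table = nlf_table()) {
  encode_by_table(seq, table, pooled = pooled, pad_char = pad_char)
}

#' ProtVec encode a sequence from a supplied 3-gram table
#'
#' Averages the vectors of all overlapping 3-grams of the sequence.
#' Out-of-vocabulary 3-grams contribute a zero vector (they still count in
#' the denominator). Pad characters are stripped before 3-gram extraction.
#'
#' @param seq amino-acid string of length >= 3 (after pad stripping).
#' @param trigram_table numeric matrix with 3-gram rownames (typically 100
#'   columns), e.g. from [read_trigram_table()].
#' @param pad_char pad character to strip.
#' @return numeric vector of length `ncol(trigram_table)`.
#' @export
protvec_encode <- function(seq, trigram_table, pad_char = "_") {
  seq <- gsub(pad_char, "", seq, fixed = TRUE)
  n <- nchar(seq)
  if (n < 3L) abort("sequence shorter than 3 residues after pad stripping.")
  grams <- substring(seq, 1:(n - 2L), 3:n)
  idx <- match(grams, rownames(trigram_table))
  acc <- matrix(0, nrow = length(grams), ncol = ncol(trigram_table))
  known <- !is.na(idx)
  acc[known, ] <- trigram_table[idx[known], , drop = FALSE]
  colMeans(acc)
}

#' Read a ProtVec-style 3-gram vector table
#'
#' TSV with a `trigram` column followed by numeric vector columns.
#'
#' @param path TSV file path.
#' @return numeric matrix with 3-gram rownames.
#' @export
read_trigram_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(trigram = "c", .default = "d"))
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb$trigram
  m
}

#' Annotation vocabulary for kinase augmentation
#'
#' Collects the ordered label lists used to one-hot encode kinase family,
#' group and EC memberships. The sentinel labels (`otherFamily`, `Other2`)
#' are always present so unassignable kinases encode cleanly.
#'
#' @param kinases kinase tibble or `phospho_dataset`.
#' @return a list with `families`, `groups`, `ec_classes` (sorted, unique).
#' @export
annotation_vocab <- function(kinases) {
  if (inherits(kinases, "phospho_dataset")) kinases <- kinases$kinases
  list(
    families = sort(union(unique(kinases$family), FAMILY_SENTINEL)),
    groups = sort(union(unique(kinases$group), GROUP_SENTINEL)),
    ec_classes = sort(unique(unlist(kinases$ec_classes))))
}

#' Append kinase annotation blocks to an embedding vector
#'
#' Appends, in order, a one-hot family block, a one-hot group block and a
#' multi-hot EC block (a kinase may carry several EC numbers) for whichever
#' flags are enabled. The leading coordinates of `vec` are never modified.
#'
#' @param vec kinase embedding vector.
#' @param record one-row kinase tibble (with `family`, `group`, `ec_classes`).
#' @param vocab an [annotation_vocab()].
#' @param use_family,use_group,use_ec which annotation blocks to append.
#' @return numeric vector of length `length(vec)` plus the enabled block
#'   sizes.
#' @export
augment_kinase_vector <- function(vec, record, vocab,
                                  use_family = FALSE, use_group = FALSE,
                                  use_ec = FALSE) {
  out <- vec
  if (use_family) {
    block <- as.numeric(vocab$families == record$family)
    out <- c(out, block)
  }
  if (use_group) {
    block <- as.numeric(vocab$groups == record$group)
    out <- c(out, block)
  }
  if (use_ec) {
    ecs <- record$ec_classes
    if (is.list(ecs)) ecs <- ecs[[1]]
    block <- as.numeric(vocab$ec_classes %in% ecs)
    out <- c(out, block)
  }
  out
}

encoder_fun <- function(encoding, trigram_table = NULL, nlf = NULL,
                        pad_char = "_") {
  switch(encoding,
    onehot = function(seq, pooled) one_hot_encode(seq, pooled = pooled,
                                                  pad_char = pad_char),
    blosum62 = function(seq, pooled) blosum62_encode(seq, pooled = pooled,
                                                     pad_char = pad_char),
    nlf = function(seq, pooled) nlf_encode(seq, pooled = pooled,
                                           pad_char = pad_char,
                                           table = nlf %||% nlf_table()),
    protvec = function(seq, pooled) protvec_encode(seq, trigram_table,
                                                   pad_char = pad_char),
    abort(sprintf("unknown encoding '%s'", encoding)))
}

#' Encode all phosphosite windows of a dataset
#'
#' @param sites site tibble or `phospho_dataset`.
#' @param encoding one of `"onehot"`, `"blosum62"`, `"nlf"`, `"protvec"`.
#' @param trigram_table required for `encoding = "protvec"`.
#' @param nlf optional NLF table override.
#' @param pad_char window pad character.
#' @return an [embedding_store()] keyed by site id.
#' @export
encode_sites <- function(sites, encoding = "onehot", trigram_table = NULL,
                         nlf = NULL, pad_char = "_") {
  if (inherits(sites, "phospho_dataset")) sites <- sites$sites
  f <- encoder_fun(encoding, trigram_table, nlf, pad_char)
  vecs <- lapply(sites$window, f, pooled = FALSE)
  m <- do.call(rbind, vecs)
  rownames(m) <- sites$site_id
  embedding_store(m)
}

#' Encode all kinase domains of a dataset
#'
#' Variable-length domain sequences are position-averaged (pooled) under the
#' chosen encoding, then optionally augmented with annotation blocks.
#'
#' @param kinases kinase tibble or `phospho_dataset`.
#' @inheritParams encode_sites
#' @param vocab an [annotation_vocab()]; derived from `kinases` when any
#'   augmentation flag is on and `vocab` is `NULL`.
#' @inheritParams augment_kinase_vector
#' @return an [embedding_store()] keyed by kinase id.
#' @export
encode_kinases <- function(kinases, encoding = "onehot", trigram_table = NULL,
                           nlf = NULL, vocab = NULL, use_family = FALSE,
                           use_group = FALSE, use_ec = FALSE, pad_char = "_") {
  if (inherits(kinases, "phospho_dataset")) kinases <- kinases$kinases
  f <- encoder_fun(encoding, trigram_table, nlf, pad_char)
  if (is.null(vocab) && (use_family || use_group || use_ec)) {
    vocab <- annotation_vocab(kinases)
  }
  vecs <- lapply(seq_len(nrow(kinases)), function(i) {
    v <- f(kinases$domain_sequence[i], pooled = TRUE)
    if (use_family || use_group || use_ec) {
      v <- augment_kinase_vector(v, kinases[i, ], vocab,
                                 use_family = use_family,
                                 use_group = use_group, use_ec = use_ec)
    }
    v
  })
  m <- do.call(rbind, vecs)
  rownames(m) <- kinases$kinase_id
  embedding_store(m)
}

#' Append annotation blocks to every vector of a kinase embedding store
#'
#' @param store kinase [embedding_store()].
#' @param kinases kinase tibble or `phospho_dataset` supplying annotations.
#' @inheritParams encode_kinases
#' @return a new `embedding_store` with augmented vectors.
#' @export
augment_store <- function(store, kinases, vocab = NULL, use_family = FALSE,
                          use_group = FALSE, use_ec = FALSE) {
  if (inherits(kinases, "phospho_dataset")) kinases <- kinases$kinases
  if (is.null(vocab)) vocab <- annotation_vocab(kinases)
  ids <- rownames(store$vectors)
  rows <- match(ids, kinases$kinase_id)
  if (anyNA(rows)) abort("store identifiers missing from kinase table.")
  vecs <- lapply(seq_along(ids), function(i) {
    augment_kinase_vector(store$vectors[i, ], kinases[rows[i], ], vocab,
                          use_family = use_family, use_group = use_group,
                          use_ec = use_ec)
  })
  m <- do.call(rbind, vecs)
  rownames(m) <- ids
  embedding_store(m)
}
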