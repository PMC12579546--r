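# Pairwise global alignment identity and single-linkage identity clustering.
#
# Identity is the leakage-relevant quantity: two kinase domains with >= 90%
# identity must never end up on opposite sides of a zero-shot split.

#' Default global-alignment scoring
#'
#' Needleman–Wunsch with BLOSUM62 substitution scores, gap opening 10 and gap
#' extension 0.5 (the EMBOSS needle defaults).
#'
#' @param matrix substitution matrix name (passed to Biostrings).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return a named list used by [pairwise_identity()].
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

get_sub_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Sequence identity after pairwise global alignment
#'
#' Aligns two amino-acid sequences end to end under the configured scoring
#' and returns the fraction of alignment columns (gap columns included in the
#' denominator) in which the aligned residues are identical.
#'
#' @param seq_a,seq_b amino-acid sequences (single strings).
#' @param scoring output of [alignment_scoring()].
#' @return identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("PEPTIDE", "PEPTIDE")   # 1
#' pairwise_identity("PEPTIDE", "PEPTIDA")   # 6/7
pairwise_identity <- function(seq_a, seq_b, scoring = alignment_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty.")
  sub <- get_sub_matrix(scoring$matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = sub, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "global")
  aln_identity(aln, nchar(seq_a), nchar(seq_b))
}

# identical columns over the full alignment length, terminal gaps included.
# Every alignment column consumes a residue of a, of b, or of both, so
# length = nchar(a) + nchar(b) - (matches + mismatches).
aln_identity <- function(aln, len_a, len_b) {
  both <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  Biostrings::nmatch(aln) / (len_a + len_b - both)
}

#' All-vs-all identity matrix for a kinase table
#'
#' @param kinases tibble with `kinase_id` and `domain_sequence` (or a
#'   `phospho_dataset`).
#' @param scoring output of [alignment_scoring()].
#' @return symmetric numeric matrix with kinase ids as dimnames; unit
#'   diagonal.
#' @export
identity_matrix <- function(kinases, scoring = alignment_scoring()) {
  if (inherits(kinases, "phospho_dataset")) kinases <- kinases$kinases
  ids <- kinases$kinase_id
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  sub <- get_sub_matrix(scoring$matrix)
  seqs <- Biostrings::AAStringSet(setNames(kinases$domain_sequence, ids))
  for (j in 2:n) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[seq_len(j - 1L)], seqs[[j]],
      substitutionMatrix = sub, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, type = "global")
    p <- aln_identity(aln, Biostrings::width(seqs)[seq_len(j - 1L)],
                      Biostrings::width(seqs)[j])
    m[seq_len(j - 1L), j] <- p
    m[j, seq_len(j - 1L)] <- p
  }
  m
}

#' Single-linkage clustering of kinases by sequence identity
#'
#' Builds the graph whose edges connect kinase pairs with identity at or above
#' `threshold` and returns its connected components (single linkage): every
#' kinase belongs to exactly one cluster, and any chain of high-identity pairs
#' is merged transitively.
#'
#' @param kinases kinase tibble or `phospho_dataset`.
#' @param threshold identity threshold in `(0, 1]` (default 0.90).
#' @param id_matrix optional precomputed [identity_matrix()] (avoids
#'   realignment).
#' @param scoring alignment scoring used when `id_matrix` is `NULL`.
#' @return tibble with `kinase_id` and integer `cluster`; cluster ids are
#'   dense and ordered by first appearance.
#' @export
cluster_by_identity <- function(kinases, threshold = 0.90, id_matrix = NULL,
                                scoring = alignment_scoring()) {
  if (inherits(kinases, "phospho_dataset")) kinases <- kinases$kinases
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  if (is.null(id_matrix)) id_matrix <- identity_matrix(kinases, scoring)
  ids <- kinases$kinase_id
  n <- length(ids)
  # union-find over the thresholded graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (id_matrix[ids[i], ids[j]] >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble(kinase_id = ids, cluster = as.integer(factor(roots, levels = unique(roots))))
}
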