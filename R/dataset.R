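# Dataset model: kinase tables, phosphosite tables, association pairs.
#
# Conventions: 1-based site positions (UniProt style); phosphosite windows are
# odd-length strings with the phosphoacceptor at the centre; the pad character
# defaults to "_" and may only appear as a contiguous prefix and/or suffix.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

GROUP_SENTINEL <- "Other2"
FAMILY_SENTINEL <- "otherFamily"

#' Amino-acid alphabets used by the encoders
#'
#' Kinase domain sequences use the 20 canonical residues plus the ambiguity
#' code `X` (21 symbols). Phosphosite windows additionally admit a pad
#' character (22 symbols) so that windows near a protein terminus stay
#' centred on the phosphoacceptor.
#'
#' @param include_x include the ambiguity code `X`.
#' @param pad_char pad character to append, or `NULL` for none.
#' @return character vector of single-letter symbols.
#' @export
#' @examples
#' aa_alphabet()                  # 21 symbols, domains
#' aa_alphabet(pad_char = "_")    # 22 symbols, windows
aa_alphabet <- function(include_x = TRUE, pad_char = NULL) {
  out <- AA20
  if (include_x) out <- c(out, "X")
  if (!is.null(pad_char)) {
    stopifnot(is.character(pad_char), nchar(pad_char) == 1L)
    out <- c(out, pad_char)
  }
  out
}

#' Extract a centred phosphosite window from a substrate sequence
#'
#' Returns the subsequence of length `2 * flank + 1` centred on `position`,
#' padding with `pad_char` where the window runs past either terminus so the
#' phosphoacceptor always sits at the centre (index `flank + 1`).
#'
#' @param sequence substrate amino-acid sequence (single string).
#' @param position 1-based position of the phosphoacceptor residue.
#' @param flank number of residues kept on each side (default 7, i.e. 15-mers).
#' @param pad_char single pad character (default `"_"`).
#' @return a string of length `2 * flank + 1`.
#' @export
#' @examples
#' extract_window("ACDEFGHIKLMNPQR", 8)      # the full 15-mer
#' extract_window("ACDEFG", 1)               # padded on both sides
extract_window <- function(sequence, position, flank = 7L, pad_char = "_") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) abort("`sequence` must be non-empty.")
  position <- as.integer(position)
  flank <- as.integer(flank)
  if (flank < 0L) abort("`flank` must be >= 0.")
  if (is.na(position) || position < 1L || position > n) {
    abort(sprintf("`position` (%s) outside sequence of length %d.", position, n))
  }
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(lo, 1L), min(hi, n))
  left <- strrep(pad_char, max(0L, 1L - lo))
  right <- strrep(pad_char, max(0L, hi - n))
  paste0(left, core, right)
}

#' Compose the canonical site identifier
#'
#' Site identifiers are `"<substrate_id>_<position>"`.
#'
#' @param substrate_id substrate accession.
#' @param position 1-based phosphosite position.
#' @return character vector of site ids.
#' @export
make_site_id <- function(substrate_id, position) {
  paste0(substrate_id, "_", as.integer(position))
}

split_ec <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
}

join_ec <- function(x) {
  vapply(x, function(s) paste(s, collapse = ","), character(1))
}

#' Assemble and validate a phosphosite benchmark dataset
#'
#' Bundles a kinase table, a phosphosite table and an association pair list
#' into a validated `phospho_dataset`. All cross-references must resolve:
#' every pair names an existing site and kinase. Pair order is preserved and
#' duplicate pairs are rejected.
#'
#' @param kinases tibble with columns `kinase_id`, `domain_sequence`, `group`,
#'   `family`, and `ec_classes` (list of character vectors) or `ec`
#'   (comma-joined string).
#' @param sites tibble with columns `site_id`, `substrate_id`, `position`,
#'   `residue`, `window`.
#' @param pairs tibble with columns `site_id`, `kinase_id`.
#' @param pad_char pad character expected in windows.
#' @return an object of class `phospho_dataset`: a list with tibbles
#'   `kinases`, `sites`, `pairs`.
#' @export
phospho_dataset <- function(kinases, sites, pairs, pad_char = "_") {
  kinases <- as_tibble(kinases)
  sites <- as_tibble(sites)
  pairs <- as_tibble(pairs)

  if (!"ec_classes" %in% names(kinases)) {
    kinases$ec_classes <- split_ec(kinases$ec %||% rep("", nrow(kinases)))
  }
  kinases$ec <- NULL
  req_k <- c("kinase_id", "domain_sequence", "group", "family", "ec_classes")
  req_s <- c("site_id", "substrate_id", "position", "residue", "window")
  if (!all(req_k %in% names(kinases))) {
    abort(paste0("kinase table must have columns: ", paste(req_k, collapse = ", ")))
  }
  if (!all(req_s %in% names(sites))) {
    abort(paste0("site table must have columns: ", paste(req_s, collapse = ", ")))
  }
  if (!all(c("site_id", "kinase_id") %in% names(pairs))) {
    abort("pair table must have columns: site_id, kinase_id")
  }
  kinases <- kinases[, req_k]
  sites <- sites[, req_s]
  sites$position <- as.integer(sites$position)
  pairs <- pairs[, c("site_id", "kinase_id")]

  if (anyDuplicated(kinases$kinase_id)) abort("duplicate kinase_id in kinase table.")
  if (anyDuplicated(sites$site_id)) abort("duplicate site_id in site table.")
  if (any(!nzchar(kinases$domain_sequence))) abort("empty domain_sequence.")
  bad_seq <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", kinases$domain_sequence)
  if (any(bad_seq)) {
    abort(sprintf("domain_sequence outside the amino-acid alphabet for: %s",
                  paste(head(kinases$kinase_id[bad_seq], 5), collapse = ", ")))
  }
  kinases$group[is.na(kinases$group) | !nzchar(kinases$group)] <- GROUP_SENTINEL
  kinases$family[is.na(kinases$family) | !nzchar(kinases$family)] <- FAMILY_SENTINEL

  wlen <- nchar(sites$window)
  if (length(wlen) && length(unique(wlen)) > 1L) {
    abort("phosphosite windows have inconsistent lengths.")
  }
  if (length(wlen) && wlen[1] %% 2L == 0L) abort("window length must be odd.")
  if (nrow(sites)) {
    centre <- (wlen[1] + 1L) %/% 2L
    mid <- substr(sites$window, centre, centre)
    bad <- mid != sites$residue
    if (any(bad)) {
      abort(sprintf("window centre does not match residue for site(s): %s",
                    paste(head(sites$site_id[bad], 5), collapse = ", ")))
    }
    if (!all(sites$residue %in% c("S", "T", "Y"))) {
      abort("phosphosite residue must be one of S, T, Y.")
    }
    pad_re <- gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", pad_char)
    # strip pads from both ends; none may remain in the interior
    stripped <- gsub(paste0("^", pad_re, "+|", pad_re, "+$"), "", sites$window)
    if (any(grepl(pad_re, stripped))) {
      abort("pad characters must form a contiguous prefix and/or suffix.")
    }
  }

  dup <- duplicated(paste(pairs$site_id, pairs$kinase_id, sep = "\r"))
  if (any(dup)) abort("duplicate (site_id, kinase_id) pairs.")
  miss_k <- setdiff(pairs$kinase_id, kinases$kinase_id)
  if (length(miss_k)) {
    abort(sprintf("pair rows reference unknown kinase(s): %s",
                  paste(head(miss_k, 5), collapse = ", ")))
  }
  miss_s <- setdiff(pairs$site_id, sites$site_id)
  if (length(miss_s)) {
    abort(sprintf("pair rows reference unknown site(s): %s",
                  paste(head(miss_s, 5), collapse = ", ")))
  }

  structure(list(kinases = kinases, sites = sites, pairs = pairs,
                 pad_char = pad_char),
            class = "phospho_dataset")
}

#' @export
print.phospho_dataset <- function(x, ...) {
  cat(sprintf("<phospho_dataset> %d kinases, %d sites, %d pairs\n",
              nrow(x$kinases), nrow(x$sites), nrow(x$pairs)))
  cat(sprintf("  groups: %s\n", paste(sort(unique(x$kinases$group)), collapse = ", ")))
  invisible(x)
}

#' Site label sets derived from an association pair list
#'
#' @param pairs tibble with `site_id`, `kinase_id` (or a `phospho_dataset`).
#' @return named list mapping each site id to the character vector of its
#'   associated kinase ids (in pair order).
#' @export
site_labels <- function(pairs) {
  if (inherits(pairs, "phospho_dataset")) pairs <- pairs$pairs
  split(pairs$kinase_id, factor(pairs$site_id, levels = unique(pairs$site_id)))
}

#' Read a phosphosite benchmark dataset from TSV files
#'
#' Expects UTF-8 tab-separated files with header rows:
#' `kinases.tsv` (`kinase_id`, `domain_sequence`, `group`, `family`, `ec`
#' comma-joined), `sites.tsv` (`site_id`, `substrate_id`, `position`,
#' `residue`, `window`) and `pairs.tsv` (`site_id`, `kinase_id`). Optionally a
#' FASTA file of full substrate sequences can be supplied to (re)derive the
#' windows; sites whose substrate is present are re-windowed from sequence.
#'
#' @param kinase_path,site_path,pairs_path paths to the three TSV files.
#' @param fasta_path optional FASTA of substrate sequences.
#' @param pad_char pad character for windows.
#' @return a [phospho_dataset()].
#' @export
read_dataset <- function(kinase_path, site_path, pairs_path,
                         fasta_path = NULL, pad_char = "_") {
  kin <- readr::read_tsv(kinase_path, col_types = readr::cols(.default = "c"))
  sit <- readr::read_tsv(site_path, col_types = readr::cols(
    site_id = "c", substrate_id = "c", position = "i", residue = "c", window = "c"))
  prs <- readr::read_tsv(pairs_path, col_types = readr::cols(.default = "c"))
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readAAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    have <- sit$substrate_id %in% names(seqs)
    if (any(have)) {
      flank <- (nchar(sit$window[1]) - 1L) %/% 2L
      sit$window[have] <- mapply(function(sub, pos) {
        extract_window(as.character(seqs[[sub]]), pos, flank = flank,
                       pad_char = pad_char)
      }, sit$substrate_id[have], sit$position[have])
    }
  }
  phospho_dataset(kin, sit, prs, pad_char = pad_char)
}

#' Write a phosphosite benchmark dataset as TSV files
#'
#' Inverse of [read_dataset()]: emits `kinases.tsv`, `sites.tsv` and
#' `pairs.tsv` under `dir`. Round-tripping preserves record fields and the
#' pair list byte for byte.
#'
#' @param dataset a `phospho_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phospho_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kin <- dataset$kinases
  kin$ec <- join_ec(kin$ec_classes)
  kin$ec_classes <- NULL
  readr::write_tsv(kin, file.path(dir, "kinases.tsv"))
  readr::write_tsv(dataset$sites, file.path(dir, "sites.tsv"))
  readr::write_tsv(dataset$pairs, file.path(dir, "pairs.tsv"))
  invisible(dir)
}

#' Per-kinase association counts
#'
#' @param dataset a `phospho_dataset`.
#' @return tibble with `kinase_id`, `group`, `family`, `n_pairs`, sorted by
#'   decreasing `n_pairs`.
#' @export
kinase_pair_counts <- function(dataset) {
  stopifnot(inherits(dataset, "phospho_dataset"))
  dataset$kinases |>
    dplyr::select("kinase_id", "group", "family") |>
    left_join(count(dataset$pairs, .data$kinase_id, name = "n_pairs"),
              by = "kinase_id") |>
    mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L)) |>
    arrange(dplyr::desc(.data$n_pairs), .data$kinase_id)
}
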