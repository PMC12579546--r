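# Embedding stores: identifier-keyed fixed-dimension vectors, plus
# token-level matrices (one row per sequence token) awaiting pooling.

#' Construct an embedding store
#'
#' An embedding store maps identifiers (site ids or kinase ids) to real
#' vectors of a common dimension. Internally a numeric matrix with the
#' identifiers as rownames.
#'
#' @param vectors numeric matrix with identifier rownames, or a data frame /
#'   tibble whose first column (`id`) holds identifiers and remaining columns
#'   the coordinates.
#' @return an `embedding_store`.
#' @export
embedding_store <- function(vectors) {
  if (is.data.frame(vectors)) {
    ids <- as.character(vectors[[1]])
    m <- as.matrix(vectors[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    vectors <- m
  }
  stopifnot(is.matrix(vectors), is.numeric(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) abort("duplicate identifiers in store.")
  if (anyNA(vectors)) abort("embedding store contains NA values.")
  structure(list(dim = ncol(vectors), vectors = vectors), class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> %d identifiers x %d dims\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @method as_tibble embedding_store
#' @export
as_tibble.embedding_store <- function(x, ...) {
  out <- as_tibble(x$vectors, .name_repair = "minimal")
  names(out) <- paste0("V", seq_len(ncol(out)))
  dplyr::bind_cols(tibble(id = rownames(x$vectors)), out)
}

#' Look up vectors in an embedding store
#'
#' @param store an [embedding_store()].
#' @param ids identifiers to fetch.
#' @return numeric matrix (`length(ids)` rows) in the order of `ids`.
#' @export
store_vectors <- function(store, ids) {
  missing <- setdiff(ids, rownames(store$vectors))
  if (length(missing)) {
    abort(sprintf("identifiers missing from embedding store: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  store$vectors[ids, , drop = FALSE]
}

#' Read / write an embedding store as TSV
#'
#' The file format is a header row `id  V1 ... Vd` followed by one row per
#' identifier.
#'
#' @param path TSV file path.
#' @return [read_embedding_store()] returns an `embedding_store`;
#'   `write_embedding_store()` returns `path` invisibly.
#' @export
read_embedding_store <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", .default = "d"))
  embedding_store(tb)
}

#' @rdname read_embedding_store
#' @param store an `embedding_store`.
#' @export
write_embedding_store <- function(store, path) {
  readr::write_tsv(as_tibble(store), path)
  invisible(path)
}

#' Pool a token-level embedding matrix into a single vector
#'
#' `avg` pooling takes the column-wise mean over non-pad rows; `cls` pooling
#' returns the row at the classification-token position verbatim.
#'
#' @param token_matrix numeric matrix, one row per token.
#' @param pad_mask logical vector, `TRUE` where the row is a PAD token.
#' @param mode `"avg"` or `"cls"`.
#' @param cls_index row index of the CLS token (default 1).
#' @return numeric vector of length `ncol(token_matrix)`.
#' @export
pool_tokens <- function(token_matrix, pad_mask = NULL,
                        mode = c("avg", "cls"), cls_index = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(token_matrix), nrow(token_matrix) >= 1L)
  if (is.null(pad_mask)) pad_mask <- rep(FALSE, nrow(token_matrix))
  if (length(pad_mask) != nrow(token_matrix)) {
    abort("`pad_mask` length must equal the number of token rows.")
  }
  if (mode == "cls") {
    if (cls_index < 1L || cls_index > nrow(token_matrix)) {
      abort("`cls_index` outside the token matrix.")
    }
    return(token_matrix[cls_index, ])
  }
  keep <- !pad_mask
  if (!any(keep)) abort("all token rows are masked; nothing to average.")
  colMeans(token_matrix[keep, , drop = FALSE])
}

#' Read a token-level embedding store from long-format TSV
#'
#' One row per (identifier, token): columns `id`, `token` (1-based index),
#' `is_pad` (0/1), `is_cls` (0/1, at most one per identifier), then `V1..Vd`.
#'
#' @param path TSV file path.
#' @return a named list: per identifier a list with `matrix`, `pad_mask`,
#'   `cls_index` (`NA` when no CLS row is present).
#' @export
read_token_store <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", token = "i", is_pad = "i", is_cls = "i", .default = "d"))
  vcols <- setdiff(names(tb), c("id", "token", "is_pad", "is_cls"))
  out <- lapply(split(tb, factor(tb$id, levels = unique(tb$id))), function(d) {
    d <- d[order(d$token), ]
    ci <- which(d$is_cls == 1L)
    list(matrix = as.matrix(d[, vcols]),
         pad_mask = d$is_pad == 1L,
         cls_index = if (length(ci)) ci[1] else NA_integer_)
  })
  out
}

#' Pool a whole token store into an embedding store
#'
#' @param token_store output of [read_token_store()].
#' @param mode `"avg"` or `"cls"`; `"cls"` requires a CLS row for every
#'   identifier.
#' @return an [embedding_store()].
#' @export
pool_token_store <- function(token_store, mode = c("avg", "cls")) {
  mode <- match.arg(mode)
  vecs <- lapply(names(token_store), function(id) {
    e <- token_store[[id]]
    if (mode == "cls" && is.na(e$cls_index)) {
      abort(sprintf("identifier %s has no CLS row.", id))
    }
    pool_tokens(e$matrix, e$pad_mask, mode = mode,
                cls_index = if (is.na(e$cls_index)) 1L else e$cls_index)
  })
  m <- do.call(rbind, vecs)
  rownames(m) <- names(token_store)
  embedding_store(m)
}
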