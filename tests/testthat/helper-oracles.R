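# Independent oracles, deliberately implemented by different means than the
# package code paths they check.

# --- Needleman-Wunsch / Gotoh affine-gap global alignment ------------------
# Returns list(score, n_identical, aln_length). Gap of length L costs
# open + ext * L. Traceback prefers match, then gap-in-b, then gap-in-a.
oracle_global_identity <- function(a, b, sub, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub[A[i], B[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback
  i <- n; j <- m
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                        Y[n + 1, m + 1]))]
  ident <- 0L; len <- 0L
  tol <- 1e-9
  while (i > 0 || j > 0) {
    len <- len + 1L
    if (state == "M") {
      if (A[i] == B[j]) ident <- ident + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which(abs(prev + sub[A[i], B[j]] -
                                            M[i + 1, j + 1]) < tol)[1]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      cand <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                Y[i, j + 1] - open - ext)
      state <- c("M", "X", "Y")[which(abs(cand - X[i + 1, j + 1]) < tol)[1]]
      i <- i - 1L
    } else {
      cand <- c(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                X[i + 1, j] - open - ext)
      state <- c("M", "Y", "X")[which(abs(cand - Y[i + 1, j + 1]) < tol)[1]]
      j <- j - 1L
    }
  }
  list(score = score, n_identical = ident, aln_length = len,
       identity = ident / len)
}

oracle_blosum62 <- function() {
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
}

# --- counting-based (sort-free) average precision --------------------------
# rank = 1 + (#items with strictly larger score) + (#earlier items tied);
# precision at a positive = (#positives with rank <= its rank) / its rank.
bf_average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels)) return(NA_real_)
  n <- length(scores)
  ranks <- vapply(seq_len(n), function(i) {
    1L + sum(scores > scores[i]) +
      (if (i > 1L) sum(scores[seq_len(i - 1L)] == scores[i]) else 0L)
  }, integer(1))
  mean(vapply(which(labels), function(i) {
    sum(labels & ranks <= ranks[i]) / ranks[i]
  }, numeric(1)))
}

bf_macro_ap <- function(S, L) {
  ap <- vapply(seq_len(ncol(S)), function(j) bf_average_precision(S[, j], L[, j]),
               numeric(1))
  mean(ap, na.rm = TRUE)
}

bf_phosphosite_ap <- function(S, L) {
  ap <- vapply(seq_len(nrow(S)), function(i) bf_average_precision(S[i, ], L[i, ]),
               numeric(1))
  mean(ap, na.rm = TRUE)
}

bf_aggregated_ap <- function(S, L, mapping, agg = "max") {
  classes <- unique(unname(mapping[colnames(S)]))
  Sc <- matrix(0, nrow(S), length(classes), dimnames = list(rownames(S), classes))
  Lc <- matrix(FALSE, nrow(S), length(classes), dimnames = list(rownames(S), classes))
  for (ci in seq_along(classes)) {
    member <- which(mapping[colnames(S)] == classes[ci])
    for (i in seq_len(nrow(S))) {
      v <- S[i, member]
      Sc[i, ci] <- if (agg == "max") max(v) else sum(v)
      Lc[i, ci] <- any(L[i, member])
    }
  }
  bf_macro_ap(Sc, Lc)
}

bf_masked_group_ap <- function(S, L, groups) {
  S2 <- S
  for (i in seq_len(nrow(S))) {
    allowed <- unique(groups[colnames(S)[L[i, ]]])
    S2[i, !(groups[colnames(S)] %in% allowed)] <- -Inf
  }
  bf_macro_ap(S2, L)
}

bf_hit_at_k <- function(S, L, k) {
  hits <- vapply(seq_len(nrow(S)), function(i) {
    ranks <- vapply(seq_len(ncol(S)), function(j) {
      1L + sum(S[i, ] > S[i, j]) +
        (if (j > 1L) sum(S[i, seq_len(j - 1L)] == S[i, j]) else 0L)
    }, integer(1))
    any(ranks[L[i, ]] <= k)
  }, logical(1))
  mean(hits)
}

# --- brute-force zero-shot k-NN --------------------------------------------
bf_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

bf_knn_scores <- function(site_vec, train_pairs, site_vecs, kin_vecs,
                          dark_ids, k) {
  sims <- vapply(seq_len(nrow(train_pairs)), function(i) {
    bf_cosine(site_vec, site_vecs[train_pairs$site_id[i], ])
  }, numeric(1))
  pos <- vapply(seq_along(sims), function(i) {
    1L + sum(sims > sims[i]) +
      (if (i > 1L) sum(sims[seq_len(i - 1L)] == sims[i]) else 0L)
  }, integer(1))
  nb <- which(pos <= k)
  labs <- train_pairs$kinase_id[nb]
  cnt <- table(labs)
  winners <- names(cnt)[cnt == max(cnt)]
  light <- if (length(winners) == 1L) winners else train_pairs$kinase_id[pos == 1L][1]
  vapply(dark_ids, function(d) bf_cosine(kin_vecs[light, ], kin_vecs[d, ]),
         numeric(1))
}

# --- exhaustive permutations (small n) -------------------------------------
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}
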