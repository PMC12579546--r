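test_that("one-hot encoding produces indicators and pooled frequencies", {
  v <- one_hot_encode("A", pooled = FALSE)
  expect_identical(sum(v), 1)
  expect_identical(v[1], 1)                       # A is first in the alphabet
  w <- strrep("A", 7) |> paste0("S", strrep("C", 7))
  vw <- one_hot_encode(w, pooled = FALSE)
  expect_identical(length(vw), 15L * 22L)
  expect_identical(sum(vw), 15)                   # one indicator per position
  p <- one_hot_encode("AAC", pooled = TRUE)
  expect_equal(p[1], 2 / 3)
  expect_equal(p[2], 1 / 3)                       # C is second
  expect_equal(sum(p), 1)
  expect_error(one_hot_encode("AB1", pooled = FALSE), "outside alphabet")
})

test_that("pooled one-hot encodings lie on the probability simplex", {
  set.seed(31)
  aa <- aa_alphabet()
  for (rep in 1:20) {
    s <- paste(sample(aa, sample(5:60, 1), TRUE), collapse = "")
    p <- one_hot_encode(s, pooled = TRUE)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("BLOSUM62 encoding uses substitution rows and zero pads", {
  v <- blosum62_encode("A", pooled = FALSE)
  expect_identical(length(v), 20L)
  expect_identical(v[1], 4)                       # BLOSUM62[A, A] = 4
  expect_identical(unname(blosum62_encode(strrep("_", 15))),
                   rep(0, 15 * 20))               # all-pad window
  expect_identical(blosum62_encode("MKLS"), blosum62_encode("MKLS"))
})

test_that("NLF encoding has the contracted shape and order-invariant pooling", {
  tab <- nlf_table()
  expect_identical(ncol(tab), 18L)
  w <- paste0("ACDEFGH", "S", "IKLMNPQ")
  v <- nlf_encode(w)
  expect_identical(length(v), 15L * 18L)
  # same residue at two positions -> identical row blocks
  v2 <- nlf_encode("AA")
  expect_identical(v2[1:18], v2[19:36])
  # reversal permutes blocks but leaves the pooled average unchanged
  wr <- paste(rev(strsplit(w, "")[[1]]), collapse = "")
  expect_equal(nlf_encode(w, pooled = TRUE), nlf_encode(wr, pooled = TRUE),
               tolerance = 1e-12)
})

test_that("ProtVec encoding averages overlapping 3-gram vectors", {
  trig <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("ACD", "CDE"), NULL))
  expect_equal(unname(protvec_encode("ACD", trig)), c(1, 3))
  expect_equal(unname(protvec_encode("ACDE", trig)), c(1.5, 3.5))  # mean(ACD, CDE)
  expect_equal(unname(protvec_encode("WWWW", trig)), c(0, 0))      # all OOV
  expect_error(protvec_encode("AC", trig), "shorter")
})

test_that("token pooling averages non-pad rows and returns the CLS row verbatim", {
  m <- rbind(c(1, 1), c(3, 3))
  expect_equal(pool_tokens(m, c(FALSE, FALSE), mode = "avg"), c(2, 2))
  expect_equal(pool_tokens(m, c(FALSE, TRUE), mode = "avg"), c(1, 1))
  expect_equal(pool_tokens(m, mode = "cls", cls_index = 1), c(1, 1))
  # cls ignores every other row; avg ignores masked values entirely
  m2 <- rbind(c(1, 1), c(999, -999))
  expect_equal(pool_tokens(m2, c(FALSE, TRUE), mode = "avg"),
               pool_tokens(rbind(c(1, 1), c(0, 0)), c(FALSE, TRUE), mode = "avg"))
  expect_error(pool_tokens(m, c(TRUE, TRUE), mode = "avg"), "masked")
})

test_that("annotation augmentation appends one-hot/multi-hot blocks", {
  kin <- tiny_kinases()
  vocab <- annotation_vocab(kin)
  vec <- c(0.5, -1)
  rec <- kin[1, ]
  expect_identical(augment_kinase_vector(vec, rec, vocab), vec)  # all flags off
  g <- augment_kinase_vector(vec, rec, vocab, use_group = TRUE)
  expect_identical(length(g), 2L + length(vocab$groups))
  expect_identical(g[1:2], vec)
  expect_identical(sum(g[-(1:2)]), 1)
  expect_identical(which(g[-(1:2)] == 1), which(vocab$groups == "CMGC"))
  full <- augment_kinase_vector(vec, rec, vocab, use_family = TRUE,
                                use_group = TRUE, use_ec = TRUE)
  expect_identical(length(full), 2L + length(vocab$families) +
                     length(vocab$groups) + length(vocab$ec_classes))
  # EC block is multi-hot and empty EC sets encode as zeros
  ec_only <- augment_kinase_vector(vec, kin[2, ], vocab, use_ec = TRUE)
  expect_identical(sum(ec_only[-(1:2)]), 0)
})

test_that("the sentinel labels are always in the vocabulary", {
  vocab <- annotation_vocab(tiny_kinases())
  expect_true("Other2" %in% vocab$groups)
  expect_true("otherFamily" %in% vocab$families)
})

test_that("embedding stores round-trip through TSV and resolve lookups", {
  m <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL))
  st <- embedding_store(m)
  expect_identical(st$dim, 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_store(st, path)
  back <- read_embedding_store(path)
  expect_equal(store_vectors(back, c("b", "a")),
               st$vectors[c("b", "a"), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(store_vectors(st, "ghost"), "missing")
})

test_that("token stores read from long TSV and pool per identifier", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    id = c("p1", "p1", "p1", "p2", "p2"),
    token = c(1L, 2L, 3L, 1L, 2L),
    is_pad = c(0L, 0L, 1L, 0L, 0L),
    is_cls = c(1L, 0L, 0L, 0L, 0L),
    V1 = c(9, 1, 100, 2, 4), V2 = c(9, 3, 100, 2, 0)), path)
  ts <- read_token_store(path)
  avg <- pool_token_store(ts, mode = "avg")
  expect_equal(unname(store_vectors(avg, "p1")[1, ]), c(5, 6))   # pad excluded
  expect_equal(unname(store_vectors(avg, "p2")[1, ]), c(3, 1))
  cls <- pool_tokens(ts$p1$matrix, ts$p1$pad_mask, "cls", ts$p1$cls_index)
  expect_equal(unname(cls), c(9, 9))
  expect_error(pool_token_store(ts, mode = "cls"), "no CLS")     # p2 lacks CLS
})

test_that("site and kinase encoders assemble stores with consistent dims", {
  ds <- tiny_dataset()
  ss <- encode_sites(ds, "blosum62")
  expect_identical(ss$dim, 15L * 20L)
  expect_setequal(rownames(ss$vectors), ds$sites$site_id)
  ks <- encode_kinases(ds, "onehot", use_family = TRUE, use_group = TRUE,
                       use_ec = TRUE)
  vocab <- annotation_vocab(ds)
  expect_identical(ks$dim, 21L + length(vocab$families) +
                     length(vocab$groups) + length(vocab$ec_classes))
  # augmentation never touches the leading coordinates
  base <- encode_kinases(ds, "onehot")
  expect_equal(ks$vectors[, 1:21], base$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
})
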