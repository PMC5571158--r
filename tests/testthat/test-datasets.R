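make_recs <- function(seqs, ...) hairpin_records(seqs, ...)

test_that("identical-sequence removal keeps the first occurrence", {
  r <- make_recs(c("ACGUACGU", "ACGUACGU", "GGGCCCAA"),
                 id = c("a", "b", "c"))
  d <- dedup_identical(r)
  expect_equal(d$id, c("a", "c"))
  u <- make_recs(c("AAAAC", "CCCCA"))
  expect_identical(dedup_identical(u), u)
  expect_equal(nrow(dedup_identical(u[0, ])), 0L)
})

test_that("length filtering uses inclusive 36/180 bounds", {
  lens <- c(35, 36, 100, 180, 181)
  r <- make_recs(vapply(lens, function(L) strrep("A", L), ""))
  kept <- filter_by_length(r)
  expect_equal(nchar(kept$seq), c(36, 100, 180))
  expect_error(filter_by_length(r, 100, 50), "exceeds")
})

test_that("RPM filtering keeps >= 100 and reports records missing metadata", {
  r <- make_recs(c("ACGUA", "CCGUA", "GCGUA"), rpm = c(100, 99.9, 1000))
  expect_equal(filter_by_rpm(r)$rpm, c(100, 1000))
  r2 <- make_recs(c("ACGUA", "CCGUA"), id = c("x", "y"),
                  rpm = c(50, NA))
  expect_error(filter_by_rpm(r2), "y")
  expect_equal(nrow(filter_by_rpm(r[0, ])), 0L)
})

test_that("shuffling preserves every residue multiset and is seed-driven", {
  hp <- make_hairpin_sequences(25, 0, seed = 4)$positive
  s1 <- make_shuffled(hp, seed = 10)
  s2 <- make_shuffled(hp, seed = 10)
  s3 <- make_shuffled(hp, seed = 11)
  expect_identical(s1$seq, s2$seq)
  expect_false(identical(s1$seq, s3$seq))
  expect_equal(nrow(s1), nrow(hp))
  sorted <- function(x) vapply(strsplit(x, ""),
                               function(s) paste(sort(s), collapse = ""), "")
  expect_identical(sorted(s1$seq), sorted(hp$seq))
  expect_equal(make_shuffled(make_recs("AAAA"), seed = 1)$seq, "AAAA")
  expect_equal(attr(s1, "provenance")$seed, 10)
})

test_that("dinucleotide-mode shuffling preserves dinucleotide counts", {
  hp <- make_hairpin_sequences(10, 0, seed = 6)$positive
  sd <- make_shuffled(hp, seed = 2, mode = "dinucleotide")
  dicounts <- function(x) {
    s <- strsplit(x, "")[[1]]
    sort(table(paste0(s[-length(s)], s[-1])))
  }
  for (k in seq_len(nrow(hp)))
    expect_identical(dicounts(sd$seq[k]), dicounts(hp$seq[k]))
})

test_that("suboptimal-fold decoys keep the sequence but not the optimal fold", {
  hp <- make_hairpin_sequences(15, 0, seed = 8)$positive
  nbf <- make_notbestfold(hp)
  expect_lte(nrow(nbf), nrow(hp))
  expect_identical(nbf$seq, hp$seq[match(sub("_nbf$", "", nbf$id), hp$id)])
  for (k in seq_len(nrow(nbf))) {
    mfe <- fold_rna(nbf$seq[k])
    expect_false(identical(nbf$struct[k], mfe$structure))
    expect_silent(parse_dotbracket(nbf$struct[k]))
  }
  single <- make_notbestfold(make_recs("GGGAAACCC"))
  expect_equal(nrow(parse_dotbracket(single$struct)), 2L)
})

test_that("feature-space sets respect their per-feature intervals and nest", {
  hp <- make_hairpin_sequences(30, 0, seed = 12)$positive
  m <- compute_features(hp)
  n <- 200L
  sets <- lapply(c(FR = "FR", BQ = "BQ", AM = "AM"), function(mode)
    make_feature_space_set(m, mode, n = n, seed = 3))
  for (mode in names(sets)) {
    pv <- attr(sets[[mode]], "provenance")
    expect_equal(nrow(sets[[mode]]), n)
    for (j in seq_len(ncol(m))) {
      expect_true(all(sets[[mode]][, j] >= pv$lo[j] - 1e-12))
      expect_true(all(sets[[mode]][, j] <= pv$hi[j] + 1e-12))
    }
  }
  fr <- attr(sets$FR, "provenance"); bq <- attr(sets$BQ, "provenance")
  am <- attr(sets$AM, "provenance")
  expect_true(all(bq$lo >= fr$lo & bq$hi <= fr$hi))
  expect_true(all(am$lo >= bq$lo & am$hi <= bq$hi))
  # constant input column stays constant
  m2 <- m; m2[, "length"] <- 46
  cst <- make_feature_space_set(m2, "FR", n = 20, seed = 1)
  expect_true(all(cst[, "length"] == 46))
  expect_error(make_feature_space_set(m[0, , drop = FALSE], "FR"), "empty")
  # deterministic under seed
  expect_identical(make_feature_space_set(m, "BQ", n = 50, seed = 9),
                   make_feature_space_set(m, "BQ", n = 50, seed = 9))
})

test_that("the lower-quartile estimator matches linear interpolation", {
  expect_equal(derive_threshold(c(0.8, 0.9, 1.0, 1.0)), 0.875)
  expect_equal(derive_threshold(rep(0.7, 10)), 0.7)
  expect_error(derive_threshold(c(0.9, 0.8)), "at least 4")
  # consistency with the quantile convention used by the BQ constructor
  x <- c(0.1, 0.4, 0.55, 0.62, 0.8, 0.97)
  m <- matrix(x, ncol = 1, dimnames = list(NULL, "f"))
  bq <- attr(make_feature_space_set(m, "BQ", n = 5, seed = 1), "provenance")
  expect_equal(unname(bq$lo), derive_threshold(x))
})
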