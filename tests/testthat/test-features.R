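test_that("sequence composition blocks are normalized and GC is exact", {
  v <- seq_composition("GCGC")
  expect_equal(v[["gc_content"]], 1.0)
  v2 <- seq_composition("AUGC")
  expect_equal(unname(v2[paste0("freq_", c("A", "C", "G", "U"))]),
               rep(0.25, 4))
  expect_equal(seq_composition("AAA")[["di_AA"]], 1.0)
  set.seed(3)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(2:50, 1), replace = TRUE),
               collapse = "")
    v <- seq_composition(s)
    expect_equal(sum(v[1:4]), 1, tolerance = 1e-9)
    expect_equal(sum(v[5:20]), 1, tolerance = 1e-9)
  }
  expect_error(seq_composition("A"), "shorter than 2")
})

test_that("triplet features bin paired status with the center nucleotide", {
  v <- triplet_features("AAAAA", ".....")
  expect_equal(v[["tri_uuu_A"]], 1.0)
  expect_equal(sum(v), 1.0)
  # both bracket characters map to 'paired' before windowing
  left <- triplet_features("ACGU", ".((.")
  right <- triplet_features("ACGU", ".)).")
  expect_identical(left, right)
  expect_error(triplet_features("ACGU", "..."), "lengths differ")
  set.seed(5)
  for (i in 1:10) {
    hp <- fold_rna(paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE),
                         collapse = ""))
    expect_equal(sum(triplet_features(hp$sequence, hp$structure)), 1,
                 tolerance = 1e-9)
  }
})

test_that("structural features count stems, loops and pair types correctly", {
  v <- struct_features("GGGAAACCC", "(((...)))")
  expect_equal(v[["n_bp"]], 3)
  expect_equal(v[["terminal_loop_len"]], 3)
  expect_equal(v[["longest_stack"]], 3)
  expect_equal(v[["n_stems"]], 1)
  expect_equal(v[["dP"]], 3 / 9, tolerance = 1e-12)
  expect_equal(v[["n_pairs_GC"]], 3)
  expect_equal(v[["n_pairs_AU"]], 0)
  expect_equal(v[["n_pairs_GU"]], 0)
  z <- struct_features("AAAA", "....")
  expect_equal(z[["n_bp"]], 0)
  expect_equal(z[["paired_fraction"]], 0)
  # bulged stem: two stacked runs of 2, no >=3-stem
  b <- struct_features("GGAGGAAACCACC", "((.((...)).))")
  expect_equal(b[["longest_stack"]], 2)
  expect_equal(b[["n_stems"]], 0)
  expect_equal(b[["n_loops"]], 3) # bulge, terminal loop, internal-loop side
})

test_that("thermodynamic indices follow their definitions with zero guards", {
  v <- thermo_features(strrep("GC", 50), strrep(".", 100), -20)
  expect_equal(v[["dG"]], -0.2)
  expect_equal(v[["MFEI1"]], -0.2 / 100) # GC% = 100 for a pure-GC sequence
  expect_equal(v[["MFEI4"]], 0) # n_bp = 0 guard
  w <- thermo_features("GGGAAACCC", "(((...)))", -3)
  expect_equal(w[["MFEI1"]], (-3 / 9) / (2 / 3 * 100), tolerance = 1e-12)
  expect_equal(w[["MFEI2"]], (-3 / 9) / 1)
  expect_equal(w[["MFEI4"]], -1)
})

test_that("the registry has at least 70 uniquely named, grouped features", {
  reg <- feature_registry()
  expect_gte(nrow(reg), 70L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_setequal(unique(reg$group), c("SEQ", "TRIPLET", "STRUCT", "THERMO"))
  full <- feature_registry("partition_function")
  expect_true(all(c("mean_bp_prob", "positional_entropy") %in% full$name))
  expect_false(any(full$name[full$group == "PROB"] %in% reg$name))
})

test_that("all 13 study profiles exist with their declared feature counts", {
  prof <- study_profiles()
  expect_length(prof, 13L)
  declared <- vapply(prof, `[[`, 0L, "declared_count")
  expect_equal(unname(declared[c("Xue", "Chen", "Lopes", "Gao")]),
               c(32L, 99L, 13L, 57L))
  reg <- feature_registry()$name
  for (p in prof) {
    expect_true(all(p$feature_names %in% reg))
    expect_false(anyDuplicated(p$feature_names) > 0)
    if (p$count_matches)
      expect_length(p$feature_names, p$declared_count)
  }
  expect_false(prof$Chen$count_matches) # registry smaller than Chen's 99
  expect_length(prof$Xue$feature_names, 32L)
  expect_true(all(grepl("^tri_", prof$Xue$feature_names)))
})

test_that("feature matrices are deterministic, row-aligned and schema-tagged", {
  hp <- make_hairpin_sequences(4, 0, seed = 9)$positive
  m1 <- compute_features(hp)
  m2 <- compute_features(hp)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 4L)
  expect_identical(rownames(m1), hp$id)
  expect_false(anyNA(m1))
  # duplicating a hairpin duplicates its row exactly
  hp2 <- hp; hp2$id <- paste0(hp$id, "_copy")
  both <- rbind(hp, hp2)
  class(both) <- class(hp)
  m3 <- compute_features(both)
  expect_identical(unname(m3[1, ]), unname(m3[5, ]))
  # empty input keeps the full header
  empty <- hp[0, ]
  m0 <- compute_features(empty)
  expect_equal(dim(m0), c(0L, ncol(m1)))
  expect_identical(colnames(m0), colnames(m1))
  # profile order is respected
  mx <- compute_features(hp, profile = study_profiles("Xue")[[1]])
  expect_identical(colnames(mx), study_profiles("Xue")[[1]]$feature_names)
})

test_that("partition-function features are gated, not silently dropped", {
  hp <- make_hairpin_sequences(2, 0, seed = 1)$positive
  expect_error(compute_features(hp, profile = c("gc_content", "mean_bp_prob")),
               "partition-function")
  expect_error(compute_features(hp, profile = "no_such_feature"), "unknown")
})
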