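test_that("performance measures follow their definitions", {
  perfect <- compute_metrics(50, 0, 50, 0)
  expect_equal(perfect[["accuracy"]], 1)
  expect_equal(perfect[["cohens_kappa"]], 1)
  expect_equal(perfect[["youdens_index"]], 1)
  # degenerate all-positive classifier on a balanced set
  deg <- compute_metrics(50, 50, 0, 0)
  expect_equal(deg[["accuracy"]], 0.5)
  expect_equal(deg[["cohens_kappa"]], 0)
  expect_equal(deg[["youdens_index"]], 0)
  expect_equal(deg[["specificity"]], 0)
  # Youden = sensitivity + specificity - 1
  m <- compute_metrics(80, 30, 70, 20)
  expect_equal(m[["youdens_index"]],
               m[["sensitivity"]] + m[["specificity"]] - 1)
  expect_equal(m[["f_measure"]],
               2 / (1 / m[["precision"]] + 1 / m[["recall"]]))
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
  # zero-denominator guard
  g <- compute_metrics(0, 0, 10, 5)
  expect_equal(g[["precision"]], 0)
  expect_true("precision" %in% attr(g, "guarded"))
})

test_that("balanced splits have 70/30 arithmetic, disjointness, determinism", {
  pos <- sprintf("p%02d", 1:10)
  neg <- sprintf("n%02d", 1:30)
  sp <- mccv_split(pos, neg, iteration = 1, seed = 5)
  expect_length(sp$train_pos, 7L)
  expect_length(sp$train_neg, 7L)
  expect_length(sp$test_pos, 3L)
  expect_length(sp$test_neg, 3L)
  train <- c(sp$train_pos, sp$train_neg)
  test <- c(sp$test_pos, sp$test_neg)
  expect_length(intersect(train, test), 0L)
  expect_identical(sp, mccv_split(pos, neg, iteration = 1, seed = 5))
  expect_false(identical(sp, mccv_split(pos, neg, iteration = 2, seed = 5)))
  expect_error(mccv_split(pos, pos[1:5], 1, 1), "insufficient negatives")
})

test_that("every iteration is balanced and disjoint at scale", {
  pos <- sprintf("p%04d", 1:1000)
  neg <- sprintf("n%04d", 1:1500)
  for (it in c(1, 2, 17, 400)) {
    sp <- mccv_split(pos, neg, iteration = it, seed = 99)
    expect_length(sp$train_pos, 700L)
    expect_length(sp$train_neg, 700L)
    expect_length(sp$test_pos, 300L)
    expect_length(sp$test_neg, 300L)
    expect_length(intersect(c(sp$train_pos, sp$train_neg),
                            c(sp$test_pos, sp$test_neg)), 0L)
    expect_false(anyDuplicated(c(sp$train_neg, sp$test_neg)) > 0)
  }
})

sep <- make_separable_features(60, 90, separation = 4, seed = 21)

test_that("MCCV training separates well-separated classes and is reproducible", {
  fit <- hairpin_mccv(sep$positive, sep$negative, profiles = NULL,
                      kinds = c("DT", "NB"), iterations = 8, seed = 3)
  sm <- summary(fit)
  expect_true(all(sm$best_accuracy >= 0.95))
  expect_true(all(sm$iterations_run == 8))
  # metric consistency: accuracy recomputed from confusion counts
  for (h in fit$history) {
    expect_equal(h$accuracy, (h$TP + h$TN) / (h$TP + h$TN + h$FP + h$FN),
                 tolerance = 1e-12)
    expect_equal(nrow(h), 8L)
  }
  fit2 <- hairpin_mccv(sep$positive, sep$negative, profiles = NULL,
                       kinds = c("DT", "NB"), iterations = 8, seed = 3)
  expect_identical(summary(fit2), sm)
  expect_identical(vapply(fit$best, `[[`, 0L, "best_iteration"),
                   vapply(fit2$best, `[[`, 0L, "best_iteration"))
})

test_that("all profiles and kinds receive identical data in each iteration", {
  hp <- make_hairpin_sequences(20, 30, seed = 13)
  pos <- compute_features(hp$positive)
  neg <- compute_features(hp$negative)
  profs <- study_profiles(c("Xue", "Lopes"))
  fit <- hairpin_mccv(pos, neg, profiles = profs, kinds = c("DT", "NB"),
                      iterations = 4, seed = 6)
  # identical split => identical test-set size decomposition per iteration
  for (h in fit$history) {
    expect_equal(h$TP + h$FN, rep(6, 4)) # 30% of 20 positives
    expect_equal(h$TN + h$FP, rep(6, 4))
  }
  # the split stream is profile-independent by construction
  expect_identical(mccv_split(rownames(pos), rownames(neg), 2, 6),
                   mccv_split(rownames(pos), rownames(neg), 2, 6))
})

test_that("stored models round-trip through the JSON envelope", {
  fit <- hairpin_mccv(sep$positive, sep$negative, profiles = NULL,
                      kinds = c("DT", "NB"), iterations = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  fit2 <- load_model(path)
  newdata <- rbind(sep$positive[1:20, ], sep$negative[1:20, ])
  expect_equal(predict(fit2, newdata), predict(fit, newdata))
  expect_identical(fit2$feature_names, fit$feature_names)
  # wrong schema names the missing features
  bad <- newdata[, 1:3]
  expect_error(predict(fit2, bad), "f04")
  # corrupted file is a structured error
  writeLines("{not json", path)
  expect_error(load_model(path), "corrupted")
})

test_that("an SVM kind trains, scores in [0,1] and persists like the others", {
  fit <- hairpin_mccv(sep$positive, sep$negative, profiles = NULL,
                      kinds = "SVM", iterations = 2, seed = 8)
  sc <- predict(fit, sep$negative[1:10, ])
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(summary(fit)$kind, "SVM")
})
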