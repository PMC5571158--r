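test_that("the majority vote fires at seven of thirteen studies", {
  v <- function(n_pos) c(rep(TRUE, n_pos), rep(FALSE, 13 - n_pos))
  expect_equal(consensus_vote(v(7)), "miRNA")
  expect_equal(consensus_vote(v(6)), "negative")
  expect_equal(consensus_vote(v(13)), "miRNA")
  expect_equal(consensus_vote(v(0)), "negative")
  expect_error(consensus_vote(c(v(7), NA)), "missing|expected")
  expect_error(consensus_vote(v(7)[1:12]), "expected 13")
})

test_that("the vote rule agrees with brute force over sampled vote vectors", {
  set.seed(2)
  for (i in 1:500) {
    votes <- stats::runif(13) < 0.5
    expect_equal(consensus_vote(votes),
                 if (sum(votes) >= 7) "miRNA" else "negative")
  }
})

test_that("score averaging labels by the 0.5 boundary, equality inclusive", {
  expect_equal(average_predict(c(0.3, 0.5))$label, "negative")  # mean 0.4
  expect_equal(average_predict(c(0.5, 0.7))$label, "miRNA")     # mean 0.6
  expect_equal(average_predict(c(0.4, 0.6))$label, "miRNA")     # mean exactly 0.5
  expect_equal(average_predict(0.2)$score, 0.2)
  expect_error(average_predict(numeric(0)), "no scores")
  expect_error(average_predict(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("the three-way rule is total with strict 0.89 and 0.5 boundaries", {
  expect_equal(consensus_rule(0.95, 0.20)$label, "miRNA") # miRNA clause first
  expect_true(consensus_rule(0.95, 0.20)$rule_conflict)
  expect_equal(consensus_rule(0.30, 0.30)$label, "negative")
  expect_equal(consensus_rule(0.70, 0.70)$label, "candidate")
  expect_equal(consensus_rule(0.89, 0.89)$label, "candidate") # strict >
  expect_equal(consensus_rule(0.50, 0.50)$label, "candidate") # strict <
  grid <- seq(0, 1, by = 0.05)
  for (a in grid) for (b in grid) {
    lab <- consensus_rule(a, b)$label
    expect_true(lab %in% c("miRNA", "negative", "candidate"))
  }
  expect_error(consensus_rule(1.2, 0.5), "\\[0,1\\]")
})

test_that("rank totals hit their analytic bounds and conserve rank sums", {
  cm <- matrix(c(90, 80, 95, 85), nrow = 2,
               dimnames = list(c("A", "B"), c("d1", "d2")))
  rt <- rank_models(cm)
  expect_equal(rt$total_rank, c(A = 2, B = 4))
  expect_equal(rt$table$model, c("A", "B"))
  # rank conservation under ties
  tied <- matrix(c(90, 90, 80, 70, 70, 70), nrow = 3,
                 dimnames = list(c("x", "y", "z"), c("d1", "d2")))
  rr <- rank_models(tied)
  expect_equal(colSums(rr$ranks), c(d1 = 6, d2 = 6)) # M(M+1)/2 = 6
  expect_error(rank_models(matrix(c(1, NA), 1)), "missing")
})

test_that("ROC/AUC equals the pair-concordance statistic and its bounds", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(T, T, F, F))$auc, 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(T, T, F, F))$auc, 0.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(T, F, T, F))$auc, 0.75)
  # Mann-Whitney equivalence on random score sets, including ties
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))
    truth <- stats::runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    conc <- outer(scores[truth], scores[!truth],
                  function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc_auc(scores, truth)$auc, mean(conc), tolerance = 1e-9)
  }
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- stats::runif(150)
  truth <- stats::runif(150) < 0.4
  ours <- roc_auc(scores, truth)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                           predictor = scores,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("TPR/TNR are percentages of correctly classified hairpins", {
  preds <- c(rep("miRNA", 96), rep("negative", 4))
  expect_equal(tpr_tnr(preds, "positive"), 96)
  expect_equal(tpr_tnr(preds, "negative"), 4)
  expect_equal(tpr_tnr(rep("candidate", 10), "positive"), 0)
  expect_equal(tpr_tnr(rep("miRNA", 5), "positive"), 100)
  expect_error(tpr_tnr(character(0)), "empty")
})

test_that("the MLP meta-model separates synthetic score clouds", {
  set.seed(17)
  n <- 120
  pos <- matrix(stats::runif(n * 4, 0.6, 1), nrow = n,
                dimnames = list(sprintf("p%03d", 1:n), paste0("s", 1:4)))
  neg <- matrix(stats::runif(n * 4, 0, 0.4), nrow = n,
                dimnames = list(sprintf("n%03d", 1:n), paste0("s", 1:4)))
  scores <- rbind(pos, neg)
  labels <- rep(c("positive", "negative"), each = n)
  meta <- consensus_model_train(scores, labels, iterations = 5, seed = 2)
  expect_gte(meta$metrics[["accuracy"]], 0.95)
  pred <- consensus_model_predict(meta, scores)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_gt(mean(pred[1:n]), mean(pred[n + 1:n]))
  meta2 <- consensus_model_train(scores, labels, iterations = 5, seed = 2)
  expect_equal(meta2$metrics, meta$metrics)
  expect_error(consensus_model_train(scores, rep("positive", 2 * n)),
               "both positive and negative")
  expect_error(consensus_model_predict(meta, scores[, 1:2]), "missing score")
})

test_that("ensemble prediction combines all six schemes coherently", {
  sep <- make_separable_features(40, 60, separation = 4, seed = 23)
  fit <- hairpin_mccv(sep$positive, sep$negative, profiles = NULL,
                      kinds = c("DT", "NB"), iterations = 3, seed = 1)
  sc <- predict(fit, rbind(sep$positive[1:5, ], sep$negative[1:5, ]))
  ens <- ensemble_predict(sc, vote_threshold = 1L)
  expect_equal(nrow(ens), 10L)
  expect_true(all(ens$avg_dt >= 0 & ens$avg_dt <= 1))
  expect_true(all(ens$consensus_rule %in% c("miRNA", "negative", "candidate")))
  expect_true(all(ens$average_dt[ens$avg_dt >= 0.5] == "miRNA"))
  expect_true(all(ens$average_dt[ens$avg_dt < 0.5] == "negative"))
})
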