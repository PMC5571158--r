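#' Majority-vote consensus over per-study predictions
#'
#' A hairpin is labeled `"miRNA"` when at least `threshold` of the 13
#' per-study binary predictions (one classifier kind) are positive, else
#' `"negative"`. The default threshold 7 is the majority of 13 studies.
#'
#' @param votes logical (or 0/1) vector, one named vote per study.
#' @param threshold minimum positive votes for a miRNA call.
#' @param n_studies expected vote count; fewer or more is an error (a study
#'   model that failed to load is not silently renormalized).
#' @return `"miRNA"` or `"negative"`.
#' @export
consensus_vote <- function(votes, threshold = 7L, n_studies = 13L) {
  if (anyNA(votes)) stop("missing study vote")
  if (length(votes) != n_studies)
    stop("expected ", n_studies, " study votes, got ", length(votes))
  if (sum(as.logical(votes)) >= threshold) "miRNA" else "negative"
}

#' Score-averaging prediction
#'
#' Averages per-study scores of one classifier kind; a mean below 0.5 is
#' `"negative"`, otherwise (including exactly 0.5) `"miRNA"`.
#'
#' @param scores numeric vector of per-study scores in `[0,1]`.
#' @return list with `score` (the mean) and `label`.
#' @export
average_predict <- function(scores) {
  if (!length(scores)) stop("no scores to average")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  m <- mean(scores)
  list(score = m, label = if (m < 0.5) "negative" else "miRNA")
}

#' Three-way consensus rule on averaged DT and NB scores
#'
#' If either average exceeds 0.89 the hairpin is `"miRNA"`; otherwise if
#' either average is below 0.5 it is `"negative"`; the remainder is
#' `"candidate"`. The miRNA clause is evaluated first, so the (rare) case
#' where one average exceeds 0.89 while the other falls below 0.5 is labeled
#' miRNA and flagged `rule_conflict` for audit.
#'
#' @param avg_dt,avg_nb averaged decision-tree and naive-Bayes scores.
#' @return list with `label` and logical `rule_conflict`.
#' @export
consensus_rule <- function(avg_dt, avg_nb) {
  if (any(c(avg_dt, avg_nb) < 0 | c(avg_dt, avg_nb) > 1))
    stop("average scores must lie in [0,1]")
  hi <- avg_dt > 0.89 || avg_nb > 0.89
  lo <- avg_dt < 0.5 || avg_nb < 0.5
  label <- if (hi) "miRNA" else if (lo) "negative" else "candidate"
  list(label = label, rule_conflict = hi && lo)
}

#' Meta-classifier over per-study scores (ConsensusModel)
#'
#' Trains a single-hidden-layer perceptron on the matrix of per-study
#' scores, following the same balanced Monte Carlo cross-validation
#' procedure as the base classifiers; the iteration with the highest test
#' accuracy (ties: F-measure) is stored. Hidden-layer width equals the
#' input dimension.
#'
#' @param scores numeric matrix, rows = hairpins, columns = per-study scores
#'   in `[0,1]`.
#' @param labels `"positive"`/`"negative"` per row.
#' @param iterations MCCV iterations (default 50).
#' @param seed master seed.
#' @return object of class `consensus_model`.
#' @export
consensus_model_train <- function(scores, labels, iterations = 50L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("need both positive and negative labels to train the meta-model")
  pos <- rownames(scores)[labels == "positive"]
  neg <- rownames(scores)[labels == "negative"]
  best <- NULL
  for (it in seq_len(iterations)) {
    sp <- mccv_split(pos, neg, it, seed)
    xtr <- scores[c(sp$train_pos, sp$train_neg), , drop = FALSE]
    xte <- scores[c(sp$test_pos, sp$test_neg), , drop = FALSE]
    ytr <- rep(c(1, 0), c(length(sp$train_pos), length(sp$train_neg)))
    yte <- rep(c(1, 0), c(length(sp$test_pos), length(sp$test_neg)))
    fit <- .with_seed(.iter_seed(seed, it), {
      nnet::nnet(xtr, ytr, size = ncol(scores), decay = 1e-3, maxit = 200,
                 trace = FALSE, entropy = TRUE)
    })
    sc <- as.numeric(stats::predict(fit, xte))
    pred <- sc >= 0.5
    m <- compute_metrics(sum(pred & yte == 1), sum(pred & yte == 0),
                         sum(!pred & yte == 0), sum(!pred & yte == 1))
    if (is.null(best) || m[["accuracy"]] > best$metrics[["accuracy"]] ||
        (m[["accuracy"]] == best$metrics[["accuracy"]] &&
         m[["f_measure"]] > best$metrics[["f_measure"]]))
      best <- list(model = fit, metrics = m, best_iteration = it)
  }
  structure(list(model = best$model, metrics = best$metrics,
                 best_iteration = best$best_iteration,
                 feature_names = colnames(scores),
                 spec = list(iterations = iterations, seed = seed,
                             hidden = ncol(scores))),
            class = "consensus_model")
}

#' @rdname consensus_model_train
#' @param object fitted `consensus_model`.
#' @param newdata score matrix (or vector) over the training score columns.
#' @return numeric scores clamped to `[0,1]`.
#' @export
consensus_model_predict <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, object$feature_names))
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss))
    stop("missing score column(s): ", paste(miss, collapse = ", "))
  sc <- as.numeric(stats::predict(object$model,
                                  newdata[, object$feature_names, drop = FALSE]))
  pmin(pmax(sc, 0), 1)
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("Consensus MLP meta-model over", length(x$feature_names),
      "study scores; best iteration", x$best_iteration,
      sprintf("(accuracy %.3f)\n", x$metrics[["accuracy"]]))
  invisible(x)
}

#' Confidence threshold from positive-control scores
#'
#' The lower quartile of the ensemble scores obtained on known positives,
#' the rule used to set genome-scan confidence cutoffs. Shares the
#' linear-interpolation quantile estimator used by the feature-space
#' dataset constructors.
#'
#' @param scores numeric vector of at least 4 control scores.
#' @return the lower-quartile threshold.
#' @examples
#' derive_threshold(c(0.8, 0.9, 1, 1))  # 0.875
#' @export
derive_threshold <- function(scores) {
  if (length(scores) < 4L)
    stop("need at least 4 control scores to derive a threshold")
  stats::quantile(scores, 0.25, type = 7, names = FALSE)
}

#' True/false-rate percentages on single-label data sets
#'
#' TPR = correctly-positive calls / all hairpins x 100 on a positive set;
#' TNR likewise on a negative set. `truth` selects which is computed.
#'
#' @param predictions character labels (`"miRNA"`/`"negative"`/`"candidate"`).
#' @param truth `"positive"` or `"negative"` (the data set's label).
#' @return percentage in `[0, 100]`.
#' @export
tpr_tnr <- function(predictions, truth = c("positive", "negative")) {
  truth <- match.arg(truth)
  if (!length(predictions)) stop("empty prediction vector")
  want <- if (truth == "positive") "miRNA" else "negative"
  100 * sum(predictions == want) / length(predictions)
}

#' Rank models across data sets
#'
#' Given a correctness matrix (models x data sets, percent correct), ranks
#' models per data set (rank 1 = best; ties get the average rank by default)
#' and totals the ranks across data sets, weighting every data set equally.
#' With M models and D data sets a model ranked best everywhere totals D,
#' and worst everywhere (no ties) M*D.
#'
#' @param correctness complete numeric matrix with model rownames.
#' @param ties `"average"` (default) or `"min"` rank for ties.
#' @return list with `ranks` (matrix), `total_rank` (named, ascending), and
#'   `table` (correctness + ranks + total, sorted by total rank).
#' @export
rank_models <- function(correctness, ties = c("average", "min")) {
  ties <- match.arg(ties)
  if (anyNA(correctness)) stop("correctness matrix has missing cells")
  ranks <- apply(correctness, 2L, function(col)
    rank(-col, ties.method = ties))
  total <- rowSums(ranks)
  ord <- order(total)
  tab <- data.frame(model = rownames(correctness)[ord],
                    correctness[ord, , drop = FALSE],
                    total_rank = total[ord], check.names = FALSE)
  rownames(tab) <- NULL
  list(ranks = ranks[ord, , drop = FALSE], total_rank = total[ord],
       table = tab)
}

#' ROC curve and area under the curve
#'
#' Full threshold sweep over the distinct scores (equal scores grouped),
#' area by the trapezoidal rule. Equals the Mann-Whitney pair-concordance
#' statistic (ties counted 1/2).
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param truth logical or `"positive"`/`"negative"` per score.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  if (is.character(truth)) truth <- truth == "positive"
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0L || nn == 0L)
    stop("both classes must be present to compute a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !truth) / nn, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Apply all six consensus schemes to a score matrix
#'
#' Convenience wrapper combining per-study DT and NB score columns (named
#' `<profile>.DT` / `<profile>.NB` as produced by [predict.hairpin_mccv()])
#' into the six ensemble outputs per hairpin.
#'
#' @param scores score matrix from [predict.hairpin_mccv()].
#' @param meta optional `consensus_model` for the ConsensusModel column.
#' @param vote_threshold majority-vote threshold (default 7).
#' @return data.frame: id, avg_dt, avg_nb, consensus_dt, consensus_nb,
#'   consensus_rule, rule_conflict, average_dt, average_nb, and
#'   consensus_model score when `meta` is supplied.
#' @export
ensemble_predict <- function(scores, meta = NULL, vote_threshold = 7L) {
  dt_cols <- grep("\\.DT$", colnames(scores), value = TRUE)
  nb_cols <- grep("\\.NB$", colnames(scores), value = TRUE)
  n_st <- length(dt_cols)
  out <- data.frame(id = rownames(scores) %||% seq_len(nrow(scores)))
  out$avg_dt <- rowMeans(scores[, dt_cols, drop = FALSE])
  out$avg_nb <- rowMeans(scores[, nb_cols, drop = FALSE])
  out$consensus_dt <- apply(scores[, dt_cols, drop = FALSE] >= 0.5, 1L,
                            consensus_vote, threshold = vote_threshold,
                            n_studies = n_st)
  out$consensus_nb <- apply(scores[, nb_cols, drop = FALSE] >= 0.5, 1L,
                            consensus_vote, threshold = vote_threshold,
                            n_studies = length(nb_cols))
  cr <- mapply(function(d, n) consensus_rule(d, n), out$avg_dt, out$avg_nb,
               SIMPLIFY = FALSE)
  out$consensus_rule <- vapply(cr, `[[`, "", "label")
  out$rule_conflict <- vapply(cr, `[[`, NA, "rule_conflict")
  out$average_dt <- ifelse(out$avg_dt < 0.5, "negative", "miRNA")
  out$average_nb <- ifelse(out$avg_nb < 0.5, "negative", "miRNA")
  if (!is.null(meta))
    out$consensus_model <- consensus_model_predict(meta, scores)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
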