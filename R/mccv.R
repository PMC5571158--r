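#' Classification performance measures from a confusion matrix
#'
#' The eight measures tracked for every cross-validation iteration: recall,
#' precision, sensitivity, specificity, F-measure, accuracy, Cohen's kappa
#' and Youden's index, plus the raw confusion counts. Any measure with a
#' zero denominator is defined as 0 and listed in the `guarded` attribute.
#'
#' @param tp,fp,tn,fn non-negative confusion counts; total must be positive.
#' @return named numeric vector (class `performance_record`).
#' @examples
#' compute_metrics(50, 0, 50, 0)[["accuracy"]]  # 1
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  guarded <- character(0)
  div <- function(a, b, what) {
    if (b == 0) { guarded <<- c(guarded, what); return(0) }
    a / b
  }
  recall <- div(tp, tp + fn, "recall")
  precision <- div(tp, tp + fp, "precision")
  specificity <- div(tn, tn + fp, "specificity")
  f <- div(2 * precision * recall, precision + recall, "f_measure")
  accuracy <- (tp + tn) / total
  # chance agreement from the marginals
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- div(accuracy - pe, 1 - pe, "cohens_kappa")
  out <- c(recall = recall, precision = precision, sensitivity = recall,
           specificity = specificity, f_measure = f, accuracy = accuracy,
           cohens_kappa = kappa, youdens_index = recall + specificity - 1,
           TP = tp, FP = fp, TN = tn, FN = fn)
  attr(out, "guarded") <- guarded
  class(out) <- "performance_record"
  out
}

#' @export
print.performance_record <- function(x, ...) {
  v <- unclass(x)[1:8]
  cat(paste(sprintf("%s=%.4f", names(v), v), collapse = " "), "\n")
  invisible(x)
}

# deterministic per-iteration substream seed below 2^31
.iter_seed <- function(seed, iteration) {
  (as.numeric(seed) * 7919 + iteration * 104729) %% 2147483629
}

#' One balanced Monte Carlo cross-validation split
#'
#' Positives drive the split sizes: `floor(train_fraction * n_pos)` positives
#' train, the rest test; equal numbers of negatives are sampled without
#' replacement for each side, disjointly. Deterministic given
#' `(seed, iteration)`, so any iteration is reproducible in isolation.
#'
#' @param pos_ids,neg_ids record identifier vectors for each class.
#' @param iteration iteration index (1-based).
#' @param seed master seed.
#' @param train_fraction fraction of positives used for training.
#' @return list with `train_pos`, `train_neg`, `test_pos`, `test_neg`.
#' @export
mccv_split <- function(pos_ids, neg_ids, iteration = 1L, seed = 1L,
                       train_fraction = 0.7) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_pos <- length(pos_ids)
  n_train <- floor(train_fraction * n_pos)
  n_test <- n_pos - n_train
  if (length(neg_ids) < n_pos)
    stop("insufficient negatives: need ", n_pos, ", have ", length(neg_ids))
  .with_seed(.iter_seed(seed, iteration), {
    ord_pos <- sample(pos_ids)
    negs <- sample(neg_ids, n_pos)
    list(train_pos = ord_pos[seq_len(n_train)],
         train_neg = negs[seq_len(n_train)],
         test_pos = ord_pos[n_train + seq_len(n_test)],
         test_neg = negs[n_train + seq_len(n_test)])
  })
}

.fit_classifier <- function(kind, x, y) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c("negative", "positive"))
  switch(kind,
    DT = rpart::rpart(.y ~ ., data = df, method = "class"),
    NB = e1071::naiveBayes(.y ~ ., data = df),
    SVM = e1071::svm(.y ~ ., data = df, probability = TRUE),
    stop("unknown classifier kind: ", kind))
}

.score_classifier <- function(kind, model, x) {
  df <- as.data.frame(x)
  s <- switch(kind,
    DT = stats::predict(model, df, type = "prob")[, "positive"],
    NB = stats::predict(model, df, type = "raw")[, "positive"],
    SVM = attr(stats::predict(model, df, probability = TRUE),
               "probabilities")[, "positive"])
  unname(s)
}

#' Balanced Monte Carlo cross-validated training of hairpin classifiers
#'
#' The package's model-fitting entry point. For each iteration one balanced
#' 70/30 train/test split is drawn from the positive and negative feature
#' pools, and every (study profile, classifier kind) pair is fitted and
#' evaluated on that identical split, guaranteeing a fair comparison. The
#' best model per pair is selected by test accuracy (ties: higher F-measure,
#' then lower iteration index; `select_by` switches the primary criterion)
#' and retained for prediction together with the full per-iteration metric
#' distribution.
#'
#' @param pos,neg numeric feature matrices (rows = hairpins, rownames = ids)
#'   over the full registry, or `hairpin_records` (features computed here).
#' @param profiles list of `study_profile` objects (default: all 13) or
#'   `NULL` to fit one profile named `"all"` over every shared column.
#' @param kinds classifier kinds, subset of `"DT"`, `"NB"`, `"SVM"`.
#' @param iterations number of Monte Carlo iterations (study default 1000).
#' @param train_fraction positive-class training fraction (default 0.7).
#' @param seed master seed; per-iteration substreams are derived from it.
#' @param select_by `"accuracy"` (default), `"f_measure"` or
#'   `"youdens_index"` best-model criterion.
#' @return object of class `hairpin_mccv`: per-pair best models, metric
#'   distributions and provenance. Methods: `print`, `summary`, `predict`.
#' @export
hairpin_mccv <- function(pos, neg, profiles = study_profiles(),
                         kinds = c("DT", "NB"), iterations = 1000L,
                         train_fraction = 0.7, seed = 1L,
                         select_by = c("accuracy", "f_measure",
                                       "youdens_index")) {
  select_by <- match.arg(select_by)
  kinds <- match.arg(kinds, c("DT", "NB", "SVM"), several.ok = TRUE)
  if (inherits(pos, "hairpin_records")) pos <- compute_features(pos)
  if (inherits(neg, "hairpin_records")) neg <- compute_features(neg)
  shared <- intersect(colnames(pos), colnames(neg))
  if (is.null(profiles))
    profiles <- list(all = structure(list(study = "all",
                                          feature_names = shared,
                                          declared_count = length(shared),
                                          count_matches = TRUE),
                                     class = "study_profile"))
  for (p in profiles)
    if (!all(p$feature_names %in% shared))
      stop("profile '", p$study, "' requests features absent from the data: ",
           paste(setdiff(p$feature_names, shared), collapse = ", "))
  pos_ids <- rownames(pos); neg_ids <- rownames(neg)
  if (is.null(pos_ids) || is.null(neg_ids))
    stop("feature matrices must carry record ids as rownames")
  pairs <- expand.grid(profile = names(profiles), kind = kinds,
                       stringsAsFactors = FALSE)
  key <- paste(pairs$profile, pairs$kind, sep = ".")
  hist <- stats::setNames(vector("list", nrow(pairs)), key)
  best <- stats::setNames(vector("list", nrow(pairs)), key)
  failures <- list()
  for (it in seq_len(iterations)) {
    sp <- mccv_split(pos_ids, neg_ids, it, seed, train_fraction)
    y_train <- rep(c("positive", "negative"),
                   c(length(sp$train_pos), length(sp$train_neg)))
    y_test <- rep(c("positive", "negative"),
                  c(length(sp$test_pos), length(sp$test_neg)))
    xtr_full <- rbind(pos[sp$train_pos, shared, drop = FALSE],
                      neg[sp$train_neg, shared, drop = FALSE])
    xte_full <- rbind(pos[sp$test_pos, shared, drop = FALSE],
                      neg[sp$test_neg, shared, drop = FALSE])
    for (w in seq_len(nrow(pairs))) {
      pf <- profiles[[pairs$profile[w]]]
      xtr <- xtr_full[, pf$feature_names, drop = FALSE]
      xte <- xte_full[, pf$feature_names, drop = FALSE]
      fit <- tryCatch(.fit_classifier(pairs$kind[w], xtr, y_train),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <-
          list(pair = key[w], iteration = it, message = conditionMessage(fit))
        next
      }
      sc <- .score_classifier(pairs$kind[w], fit, xte)
      pred_pos <- sc >= 0.5
      m <- compute_metrics(tp = sum(pred_pos & y_test == "positive"),
                           fp = sum(pred_pos & y_test == "negative"),
                           tn = sum(!pred_pos & y_test == "negative"),
                           fn = sum(!pred_pos & y_test == "positive"))
      row <- c(iteration = it, unclass(m))
      hist[[key[w]]][[length(hist[[key[w]]]) + 1L]] <- row
      b <- best[[key[w]]]
      better <- is.null(b) ||
        m[[select_by]] > b$metrics[[select_by]] ||
        (m[[select_by]] == b$metrics[[select_by]] &&
         m[["f_measure"]] > b$metrics[["f_measure"]])
      if (better)
        best[[key[w]]] <- list(profile = pf$study, kind = pairs$kind[w],
                               feature_names = pf$feature_names,
                               model = fit, best_iteration = it, metrics = m)
    }
  }
  hist <- lapply(hist, function(h) {
    as.data.frame(do.call(rbind, h))
  })
  structure(list(best = best, history = hist, pairs = pairs,
                 profiles = profiles, kinds = kinds, failures = failures,
                 spec = list(iterations = iterations,
                             train_fraction = train_fraction, seed = seed,
                             select_by = select_by),
                 feature_names = shared),
            class = "hairpin_mccv")
}

#' @export
print.hairpin_mccv <- function(x, ...) {
  cat("Balanced MCCV hairpin classifier ensemble\n")
  cat("  profiles:", paste(names(x$profiles), collapse = ", "), "\n")
  cat("  kinds:   ", paste(x$kinds, collapse = ", "), "\n")
  cat("  iterations:", x$spec$iterations,
      " train fraction:", x$spec$train_fraction,
      " seed:", x$spec$seed, "\n")
  if (length(x$failures))
    cat("  fit failures:", length(x$failures), "(see $failures)\n")
  invisible(x)
}

#' @export
summary.hairpin_mccv <- function(object, ...) {
  rows <- lapply(names(object$best), function(k) {
    b <- object$best[[k]]
    h <- object$history[[k]]
    data.frame(pair = k, profile = b$profile, kind = b$kind,
               best_iteration = b$best_iteration,
               best_accuracy = b$metrics[["accuracy"]],
               best_f_measure = b$metrics[["f_measure"]],
               mean_accuracy = mean(h$accuracy),
               sd_accuracy = stats::sd(h$accuracy),
               iterations_run = nrow(h))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$best_accuracy), ]
  rownames(out) <- NULL
  class(out) <- c("summary.hairpin_mccv", "data.frame")
  out
}

#' @export
print.summary.hairpin_mccv <- function(x, ...) {
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Per-study scores for new hairpins
#'
#' Applies every stored best model to new data. Feature schemas are checked
#' strictly: missing or misordered features are an error.
#'
#' @param object a `hairpin_mccv` fit.
#' @param newdata feature matrix over the training registry (rownames = ids)
#'   or `hairpin_records`.
#' @param ... unused.
#' @return numeric matrix of scores in `[0,1]`, one column per
#'   (profile, kind) pair.
#' @export
predict.hairpin_mccv <- function(object, newdata, ...) {
  if (inherits(newdata, "hairpin_records")) newdata <- compute_features(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss))
    stop("newdata lacks feature(s) required by the model schema: ",
         paste(miss, collapse = ", "))
  out <- matrix(NA_real_, nrow = nrow(newdata), ncol = length(object$best),
                dimnames = list(rownames(newdata), names(object$best)))
  for (k in names(object$best)) {
    b <- object$best[[k]]
    x <- newdata[, b$feature_names, drop = FALSE]
    out[, k] <- .score_classifier(b$kind, b$model, x)
  }
  out
}

#' Persist a fitted MCCV ensemble
#'
#' Writes a versioned JSON envelope holding provenance, feature schema and
#' best-iteration metrics, with the fitted classifier payloads embedded as
#' base64-encoded serialized R objects. `load_model()` restores an object
#' that predicts identically.
#'
#' @param object a `hairpin_mccv` fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "hairpin_mccv"))
  env <- list(format = "premirna-model", version = 1L,
              spec = object$spec, feature_names = object$feature_names,
              pairs = object$pairs,
              best = lapply(object$best, function(b)
                list(profile = b$profile, kind = b$kind,
                     feature_names = b$feature_names,
                     best_iteration = b$best_iteration,
                     metrics = as.list(unclass(b$metrics)),
                     payload = jsonlite::base64_enc(serialize(b$model, NULL)))),
              history = object$history,
              profiles = lapply(object$profiles, unclass))
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @param path path written by [save_model()].
#' @export
load_model <- function(path) {
  env <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("corrupted model file: ",
                                           conditionMessage(e)))
  if (!identical(env$format, "premirna-model"))
    stop("not a premirna model file: ", path)
  if (!identical(as.integer(env$version), 1L))
    stop("unsupported model schema version: ", env$version)
  best <- lapply(env$best, function(b) {
    list(profile = b$profile, kind = b$kind,
         feature_names = unlist(b$feature_names),
         model = unserialize(jsonlite::base64_dec(b$payload)),
         best_iteration = b$best_iteration,
         metrics = {
           m <- unlist(b$metrics)
           class(m) <- "performance_record"
           m
         })
  })
  profiles <- lapply(env$profiles, function(p) {
    p$feature_names <- unlist(p$feature_names)
    structure(p, class = "study_profile")
  })
  history <- lapply(env$history, function(h)
    as.data.frame(lapply(h, unlist)))
  pairs <- as.data.frame(lapply(env$pairs, unlist))
  structure(list(best = best, history = history, pairs = pairs,
                 profiles = profiles,
                 kinds = unique(pairs$kind), failures = list(),
                 spec = env$spec,
                 feature_names = unlist(env$feature_names)),
            class = "hairpin_mccv")
}
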