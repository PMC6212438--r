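#' Replicate-level trial vectors for discrimination
#'
#' Reshapes a response matrix into one row per trial — a single replicate of
#' one odorant on one day — with one column per panel unit (31 ORs plus the
#' vector control). These 32-dimensional vectors are the input to the
#' embedding and the classifiers; replicates are never averaged first.
#'
#' @param rm a `response_matrix` (typically at a single concentration).
#' @return data frame with `odorant`, `day`, `replicate` and one numeric
#'   column per panel label; attribute `panel` holds the label order.
#' @export
trial_vectors <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  tidy <- rm$tidy
  panel <- sort(unique(tidy$or_id))
  panel <- c(setdiff(panel, rm$control_id), intersect(rm$control_id, panel))
  tk <- paste(tidy$odorant_id, tidy$day, tidy$run_id, tidy$replicate, sep = "\r")
  out <- lapply(split(seq_len(nrow(tidy)), tk), function(ix) {
    v <- tidy$value[ix][match(panel, tidy$or_id[ix])]
    if (anyNA(v)) stop("incomplete panel for a trial")
    cbind(data.frame(odorant = tidy$odorant_id[ix[1]], day = tidy$day[ix[1]],
                     replicate = tidy$replicate[ix[1]],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(v, panel))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "panel") <- panel
  res
}

trial_matrix <- function(trials) {
  panel <- attr(trials, "panel")
  if (is.null(panel)) panel <- setdiff(names(trials), c("odorant", "day", "replicate"))
  as.matrix(trials[, panel, drop = FALSE])
}

#' t-SNE embedding of trial vectors
#'
#' Exact (theta = 0) t-SNE of the 32-dimensional trials into 2D, Euclidean
#' distances on the raw response values, perplexity 10 by default.
#' Deterministic for a fixed seed.
#'
#' @param trials output of [trial_vectors()] (train and test days combined
#'   is the usual input).
#' @param perplexity t-SNE perplexity; must satisfy `3 * perplexity <
#'   n_trials - 1`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return data frame `odorant`, `day`, `replicate`, `dim1`, `dim2`;
#'   attributes record perplexity and seed.
#' @export
tsne_embed <- function(trials, perplexity = 10, seed = 1L, max_iter = 500) {
  x <- trial_matrix(trials)
  if (3 * perplexity >= nrow(x) - 1)
    stop("perplexity too large for ", nrow(x), " trials")
  set.seed(seed)
  emb <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = 0,
                      pca = FALSE, max_iter = max_iter,
                      check_duplicates = FALSE)$Y
  out <- data.frame(odorant = trials$odorant, day = trials$day,
                    replicate = trials$replicate,
                    dim1 = emb[, 1], dim2 = emb[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  out
}

#' Train an odor classifier on trial vectors
#'
#' Fits a random forest (bootstrap trees, random feature subsets at each
#' split; 500 trees, mtry = floor(sqrt(p))) or a linear discriminant
#' analysis on replicate-level panel response vectors. Deterministic for a
#' fixed seed.
#'
#' @param trials training trials from [trial_vectors()].
#' @param method `"random_forest"` or `"lda"`.
#' @param seed integer seed (random forest only; LDA is deterministic).
#' @param ntree number of trees for the random forest.
#' @return object of class `or_classifier` carrying the fitted model, the
#'   panel column order and the training-day labels.
#' @export
train_classifier <- function(trials, method = c("random_forest", "lda"),
                             seed = 1L, ntree = 500) {
  method <- match.arg(method)
  x <- trial_matrix(trials)
  y <- factor(trials$odorant)
  if (nlevels(y) < 2) stop("need at least 2 odor classes")
  if (min(table(y)) < 2) stop("need at least 2 trials per class")
  fit <- switch(method,
    random_forest = {
      set.seed(seed)
      randomForest::randomForest(x, y, ntree = ntree,
                                 mtry = max(1, floor(sqrt(ncol(x)))))
    },
    lda = suppressWarnings(MASS::lda(x, grouping = y, tol = 1e-9)))
  structure(list(method = method, fit = fit,
                 panel = colnames(x), classes = levels(y),
                 train_days = unique(trials$day), seed = seed),
            class = "or_classifier")
}

#' Evaluate a classifier on held-out trials
#'
#' Predicts the odorant of each test trial and reports the confusion
#' matrix and percent accuracy. Test trials must come from days disjoint
#' from the training days — the cross-day design is what demonstrates that
#' the panel's code generalizes across experiments — and an empty test set
#' is an error, not 0%.
#'
#' @param model an `or_classifier`.
#' @param test_trials trials from [trial_vectors()] with day labels
#'   disjoint from the model's training days.
#' @return object of class `classifier_report`: `method`, `predictions`
#'   (per-trial data frame), `confusion` (true x predicted), `accuracy`
#'   (percent), `train_days`, `test_days`, `seed`.
#' @export
evaluate_classifier <- function(model, test_trials) {
  stopifnot(inherits(model, "or_classifier"))
  if (nrow(test_trials) == 0) stop("empty test set")
  if (length(intersect(model$train_days, unique(test_trials$day))))
    stop("test trials share day labels with the training set; ",
         "cross-day evaluation requires disjoint days")
  x <- trial_matrix(test_trials)
  if (!identical(colnames(x), model$panel))
    stop("test trials do not match the model's panel dimension/order")
  pred <- switch(model$method,
    random_forest = stats::predict(model$fit, x),
    lda = stats::predict(model$fit, x)$class)
  pred <- as.character(pred)
  labs <- sort(unique(c(model$classes, test_trials$odorant)))
  confusion <- table(true = factor(test_trials$odorant, levels = labs),
                     predicted = factor(pred, levels = labs))
  acc <- 100 * sum(diag(confusion)) / nrow(test_trials)
  structure(list(method = model$method,
                 predictions = data.frame(odorant = test_trials$odorant,
                                          day = test_trials$day,
                                          replicate = test_trials$replicate,
                                          predicted = pred,
                                          correct = pred == test_trials$odorant,
                                          stringsAsFactors = FALSE),
                 confusion = confusion, accuracy = acc,
                 train_days = model$train_days,
                 test_days = unique(test_trials$day),
                 seed = model$seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report (", x$method, "): accuracy ",
      formatC(x$accuracy, format = "f", digits = 1), "% on ",
      nrow(x$predictions), " cross-day trials\n", sep = "")
  cat("  train days:", paste(x$train_days, collapse = ", "),
      "| test days:", paste(x$test_days, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-day classification from two plate runs
#'
#' End-to-end convenience: quantify both days, build trial vectors, train
#' on the first day and evaluate on the second.
#'
#' @param run_train,run_test `plate_run`s with distinct day labels.
#' @param method `"random_forest"` or `"lda"`.
#' @param mode quantification mode for [build_response_matrix()].
#' @param seed classifier seed.
#' @param ntree random-forest tree count.
#' @return a `classifier_report`.
#' @export
cross_day_classify <- function(run_train, run_test,
                               method = c("random_forest", "lda"),
                               mode = "auc_baseline", seed = 1L, ntree = 500) {
  method <- match.arg(method)
  tr <- trial_vectors(build_response_matrix(run_train, mode = mode))
  te <- trial_vectors(build_response_matrix(run_test, mode = mode))
  model <- train_classifier(tr, method = method, seed = seed, ntree = ntree)
  evaluate_classifier(model, te)
}
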