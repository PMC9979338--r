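# Weighted sequential forward selection over (channel, feature) pairs and
# per-participant RBF-SVM classification with Monte-Carlo cross-validation.
#
# Pre-MF is the positive class throughout: sensitivity is the correct
# Pre-MF rate, specificity the correct Post-MF rate, and positive decision
# scores point toward Pre-MF.

.CLASS_LEVELS <- c("PreMF", "PostMF")

#' Candidate pool of (channel, feature) pairs
#'
#' The 133 candidates in channel-major order, matching the column order of
#' a `feature_table`.
#'
#' @param channels channel labels (default the 19 feature channels).
#' @param features feature names (default the 7 spectral features).
#' @return data.frame with `channel`, `feature`, `column`.
#' @export
candidate_pool <- function(channels = feature_channels(),
                           features = .FEATURE_NAMES) {
  data.frame(channel = rep(channels, each = length(features)),
             feature = rep(features, times = length(channels)),
             column = as.vector(outer(features, channels,
                                      function(f, ch) paste(ch, f, sep = "."))))
}

# Stratified k-fold assignment; reduces k (with warning) when a class has
# fewer members than folds.
.make_folds <- function(y, k, seed) {
  counts <- table(y)
  if (min(counts) < k) {
    warning("fewer epochs than folds; reducing folds to ", min(counts))
    k <- min(counts)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(fold, "k") <- k
  fold
}

#' Train an RBF-SVM yielding continuous decision scores
#'
#' Fixed hyperparameters (cost 1, kernel width 1/(d * overall feature
#' variance), no inner search).  The returned object scores new epochs
#' with a signed decision value whose positive direction is Pre-MF.
#'
#' @param X epochs x features numeric matrix (z-scored columns).
#' @param y class labels (`"PreMF"`/`"PostMF"`), both present.
#' @return an object of class `mf_svm`.
#' @export
train_score_classifier <- function(X, y) {
  y <- factor(as.character(y), levels = .CLASS_LEVELS)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- as.matrix(X)
  v <- stats::var(as.vector(X))
  gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1
  m <- e1071::svm(X, y, kernel = "radial", cost = 1, gamma = gamma,
                  scale = FALSE)
  # e1071 decision values are positive for the first training label
  flip <- if (levels(y)[m$labels[1]] == "PreMF") 1 else -1
  structure(list(model = m, flip = flip, d = ncol(X)), class = "mf_svm")
}

#' Decision scores and predicted labels from an `mf_svm`
#'
#' @param object an `mf_svm`.
#' @param newdata epochs x features matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of signed scores (positive = Pre-MF); the
#'   predicted labels are attached as attribute `"labels"`.
#' @export
predict.mf_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("feature mismatch: model expects ", object$d, " columns")
  pr <- predict(object$model, newdata, decision.values = TRUE)
  sc <- object$flip * as.vector(attr(pr, "decision.values"))
  attr(sc, "labels") <- ifelse(sc > 0, "PreMF", "PostMF")
  sc
}

# Classification metrics from true/predicted labels (percent scale,
# F1 on [0, 1] with Pre-MF positive).
.clf_metrics <- function(truth, pred) {
  tp <- sum(truth == "PreMF" & pred == "PreMF")
  tn <- sum(truth == "PostMF" & pred == "PostMF")
  fp <- sum(truth == "PostMF" & pred == "PreMF")
  fn <- sum(truth == "PreMF" & pred == "PostMF")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  c(accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = 100 * sens, specificity = 100 * spec, f1 = f1)
}

#' Class-balanced cross-validated cost of a candidate feature set
#'
#' Mean over `mc` seeded Monte-Carlo runs of the stratified k-fold
#' accuracy minus `lambda` times the absolute sensitivity-specificity gap
#' (all on the 0-1 scale).  This is the cost maximized by the forward
#' selection.
#'
#' @param X epochs x all-features matrix.
#' @param y class labels.
#' @param columns column names (or indices) of the candidate set.
#' @param folds number of folds.
#' @param mc number of Monte-Carlo repetitions.
#' @param lambda balance-penalty weight.
#' @param seed integer seed; run r uses seed + r.
#' @return the scalar cost.
#' @export
balanced_cv_cost <- function(X, y, columns, folds = 10, mc = 5,
                             lambda = 0.5, seed = 1) {
  if (!length(columns)) stop("candidate set must be non-empty")
  Xs <- X[, columns, drop = FALSE]
  y <- factor(as.character(y), levels = .CLASS_LEVELS)
  costs <- numeric(mc)
  for (r in seq_len(mc)) {
    fold <- .make_folds(y, folds, subseed(seed, r))
    pred <- character(length(y))
    for (k in seq_len(attr(fold, "k"))) {
      te <- fold == k
      m <- train_score_classifier(Xs[!te, , drop = FALSE], y[!te])
      pred[te] <- attr(predict(m, Xs[te, , drop = FALSE]), "labels")
    }
    met <- .clf_metrics(as.character(y), pred)
    costs[r] <- met[["accuracy"]] / 100 -
      lambda * abs(met[["sensitivity"]] - met[["specificity"]]) / 100
  }
  mean(costs)
}

#' Weighted sequential forward selection
#'
#' Greedy bottom-up search over the candidate pool: at each step every
#' remaining candidate is scored by [balanced_cv_cost()] added to the
#' current set, the argmax is added (ties broken by lowest pool index),
#' and the search stops when the best improvement falls below `tol` or
#' `max_pairs` is reached.  The empty selection (cost = chance, 0.5) is
#' allowed when no candidate beats chance + `tol`.
#'
#' @param X epochs x 133 matrix (columns named as in [candidate_pool()]).
#' @param y class labels.
#' @param pool candidate pool (default [candidate_pool()]).
#' @param folds,mc,lambda,seed passed to [balanced_cv_cost()].
#' @param tol minimum cost improvement to keep adding.
#' @param max_pairs selection cap.
#' @return an object of class `wsfs_selection`: list with `pairs`
#'   (data.frame of selected channel/feature/column in order), `cost_trace`
#'   and `config`.
#' @export
wsfs_select <- function(X, y, pool = candidate_pool(), folds = 10, mc = 5,
                        lambda = 0.5, seed = 1, tol = 0.001, max_pairs = 20) {
  stopifnot(all(pool$column %in% colnames(X)))
  selected <- integer(0)
  remaining <- seq_len(nrow(pool))
  current <- 0.5                      # chance-level baseline
  trace <- numeric(0)
  repeat {
    if (length(selected) >= max_pairs || !length(remaining)) break
    costs <- vapply(remaining, function(ci) {
      balanced_cv_cost(X, y, pool$column[c(selected, ci)], folds = folds,
                       mc = mc, lambda = lambda,
                       seed = subseed(seed, length(selected), 1))
    }, numeric(1))
    best <- which.max(costs)          # first max = lowest pool index
    if (costs[best] < current + tol) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    current <- costs[best]
    trace <- c(trace, current)
  }
  structure(list(pairs = pool[selected, , drop = FALSE],
                 cost_trace = trace,
                 config = list(folds = folds, mc = mc, lambda = lambda,
                               tol = tol, max_pairs = max_pairs, seed = seed)),
            class = "wsfs_selection")
}

#' @export
print.wsfs_selection <- function(x, ...) {
  cat("<wsfs_selection> ", nrow(x$pairs), " pairs, final cost ",
      if (length(x$cost_trace)) round(max(x$cost_trace), 3) else 0.5,
      "\n", sep = "")
  if (nrow(x$pairs))
    cat("  ", paste(x$pairs$column, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a participant's Pre/Post classifier
#'
#' Runs `mc` Monte-Carlo repetitions of stratified k-fold cross-validation
#' on the selected columns.  Per repetition, out-of-fold decision scores
#' and predicted labels are collected for every epoch; metrics are
#' averaged over repetitions and per-epoch scores over the Monte-Carlo
#' ensemble.
#'
#' @param X_pre,X_post epochs x features matrices of the two classes
#'   (all 133 columns; the selection picks the columns).
#' @param selection a `wsfs_selection` (or character vector of columns).
#' @param folds number of folds.
#' @param mc number of Monte-Carlo repetitions.
#' @param seed integer seed.
#' @return an object of class `participant_eval`: metrics (averaged, in
#'   percent; `f1` on 0-1), per-epoch `scores_pre`/`scores_post`, and the
#'   trained `ensemble` (a list of per-run fold models) for scoring the
#'   flanking states.
#' @export
evaluate_participant <- function(X_pre, X_post, selection, folds = 5,
                                 mc = 100, seed = 1) {
  cols <- if (inherits(selection, "wsfs_selection")) selection$pairs$column
          else selection
  if (!length(cols)) {
    # empty selection: chance-level classifier, zero scores
    return(structure(list(
      metrics = c(accuracy = 50, sensitivity = 50, specificity = 50, f1 = 0.5),
      scores_pre = rep(0, nrow(X_pre)), scores_post = rep(0, nrow(X_post)),
      ensemble = list(), columns = character(0),
      config = list(folds = folds, mc = mc, seed = seed)),
      class = "participant_eval"))
  }
  Xp <- as.matrix(X_pre[, cols, drop = FALSE])
  Xq <- as.matrix(X_post[, cols, drop = FALSE])
  X <- rbind(Xp, Xq)
  y <- factor(rep(.CLASS_LEVELS, c(nrow(Xp), nrow(Xq))), levels = .CLASS_LEVELS)
  score_sum <- numeric(length(y))
  mets <- matrix(0, mc, 4)
  ensemble <- vector("list", mc)
  for (r in seq_len(mc)) {
    fold <- .make_folds(y, folds, subseed(seed, r, 7))
    pred <- character(length(y))
    sc <- numeric(length(y))
    models <- vector("list", attr(fold, "k"))
    for (k in seq_len(attr(fold, "k"))) {
      te <- fold == k
      m <- train_score_classifier(X[!te, , drop = FALSE], y[!te])
      s <- predict(m, X[te, , drop = FALSE])
      sc[te] <- s
      pred[te] <- attr(s, "labels")
      models[[k]] <- m
    }
    mets[r, ] <- .clf_metrics(as.character(y), pred)
    score_sum <- score_sum + sc
    ensemble[[r]] <- models
  }
  scores <- score_sum / mc
  structure(list(
    metrics = setNames(colMeans(mets),
                       c("accuracy", "sensitivity", "specificity", "f1")),
    scores_pre = scores[seq_len(nrow(Xp))],
    scores_post = scores[-seq_len(nrow(Xp))],
    ensemble = ensemble, columns = cols,
    config = list(folds = folds, mc = mc, seed = seed)),
    class = "participant_eval")
}

#' Score the flanking resting states with the frozen classifier
#'
#' Applies the Monte-Carlo ensemble trained on Pre/Post (no retraining)
#' to TaskRest1 and TaskRest2 epochs.  Per run, each flanking epoch is
#' scored by one (seeded, randomly assigned) fold model — the same
#' one-model-per-epoch-per-run structure the out-of-fold Pre/Post scores
#' have, so the score distributions of trained and flanking states are
#' comparable — and scores are then averaged over runs.
#'
#' @param eval a `participant_eval` from [evaluate_participant()].
#' @param X_taskrest1,X_taskrest2 epochs x features matrices (all 133
#'   columns).
#' @return list with score vectors `taskrest1` and `taskrest2`.
#' @export
score_flanking_states <- function(eval, X_taskrest1, X_taskrest2) {
  score_one <- function(X, which_state) {
    if (!length(eval$columns)) return(rep(0, nrow(X)))
    if (!all(eval$columns %in% colnames(X)))
      stop("feature mismatch: scoring data lacks the selected columns")
    Xs <- as.matrix(X[, eval$columns, drop = FALSE])
    acc <- numeric(nrow(Xs))
    for (r in seq_along(eval$ensemble)) {
      models <- eval$ensemble[[r]]
      assign <- with_seed(subseed(eval$config$seed, r, 31 + which_state),
                          sample.int(length(models), nrow(Xs), replace = TRUE))
      for (j in seq_along(models)) {
        idx <- assign == j
        if (any(idx))
          acc[idx] <- acc[idx] + as.vector(predict(models[[j]],
                                                   Xs[idx, , drop = FALSE]))
      }
    }
    acc / length(eval$ensemble)
  }
  list(taskrest1 = score_one(X_taskrest1, 1),
       taskrest2 = score_one(X_taskrest2, 2))
}

#' Feature and channel occurrence summary
#'
#' Counts every selected (channel, feature) pair across participants and
#' reports the percentage occurrence of each feature name and each
#' channel, each set normalized to 100%.
#'
#' @param selections list of `wsfs_selection` objects (or data.frames with
#'   `channel`/`feature` columns).
#' @return list with `features` and `channels`, each a named percentage
#'   vector sorted decreasingly.
#' @export
occurrence_summary <- function(selections) {
  pairs <- do.call(rbind, lapply(selections, function(s) {
    if (!is.data.frame(s) && !is.null(s$pairs)) s <- s$pairs
    s[, c("channel", "feature"), drop = FALSE]
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    warning("no selected pairs anywhere; occurrence summary is all zero")
    return(list(features = setNames(numeric(length(.FEATURE_NAMES)),
                                    .FEATURE_NAMES),
                channels = setNames(numeric(length(feature_channels())),
                                    feature_channels())))
  }
  pct <- function(x, all_levels) {
    tab <- table(factor(x, levels = all_levels))
    out <- setNames(100 * as.vector(tab) / sum(tab), all_levels)
    sort(out, decreasing = TRUE)
  }
  list(features = pct(pairs$feature, .FEATURE_NAMES),
       channels = pct(pairs$channel, feature_channels()))
}

#' Held-out accuracy of the selection + classification pipeline
#'
#' Splits each class's epochs in half (stratified, seeded), runs the
#' forward selection and trains the final classifier on the first half
#' only, and reports accuracy on the untouched second half.  Guards
#' against selection bias: on a null participant this is chance.
#'
#' @param X_pre,X_post epochs x 133 matrices.
#' @param folds,mc,lambda,tol,max_pairs selection parameters
#'   (see [wsfs_select()]).
#' @param seed integer seed.
#' @return list with `accuracy` (percent), `selection` and the index split.
#' @export
heldout_accuracy <- function(X_pre, X_post, folds = 5, mc = 2, lambda = 0.5,
                             tol = 0.001, max_pairs = 8, seed = 1) {
  split_half <- function(n, s) with_seed(s, {
    idx <- sample(n)
    list(train = sort(idx[seq_len(floor(n / 2))]),
         test = sort(idx[(floor(n / 2) + 1):n]))
  })
  sp <- split_half(nrow(X_pre), subseed(seed, 11))
  sq <- split_half(nrow(X_post), subseed(seed, 13))
  Xtr <- rbind(X_pre[sp$train, , drop = FALSE], X_post[sq$train, , drop = FALSE])
  ytr <- rep(.CLASS_LEVELS, c(length(sp$train), length(sq$train)))
  sel <- wsfs_select(Xtr, ytr, folds = folds, mc = mc, lambda = lambda,
                     seed = subseed(seed, 17), tol = tol, max_pairs = max_pairs)
  Xte <- rbind(X_pre[sp$test, , drop = FALSE], X_post[sq$test, , drop = FALSE])
  yte <- rep(.CLASS_LEVELS, c(length(sp$test), length(sq$test)))
  if (!nrow(sel$pairs)) {
    acc <- 50
  } else {
    m <- train_score_classifier(Xtr[, sel$pairs$column, drop = FALSE], ytr)
    pred <- attr(predict(m, Xte[, sel$pairs$column, drop = FALSE]), "labels")
    acc <- 100 * mean(pred == yte)
  }
  list(accuracy = acc, selection = sel,
       split = list(pre = sp, post = sq))
}
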