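# Cohort pipeline: simulate/ingest -> preprocess -> features -> selection +
# classification -> state comparisons -> validation, with a serializable
# run configuration and reproducible outputs.

#' Pipeline run configuration
#'
#' All tunable parameters with their study defaults.  The `"fast"`
#' profile reduces the Monte-Carlo load (5-fold x 2-MC selection with an
#' 8-pair cap, 5-fold x 10-MC evaluation) for continuous-integration
#' scale runs; the default profile is 10-fold x 5-MC selection (20-pair
#' cap) and 5-fold x 100-MC evaluation.
#'
#' @param profile `"default"` or `"fast"`.
#' @param ... named overrides of individual fields.
#' @return a list of class `mf_config`.
#' @export
mf_config <- function(profile = c("default", "fast"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    target_rate = 300,     # Hz, common analysis rate
    filter_lo = 1,         # Hz
    filter_hi = 30,        # Hz
    epoch_length = 1,      # s
    flat_floor = 1e-6,     # µV peak-to-peak over the flat window
    flat_window = 5,       # s
    line_sd = 4,           # bad-channel line-noise z threshold
    asr_cutoff = 30,       # component-sd multiple
    seg_z = 20,            # segment rejection z threshold
    seg_frac = 0.25,       # fraction of channels
    sel_folds = 10, sel_mc = 5, max_pairs = 20,
    eval_folds = 5, eval_mc = 100,
    lambda = 0.5, tol = 0.001,
    kde_grid = 512, hist_bins = 20,
    seed = 1)
  if (profile == "fast") {
    cfg$sel_folds <- 5; cfg$sel_mc <- 2; cfg$max_pairs <- 8
    cfg$eval_mc <- 10
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "mf_config")
}

#' Read and write run configurations as YAML
#'
#' @param cfg an [mf_config()].
#' @param path file path.
#' @return `read_config` returns an `mf_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(mf_config, c(list(profile = cfg$profile),
                       cfg[setdiff(names(cfg), "profile")]))
}

#' Preprocess one participant and extract normalized features
#'
#' Runs the cleaning chain on each of the four resting-state recordings,
#' extracts the 133 spectral features per epoch and returns both the raw
#' combined feature table (used for the rank-sum comparisons) and its
#' per-participant z-scored version (used by the classifier).
#'
#' @param participant one element of an `rs_cohort` (fields `id`, `site`,
#'   `recordings`), or a named list of four [rs_recording()]s.
#' @param config an [mf_config()].
#' @return list with `raw` and `normalized` `feature_table`s and the
#'   preprocessing `logs`.
#' @export
prepare_features <- function(participant, config = mf_config()) {
  recs <- if (!is.null(participant$recordings)) participant$recordings
          else participant
  states <- c("TaskRest1", "PreMF", "PostMF", "TaskRest2")
  stopifnot(all(states %in% names(recs)))
  tabs <- list(); logs <- list()
  for (s in states) {
    pp <- preprocess_recording(
      recs[[s]], target_rate = config$target_rate, lo = config$filter_lo,
      hi = config$filter_hi, epoch_length = config$epoch_length,
      flat_floor = config$flat_floor, flat_window = config$flat_window,
      line_sd = config$line_sd, asr_cutoff = config$asr_cutoff,
      seg_z = config$seg_z, seg_frac = config$seg_frac)
    tabs[[s]] <- extract_features(pp$epochs)
    logs[[s]] <- pp$log
  }
  raw <- combine_features(tabs)
  list(raw = raw, normalized = zscore_normalize(raw), logs = logs)
}

#' Fit the per-participant meditation classifier
#'
#' The core per-participant model: weighted sequential forward selection
#' of (channel, feature) pairs on the z-scored Pre-MF/Post-MF epochs,
#' Monte-Carlo cross-validated RBF-SVM evaluation, and decision scores
#' for all four resting states (the flanking states scored by the frozen
#' Pre/Post ensemble).
#'
#' Selection hygiene: the forward selection sees only a seeded half of
#' the Pre/Post epochs.  Classifier metrics are the Monte-Carlo
#' cross-validated rates over all epochs, but the score samples used for
#' the density validation are restricted to the epochs the selection
#' never saw, so the Pre/Post score separation is not inflated by
#' selection bias and the four states' score distributions are
#' exchangeable under the null.
#'
#' @param features a z-scored `feature_table` holding all four states
#'   (e.g. `prepare_features(...)$normalized`).
#' @param config an [mf_config()].
#' @param seed integer seed (default from the config).
#' @return an object of class `mf_fit` with fields `participant`, `site`,
#'   `selection`, `metrics` (accuracy/sensitivity/specificity in percent,
#'   `f1` on 0-1), `scores` (per-state decision-score vectors used for
#'   validation) and `model` (the final classifier trained on all
#'   Pre/Post epochs).
#' @export
mf_fit <- function(features, config = mf_config(), seed = config$seed) {
  stopifnot(inherits(features, "feature_table"))
  st <- features$state
  X <- features$values
  Xpre <- X[st == "PreMF", , drop = FALSE]
  Xpost <- X[st == "PostMF", , drop = FALSE]
  if (!nrow(Xpre) || !nrow(Xpost)) stop("need Pre-MF and Post-MF epochs")
  half <- function(n, s) with_seed(s, sort(sample.int(n, floor(n / 2))))
  sel_pre <- half(nrow(Xpre), subseed(seed, 41))
  sel_post <- half(nrow(Xpost), subseed(seed, 43))
  sel <- wsfs_select(rbind(Xpre[sel_pre, , drop = FALSE],
                           Xpost[sel_post, , drop = FALSE]),
                     rep(.CLASS_LEVELS, c(length(sel_pre), length(sel_post))),
                     folds = config$sel_folds, mc = config$sel_mc,
                     lambda = config$lambda, seed = subseed(seed, 3),
                     tol = config$tol, max_pairs = config$max_pairs)
  ev <- evaluate_participant(Xpre, Xpost, sel, folds = config$eval_folds,
                             mc = config$eval_mc, seed = subseed(seed, 5))
  fl <- score_flanking_states(ev, X[st == "TaskRest1", , drop = FALSE],
                              X[st == "TaskRest2", , drop = FALSE])
  val_pre <- ev$scores_pre[-sel_pre]
  val_post <- ev$scores_post[-sel_post]
  final <- if (nrow(sel$pairs))
    train_score_classifier(rbind(Xpre, Xpost)[, sel$pairs$column, drop = FALSE],
                           rep(.CLASS_LEVELS, c(nrow(Xpre), nrow(Xpost))))
  else NULL
  structure(list(participant = features$participant, site = features$site,
                 selection = sel, metrics = ev$metrics,
                 scores = list(taskrest1 = fl$taskrest1, pre = val_pre,
                               post = val_post, taskrest2 = fl$taskrest2),
                 scores_insample = list(pre = ev$scores_pre,
                                        post = ev$scores_post),
                 model = final, config = config, seed = seed),
            class = "mf_fit")
}

#' @export
print.mf_fit <- function(x, ...) {
  cat("<mf_fit> participant ", x$participant, " (site ", x$site, ")\n", sep = "")
  cat(sprintf("  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, F1 %.2f\n",
              x$metrics[["accuracy"]], x$metrics[["sensitivity"]],
              x$metrics[["specificity"]], x$metrics[["f1"]]))
  cat("  ", nrow(x$selection$pairs), " selected pairs: ",
      paste(utils::head(x$selection$pairs$column, 6), collapse = " "),
      if (nrow(x$selection$pairs) > 6) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.mf_fit <- function(object, ...) {
  s <- object$scores
  cat("Per-participant meditation classifier -- ", object$participant, "\n")
  print(round(object$metrics, 2))
  cat("mean scores: TaskRest1 ", round(mean(s$taskrest1), 3),
      ", Pre-MF ", round(mean(s$pre), 3),
      ", Post-MF ", round(mean(s$post), 3),
      ", TaskRest2 ", round(mean(s$taskrest2), 3), "\n", sep = "")
  invisible(object)
}

#' Score new epochs with a fitted participant classifier
#'
#' @param object an `mf_fit`.
#' @param newdata a `feature_table` (z-scored like the training table) or
#'   an epochs x 133 matrix.
#' @param ... unused.
#' @return signed decision scores (positive = Pre-MF like).
#' @export
predict.mf_fit <- function(object, newdata, ...) {
  if (is.null(object$model)) stop("empty selection; no classifier was trained")
  X <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  predict(object$model, X[, object$selection$pairs$column, drop = FALSE])
}

#' Run the full cohort pipeline
#'
#' For every participant: cleaning chain, spectral features, z-scoring,
#' forward selection, Monte-Carlo evaluation and flanking-state scoring.
#' Cohort-level outputs: the six state-pair rank-sum tables over all
#' channels and per brain region, the feature/channel occurrence summary,
#' the distance validation, and (when both sites have two or more
#' participants) the cross-site metric test.  A participant whose stage
#' fails is logged and skipped.
#'
#' @param cohort an `rs_cohort` (see [simulate_cohort()]) or a list of
#'   participants, each a list with `id`, `site`, `recordings`.
#' @param config an [mf_config()].
#' @param out_dir optional output directory; when given, the resolved
#'   config (YAML), the report (JSON) and the comparison tables (CSV) are
#'   written there.
#' @return an object of class `mf_cohort`.
#' @export
mf_run <- function(cohort, config = mf_config(), out_dir = NULL) {
  fits <- list(); raw_tables <- list(); failures <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    id <- if (!is.null(p$id)) p$id else sprintf("P%02d", i)
    res <- tryCatch({
      pf <- prepare_features(p, config)
      fit <- mf_fit(pf$normalized, config, seed = subseed(config$seed, i, 23))
      list(fit = fit, raw = pf$raw)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("participant ", id, " failed: ", conditionMessage(res))
      failures[[id]] <- conditionMessage(res)
    } else {
      fits[[id]] <- res$fit
      raw_tables[[id]] <- res$raw
    }
  }
  if (!length(fits)) stop("no participant completed the pipeline")
  comparisons_all <- state_comparison_table(raw_tables, scope = "all")
  comparisons_region <- state_comparison_table(raw_tables, scope = "region")
  occurrence <- occurrence_summary(lapply(fits, `[[`, "selection"))
  validation <- cohort_validation(lapply(fits, `[[`, "scores"),
                                  grid_n = config$kde_grid,
                                  bins = config$hist_bins)
  metrics <- data.frame(
    participant = names(fits),
    site = vapply(fits, `[[`, numeric(1), "site"),
    t(vapply(fits, `[[`, numeric(4), "metrics")))
  site_test <- NULL
  if (length(unique(metrics$site)) == 2 && min(table(metrics$site)) >= 2)
    site_test <- site_effect_test(metrics, metrics$site)
  out <- structure(list(fits = fits, metrics = metrics,
                        comparisons_all = comparisons_all,
                        comparisons_region = comparisons_region,
                        occurrence = occurrence, validation = validation,
                        site_test = site_test, failures = failures,
                        config = config),
                   class = "mf_cohort")
  if (!is.null(out_dir)) write_cohort_outputs(out, out_dir)
  out
}

#' Write cohort pipeline outputs
#'
#' Writes `config.yaml`, `report.json` (metrics, occurrence,
#' probabilities, site test), and the two comparison tables as CSV.
#'
#' @param result an `mf_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(result$config, file.path(out_dir, "config.yaml"))
  report <- list(
    metrics = result$metrics,
    mean_metrics = as.list(colMeans(result$metrics[, c("accuracy", "sensitivity",
                                                       "specificity", "f1")])),
    occurrence = lapply(result$occurrence, as.list),
    p_distance1 = result$validation$p_distance1,
    p_distance2 = result$validation$p_distance2,
    site_test = as.list(result$site_test),
    failures = result$failures)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_comparison_csv(result$comparisons_all,
                       file.path(out_dir, "comparisons_all_channels.csv"))
  write_comparison_csv(result$comparisons_region,
                       file.path(out_dir, "comparisons_regions.csv"))
  invisible(out_dir)
}

#' @export
print.mf_cohort <- function(x, ...) {
  m <- x$metrics
  cat("<mf_cohort> ", nrow(m), " participants (profile ",
      x$config$profile, ")\n", sep = "")
  cat(sprintf("  mean accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, F1 %.2f\n",
              mean(m$accuracy), mean(m$sensitivity), mean(m$specificity),
              mean(m$f1)))
  cat("  P(Distance1 > 0) = ", round(x$validation$p_distance1, 4),
      ", P(Distance2 > 0) = ", round(x$validation$p_distance2, 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.mf_cohort <- function(object, ...) {
  print(object)
  cat("\nPer-participant metrics:\n")
  print(object$metrics, row.names = FALSE, digits = 4)
  cat("\nTop selected features (%):\n")
  print(round(object$occurrence$features, 2))
  cat("\nTop selected channels (%):\n")
  print(round(utils::head(object$occurrence$channels, 8), 2))
  if (!is.null(object$site_test)) {
    cat("\nCross-site rank-sum p-values:\n")
    print(round(object$site_test, 4))
  }
  sig <- object$comparisons_all[object$comparisons_all$pair == "PreMF vs PostMF", ]
  cat("\nPre-MF vs Post-MF (all channels):\n")
  print(sig[, c("feature", "direction", "p")], row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.mf_cohort <- function(x, ...) {
  plot(x$validation, ...)
  invisible(x)
}

#' Held-out null/effect calibration of the cohort pipeline
#'
#' For every participant, splits the Pre/Post epochs in half, runs the
#' forward selection and final training on one half only and measures
#' accuracy on the untouched half ([heldout_accuracy()]); returns the
#' cohort mean.  On a null cohort this is an unbiased chance-level check
#' that guards against selection bias.
#'
#' @param cohort an `rs_cohort`.
#' @param config an [mf_config()].
#' @return list with `mean_accuracy` (percent) and per-participant
#'   accuracies.
#' @export
cohort_heldout_accuracy <- function(cohort, config = mf_config("fast")) {
  accs <- numeric(0)
  for (i in seq_along(cohort)) {
    pf <- prepare_features(cohort[[i]], config)
    st <- pf$normalized$state
    X <- pf$normalized$values
    h <- heldout_accuracy(X[st == "PreMF", , drop = FALSE],
                          X[st == "PostMF", , drop = FALSE],
                          folds = config$sel_folds, mc = config$sel_mc,
                          lambda = config$lambda, tol = config$tol,
                          max_pairs = config$max_pairs,
                          seed = subseed(config$seed, i, 29))
    accs <- c(accs, h$accuracy)
  }
  list(mean_accuracy = mean(accs), accuracy = accs)
}
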