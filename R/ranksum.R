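# Wilcoxon rank-sum machinery used for the state and region comparisons:
# exact enumeration at small sample sizes, tie-corrected normal
# approximation with continuity correction otherwise, plus the table
# builders pooling epoch-level averages across participants.

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of two independent samples with midrank ties.
#' When the pooled size is below `exact_max` the null distribution of the
#' rank-sum statistic is enumerated over all assignments of the midranks;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.  The direction is the sign of the
#' median ordering, reported only when `p < alpha`.
#'
#' @param x,y numeric samples (non-empty).
#' @param alpha significance level used to gate the direction label.
#' @param exact_max maximum pooled size for exact enumeration.
#' @return list with `statistic` (rank sum of `x`), `p` (two-sided),
#'   `direction` (`"greater"`, `"less"` or `"ns"`, meaning `x` vs `y`)
#'   and `method`.
#' @export
rank_sum <- function(x, y, alpha = 0.05, exact_max = 10) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  if (length(unique(pooled)) == 1) {
    return(list(statistic = W, p = 1, direction = "ns", method = "degenerate"))
  }
  if (n <= exact_max) {
    # enumerate the rank-sum null over all C(n, n1) midrank assignments
    sums <- utils::combn(n, n1, FUN = function(idx) sum(r[idx]))
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    method <- "exact"
  } else {
    U <- W - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  direction <- "ns"
  if (p < alpha) {
    mx <- stats::median(x); my <- stats::median(y)
    if (mx != my) direction <- if (mx > my) "greater" else "less"
    else direction <- if (mean(r[seq_len(n1)]) > mean(r[-seq_len(n1)]))
      "greater" else "less"
  }
  list(statistic = W, p = p, direction = direction, method = method)
}

#' Average features over a channel set
#'
#' Per epoch and per feature, the mean of the feature's columns over the
#' named channels (all channels, or one brain region).
#'
#' @param table a `feature_table`.
#' @param channels channel labels (subset of the table's channels).
#' @return an epochs x 7 matrix of channel-averaged features.
#' @export
average_over_channels <- function(table, channels) {
  stopifnot(inherits(table, "feature_table"))
  unknown <- setdiff(channels, table$channels)
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  out <- matrix(0, nrow(table$values), length(table$features),
                dimnames = list(NULL, table$features))
  for (fi in seq_along(table$features)) {
    cols <- paste(channels, table$features[fi], sep = ".")
    out[, fi] <- rowMeans(table$values[, cols, drop = FALSE])
  }
  out
}

.STATE_PAIRS <- list(
  c("TaskRest1", "PreMF"), c("TaskRest1", "PostMF"),
  c("TaskRest1", "TaskRest2"), c("PreMF", "PostMF"),
  c("PreMF", "TaskRest2"), c("PostMF", "TaskRest2"))

#' State-pair comparison tables
#'
#' For every spectral feature and every one of the six ordered state
#' pairs, pools the channel-averaged epoch values of all participants
#' into two vectors and applies [rank_sum()].  `scope = "all"` averages
#' over all 19 feature channels; `scope = "region"` produces one
#' comparison per brain region.  When `unit = "participant"` the sampling
#' unit is the participant mean rather than the epoch.
#'
#' @param tables list of per-participant `feature_table`s, each holding
#'   all four states (participants with missing states are excluded with
#'   a warning).
#' @param scope `"all"` or `"region"`.
#' @param alpha significance level for direction reporting.
#' @param unit `"epoch"` (pool epochs) or `"participant"` (pool
#'   participant means).
#' @return data.frame of class `comparison_table` with columns `feature`,
#'   `pair`, `region` (`"all"` when scope is all), `direction`
#'   (first state vs second), `p`.
#' @export
state_comparison_table <- function(tables, scope = c("all", "region"),
                                   alpha = 0.05, unit = c("epoch", "participant")) {
  scope <- match.arg(scope)
  unit <- match.arg(unit)
  states <- c("TaskRest1", "PreMF", "PostMF", "TaskRest2")
  keep <- vapply(tables, function(t) all(states %in% t$state), TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " participant(s) excluded: missing resting states")
    tables <- tables[keep]
  }
  if (!length(tables)) stop("no participant has all four states")
  groups <- if (scope == "all") list(all = feature_channels()) else region_map()
  feats <- tables[[1]]$features
  rows <- list()
  for (gname in names(groups)) {
    # pooled[[state]] is a matrix (pooled units x 7 features)
    pooled <- setNames(vector("list", 4), states)
    for (t in tables) {
      avg <- average_over_channels(t, groups[[gname]])
      for (s in states) {
        m <- avg[t$state == s, , drop = FALSE]
        if (unit == "participant") m <- matrix(colMeans(m), 1,
                                               dimnames = list(NULL, feats))
        pooled[[s]] <- rbind(pooled[[s]], m)
      }
    }
    for (fi in seq_along(feats)) {
      for (pair in .STATE_PAIRS) {
        rs <- rank_sum(pooled[[pair[1]]][, fi], pooled[[pair[2]]][, fi],
                       alpha = alpha)
        rows[[length(rows) + 1]] <- data.frame(
          feature = feats[fi], pair = paste(pair, collapse = " vs "),
          region = gname, direction = rs$direction, p = rs$p)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "multiple_testing") <- "none (per-cell alpha, as reported)"
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table as a wide CSV
#'
#' Feature rows by pair (or region) columns, each cell formatted
#' `"A > B (p=...)"` for significant cells and `"p=..."` otherwise.
#'
#' @param table a `comparison_table`.
#' @param path output path.
#' @param by column variable: `"pair"` or `"region"`.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(table, path, by = c("pair", "region")) {
  by <- match.arg(by)
  cell <- function(d) {
    ab <- strsplit(d$pair, " vs ", fixed = TRUE)[[1]]
    if (d$direction == "greater") sprintf("%s > %s (p=%.3g)", ab[1], ab[2], d$p)
    else if (d$direction == "less") sprintf("%s > %s (p=%.3g)", ab[2], ab[1], d$p)
    else sprintf("p=%.3g", d$p)
  }
  cols <- unique(table[[by]])
  feats <- unique(table$feature)
  wide <- matrix("", length(feats), length(cols),
                 dimnames = list(feats, cols))
  for (i in seq_len(nrow(table))) {
    d <- table[i, ]
    wide[d$feature, d[[by]]] <- cell(d)
  }
  utils::write.csv(as.data.frame(wide), path)
  invisible(path)
}

#' Cross-site test of classifier metrics
#'
#' Two-sided rank-sum comparison of per-participant accuracy, sensitivity
#' and specificity between the two recording sites.
#'
#' @param metrics data.frame with columns `accuracy`, `sensitivity`,
#'   `specificity`.
#' @param sites site label per row (two levels, each with >= 2 rows).
#' @return named numeric vector of p-values for the three metrics.
#' @export
site_effect_test <- function(metrics, sites) {
  lv <- unique(sites)
  if (length(lv) != 2) stop("need exactly two sites")
  if (min(table(sites)) < 2) stop("need at least 2 participants per site")
  vapply(c("accuracy", "sensitivity", "specificity"), function(m) {
    rank_sum(metrics[[m]][sites == lv[1]], metrics[[m]][sites == lv[2]])$p
  }, numeric(1))
}
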