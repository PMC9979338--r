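# Validation that the Pre/Post separation exceeds temporal drift:
# Gaussian-kernel densities of the SVM scores on a shared grid, symmetric
# Kullback-Leibler distances between consecutive resting states, and the
# normalized Distance1/Distance2 contrasts summarized over the cohort.

#' Kernel density estimate of SVM scores on a shared grid
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on
#' the supplied uniform grid, floored at `floor_eps` and renormalized so
#' the trapezoidal integral is 1.  Zero-variance score sets degenerate to
#' a (floored) spike at the common value, with a warning.
#'
#' @param scores numeric vector of at least 5 scores.
#' @param grid uniform increasing grid of score values.
#' @param floor_eps density floor keeping the KL log terms finite.
#' @return an object of class `score_density`: list with `grid`,
#'   `density`, `bandwidth`, `n`.
#' @export
estimate_density <- function(scores, grid, floor_eps = 1e-12) {
  if (length(scores) < 5) stop("need at least 5 scores")
  if (length(grid) < 2 || is.unsorted(grid)) stop("grid must be increasing")
  step <- diff(grid)
  if (max(step) - min(step) > 1e-8 * mean(step)) stop("grid must be uniform")
  if (stats::sd(scores) == 0) {
    warning("degenerate (zero-variance) scores; spike density")
    d <- numeric(length(grid))
    d[which.min(abs(grid - scores[1]))] <- 1
    bw <- 0
  } else {
    bw <- stats::bw.nrd0(scores)
    kd <- stats::density(scores, bw = bw, from = grid[1],
                         to = grid[length(grid)], n = length(grid))
    d <- kd$y
  }
  d <- pmax(d, floor_eps)
  d <- d / .trapz(grid, d)
  structure(list(grid = grid, density = d, bandwidth = bw,
                 n = length(scores)), class = "score_density")
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# Trapezoid quadrature weights (mass per grid point).
.trapz_weights <- function(x) {
  n <- length(x)
  w <- c(diff(x) / 2, 0) + c(0, diff(x) / 2)
  w
}

#' Symmetric Kullback-Leibler distance
#'
#' D = 1/2 * sum_x [p(x) log(p(x)/q(x)) + q(x) log(q(x)/p(x))] in natural
#' log, where p and q are probability masses.  Accepts either two
#' `score_density` objects on an identical grid (densities are converted
#' to grid masses with trapezoid weights) or two plain probability
#' vectors.
#'
#' @param p,q `score_density` objects or probability vectors.
#' @return the non-negative symmetric KL distance (nats).
#' @export
sym_kl <- function(p, q) {
  if (inherits(p, "score_density") || inherits(q, "score_density")) {
    if (!inherits(p, "score_density") || !inherits(q, "score_density"))
      stop("both arguments must be score_density objects")
    if (length(p$grid) != length(q$grid) ||
        max(abs(p$grid - q$grid)) > 1e-10)
      stop("densities live on different grids")
    w <- .trapz_weights(p$grid)
    pp <- p$density * w; qq <- q$density * w
  } else {
    if (length(p) != length(q)) stop("probability vectors differ in length")
    pp <- p; qq <- q
  }
  pp <- pp / sum(pp); qq <- qq / sum(qq)
  if (any(pp <= 0) || any(qq <= 0))
    stop("probabilities must be strictly positive (apply a floor first)")
  0.5 * sum(pp * log(pp / qq) + qq * log(qq / pp))
}

#' Distance contrasts between meditation and drift separations
#'
#' `Distance1 = (D23 - D12) / (D12 + D23)` compares the Pre/Post
#' separation `D23` with the early drift `D12` (TaskRest1 vs Pre-MF);
#' `Distance2 = (D23 - D34) / (D23 + D34)` compares it with the late
#' drift `D34` (Post-MF vs TaskRest2).  Both lie in [-1, 1]; positive
#' values mean the meditation separation exceeds drift.
#'
#' @param d12,d23,d34 non-negative symmetric KL distances.
#' @return named numeric vector `c(Distance1, Distance2)`; a zero
#'   denominator yields `NA` with a warning.
#' @export
distance_contrasts <- function(d12, d23, d34) {
  if (any(c(d12, d23, d34) < 0)) stop("distances must be non-negative")
  dist1 <- if (d12 + d23 > 0) (d23 - d12) / (d12 + d23) else {
    warning("D12 + D23 = 0; Distance1 undefined"); NA_real_
  }
  dist2 <- if (d23 + d34 > 0) (d23 - d34) / (d23 + d34) else {
    warning("D23 + D34 = 0; Distance2 undefined"); NA_real_
  }
  c(Distance1 = dist1, Distance2 = dist2)
}

#' Per-participant score-distance summary
#'
#' Estimates the four state score densities on a shared grid and returns
#' the three consecutive symmetric KL distances and the two contrasts.
#'
#' @param scores named list with numeric score vectors `taskrest1`,
#'   `pre`, `post`, `taskrest2`.
#' @param grid shared grid; when `NULL`, 512 points spanning the pooled
#'   score range padded by 3 maximal bandwidths.
#' @param grid_n grid size used when `grid` is `NULL`.
#' @return list of class `distance_summary` with `d12`, `d23`, `d34`,
#'   `distance1`, `distance2`, `grid`, `densities`.
#' @export
distance_summary <- function(scores, grid = NULL, grid_n = 512) {
  need <- c("taskrest1", "pre", "post", "taskrest2")
  stopifnot(all(need %in% names(scores)))
  if (is.null(grid)) {
    all_sc <- unlist(scores[need])
    bws <- vapply(scores[need], function(s)
      if (stats::sd(s) > 0) stats::bw.nrd0(s) else 0, numeric(1))
    pad <- 3 * max(bws, 1e-6)
    grid <- seq(min(all_sc) - pad, max(all_sc) + pad, length.out = grid_n)
  }
  dens <- lapply(scores[need], estimate_density, grid = grid)
  d12 <- sym_kl(dens$taskrest1, dens$pre)
  d23 <- sym_kl(dens$pre, dens$post)
  d34 <- sym_kl(dens$post, dens$taskrest2)
  dc <- distance_contrasts(d12, d23, d34)
  structure(list(d12 = d12, d23 = d23, d34 = d34,
                 distance1 = dc[["Distance1"]], distance2 = dc[["Distance2"]],
                 grid = grid, densities = dens),
            class = "distance_summary")
}

#' Cohort-level validation of the meditation effect against drift
#'
#' Computes per-participant [distance_summary()]s on a cohort-shared
#' grid, normalized histograms of Distance1 and Distance2 (20 bins on
#' [-1, 1]) and the fractions of participants with positive values.
#'
#' @param score_sets list (one element per participant) of named score
#'   lists as accepted by [distance_summary()]; participants with a
#'   missing state are skipped with a warning.
#' @param grid_n size of the shared grid.
#' @param bins histogram bin count over [-1, 1].
#' @return object of class `cohort_validation`: `summaries`,
#'   `distance1`, `distance2` (per-participant values), `hist1`, `hist2`
#'   (normalized histograms), `p_distance1`, `p_distance2`.
#' @export
cohort_validation <- function(score_sets, grid_n = 512, bins = 20) {
  need <- c("taskrest1", "pre", "post", "taskrest2")
  ok <- vapply(score_sets, function(s)
    all(need %in% names(s)) && all(lengths(s[need]) >= 5), TRUE)
  if (!all(ok)) {
    warning(sum(!ok), " participant(s) skipped: missing state scores")
    score_sets <- score_sets[ok]
  }
  if (!length(score_sets)) stop("no usable participants")
  all_sc <- unlist(lapply(score_sets, function(s) unlist(s[need])))
  bws <- unlist(lapply(score_sets, function(s)
    vapply(s[need], function(x)
      if (stats::sd(x) > 0) stats::bw.nrd0(x) else 0, numeric(1))))
  pad <- 3 * max(bws, 1e-6)
  grid <- seq(min(all_sc) - pad, max(all_sc) + pad, length.out = grid_n)
  summaries <- lapply(score_sets, distance_summary, grid = grid)
  d1 <- vapply(summaries, `[[`, numeric(1), "distance1")
  d2 <- vapply(summaries, `[[`, numeric(1), "distance2")
  brks <- seq(-1, 1, length.out = bins + 1)
  h1 <- hist(pmin(pmax(d1[!is.na(d1)], -1), 1), breaks = brks, plot = FALSE)
  h2 <- hist(pmin(pmax(d2[!is.na(d2)], -1), 1), breaks = brks, plot = FALSE)
  norm_hist <- function(h) {
    h$density <- h$counts / sum(h$counts)
    h
  }
  structure(list(summaries = summaries, distance1 = d1, distance2 = d2,
                 hist1 = norm_hist(h1), hist2 = norm_hist(h2),
                 p_distance1 = mean(d1 > 0, na.rm = TRUE),
                 p_distance2 = mean(d2 > 0, na.rm = TRUE)),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("<cohort_validation> ", length(x$distance1), " participants\n", sep = "")
  cat("  P(Distance1 > 0) = ", round(x$p_distance1, 4),
      ", P(Distance2 > 0) = ", round(x$p_distance2, 4), "\n", sep = "")
  invisible(x)
}

#' Plot score densities and distance histograms
#'
#' Two-panel base-graphics figure: the four state score densities of one
#' participant (or cohort-pooled) and the Distance1/Distance2 histograms.
#'
#' @param x a `cohort_validation`.
#' @param participant index of the participant whose densities to show.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.cohort_validation <- function(x, participant = 1, ...) {
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  s <- x$summaries[[participant]]
  cols <- c("grey40", "dodgerblue3", "firebrick3", "grey70")
  plot(s$grid, s$densities$pre$density, type = "l", col = cols[2],
       xlab = "SVM score", ylab = "density",
       main = "Score densities", lwd = 2,
       ylim = range(sapply(s$densities, `[[`, "density")))
  lines(s$grid, s$densities$post$density, col = cols[3], lwd = 2)
  lines(s$grid, s$densities$taskrest1$density, col = cols[1], lty = 2)
  lines(s$grid, s$densities$taskrest2$density, col = cols[4], lty = 2)
  legend("topright", c("TaskRest1", "Pre-MF", "Post-MF", "TaskRest2"),
         col = cols[c(1, 2, 3, 4)], lty = c(2, 1, 1, 2), bty = "n", cex = 0.8)
  mids <- x$hist1$mids
  barplot(rbind(x$hist1$density, x$hist2$density), beside = TRUE,
          names.arg = round(mids, 2), las = 2,
          col = c("dodgerblue3", "firebrick3"),
          main = "Distance contrasts", ylab = "probability")
  legend("topleft", c("Distance1", "Distance2"),
         fill = c("dodgerblue3", "firebrick3"), bty = "n", cex = 0.8)
  abline(v = 0)
  invisible(x)
}
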