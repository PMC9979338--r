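test_that("score densities integrate to one and recover moments", {
  g <- seq(-6, 6, length.out = 512)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  set.seed(14)
  d <- estimate_density(rnorm(500), g)
  expect_equal(trapz(d$grid, d$density), 1, tolerance = 1e-6)
  mu <- trapz(g, g * d$density)
  s2 <- trapz(g, (g - mu)^2 * d$density)
  expect_lt(abs(mu), 0.1)
  expect_equal(sqrt(s2), 1, tolerance = 0.1)
  expect_true(all(d$density > 0))
  # two disjoint samples: bimodal with modes near the sample means
  x <- c(rnorm(300, -3, 0.3), rnorm(300, 3, 0.3))
  db <- estimate_density(x, g)
  left <- g < 0
  expect_lt(abs(g[left][which.max(db$density[left])] + 3), 0.5)
  expect_lt(abs(g[!left][which.max(db$density[!left])] - 3), 0.5)
  expect_error(estimate_density(c(1, 2), g), "at least 5")
  expect_warning(ds <- estimate_density(rep(2, 10), g), "degenerate")
  expect_equal(trapz(g, ds$density), 1, tolerance = 1e-6)
})

test_that("symmetric KL matches hand evaluation, is symmetric and zero at identity", {
  # hand-summed toy: p = (.5,.5), q = (.25,.75)
  hand <- 0.5 * ((0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75)) +
                   (0.25 * log(0.25 / 0.5) + 0.75 * log(0.75 / 0.5)))
  expect_equal(sym_kl(c(0.5, 0.5), c(0.25, 0.75)), hand, tolerance = 1e-12)
  expect_equal(sym_kl(c(0.5, 0.5), c(0.25, 0.75)), 0.137327, tolerance = 1e-5)
  # identity and symmetry on random floored distributions
  set.seed(15)
  for (i in 1:10) {
    p <- runif(20) + 1e-6; p <- p / sum(p)
    q <- runif(20) + 1e-6; q <- q / sum(q)
    expect_equal(sym_kl(p, p), 0, tolerance = 1e-12)
    expect_equal(sym_kl(p, q), sym_kl(q, p), tolerance = 1e-12)
    expect_gte(sym_kl(p, q), 0)
  }
  # density-object route agrees with direct mass summation
  g <- seq(-4, 4, length.out = 256)
  set.seed(16)
  dp <- estimate_density(rnorm(100), g)
  dq <- estimate_density(rnorm(100, 1), g)
  w <- c(diff(g) / 2, 0) + c(0, diff(g) / 2)
  pm <- dp$density * w; pm <- pm / sum(pm)
  qm <- dq$density * w; qm <- qm / sum(qm)
  expect_equal(sym_kl(dp, dq),
               0.5 * sum(pm * log(pm / qm) + qm * log(qm / pm)),
               tolerance = 1e-12)
  dq2 <- estimate_density(rnorm(100, 1), seq(-5, 5, length.out = 256))
  expect_error(sym_kl(dp, dq2), "different grids")
})

test_that("distance contrasts stay in [-1, 1] with the boundary attained", {
  expect_equal(distance_contrasts(1, 1, 1)[["Distance1"]], 0)
  expect_equal(distance_contrasts(1, 2, 1)[["Distance1"]], 1 / 3)
  expect_equal(distance_contrasts(1, 2, 0)[["Distance2"]], 1)
  expect_warning(dc <- distance_contrasts(0, 0, 1), "Distance1 undefined")
  expect_true(is.na(dc[["Distance1"]]))
  # brute-force grid: all values within [-1, 1], supremum 1 at zero drift
  dgrid <- seq(0, 10, by = 0.1)
  vals <- outer(dgrid, dgrid, function(a, b) {
    out <- (b - a) / (a + b); out[a + b == 0] <- NA; out
  })
  expect_true(all(abs(vals) <= 1, na.rm = TRUE))
  expect_equal(max(vals, na.rm = TRUE), 1)
  expect_error(distance_contrasts(-1, 2, 3), "non-negative")
})

test_that("distance summaries order separations as constructed", {
  set.seed(17)
  scores <- list(taskrest1 = rnorm(60, 0.1), pre = rnorm(60, 0),
                 post = rnorm(60, 3), taskrest2 = rnorm(60, 1.5))
  ds <- distance_summary(scores)
  expect_gt(ds$d23, ds$d12)
  expect_gt(ds$d23, ds$d34)
  expect_gt(ds$distance1, 0)
  expect_gt(ds$distance2, 0)
  expect_equal(ds$distance1, (ds$d23 - ds$d12) / (ds$d12 + ds$d23),
               tolerance = 1e-12)
  # grid refinement: doubling the KDE grid moves D by < 1%
  rng <- range(unlist(scores))
  g1 <- seq(rng[1] - 1, rng[2] + 1, length.out = 512)
  g2 <- seq(rng[1] - 1, rng[2] + 1, length.out = 1024)
  d1 <- sym_kl(estimate_density(scores$pre, g1),
               estimate_density(scores$post, g1))
  d2 <- sym_kl(estimate_density(scores$pre, g2),
               estimate_density(scores$post, g2))
  expect_lt(abs(d1 - d2) / d1, 0.01)
})

test_that("cohort validation yields probability-one for constructed separations", {
  set.seed(18)
  mk <- function() list(taskrest1 = rnorm(30, 0), pre = rnorm(30, 0),
                        post = rnorm(30, 4), taskrest2 = rnorm(30, 4.2))
  cv <- cohort_validation(replicate(6, mk(), simplify = FALSE))
  expect_equal(cv$p_distance1, 1)
  expect_equal(cv$p_distance2, 1)
  expect_equal(sum(cv$hist1$density), 1, tolerance = 1e-12)
  expect_equal(sum(cv$hist2$density), 1, tolerance = 1e-12)
  expect_length(cv$hist1$counts, 20)
  # participants missing a state are skipped with a warning
  sets <- replicate(3, mk(), simplify = FALSE)
  sets[[2]]$post <- NULL
  expect_warning(cv2 <- cohort_validation(sets), "skipped")
  expect_length(cv2$distance1, 2)
})
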