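test_that("the Spendley construction yields a regular simplex of edge a", {
  for (a in c(1, 0.35)) {
    v <- spendley_simplex(c(0, 0), a = a)
    expect_equal(nrow(v), 3)
    d <- as.matrix(dist(v))
    expect_equal(d[upper.tri(d)], rep(a, 3), tolerance = 1e-12)
  }
  # offsets scale linearly with a
  v1 <- spendley_simplex(rep(0, 5), a = 1)
  v3 <- spendley_simplex(rep(0, 5), a = 3)
  expect_equal(v3, 3 * v1, tolerance = 1e-12)
  # clipping keeps vertices inside the box even from a boundary start
  vb <- spendley_simplex(c(1, 1), a = 0.5, lower = c(0, 0), upper = c(1, 1))
  expect_true(all(vb >= 0 & vb <= 1))
  expect_error(spendley_simplex(c(0, 0), a = -1), "> 0")
})

test_that("vertex ordering finds best, second-worst and worst stably", {
  idx <- order_vertices(c(3, 1, 2))
  expect_equal(idx$best, 2L)
  expect_equal(idx$worst, 1L)
  expect_equal(idx$second, 3L)
  # ties break by vertex index
  tie <- order_vertices(c(5, 5, 5))
  expect_equal(tie$best, 1L)
  expect_equal(tie$worst, 3L)
  withr::with_seed(8, vals <- rnorm(13))
  idx <- order_vertices(vals)
  ord <- order(vals)
  expect_equal(idx$best, ord[1])
  expect_equal(idx$second, ord[12])
  expect_equal(idx$worst, ord[13])
})

test_that("the centroid excludes the worst vertex", {
  v <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(simplex_centroid(v, exclude = 3), c(1, 0))
  vd <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(simplex_centroid(vd, exclude = 2), c(1, 1))
  withr::with_seed(3, v13 <- matrix(rnorm(13 * 12), 13, 12))
  loop <- colSums(v13[-5, ]) / 12
  expect_equal(simplex_centroid(v13, exclude = 5), loop)
})

test_that("a single update improves the worst vertex on convex geometry", {
  f <- function(x) sum((x - c(0.3, 0.7))^2)
  v <- spendley_simplex(c(0.5, 0.5), a = 0.2)
  vals <- apply(v, 1, f)
  st <- nm_step(v, vals, f, lower = c(0, 0), upper = c(1, 1))
  expect_lt(min(st$values), min(vals) + 1e-15)
  expect_lt(max(st$values), max(vals))
  # 50 steps home in on the analytic minimum
  for (i in 1:50) {
    st <- nm_step(st$vertices, st$values, f, lower = c(0, 0), upper = c(1, 1))
  }
  best <- st$vertices[which.min(st$values), ]
  expect_equal(best, c(0.3, 0.7), tolerance = 1e-3)
})

test_that("candidates are projected onto the box before evaluation", {
  seen <- list()
  f <- function(x) { seen[[length(seen) + 1]] <<- x; sum((x - 5)^2) }
  fit <- nm_minimize(f, c(0.5, 0.5), c(0, 0), c(1, 1),
                     nm_control(n_restarts = 3, seed = 7, max_iter = 200,
                                explore_iter = 200))
  pts <- do.call(rbind, seen)
  expect_true(all(pts >= -1e-12 & pts <= 1 + 1e-12))
  # exterior minimum: solution sits on the box corner
  expect_equal(unname(fit$par), c(1, 1), tolerance = 1e-6)
})

test_that("minimize matches a reference simplex optimizer on 12-D quadratics", {
  b <- default_bounds()
  withr::with_seed(21, {
    for (rep in 1:3) {
      center <- b$lower + (0.25 + 0.5 * runif(12)) * (b$upper - b$lower)
      w <- 0.5 + runif(12)
      scale <- (b$upper - b$lower)^2
      f <- function(x) sum(w * (x - center)^2 / scale)
      x0 <- b$lower + 0.5 * (b$upper - b$lower)
      fit <- nm_minimize(f, x0, b$lower, b$upper,
                         nm_control(n_restarts = 2, seed = rep))
      ref <- optim_restarted(f, x0)
      expect_lt(abs(fit$value - ref$value), 1e-6)
      expect_equal(unname(fit$par), unname(center), tolerance = 1e-3)
    }
  })
})

test_that("flat objectives converge immediately near the starting point", {
  f <- function(x) 1
  fit <- nm_minimize(f, c(0.4, 0.6), c(0, 0), c(1, 1),
                     nm_control(n_restarts = 1))
  expect_true(fit$converged)
  # every vertex is equivalent; the result stays inside the initial simplex
  expect_lt(max(abs(unname(fit$par) - c(0.4, 0.6))), 0.15)
  expect_equal(fit$value, 1)
})

test_that("identical seeds give bit-identical results and monotone traces", {
  f <- function(x) sum((x - 0.2)^2) + 0.1 * sum(abs(x))
  ctl <- nm_control(n_restarts = 4, seed = 123)
  f1 <- nm_minimize(f, rep(0.5, 4), rep(0, 4), rep(1, 4), ctl)
  f2 <- nm_minimize(f, rep(0.5, 4), rep(0, 4), rep(1, 4), ctl)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace) <= 0))
})

test_that("non-finite costs are rejected or treated as infinite", {
  f_nan <- function(x) NaN
  expect_error(nm_minimize(f_nan, c(0.5, 0.5), c(0, 0), c(1, 1),
                           nm_control(n_restarts = 1)),
               "non-finite")
  # a partially undefined objective is still minimized on its finite region
  f_part <- function(x) if (x[1] > 0.8) NaN else sum((x - 0.2)^2)
  fit <- nm_minimize(f_part, c(0.5, 0.5), c(0, 0), c(1, 1),
                     nm_control(n_restarts = 2, seed = 5))
  expect_equal(unname(fit$par), c(0.2, 0.2), tolerance = 1e-4)
})

test_that("tidy and glance summarize an nm_fit", {
  f <- function(x) sum((x - 0.5)^2)
  fit <- nm_minimize(f, c(a = 0.2, b = 0.9), c(0, 0), c(1, 1),
                     nm_control(n_restarts = 1))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate, c(0.5, 0.5), tolerance = 1e-5)
  gl <- glance(fit)
  expect_true(all(c("objective", "n_iter", "converged", "restart") %in% names(gl)))
  expect_equal(gl$n_restarts, 1L)
})
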