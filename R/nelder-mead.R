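#' Control settings for the Nelder-Mead simplex fitter
#'
#' @param delta_reflect,delta_expand,delta_contract,delta_shrink Coefficients
#'   of the four simplex moves; the classical values 1, 2, 0.5 and 0.5 are the
#'   defaults.
#' @param simplex_size Edge length `a` of the initial regular (Spendley)
#'   simplex, in box-normalized coordinates (each parameter scaled to
#'   \[0, 1\] by its bounds).
#' @param max_iter Iteration cap per restart.
#' @param tol_x Convergence tolerance on the simplex diameter (normalized
#'   coordinates, infinity norm).
#' @param tol_f Relative convergence tolerance on the spread of cost values
#'   across vertices: a run stops when the spread falls below
#'   `tol_f * (1 + |J_best|)` (or the diameter below `tol_x`).
#' @param n_restarts Number of restarts; the first starts from the supplied
#'   point, the rest from uniform draws inside the box. The best final cost
#'   wins.
#' @param n_polish After a run's simplex converges, the search is re-inflated
#'   around the incumbent best point and re-run, up to `n_polish` times or
#'   until the relative improvement falls below `polish_tol`. This escapes
#'   the premature simplex collapse Nelder-Mead is prone to in narrow curved
#'   valleys.
#' @param polish_tol Relative-improvement threshold that stops the polish
#'   cycles.
#' @param explore_iter Iteration cap used during the exploration phase (each
#'   restart is first run with this lighter budget to rank basins of
#'   attraction).
#' @param n_finish Number of top-ranked restarts that receive the full
#'   finishing treatment (`max_iter` budget, tightened tolerances, deep
#'   polish).
#' @param target Stop finishing further candidates once the incumbent cost
#'   is at or below this value (useful when the attainable minimum is known,
#'   e.g. 0 for noiseless self-consistency runs). Default `-Inf`: finish all
#'   `n_finish` candidates.
#' @param seed Optional integer seed making the restart draws reproducible.
#'
#' @return A list of class `nm_control`.
#' @export
nm_control <- function(delta_reflect = 1, delta_expand = 2,
                       delta_contract = 0.5, delta_shrink = 0.5,
                       simplex_size = 0.1, max_iter = 5000,
                       tol_x = 1e-9, tol_f = 1e-11,
                       n_restarts = 10, n_polish = 6, polish_tol = 1e-6,
                       explore_iter = 500, n_finish = 3, target = -Inf,
                       seed = NULL) {
  stopifnot(
    delta_reflect > 0, delta_expand > 0, delta_contract > 0, delta_shrink > 0,
    simplex_size > 0, max_iter >= 1, tol_x >= 0, tol_f >= 0, n_restarts >= 1,
    n_polish >= 0, polish_tol >= 0, explore_iter >= 1, n_finish >= 1
  )
  structure(
    list(
      delta_reflect = delta_reflect, delta_expand = delta_expand,
      delta_contract = delta_contract, delta_shrink = delta_shrink,
      simplex_size = simplex_size, max_iter = as.integer(max_iter),
      tol_x = tol_x, tol_f = tol_f, n_restarts = as.integer(n_restarts),
      n_polish = as.integer(n_polish), polish_tol = polish_tol,
      explore_iter = as.integer(explore_iter),
      n_finish = as.integer(n_finish), target = target, seed = seed
    ),
    class = "nm_control"
  )
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Regular initial simplex of edge length `a` around a starting point
#'
#' Spendley's construction: vertex `j` (for `j = 1, ..., n`) is
#' `x0 + p e_j + sum_{k != j} q e_k` with
#' `p = a/(n sqrt(2)) (sqrt(n+1) + n - 1)` and
#' `q = a/(n sqrt(2)) (sqrt(n+1) - 1)`, so every edge of the simplex formed by
#' those `n` vertices together with `x0` has length exactly `a` (before any
#' bound clipping). `x0` itself is kept as the `(n+1)`-th vertex.
#'
#' @param x0 Starting point (length `n`).
#' @param a Edge length, `> 0`.
#' @param lower,upper Optional box; vertices are clipped componentwise.
#'
#' @return `(n+1) x n` matrix, one vertex per row; the last row is `x0`.
#' @export
spendley_simplex <- function(x0, a, lower = NULL, upper = NULL) {
  if (a <= 0) abort("simplex size `a` must be > 0")
  n <- length(x0)
  p <- a / (n * sqrt(2)) * (sqrt(n + 1) + n - 1)
  q <- a / (n * sqrt(2)) * (sqrt(n + 1) - 1)
  v <- matrix(rep(x0, each = n + 1), nrow = n + 1)
  for (j in seq_len(n)) {
    v[j, ] <- v[j, ] + q
    v[j, j] <- v[j, j] + (p - q)
  }
  if (!is.null(lower)) {
    for (i in seq_len(n + 1)) v[i, ] <- clip_box(v[i, ], lower, upper)
  }
  v
}

#' Identify best, second-worst and worst vertices
#'
#' Ranks vertices by cost so that `J(best) <= J(second) <= J(worst)`; ties are
#' broken by vertex index (stable sort).
#'
#' @param values Cost at each vertex.
#' @return List with integer indices `best`, `second` (second-worst) and
#'   `worst`.
#' @export
order_vertices <- function(values) {
  ord <- order(values)
  m <- length(values)
  list(best = ord[1], second = ord[m - 1], worst = ord[m])
}

#' Centroid of a simplex excluding one vertex
#'
#' @param vertices Vertex matrix, one vertex per row.
#' @param exclude Row index to leave out (the worst vertex).
#' @return Numeric vector: the mean of the remaining vertices.
#' @export
simplex_centroid <- function(vertices, exclude) {
  colMeans(vertices[-exclude, , drop = FALSE])
}

eval_clipped <- function(f, x, lower, upper) {
  x <- clip_box(x, lower, upper)
  v <- f(x)
  if (!is.finite(v)) v <- Inf
  list(x = x, value = v)
}

# One Nelder-Mead iteration on a simplex (vertices + values), with every
# candidate projected onto the box before evaluation. Standard acceptance
# logic: reflect; expand when the reflected point beats the best; outside/
# inside contract when it is poor; shrink toward the best vertex as fallback.
nm_step_impl <- function(vertices, values, f, cfg, lower, upper) {
  idx <- order_vertices(values)
  h <- idx$worst
  cent <- simplex_centroid(vertices, h)
  xh <- vertices[h, ]
  refl <- eval_clipped(f, cent + cfg$delta_reflect * (cent - xh), lower, upper)
  if (refl$value < values[idx$best]) {
    exp_ <- eval_clipped(f, cent + cfg$delta_expand * (refl$x - cent), lower, upper)
    keep <- if (exp_$value < refl$value) exp_ else refl
    vertices[h, ] <- keep$x; values[h] <- keep$value
  } else if (refl$value < values[idx$second]) {
    vertices[h, ] <- refl$x; values[h] <- refl$value
  } else {
    if (refl$value < values[h]) {
      ctr <- eval_clipped(f, cent + cfg$delta_contract * (refl$x - cent), lower, upper)
      ok <- ctr$value <= refl$value
    } else {
      ctr <- eval_clipped(f, cent + cfg$delta_contract * (xh - cent), lower, upper)
      ok <- ctr$value < values[h]
    }
    if (ok) {
      vertices[h, ] <- ctr$x; values[h] <- ctr$value
    } else {
      l <- idx$best
      xl <- vertices[l, ]
      for (i in seq_len(nrow(vertices))) {
        if (i == l) next
        sh <- eval_clipped(f, xl + cfg$delta_shrink * (vertices[i, ] - xl), lower, upper)
        vertices[i, ] <- sh$x; values[i] <- sh$value
      }
    }
  }
  list(vertices = vertices, values = values)
}

#' One iteration of the box-constrained Nelder-Mead update
#'
#' Exposed mainly for testing and didactic traces; [nm_minimize()] drives the
#' full loop.
#'
#' @param vertices `(n+1) x n` vertex matrix.
#' @param values Cost at each vertex.
#' @param f Cost function taking a length-`n` vector.
#' @param control An [nm_control()] list.
#' @param lower,upper Box bounds (length `n`).
#'
#' @return List with updated `vertices` and `values`.
#' @export
nm_step <- function(vertices, values, f, control = nm_control(),
                    lower = rep(-Inf, ncol(vertices)),
                    upper = rep(Inf, ncol(vertices))) {
  nm_step_impl(vertices, values, f, control, lower, upper)
}

nm_run_single <- function(f, x0, lower, upper, cfg) {
  n <- length(x0)
  vertices <- spendley_simplex(x0, cfg$simplex_size, lower, upper)
  values <- apply(vertices, 1, function(x) {
    v <- f(x)
    if (is.finite(v)) v else Inf
  })
  if (all(!is.finite(values))) {
    abort("cost function returned a non-finite value at every initial vertex")
  }
  trace <- numeric(cfg$max_iter)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    st <- nm_step_impl(vertices, values, f, cfg, lower, upper)
    vertices <- st$vertices
    values <- st$values
    trace[iter] <- min(values)
    l <- which.min(values)
    diam <- max(abs(t(vertices) - vertices[l, ]))
    spread <- max(values) - values[l]
    # either the simplex has collapsed in space, or the cost surface is flat
    # across it relative to the incumbent value; further precision is the
    # polish cycles' job
    if (diam <= cfg$tol_x || spread <= cfg$tol_f * (1 + abs(values[l]))) {
      converged <- TRUE
      break
    }
  }
  l <- which.min(values)
  list(
    par = vertices[l, ], value = values[l], n_iter = iter,
    converged = converged, trace = trace[seq_len(iter)]
  )
}

# One restart = an NM run plus up to n_polish re-inflated re-runs from the
# incumbent best. The incumbent is a vertex of each new simplex, so the
# concatenated best-cost trace stays monotone nonincreasing.
nm_run_polished <- function(f, x0, lower, upper, cfg) {
  res <- nm_run_single(f, x0, lower, upper, cfg)
  polish <- 0L
  while (polish < cfg$n_polish) {
    polish <- polish + 1L
    again <- nm_run_single(f, res$par, lower, upper, cfg)
    improved <- res$value - again$value
    again$trace <- pmin(again$trace, res$value)
    res <- list(
      par = if (again$value < res$value) again$par else res$par,
      value = min(again$value, res$value),
      n_iter = res$n_iter + again$n_iter,
      converged = again$converged,
      trace = c(res$trace, again$trace)
    )
    if (improved <= cfg$polish_tol * (1 + abs(res$value))) break
  }
  res
}

#' Minimize a cost function over a box with restarted Nelder-Mead
#'
#' Runs the simplex search in box-normalized coordinates (each parameter
#' mapped to \[0, 1\] by its bounds, so a single initial simplex size is
#' meaningful across parameters of very different magnitudes), starting from
#' `x0` and, for `n_restarts > 1`, from seeded uniform draws inside the box;
#' the restart with the lowest final cost wins. Every point evaluated is first
#' projected componentwise onto the box, so the search never leaves it, and
#' the best-vertex cost never increases along the returned trace.
#'
#' @param f Cost function mapping a parameter vector (original scale) to a
#'   scalar; non-finite values are treated as `+Inf`.
#' @param x0 Starting point inside the box.
#' @param lower,upper Finite box bounds, same length as `x0`.
#' @param control An [nm_control()] list.
#' @param starts Optional list of explicit restart starting points (original
#'   scale, clipped to the box), one per restart; overrides the default
#'   scheme of `x0` plus uniform draws.
#'
#' @return An object of class `nm_fit`: list with `par` (named like `x0`),
#'   `value`, `n_iter`, `converged`, `trace` (best cost per iteration of the
#'   winning restart), `restart` (1-based index of the winning restart) and
#'   `n_restarts`.
#' @examples
#' f <- function(x) sum((x - c(0.3, 0.7))^2)
#' fit <- nm_minimize(f, c(0.5, 0.5), c(0, 0), c(1, 1),
#'                    nm_control(n_restarts = 1))
#' fit$par
#' @export
nm_minimize <- function(f, x0, lower, upper, control = nm_control(),
                        starts = NULL) {
  cfg <- control
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    abort("nm_minimize requires finite box bounds")
  }
  if (any(lower > upper)) abort("each lower bound must be <= its upper bound")
  if (any(x0 < lower - 1e-12) || any(x0 > upper + 1e-12)) {
    abort("`x0` must lie inside the box")
  }
  span <- upper - lower
  fixed <- span == 0
  span[fixed] <- 1
  to_unit <- function(x) ifelse(fixed, 0, (x - lower) / span)
  from_unit <- function(z) lower + z * span
  f_unit <- function(z) f(from_unit(z))
  z0 <- clip_box(to_unit(x0), 0, 1)
  zl <- rep(0, n); zu <- rep(1, n)

  if (!is.null(starts) && length(starts) != cfg$n_restarts) {
    abort("`starts` must supply one point per restart")
  }
  # Exploration phase: every restart gets a light iteration budget, enough to
  # settle into its basin of attraction and rank it.
  cfg_explore <- cfg
  cfg_explore$max_iter <- min(cfg$explore_iter, cfg$max_iter)
  cfg_explore$n_polish <- min(cfg$n_polish, 1L)
  cfg_explore$polish_tol <- max(cfg$polish_tol, 1e-8)
  run_all <- function() {
    runs <- vector("list", cfg$n_restarts)
    for (r in seq_len(cfg$n_restarts)) {
      zs <- if (!is.null(starts)) {
        clip_box(to_unit(starts[[r]]), 0, 1)
      } else if (r == 1) {
        z0
      } else {
        stats::runif(n)
      }
      runs[[r]] <- nm_run_polished(f_unit, zs, zl, zu, cfg_explore)
      runs[[r]]$restart <- r
    }
    # Finishing phase: the top-ranked basins get the full budget and deep
    # polish at tightened tolerances.
    ranked <- order(vapply(runs, function(x) x$value, numeric(1)))
    best <- NULL
    for (r in ranked[seq_len(min(cfg$n_finish, cfg$n_restarts))]) {
      fin <- nm_run_polished(f_unit, runs[[r]]$par, zl, zu, cfg)
      fin$trace <- pmin(fin$trace, runs[[r]]$value)
      cand <- list(
        par = if (fin$value < runs[[r]]$value) fin$par else runs[[r]]$par,
        value = min(fin$value, runs[[r]]$value),
        n_iter = runs[[r]]$n_iter + fin$n_iter,
        converged = fin$converged,
        trace = c(runs[[r]]$trace, fin$trace),
        restart = r
      )
      if (is.null(best) || cand$value < best$value) best <- cand
      if (best$value <= cfg$target) break
    }
    best
  }
  best <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run_all()) else run_all()

  structure(
    list(
      par = stats::setNames(from_unit(best$par), names(x0)),
      value = best$value, n_iter = best$n_iter, converged = best$converged,
      trace = best$trace, restart = best$restart, n_restarts = cfg$n_restarts,
      control = cfg
    ),
    class = "nm_fit"
  )
}

#' @export
print.nm_fit <- function(x, ...) {
  cat(sprintf(
    "<nm_fit> J = %.6g after %d iterations (restart %d/%d, %s)\n",
    x$value, x$n_iter, x$restart, x$n_restarts,
    if (x$converged) "converged" else "iteration cap"
  ))
  invisible(x)
}

#' @rdname nm_minimize
#' @param x An `nm_fit` object.
#' @param ... Unused.
#' @export
tidy.nm_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par) %||% paste0("x", seq_along(x$par)),
    estimate = unname(x$par)
  )
}

#' @rdname nm_minimize
#' @export
glance.nm_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$value, n_iter = x$n_iter, converged = x$converged,
    restart = x$restart, n_restarts = x$n_restarts
  )
}
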