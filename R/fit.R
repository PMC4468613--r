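#' Data-driven starting point for the constrained fit
#'
#' The cost surface is strongly multimodal in the three physiological
#' frequencies (on a 50 s window neighbouring frequency basins are only about
#' 0.02 Hz apart), which defeats purely local starts. This start constructor
#' profiles the frequencies out first: holding the HRF shape at its canonical
#' values, it scans each frequency band on a grid, scoring each candidate by
#' the residual sum of squares of a linear least-squares fit of
#' `[1, HRF, sin(2 pi f t)]`, then solves for all five amplitudes
#' `(a0, a1, a_c, a_r, a_m)` jointly at the selected frequency triple. The
#' returned vector (canonical shape, profiled frequencies, least-squares
#' amplitudes clipped to the box) then seeds the full 12-D simplex search,
#' which refines all parameters jointly.
#'
#' @inheritParams fit_channel
#' @param shape Shape values used during profiling.
#' @param step_c,step_r,step_m Grid steps (Hz) for the cardiac, respiratory
#'   and Mayer bands.
#'
#' @return Named 12-vector inside the box.
#' @export
profiled_start <- function(observed, paradigm = nirsfit::paradigm(),
                           bounds = default_bounds(),
                           shape = c(alpha1 = 6, alpha2 = 16,
                                     beta1 = 1, beta2 = 1),
                           step_c = 0.01, step_r = 0.01, step_m = 0.005) {
  check_paradigm(paradigm)
  b <- as_bounds(bounds)
  t_k <- paradigm$time
  hrf <- evoked_response(paradigm, as.list(shape))
  base <- cbind(1, hrf)
  # Prefer candidates whose sinusoid enters with positive amplitude: the box
  # constrains amplitudes to be nonnegative, and above-Nyquist frequencies
  # alias onto mirror frequencies with the opposite sign, so the aliased twin
  # of a true component fits equally well but is unusable for the model.
  scan_band <- function(lo, hi, step) {
    grid <- seq(max(lo, step), hi, by = step)
    fits <- vapply(grid, function(f) {
      lf <- stats::.lm.fit(cbind(base, sin(2 * pi * f * t_k)), observed)
      c(sum(lf$residuals^2), lf$coefficients[3])
    }, numeric(2))
    pos <- fits[2, ] > 1e-12
    if (any(pos)) grid[pos][which.min(fits[1, pos])] else grid[which.min(fits[1, ])]
  }
  f_c <- scan_band(b$lower["f_c"], b$upper["f_c"], step_c)
  f_r <- scan_band(b$lower["f_r"], b$upper["f_r"], step_r)
  f_m <- scan_band(b$lower["f_m"], b$upper["f_m"], step_m)
  X <- cbind(base,
             sin(2 * pi * f_c * t_k),
             sin(2 * pi * f_r * t_k),
             sin(2 * pi * f_m * t_k))
  coef <- stats::.lm.fit(X, observed)$coefficients
  start <- c(
    shape[c("alpha1", "alpha2", "beta1", "beta2")],
    a0 = unname(coef[1]), a1 = unname(coef[2]),
    a_c = unname(coef[3]), a_m = unname(coef[5]), a_r = unname(coef[4]),
    f_c = unname(f_c), f_r = unname(f_r), f_m = unname(f_m)
  )
  clip_box(start[.param_names], b$lower, b$upper)
}

# Coarse scan of the 4-D HRF shape box, jointly with the Mayer frequency,
# at the profiled cardiac/respiratory frequencies: for each grid shape and
# each Mayer candidate the amplitudes are solved by linear least squares and
# the residual sum of squares scored. The Mayer band must be scanned jointly
# because a slow sinusoid and an HRF-shape mismatch are mutually
# confounded; the cardiac/respiratory bands are fast enough to decouple.
# Returns the best `k` distinct shapes with their frequency and amplitude
# solutions — a few thousand small LS solves, an effective way to seed the
# simplex search across shape basins.
shape_scan <- function(observed, paradigm, b, prof, k = 6) {
  t_k <- paradigm$time
  sin_c <- sin(2 * pi * prof["f_c"] * t_k)
  sin_r <- sin(2 * pi * prof["f_r"] * t_k)
  fm_grid <- seq(0.01, b$upper["f_m"], by = 0.01)
  fm_grid <- fm_grid[fm_grid >= b$lower["f_m"] - 1e-12]
  sin_m <- vapply(fm_grid, function(f) sin(2 * pi * f * t_k),
                  numeric(length(t_k)))
  grid <- expand.grid(
    alpha1 = seq(2.5, 9.5, by = 1),
    alpha2 = seq(7, 19, by = 3),
    beta1 = seq(0.6, 1.8, by = 0.4),
    beta2 = c(0.15, 0.75, 1.35)
  )
  score <- matrix(NA_real_, nrow(grid), length(fm_grid))
  for (i in seq_len(nrow(grid))) {
    h <- evoked_response(paradigm, as.list(grid[i, ]))
    base <- cbind(1, h, sin_c, sin_r)
    for (j in seq_along(fm_grid)) {
      lf <- stats::.lm.fit(cbind(base, sin_m[, j]), observed)
      score[i, j] <- sum(lf$residuals^2)
    }
  }
  best_fm <- apply(score, 1, which.min)
  shape_score <- score[cbind(seq_len(nrow(grid)), best_fm)]
  # Rank one candidate per (alpha1, beta2) stratum: raw residual score is a
  # poor predictor of which basin a start funnels into, so diversity across
  # the response-delay / undershoot-dispersion plane matters more than raw
  # score rank.
  stratum <- interaction(grid$alpha1, grid$beta2, drop = TRUE)
  per_stratum <- vapply(split(seq_len(nrow(grid)), stratum),
                        function(ix) ix[which.min(shape_score[ix])],
                        integer(1))
  per_stratum <- per_stratum[order(shape_score[per_stratum])]
  rest <- setdiff(order(shape_score), per_stratum)
  top <- utils::head(c(per_stratum, rest), k)
  purrr::map(top, function(i) {
    h <- evoked_response(paradigm, as.list(grid[i, ]))
    f_m <- fm_grid[best_fm[i]]
    coef <- stats::.lm.fit(
      cbind(1, h, sin_c, sin_r, sin(2 * pi * f_m * t_k)), observed
    )$coefficients
    x <- c(unlist(grid[i, ]),
           a0 = unname(coef[1]), a1 = unname(coef[2]),
           a_c = unname(coef[3]), a_m = unname(coef[5]), a_r = unname(coef[4]),
           f_c = unname(prof["f_c"]), f_r = unname(prof["f_r"]),
           f_m = unname(f_m))
    stats::setNames(clip_box(x[.param_names], b$lower, b$upper), .param_names)
  })
}

# Restart start points for one channel: the canonical-shape profiled start,
# then the best shapes from the coarse shape scan, then seeded draws (even
# draws keep the profiled frequencies, lightly jittered; odd draws are fully
# uniform).
build_starts <- function(n_restarts, observed, paradigm, b, prof, seed) {
  f_idx <- match(c("f_c", "f_r", "f_m"), .param_names)
  n_scan <- min(30, max(0, n_restarts - 2))
  scanned <- if (n_scan > 0) shape_scan(observed, paradigm, b, prof, n_scan) else list()
  draw <- function() b$lower + stats::runif(12) * (b$upper - b$lower)
  gen <- function() {
    starts <- c(list(prof), scanned)
    r <- length(starts)
    while (r < n_restarts) {
      r <- r + 1
      x <- draw()
      if (r %% 2 == 0) {
        x[f_idx] <- prof[f_idx] + stats::runif(3, -0.005, 0.005)
      }
      starts[[r]] <- stats::setNames(clip_box(x, b$lower, b$upper), .param_names)
    }
    starts[seq_len(n_restarts)]
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Fit the twelve-parameter response model to one channel
#'
#' Minimizes the sum-of-squares cost [hrf_cost()] over the constraint box
#' with the restarted, box-constrained Nelder-Mead search [nm_minimize()],
#' starting from [default_start()].
#'
#' @param observed Numeric vector of observed HbO values (one channel).
#' @param paradigm A [paradigm()] object matching the series length.
#' @param bounds Constraint box, as [default_bounds()].
#' @param control [nm_control()] optimizer settings.
#' @param start Optional named starting vector; by default the
#'   frequency-profiled start [profiled_start()] seeds the first restart and
#'   the remaining restarts mix uniform draws with draws anchored at the
#'   profiled frequencies.
#'
#' @return An `nm_fit` object whose `par` is the named 12-vector of
#'   estimates.
#' @examples
#' p <- paradigm()
#' truth <- dplyr::filter(reference_params(), dataset == 10)
#' y <- simulate_channel(truth, p, noise_sd = 0.2, seed = 3)$y
#' fit <- fit_channel(y, p, control = nm_control(n_restarts = 2, seed = 1))
#' tidy(fit)
#' @export
fit_channel <- function(observed, paradigm = nirsfit::paradigm(),
                        bounds = default_bounds(), control = nm_control(),
                        start = NULL) {
  check_paradigm(paradigm)
  if (!all(is.finite(observed))) abort("`observed` contains non-finite values")
  if (length(observed) < 14) {
    abort("series too short: need at least two more samples than parameters")
  }
  b <- as_bounds(bounds)
  f <- make_cost(observed, paradigm)
  if (!is.null(start)) {
    x0 <- clip_box(as_param_vector(start), b$lower, b$upper)
    return(nm_minimize(f, x0, b$lower, b$upper, control))
  }
  prof <- profiled_start(observed, paradigm, bounds)
  starts <- build_starts(control$n_restarts, observed, paradigm, b, prof,
                         control$seed)
  res <- nm_minimize(f, prof, b$lower, b$upper, control, starts = starts)
  # Re-profiling rounds: small-amplitude sinusoids can be invisible to the
  # initial frequency scan (which assumes the canonical shape) yet obvious
  # once the response shape has been fitted; rescanning the bands at the
  # fitted shape and refitting from that start recovers them. The simplex
  # itself cannot hop between frequency basins (~0.02 Hz apart).
  ctl1 <- control
  ctl1$n_restarts <- 1L
  ctl1$n_finish <- 1L
  ctl1$explore_iter <- min(control$explore_iter, 300L)
  for (round in 1:2) {
    if (res$value < 1e-10) break
    shp <- res$par[c("alpha1", "alpha2", "beta1", "beta2")]
    prof2 <- profiled_start(observed, paradigm, bounds, shape = shp)
    again <- nm_minimize(f, prof2, b$lower, b$upper, ctl1)
    if (again$value < res$value * (1 - 1e-8)) {
      res <- structure(
        list(par = again$par, value = again$value,
             n_iter = res$n_iter + again$n_iter, converged = again$converged,
             trace = c(res$trace, pmin(again$trace, res$value)),
             restart = res$restart, n_restarts = res$n_restarts,
             control = control),
        class = "nm_fit"
      )
    } else {
      break
    }
  }
  res
}

#' Fit the response model to every channel of a recording
#'
#' Takes a wide data frame of HbO series (one column per channel, optional
#' `time` column ignored) and fits each channel independently with
#' [fit_channel()]. Restart seeds are split deterministically per channel
#' from the control seed, so a fixed seed reproduces the whole multichannel
#' fit.
#'
#' @param data Wide data frame: one numeric column per channel.
#' @param paradigm A [paradigm()] object; `nrow(data)` must equal its sample
#'   count.
#' @inheritParams fit_channel
#'
#' @return An `hrf_fit` tibble with one row per channel: `channel`, `j_opt`,
#'   `n_iter`, `converged`, `restart`, and list-columns `fit` (the `nm_fit`)
#'   and `data` (the observed series). The paradigm and bounds are attached
#'   as attributes.
#' @export
fit_hrf <- function(data, paradigm = nirsfit::paradigm(),
                    bounds = default_bounds(), control = nm_control()) {
  check_paradigm(paradigm)
  channels <- setdiff(names(data), "time")
  if (length(channels) == 0) abort("no channel columns in `data`")
  fits <- purrr::imap(
    stats::setNames(channels, channels),
    function(ch, nm) {
      y <- data[[ch]]
      ctl <- control
      ctl$seed <- derive_seed(control$seed %||% 0, 20000 + match(ch, channels))
      fit_channel(y, paradigm, bounds = bounds, control = ctl)
    }
  )
  out <- tibble::tibble(
    channel = channels,
    j_opt = purrr::map_dbl(fits, "value"),
    n_iter = purrr::map_int(fits, "n_iter"),
    converged = purrr::map_lgl(fits, "converged"),
    restart = purrr::map_int(fits, "restart"),
    fit = unname(fits),
    data = purrr::map(channels, function(ch) as.numeric(data[[ch]]))
  )
  attr(out, "paradigm") <- paradigm
  attr(out, "bounds") <- bounds
  class(out) <- c("hrf_fit", class(out))
  out
}

#' @rdname fit_hrf
#' @param x An `hrf_fit` object.
#' @param ... Unused.
#' @export
tidy.hrf_fit <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("channel", "fit") |>
    dplyr::mutate(est = purrr::map(.data$fit, tidy)) |>
    dplyr::select(-"fit") |>
    tidyr::unnest("est")
}

#' @rdname fit_hrf
#' @export
glance.hrf_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("channel", "j_opt", "n_iter", "converged", "restart")]
}

#' Fitted model series for each channel of an `hrf_fit`
#'
#' @param fits An `hrf_fit` object.
#' @return Long tibble with `channel`, `time`, `observed`, `fitted`.
#' @export
fitted_signal <- function(fits) {
  pdg <- attr(fits, "paradigm")
  tibble::as_tibble(fits) |>
    dplyr::select("channel", "fit", "data") |>
    dplyr::mutate(
      time = list(pdg$time),
      fitted = purrr::map(.data$fit, function(f) model_signal(f$par, pdg)),
      observed = .data$data
    ) |>
    dplyr::select("channel", "time", "observed", "fitted") |>
    tidyr::unnest(c("time", "observed", "fitted"))
}

#' @rdname fit_hrf
#' @param object An `hrf_fit` object.
#' @export
autoplot.hrf_fit <- function(object, ...) {
  df <- fitted_signal(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d1495b") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "HbO (a.u.)"),
                  title = "Observed vs fitted channel series")
}
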