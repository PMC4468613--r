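#' Linearized design matrix at fixed nonlinear parameters
#'
#' With the HRF shape and the three physiological frequencies held fixed, the
#' signal model is linear in `(a0, a1, a_c, a_r, a_m)`; this returns the
#' corresponding design matrix
#' `X = [1, HRF(k), sin(2 pi f_c t), sin(2 pi f_r t), sin(2 pi f_m t)]`.
#'
#' @param params Named parameter vector (only the shape parameters and
#'   frequencies are used).
#' @param paradigm A [paradigm()] object.
#'
#' @return `n_samples x 5` matrix with columns `baseline`, `hrf`, `cardiac`,
#'   `respiratory`, `mayer`.
#' @export
linearized_design <- function(params, paradigm) {
  check_paradigm(paradigm)
  th <- as.list(params)
  t_k <- paradigm$time
  X <- cbind(
    baseline = 1,
    hrf = evoked_response(paradigm, th),
    cardiac = sin(2 * pi * th$f_c * t_k),
    respiratory = sin(2 * pi * th$f_r * t_k),
    mayer = sin(2 * pi * th$f_m * t_k)
  )
  X
}

#' Standard error of the activity-strength estimate
#'
#' GLM-style standard error for `a1` computed on the design linearized at the
#' fitted nonlinear parameters: `sigma2 = SSR / (N - p)` with `p = 12` (all
#' fitted parameters, a conservative residual degrees-of-freedom choice) and
#' `SE(a1) = sqrt(sigma2 * [(X'X)^-1]_hrf,hrf)`. `SSR` is the residual sum of
#' squares of the full nonlinear model at the optimum.
#'
#' @param observed Observed channel series.
#' @param params Fitted parameter vector (e.g. `fit$par` from
#'   [fit_channel()]).
#' @param paradigm A [paradigm()] object.
#' @param p Number of fitted parameters charged against the degrees of
#'   freedom.
#'
#' @return List with `se`, `sigma2`, `dof` and the residual sum of squares
#'   `ssr`.
#' @export
standard_error_a1 <- function(observed, params, paradigm, p = 12) {
  check_paradigm(paradigm)
  n <- paradigm$n_samples
  if (length(observed) != n) abort("series length does not match paradigm")
  if (n <= p) abort("not enough samples for the residual degrees of freedom")
  X <- linearized_design(params, paradigm)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("collinear linearized design (coincident frequencies?)")
  }
  ssr <- hrf_cost(params, observed, paradigm)
  dof <- n - p
  sigma2 <- ssr / dof
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  list(se = se, sigma2 = sigma2, dof = dof, ssr = ssr)
}

#' One-sided t-test of the activity-strength parameter
#'
#' Tests the null hypothesis `a1 = 0` against activation (`a1 > 0`, the only
#' side the constraint box allows) with `t = a1 / SE(a1)` and a one-sided
#' p-value from the t distribution. A channel is significant when both
#' `t > t_critical` and `p < alpha` (strict inequalities). A perfect fit
#' (`SE = 0` with `a1 > 0`) is reported as `t = Inf`, `p = 0`.
#'
#' @param a1 Estimated activity strength.
#' @param se Its standard error, from [standard_error_a1()].
#' @param dof Residual degrees of freedom.
#' @param alpha Significance level.
#'
#' @return Tibble with `t`, `p`, `t_critical`, `significant`.
#' @export
t_test_a1 <- function(a1, se, dof, alpha = 0.05) {
  if (se < 0) abort("`se` must be >= 0")
  t_crit <- qt(1 - alpha, dof)
  t <- if (se == 0) {
    if (a1 == 0) 0 else Inf
  } else {
    a1 / se
  }
  p <- pt(t, dof, lower.tail = FALSE)
  tibble::tibble(
    t = t, p = p, t_critical = t_crit,
    significant = t > t_crit & p < alpha
  )
}

#' Least-squares amplitude fit at fixed nonlinear parameters
#'
#' The linearized counterpart of the full fit: ordinary least squares of the
#' observed series on [linearized_design()], reporting the HbO-response
#' coefficient with the package's standard-error convention
#' (`sigma2 = SSR / (N - p)`, default `p = 12`). Used for calibration checks
#' (type-I error, scale equivariance) where the nonlinear parameters are
#' known.
#'
#' @inheritParams standard_error_a1
#' @param alpha Significance level.
#'
#' @return Tibble with `a1`, `se`, `dof`, `t`, `p`, `t_critical`,
#'   `significant`.
#' @export
linearized_fit <- function(observed, params, paradigm, p = 12, alpha = 0.05) {
  check_paradigm(paradigm)
  X <- linearized_design(params, paradigm)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("collinear linearized design (coincident frequencies?)")
  }
  beta <- qr.coef(qx, observed)
  res <- observed - X %*% beta
  ssr <- sum(res^2)
  dof <- paradigm$n_samples - p
  sigma2 <- ssr / dof
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tt <- t_test_a1(unname(beta[2]), se, dof, alpha)
  tibble::tibble(a1 = unname(beta[2]), se = se, dof = dof,
                 t = tt$t, p = tt$p, t_critical = tt$t_critical,
                 significant = tt$significant)
}

#' Default 16-channel optode layout
#'
#' The emitter-detector pairs over the left motor cortex arranged as a 4 x 4
#' grid, channels `CH01` to `CH16` in row-major order. A custom montage can
#' be supplied to [activation_map()] as any data frame with `channel`,
#' `grid_row`, `grid_col`.
#'
#' @return Tibble with columns `channel`, `grid_row`, `grid_col`.
#' @export
default_layout <- function() {
  tibble::tibble(
    channel = sprintf("CH%02d", 1:16),
    grid_row = rep(1:4, each = 4),
    grid_col = rep(1:4, times = 4)
  )
}

#' Per-channel activation map from fitted models
#'
#' Computes the activity-strength t-statistic for every channel of an
#' [fit_hrf()] result and lays the values out on the optode grid. A channel
#' is flagged significant when `t > t_critical` and `p < alpha`; with
#' `bonferroni = TRUE` the per-channel level is `alpha / n_channels`.
#'
#' @param fits An `hrf_fit` object.
#' @param layout Channel grid, as [default_layout()]; every layout channel
#'   must have a fit.
#' @param alpha Family significance level.
#' @param bonferroni Apply Bonferroni correction across channels?
#'
#' @return An `activation_map` tibble: `channel`, `grid_row`, `grid_col`,
#'   `a1`, `se`, `t`, `p`, `significant`, with `alpha`, `t_critical` and
#'   `dof` attached as attributes.
#' @export
activation_map <- function(fits, layout = default_layout(), alpha = 0.05,
                           bonferroni = FALSE) {
  pdg <- attr(fits, "paradigm")
  missing <- setdiff(layout$channel, fits$channel)
  if (length(missing) > 0) {
    abort(paste0("incomplete layout: no fit for channel(s) ",
                 paste(missing, collapse = ", ")))
  }
  level <- if (bonferroni) alpha / nrow(layout) else alpha
  stats_tbl <- purrr::map(seq_len(nrow(fits)), function(i) {
    par <- fits$fit[[i]]$par
    y <- fits$data[[i]]
    err <- standard_error_a1(y, par, pdg)
    tt <- t_test_a1(unname(par["a1"]), err$se, err$dof, level)
    tibble::tibble(channel = fits$channel[i], a1 = unname(par["a1"]),
                   se = err$se, t = tt$t, p = tt$p,
                   significant = tt$significant, dof = err$dof,
                   t_critical = tt$t_critical)
  }) |>
    dplyr::bind_rows()
  out <- dplyr::inner_join(layout, stats_tbl, by = "channel") |>
    dplyr::arrange(.data$grid_row, .data$grid_col)
  attr(out, "alpha") <- level
  attr(out, "t_critical") <- stats_tbl$t_critical[1]
  attr(out, "dof") <- stats_tbl$dof[1]
  out <- dplyr::select(out, "channel", "grid_row", "grid_col", "a1", "se",
                       "t", "p", "significant")
  class(out) <- c("activation_map", class(out))
  out
}

#' @rdname activation_map
#' @param object An `activation_map`.
#' @param ... Unused.
#' @export
autoplot.activation_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid_col, y = .data$grid_row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$t), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant, "*", ""),
    ), size = 8, vjust = 0.75) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "t") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Channel t-map (* significant)")
}
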