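# A hand-built hrf_fit object lets activation statistics be tested without
# running the optimizer: each channel carries known parameters and data.
fake_hrf_fit <- function(par_list, data_list, paradigm) {
  fits <- purrr::map(par_list, function(par) {
    structure(list(par = par, value = NA_real_, n_iter = 0L, converged = TRUE,
                   trace = numeric(), restart = 1L, n_restarts = 1L),
              class = "nm_fit")
  })
  out <- tibble::tibble(
    channel = names(par_list),
    j_opt = NA_real_, n_iter = 0L, converged = TRUE, restart = 1L,
    fit = unname(fits), data = unname(data_list)
  )
  attr(out, "paradigm") <- paradigm
  attr(out, "bounds") <- default_bounds()
  class(out) <- c("hrf_fit", class(out))
  out
}

test_that("the a1 standard error matches an ordinary least-squares oracle", {
  p <- std_paradigm()
  th <- ref_truth(1)
  y <- simulate_channel(th, p, noise_sd = 0.3, seed = 42)$y
  X <- linearized_design(th, p)
  lin <- linearized_fit(y, th, p)

  ols <- lm(y ~ X - 1)
  expect_equal(lin$a1, unname(coef(ols)[2]), tolerance = 1e-10)
  # the package charges p = 12 parameters against the residual dof
  se_ols <- sqrt(diag(vcov(ols)))[2]
  adj <- sqrt((p$n_samples - ncol(X)) / (p$n_samples - 12))
  expect_equal(lin$se, unname(se_ols * adj), tolerance = 1e-8)
  expect_equal(lin$t, lin$a1 / lin$se, tolerance = 1e-8)
  expect_equal(lin$dof, p$n_samples - 12)
  # p-value agrees with the t tail oracle
  expect_equal(lin$p, pt(lin$t, lin$dof, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("perfect fits report the infinite-t sentinel", {
  p <- std_paradigm()
  th <- ref_truth(1)
  y <- model_signal(th, p)
  se <- standard_error_a1(y, th, p)
  expect_identical(se$se, 0)
  tt <- t_test_a1(th[["a1"]], se$se, se$dof)
  expect_identical(tt$t, Inf)
  expect_identical(tt$p, 0)
  expect_true(tt$significant)
})

test_that("the one-sided test handles the null and the boundary", {
  tt0 <- t_test_a1(0, 1, 78)
  expect_identical(tt0$t, 0)
  expect_equal(tt0$p, 0.5)
  expect_false(tt0$significant)
  # t exactly at the critical value is not significant (strict inequality)
  tcrit <- qt(0.95, 78)
  ttb <- t_test_a1(tcrit, 1, 78)
  expect_equal(ttb$t, ttb$t_critical)
  expect_false(ttb$significant)
  expect_true(t_test_a1(tcrit + 1e-6, 1, 78)$significant)
})

test_that("coincident frequencies are flagged as collinear", {
  p <- std_paradigm()
  th <- ref_truth(1)
  th[c("f_r", "f_m")] <- 0.25
  y <- model_signal(th, p)
  expect_error(standard_error_a1(y, th, p), "collinear")
  expect_error(linearized_fit(y, th, p), "collinear")
})

test_that("the t statistic is invariant to rescaling the series", {
  p <- std_paradigm()
  th <- ref_truth(1)
  y <- simulate_channel(th, p, noise_sd = 0.3, seed = 9)$y
  a <- linearized_fit(y, th, p)
  b <- linearized_fit(5 * y, th, p)
  expect_equal(b$a1, 5 * a$a1, tolerance = 1e-10)
  expect_equal(b$se, 5 * a$se, tolerance = 1e-10)
  expect_equal(b$t, a$t, tolerance = 1e-10)
})

test_that("doubling the noise level doubles the median standard error", {
  p <- std_paradigm()
  th <- ref_truth(1)
  ses <- vapply(c(0.2, 0.4), function(sd) {
    stats::median(vapply(1:100, function(s) {
      y <- simulate_channel(th, p, noise_sd = sd, seed = 5000 + s)$y
      linearized_fit(y, th, p)$se
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ses[2] / ses[1], 2, tolerance = 0.15)
})

test_that("activation maps assemble, validate and respect order invariance", {
  p <- std_paradigm()
  layout <- default_layout()
  th_null <- ref_truth(1)
  th_null["a1"] <- 0
  pars <- purrr::map(stats::setNames(layout$channel, layout$channel),
                     function(ch) th_null)
  datas <- purrr::imap(pars, function(par, ch) {
    simulate_channel(par, p, noise_sd = 0.2,
                     seed = 100 + match(ch, layout$channel))$y
  })
  fits <- fake_hrf_fit(pars, datas, p)
  tm <- activation_map(fits, layout, alpha = 0.05)
  expect_s3_class(tm, "activation_map")
  expect_equal(nrow(tm), 16)
  # a1 = 0 in every channel: t = 0 everywhere, nothing significant
  expect_true(all(tm$t == 0))
  expect_false(any(tm$significant))

  # permuting the fit rows leaves the assembled map unchanged
  fits_perm <- fits[rev(seq_len(nrow(fits))), ]
  attr(fits_perm, "paradigm") <- p
  class(fits_perm) <- c("hrf_fit", class(tibble::tibble()))
  tm2 <- activation_map(fits_perm, layout, alpha = 0.05)
  expect_equal(tibble::as_tibble(tm2), tibble::as_tibble(tm))

  # a missing channel is an incomplete layout
  fits15 <- fits[-3, ]
  attr(fits15, "paradigm") <- p
  class(fits15) <- c("hrf_fit", class(tibble::tibble()))
  expect_error(activation_map(fits15, layout), "incomplete layout")
})

test_that("bonferroni correction tightens the per-channel level", {
  p <- std_paradigm()
  layout <- default_layout()
  th <- ref_truth(1)
  pars <- purrr::map(stats::setNames(layout$channel, layout$channel),
                     function(ch) th)
  datas <- purrr::map(pars, function(par) simulate_channel(par, p, 0.2, seed = 1)$y)
  fits <- fake_hrf_fit(pars, datas, p)
  tm_plain <- activation_map(fits, layout, alpha = 0.05)
  tm_bonf <- activation_map(fits, layout, alpha = 0.05, bonferroni = TRUE)
  expect_equal(attr(tm_bonf, "alpha"), 0.05 / 16)
  expect_gt(attr(tm_bonf, "t_critical"), attr(tm_plain, "t_critical"))
})
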