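test_that("the reference parameter table matches the published sets", {
  tp <- reference_params()
  expect_equal(dim(tp), c(15, 13))
  d1 <- dplyr::filter(tp, dataset == 1)
  expect_equal(unlist(d1[c("alpha1", "alpha2", "beta1", "beta2", "a0", "a1")],
                      use.names = FALSE),
               c(6, 16, 1, 1, 14, 10))
  d10 <- dplyr::filter(tp, dataset == 10)
  expect_equal(d10$alpha1, 5.5)
  expect_equal(d10$a1, 3)
  expect_equal(d10$f_m, 0.09)
  # several ground truths deliberately sit below the strict Mayer band edge
  expect_true(any(tp$f_m < 0.09))
  rb <- relaxed_bounds()
  for (i in 1:15) {
    th <- nirsfit:::as_param_vector(tp[i, ])
    expect_true(all(th >= rb$lower[match(names(th), rb$term)] &
                      th <= rb$upper[match(names(th), rb$term)]),
                label = paste("dataset", i, "feasible in relaxed box"))
  }
})

test_that("simulation is the model signal plus seeded Gaussian noise", {
  p <- std_paradigm()
  th <- ref_truth(10)
  clean <- simulate_channel(th, p, noise_sd = 0)
  expect_identical(clean$y, model_signal(th, p))
  expect_identical(clean$time, p$time)

  s1 <- simulate_channel(th, p, noise_sd = 0.2, seed = 99)
  s2 <- simulate_channel(th, p, noise_sd = 0.2, seed = 99)
  expect_identical(s1$y, s2$y)
  expect_false(identical(s1$y, simulate_channel(th, p, 0.2, seed = 100)$y))

  # moment check on the pooled noise over many seeds
  m <- model_signal(th, p)
  resid <- unlist(lapply(1:300, function(s)
    simulate_channel(th, p, noise_sd = 0.2, seed = s)$y - m))
  n <- length(resid)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(resid)), 4 * 0.2 / sqrt(n))
  expect_equal(var(resid), 0.04, tolerance = 0.05)
})

test_that("the suite packages fifteen seeded datasets with manifests", {
  suite <- simulate_reference_suite(noise_sd = 0.2, seed = 1)
  expect_equal(nrow(suite), 15)
  expect_true(all(vapply(suite$data, nrow, integer(1)) == std_paradigm()$n_samples))
  expect_equal(suite$truth[[1]][["alpha1"]], 6)
  expect_equal(suite$truth[[10]][["a1"]], 3)
  expect_true(all(suite$noise_sd == 0.2))
  # per-dataset seeds differ but derive deterministically from the master
  expect_equal(anyDuplicated(suite$seed), 0)
  suite2 <- simulate_reference_suite(noise_sd = 0.2, seed = 1)
  expect_identical(suite$data, suite2$data)
})

test_that("noiseless self-consistency: the truth has exactly zero cost", {
  p <- std_paradigm()
  suite <- simulate_reference_suite(noise_sd = 0, seed = 1)
  for (i in 1:15) {
    expect_identical(hrf_cost(suite$truth[[i]], suite$data[[i]]$y, p), 0)
  }
})

test_that("the recovery experiment tabulates truth, estimate and error", {
  suite <- simulate_reference_suite(noise_sd = 0, seed = 1)
  sub <- suite[suite$dataset == 1, ]
  attr(sub, "paradigm") <- attr(suite, "paradigm")
  rep <- recovery_experiment(sub, control = quick_control())
  expect_equal(nrow(rep), 12)
  expect_equal(rep$term, param_names())
  expect_true(all(c("truth", "estimate", "abs_error", "j_opt", "converged",
                    "restart") %in% names(rep)))
  expect_equal(rep$abs_error, abs(rep$estimate - rep$truth))
  # noiseless dataset 1 is recovered essentially exactly
  expect_lt(rep$j_opt[1], 1e-6)
  expect_lt(rep$abs_error[rep$term == "alpha1"], 0.1)
})

test_that("strict band edges force out-of-band slow waves into the HRF shape", {
  # dataset 1 has a 0.07 Hz Mayer wave, below the strict 0.09 Hz band edge:
  # under the strict box the optimizer distorts the response shape to absorb
  # it; under the relaxed box the same data are recovered exactly.
  p <- std_paradigm()
  th <- ref_truth(1)
  y0 <- simulate_channel(th, p, noise_sd = 0)$y
  shape_terms <- c("alpha1", "alpha2", "beta1", "beta2")
  strict <- fit_channel(y0, p, bounds = default_bounds(),
                        control = quick_control(seed = 4))
  expect_gt(strict$value, 1)
  expect_gt(max(abs(strict$par[shape_terms] - th[shape_terms])), 0.25)
  relaxed <- fit_channel(y0, p, bounds = relaxed_bounds(),
                         control = quick_control(seed = 4))
  expect_lt(relaxed$value, 1e-6)
  expect_lt(max(abs(relaxed$par[shape_terms] - th[shape_terms])), 0.1)
})

test_that("recovery improves as the noise level drops", {
  p <- std_paradigm()
  th <- ref_truth(1)
  rb <- relaxed_bounds()
  med_err <- vapply(c(0.5, 0.2, 0.05), function(sd) {
    y <- simulate_channel(th, p, noise_sd = sd, seed = 7)$y
    fit <- fit_channel(y, p, bounds = rb, control = quick_control(seed = 3))
    stats::median(abs(fit$par[c("alpha1", "alpha2", "beta1", "beta2", "a0", "a1")] -
                        th[c("alpha1", "alpha2", "beta1", "beta2", "a0", "a1")]))
  }, numeric(1))
  expect_true(all(diff(med_err) <= 1e-8))
})
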