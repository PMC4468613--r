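# Shared fixtures and independent oracles for the test suite.

# The acquisition-default paradigm used throughout.
std_paradigm <- function() paradigm()

# A short paradigm for hand-checkable fixtures (n = 5 samples at 1 Hz).
tiny_paradigm <- function() paradigm(fs = 1, rest_pre = 1, task = 2, rest_post = 2)

ref_truth <- function(ds) {
  nirsfit:::as_param_vector(dplyr::filter(reference_params(), dataset == ds))
}

# O(N^2) direct-sum causal convolution, independent of the package's
# cumulative-sum implementation.
conv_direct <- function(h, u) {
  n <- length(u)
  vapply(seq_len(n), function(k) sum(h[seq_len(k)] * u[k:1]), numeric(1))
}

# Optimizer settings for quick, deterministic fits in unit tests.
quick_control <- function(seed = 1) {
  nm_control(n_restarts = 4, n_finish = 2, seed = seed)
}

# Independent reference minimizer: base R's Nelder-Mead, restarted from its
# own output until it stops improving (a single run stalls far from the
# minimum on 12-D problems).
optim_restarted <- function(f, x0, max_restarts = 50) {
  ref <- list(par = x0, value = f(x0))
  for (i in seq_len(max_restarts)) {
    nxt <- stats::optim(ref$par, f, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
    done <- ref$value - nxt$value < 1e-12
    ref <- nxt
    if (done) break
  }
  ref
}
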