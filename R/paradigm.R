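#' Define a boxcar rest/task/rest experimental paradigm
#'
#' Builds the binary stimulus sequence `u(k)` on the sampling grid of the
#' instrument: 0 during rest, 1 during task. The defaults reproduce a single
#' finger-tapping block of 10 s rest, 10 s task and 30 s rest sampled at
#' 1.81 Hz, i.e. the session structure the packaged validation datasets use.
#'
#' Sample `k` (0-based) occurs at `t_k = k / fs` seconds; `u` is 1 exactly on
#' the half-open interval `[rest_pre, rest_pre + task)`. With `n_trials > 1`
#' the whole block is repeated back to back.
#'
#' @param fs Sampling rate in Hz.
#' @param rest_pre Initial rest duration in seconds.
#' @param task Task duration in seconds.
#' @param rest_post Final rest duration in seconds.
#' @param n_trials Number of consecutive repetitions of the block.
#'
#' @return An object of class `paradigm`: a list with `fs`, the durations,
#'   `n_samples`, the time grid `time` (seconds) and the stimulus vector `u`.
#' @examples
#' p <- paradigm()
#' sum(p$u) # task samples
#' @export
paradigm <- function(fs = 1.81, rest_pre = 10, task = 10, rest_post = 30,
                     n_trials = 1L) {
  stopifnot(fs > 0, rest_pre >= 0, task > 0, rest_post >= 0, n_trials >= 1)
  block <- rest_pre + task + rest_post
  n_block <- round(fs * block)
  if (n_block < 2) abort("paradigm too short for the sampling rate")
  n <- n_block * n_trials
  t_k <- (seq_len(n) - 1) / fs
  t_in_block <- t_k %% block
  u <- as.numeric(t_in_block >= rest_pre & t_in_block < rest_pre + task)
  structure(
    list(
      fs = fs, rest_pre = rest_pre, task = task, rest_post = rest_post,
      n_trials = as.integer(n_trials), n_samples = as.integer(n),
      time = t_k, u = u
    ),
    class = "paradigm"
  )
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf(
    "<paradigm> %g s rest / %g s task / %g s rest x %d, fs = %g Hz (%d samples)\n",
    x$rest_pre, x$task, x$rest_post, x$n_trials, x$fs, x$n_samples
  ))
  invisible(x)
}

is_paradigm <- function(x) inherits(x, "paradigm")

check_paradigm <- function(x) {
  if (!is_paradigm(x)) abort("`paradigm` must be created with paradigm()")
  if (x$n_samples < 1) abort("empty paradigm")
  invisible(x)
}
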