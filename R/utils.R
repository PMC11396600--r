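#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd kmeans cov dist simulate
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic functions in the package route through this
# so that no call mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-stochastic validation shared by the chain sampler and MSM code.
check_stochastic <- function(T, tol = 1e-12) {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(T < 0)) {
    bad <- which(apply(T, 1L, function(r) any(r < 0)))[1L]
    stop(sprintf("transition matrix has negative entries in row %d", bad),
         call. = FALSE)
  }
  rs <- rowSums(T)
  off <- abs(rs - 1)
  if (any(off > tol)) {
    bad <- which.max(off)
    stop(sprintf("row %d of transition matrix sums to %.15g, not 1", bad, rs[bad]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Generator configuration
#'
#' Shared configuration for the synthetic-data generators: the RNG seed, the
#' number of frames to produce and the frame spacing in nanoseconds. The
#' default spacing of 0.1 ns matches the trajectory-saving interval used
#' throughout the package's lag-time bookkeeping.
#'
#' @param seed Integer RNG seed. Identical seed and parameters give
#'   bit-identical output.
#' @param n_frames Positive integer number of frames.
#' @param frame_spacing_ns Positive frame spacing in nanoseconds.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed, n_frames, frame_spacing_ns = 0.1) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (!is.numeric(frame_spacing_ns) || frame_spacing_ns <= 0) {
    stop("frame_spacing_ns must be positive", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_frames = n_frames,
                 frame_spacing_ns = as.numeric(frame_spacing_ns)),
            class = "generator_config")
}

#' Convert a lag time in nanoseconds to steps
#'
#' Bookkeeping helper: a lag of 1.2 ns at a 0.1 ns frame spacing corresponds
#' to 12 steps.
#'
#' @param lag_ns Lag time in ns.
#' @param frame_spacing_ns Frame spacing in ns.
#' @return Integer number of steps.
#' @export
lag_to_steps <- function(lag_ns, frame_spacing_ns) {
  stopifnot(lag_ns > 0, frame_spacing_ns > 0)
  steps <- lag_ns / frame_spacing_ns
  if (abs(steps - round(steps)) > 1e-9) {
    stop(sprintf("lag %g ns is not a multiple of the frame spacing %g ns",
                 lag_ns, frame_spacing_ns), call. = FALSE)
  }
  as.integer(round(steps))
}

#' Number of frames spanning a simulation duration
#'
#' A 450 ns run saved every 0.1 ns yields 4500 frames.
#'
#' @param duration_ns Total simulated time in ns.
#' @param frame_spacing_ns Frame spacing in ns.
#' @return Integer frame count.
#' @export
duration_to_frames <- function(duration_ns, frame_spacing_ns) {
  stopifnot(duration_ns > 0, frame_spacing_ns > 0)
  n <- duration_ns / frame_spacing_ns
  if (abs(n - round(n)) > 1e-9) {
    stop("duration is not a multiple of the frame spacing", call. = FALSE)
  }
  as.integer(round(n))
}
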