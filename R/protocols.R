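# Task protocol definitions: stimuli, device conventions, signal conditioning.
#
# Sign convention used throughout the package: MCP joint neutral = 0 degrees,
# flexion positive, extension negative.  The simulated device workspace is
# [-30, +60] degrees from neutral.

#' Device and protocol constants
#'
#' Fixed properties of the assessment protocol shared by the simulator and the
#' metric-extraction code: sampling rate, filter cutoff, workspace limits and
#' the per-task trial counts of one assessment.
#'
#' @return A named list with elements `fs_hz` (1000), `cutoff_hz` (20),
#'   `workspace_deg` (c(-30, 60)), and `trial_counts`, a named integer vector
#'   giving the number of trials per assessment for each task
#'   (matching 21, reaching 20, rom 6, force 6, tracking 6).
#' @export
#' @examples
#' protocol_constants()$trial_counts
protocol_constants <- function() {
  list(
    fs_hz = 1000,
    cutoff_hz = 20,
    workspace_deg = c(-30, 60),
    # matching: 21 angles once each; reaching: 10 per direction;
    # rom: 3 active + 3 passive reps; force: 3 per direction;
    # tracking: 3 slow + 3 fast trials
    trial_counts = c(matching = 21L, reaching = 20L, rom = 6L,
                     force = 6L, tracking = 6L)
  )
}

#' Trajectory-following stimulus specification
#'
#' Defines the target trajectory of the trajectory-following task as a sum of
#' three superimposed sine waves around a 15-degree flexion offset.  Two
#' presets exist: `"slow"` (0.03, 0.07, 0.13 Hz) and `"fast"`
#' (0.10, 0.20, 0.40 Hz).
#'
#' The protocol assigns the three components "the same amplitude" of 15
#' degrees, which read literally gives a summed peak excursion of up to 45
#' degrees around the centre and can exceed the device workspace.  With
#' `amplitude_mode = "split"` (the default) the 15 degrees are divided
#' equally over the three components (5 degrees each), keeping the stimulus
#' inside the workspace; `amplitude_mode = "strict"` uses 15 degrees per
#' component and relies on workspace saturation downstream.
#'
#' @param label `"slow"` or `"fast"`.
#' @param amplitude_mode `"split"` (5 deg per component) or `"strict"`
#'   (15 deg per component).
#' @param duration_s Trial duration in seconds (default 30).
#' @return An object of class `trajectory_spec`: a list with
#'   `component_freqs_hz`, `component_amp_deg`, `center_deg`, `duration_s`,
#'   `label`.
#' @export
#' @examples
#' trajectory_spec("slow")
trajectory_spec <- function(label = c("slow", "fast"),
                            amplitude_mode = c("split", "strict"),
                            duration_s = 30) {
  label <- match.arg(label)
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number", call. = FALSE)
  freqs <- switch(label,
                  slow = c(0.03, 0.07, 0.13),
                  fast = c(0.10, 0.20, 0.40))
  amp <- switch(amplitude_mode, split = rep(15 / 3, 3), strict = rep(15, 3))
  structure(
    list(component_freqs_hz = freqs,
         component_amp_deg = amp,
         center_deg = 15,
         duration_s = duration_s,
         label = label,
         amplitude_mode = amplitude_mode),
    class = "trajectory_spec"
  )
}

#' Generate the target trajectory of the trajectory-following task
#'
#' Evaluates `y(t) = center + sum_i amp_i * sin(2 * pi * f_i * t)` on the
#' uniform sample grid `t = k / fs_hz`, `k = 0, ..., floor(duration_s * fs_hz)`.
#' The generation is deterministic and linear in the component amplitudes.
#'
#' @param spec A [trajectory_spec()].
#' @param fs_hz Sampling rate in Hz.
#' @return A data frame with columns `time_s` and `position_deg`.
#' @export
#' @examples
#' y <- generate_target_trajectory(trajectory_spec("slow"), fs_hz = 100)
#' y$position_deg[1]  # 15: all sines are zero at t = 0
generate_target_trajectory <- function(spec, fs_hz) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("`fs_hz` must be a single positive sampling rate", call. = FALSE)
  if (any(spec$component_freqs_hz <= 0))
    stop("component frequencies must be positive", call. = FALSE)
  t <- seq(0L, floor(spec$duration_s * fs_hz)) / fs_hz
  y <- rep(spec$center_deg, length(t))
  for (i in seq_along(spec$component_freqs_hz)) {
    y <- y + spec$component_amp_deg[i] *
      sin(2 * pi * spec$component_freqs_hz[i] * t)
  }
  data.frame(time_s = t, position_deg = y)
}

#' Generate the presented-angle sequence of the position-matching task
#'
#' One position-matching assessment presents each of the 21 integer target
#' angles 10..30 degrees flexion exactly once, in seeded random order.
#'
#' @param seed Integer seed; the same seed always yields the same order.
#' @return Integer vector of length 21, a permutation of `10:30`.
#' @export
#' @examples
#' generate_angle_sequence(1)
generate_angle_sequence <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  with_seed(as.integer(seed), sample(10:30))
}

#' Fast-target-reaching stimulus
#'
#' Returns the fixed start/target pair of the fast target reaching task:
#' flexion trials start at -10 degrees and reach toward +30 degrees,
#' extension trials start at +30 degrees and reach toward -10 degrees.
#' A 4-second response window is given in both cases.
#'
#' @param direction `"flexion"` or `"extension"`.
#' @return A list with `direction`, `start_deg`, `target_deg`, `window_s`.
#' @export
reaching_stimulus <- function(direction = c("flexion", "extension")) {
  direction <- match.arg(direction)
  if (direction == "flexion")
    list(direction = "flexion", start_deg = -10, target_deg = 30, window_s = 4)
  else
    list(direction = "extension", start_deg = 30, target_deg = -10, window_s = 4)
}

#' First-order Butterworth low-pass filter
#'
#' Applies the device's signal-conditioning filter (first-order Butterworth,
#' default cutoff 20 Hz) to a uniformly sampled signal.  The filter is applied
#' in the frequency domain using the exact analog transfer function
#' `H(f) = 1 / (1 + i f / fc)`, so the magnitude response equals the analytic
#' `1 / sqrt(1 + (f / fc)^2)` at every frequency below Nyquist and the DC gain
#' is exactly 1.  By default the causal phase response of the analog filter is
#' retained (mimicking the device's real-time filter); `zero_phase = TRUE`
#' applies the squared magnitude with zero phase, equivalent to a
#' forward-backward pass, for offline analysis.
#'
#' The signal is reflection-padded before transforming to suppress periodic
#' wrap-around at the edges.
#'
#' @param x Numeric signal vector.
#' @param cutoff_hz Cutoff frequency in Hz (default 20).
#' @param fs_hz Sampling rate in Hz (default 1000).
#' @param zero_phase Apply the filter forward-backward (zero phase lag)?
#' @return Filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' y <- lowpass(sin(2 * pi * 20 * t))   # attenuated to ~1/sqrt(2)
lowpass <- function(x, cutoff_hz = 20, fs_hz = 1000, zero_phase = FALSE) {
  stopifnot(is.numeric(x))
  if (!is.numeric(fs_hz) || fs_hz <= 0 || !is.numeric(cutoff_hz) || cutoff_hz <= 0)
    stop("`cutoff_hz` and `fs_hz` must be positive", call. = FALSE)
  if (fs_hz <= 2 * cutoff_hz)
    stop("cutoff must be below the Nyquist frequency fs_hz / 2", call. = FALSE)
  n <- length(x)
  if (n < 2L) return(x)
  # reflect ~4 filter time constants at each edge to avoid wrap-around
  npad <- min(n - 1L, ceiling(4 * fs_hz / cutoff_hz))
  xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  m <- length(xp)
  f <- c(seq(0L, floor(m / 2)), seq(-ceiling(m / 2) + 1L, -1L)) * (fs_hz / m)
  h <- 1 / (1 + 1i * f / cutoff_hz)
  if (zero_phase) h <- Mod(h)^2
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

#' Clip a position signal to the device workspace
#'
#' The simulated end-effector cannot leave the physical workspace of the
#' device, `[-30, +60]` degrees from the MCP neutral position.  Clipping
#' events are counted on the returned vector's `"n_clipped"` attribute.
#'
#' @param x Numeric position signal (degrees).
#' @param workspace Length-2 numeric, lower and upper limit (degrees).
#' @return `x` clipped to the workspace, with attribute `n_clipped`.
#' @export
clip_workspace <- function(x, workspace = protocol_constants()$workspace_deg) {
  stopifnot(is.numeric(x), length(workspace) == 2L, workspace[1] < workspace[2])
  clipped <- pmin(pmax(x, workspace[1]), workspace[2])
  attr(clipped, "n_clipped") <- sum(clipped != x)
  clipped
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit sub-seed from a master seed and stream labels.
# Keeps independent substreams stable under partial regeneration.
sub_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) utf8ToInt(paste0(p))))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) h <- (h * 31 + p) %% 2147483647
  as.integer(h)
}
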