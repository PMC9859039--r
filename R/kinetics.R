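#' Nucleation kinetics parameters
#'
#' Bundles the parameters of the saturating nucleation rate law used to
#' describe templated microtubule (MT) nucleation: an initial rate `k`
#' (MTs nucleated per second) and a capacity `n_max`, the total number
#' of activatable nucleation templates. The instantaneous rate decays as
#' templates are consumed, so count trajectories rise linearly at rate
#' `k` and saturate at `n_max`. An optional second phase (`switch_time`,
#' `k_post`) supports two-step scenarios in which the rate changes at a
#' given time (e.g. delayed activation of a slow mutant to the wildtype
#' rate).
#'
#' @param k nucleation rate, MTs/s; must be >= 0.
#' @param n_max maximum number of activatable nucleators (dimensionless
#'   count); must be > 0.
#' @param switch_time optional time (s, > 0) at which two-phase rules
#'   apply; requires `k_post`.
#' @param k_post optional post-switch rate (MTs/s); required iff
#'   `switch_time` is given.
#' @return An object of class `nucleation_kinetics`.
#' @examples
#' wt <- nucleation_kinetics(k = 24.5, n_max = 300)
#' @export
nucleation_kinetics <- function(k, n_max, switch_time = NULL, k_post = NULL) {
  .check_scalar(k, "k", lower = 0)
  .check_scalar(n_max, "n_max", lower = 0, strict = TRUE)
  if (xor(is.null(switch_time), is.null(k_post)))
    stop("'switch_time' and 'k_post' must be given together", call. = FALSE)
  if (!is.null(switch_time)) {
    .check_scalar(switch_time, "switch_time", lower = 0, strict = TRUE)
    .check_scalar(k_post, "k_post", lower = 0)
  }
  structure(list(k = k, n_max = n_max,
                 switch_time = switch_time, k_post = k_post),
            class = "nucleation_kinetics")
}

#' @export
print.nucleation_kinetics <- function(x, ...) {
  cat(sprintf("nucleation kinetics: k = %g MTs/s, n_max = %g\n", x$k, x$n_max))
  if (!is.null(x$switch_time))
    cat(sprintf("  two-phase: k -> %g MTs/s at t = %g s\n",
                x$k_post, x$switch_time))
  invisible(x)
}

.as_kinetics <- function(kin) {
  if (!inherits(kin, "nucleation_kinetics"))
    stop("'kin' must be a nucleation_kinetics object", call. = FALSE)
  kin
}

#' Closed-form nucleated-MT count
#'
#' Evaluates the saturating-exponential rate law
#' \deqn{N(t) = N_{max} (1 - e^{-k t / N_{max}})}
#' giving the cumulative number of MTs nucleated by time `t` when
#' nucleation starts at rate `k` from a finite pool of `n_max`
#' templates. `N(0) = 0`, the initial slope is exactly `k`, and
#' `N(t) -> n_max` as `t` grows.
#'
#' @param t time(s) in seconds; vectorized; all must be >= 0.
#' @param kin a [nucleation_kinetics()] object.
#' @return Numeric vector of cumulative MT counts (real-valued).
#' @examples
#' kin <- nucleation_kinetics(k = 1.2, n_max = 100)
#' nucleation_counts(c(0, 10, 1e6), kin)
#' @export
nucleation_counts <- function(t, kin) {
  kin <- .as_kinetics(kin)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  kin$n_max * (1 - exp(-kin$k * t / kin$n_max))
}

.new_trajectory <- function(time_s, count) {
  structure(data.frame(time_s = time_s, count = count),
            class = c("count_trajectory", "data.frame"))
}

#' Check/construct a count trajectory
#'
#' A count trajectory is a data frame with columns `time_s` (strictly
#' increasing, starting at 0) and `count` (non-negative, non-decreasing
#' for model output).
#'
#' @param time_s times in seconds.
#' @param count cumulative MT counts.
#' @return A `count_trajectory` data frame.
#' @export
count_trajectory <- function(time_s, count) {
  if (length(time_s) != length(count) || length(time_s) < 1L)
    stop("'time_s' and 'count' must have equal positive length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing", call. = FALSE)
  if (any(count < 0)) stop("'count' must be non-negative", call. = FALSE)
  .new_trajectory(time_s, count)
}

# One forward-difference step of the discrete rate law, clamped to the
# capacity so the count can never exceed n_max.
.step_count <- function(n, k, n_max, dt) {
  min(n_max, n + dt * k * (1 - n / n_max))
}

#' Discrete-time nucleation trajectory
#'
#' Integrates the discrete counterpart of the saturating rate law,
#' \deqn{N_t = N_{t-\Delta t} + \Delta t \, k (1 - N_{t-\Delta t}/N_{max})}
#' from `N(0) = 0`. At the default `dt = 1` s this is the standard
#' per-second update used in deterministic simulations of templated
#' nucleation; as `dt -> 0` the trajectory converges to
#' [nucleation_counts()]. Increments are clamped so the count never
#' exceeds `n_max`; counts are real-valued (integerization, if wanted,
#' happens in the movie simulator).
#'
#' @param kin a [nucleation_kinetics()] object.
#' @param duration total simulated time, s (> 0).
#' @param dt time step, s (> 0); default 1.
#' @return A `count_trajectory` data frame with times `0, dt, ...`.
#' @examples
#' nucleation_trajectory(nucleation_kinetics(2, 4), duration = 3)
#' @export
nucleation_trajectory <- function(kin, duration, dt = 1) {
  kin <- .as_kinetics(kin)
  .check_scalar(duration, "duration", lower = 0, strict = TRUE)
  .check_scalar(dt, "dt", lower = 0, strict = TRUE)
  times <- seq(0, duration, by = dt)
  counts <- numeric(length(times))
  for (i in seq_along(times)[-1])
    counts[i] <- .step_count(counts[i - 1L], kin$k, kin$n_max, dt)
  .new_trajectory(times, counts)
}

#' Two-phase nucleation trajectory
#'
#' Discrete-time trajectory in which the nucleation parameters change at
#' `switch_time`: phase 1 runs with `kin_phase1`; from the switch on,
#' the rate becomes `kin_wt$k` and the remaining capacity becomes
#' `max(0, kin_wt$n_max - N(switch_time))`, added on top of the MTs
#' already present. This models delayed activation: a slow condition
#' whose nucleators are later converted to the fast (wildtype)
#' behaviour, with the already-consumed templates subtracted from the
#' wildtype capacity. The trajectory is continuous at the switch and
#' MTs are never removed; if the wildtype capacity is already exhausted
#' the remaining capacity is floored at 0 (with a message).
#'
#' @param kin_phase1 kinetics before the switch.
#' @param kin_wt kinetics whose rate and capacity apply after the
#'   switch.
#' @param switch_time time of the switch, s; 0 < switch_time < duration.
#' @param duration total simulated time, s.
#' @param dt time step, s; default 1.
#' @return A `count_trajectory` data frame.
#' @examples
#' slow <- nucleation_kinetics(2.4, 60)
#' wt   <- nucleation_kinetics(24.5, 300)
#' traj <- two_phase_trajectory(slow, wt, switch_time = 150, duration = 300)
#' @export
two_phase_trajectory <- function(kin_phase1, kin_wt, switch_time, duration,
                                 dt = 1) {
  kin_phase1 <- .as_kinetics(kin_phase1)
  kin_wt <- .as_kinetics(kin_wt)
  .check_scalar(switch_time, "switch_time", lower = 0, strict = TRUE)
  .check_scalar(duration, "duration", lower = 0, strict = TRUE)
  if (switch_time >= duration)
    return(nucleation_trajectory(kin_phase1, duration, dt))
  times <- seq(0, duration, by = dt)
  counts <- numeric(length(times))
  n_switch <- NA_real_
  for (i in seq_along(times)[-1]) {
    if (times[i] <= switch_time) {
      counts[i] <- .step_count(counts[i - 1L], kin_phase1$k, kin_phase1$n_max,
                               dt)
    } else {
      if (is.na(n_switch)) {
        n_switch <- counts[i - 1L]
        cap2 <- kin_wt$n_max - n_switch
        if (cap2 < 0)
          .log_msg("two-phase switch: wildtype capacity %g below N(switch) = %g; remaining capacity floored at 0",
                   kin_wt$n_max, n_switch)
        cap2 <- max(0, cap2)
      }
      if (cap2 <= 0) {
        counts[i] <- counts[i - 1L]
      } else {
        m <- .step_count(counts[i - 1L] - n_switch, kin_wt$k, cap2, dt)
        counts[i] <- n_switch + m
      }
    }
  }
  .new_trajectory(times, counts)
}

#' Write / read a count trajectory as CSV
#'
#' Two-column CSV (`time_s`, `count`) with header. Values are written
#' with 12 significant digits, so a written file read back and written
#' again is byte-identical.
#'
#' @param traj a `count_trajectory` (or compatible data frame).
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a `count_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  if (!all(c("time_s", "count") %in% names(traj)))
    stop("trajectory must have columns time_s, count", call. = FALSE)
  out <- data.frame(time_s = formatC(traj$time_s, digits = 12, format = "g"),
                    count = formatC(traj$count, digits = 12, format = "g"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  if (!all(c("time_s", "count") %in% names(df)))
    stop(sprintf("'%s' is not a trajectory CSV (needs time_s, count)", path),
         call. = FALSE)
  count_trajectory(df$time_s, df$count)
}
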