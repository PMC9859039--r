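#' Fit the saturating nucleation model to a count trajectory
#'
#' Nonlinear least-squares estimation of the nucleation rate `k` and
#' capacity `n_max` of
#' \deqn{N(t) = N_{max} (1 - e^{-k t / N_{max}})}
#' on the counts inside `window` (default the first 150 s, the
#' standard counting window). The fit is bounded below at `1e-6` for
#' both parameters and multi-started: `k` from the first-difference
#' slope at the origin, `n_max` from `{1, 2, 10} x max(count)`, keeping
#' the start with the smallest residual. When the trajectory never
#' approaches saturation inside the window, `n_max` is weakly
#' identified; the fit is then flagged (`weakly_identified`) when its
#' Hessian-based 95% relative confidence half-width exceeds 100%.
#'
#' @param traj a `count_trajectory` (or data frame with `time_s`,
#'   `count`).
#' @param window fit window `c(from, to)` in s; default `c(0, 150)`.
#' @return An object of class `nucleation_fit`: `k_hat`, `n_max_hat`,
#'   `residual_norm`, `converged`, `initial_guess`,
#'   `weakly_identified`, `n_points`.
#' @examples
#' kin <- nucleation_kinetics(24.5, 300)
#' traj <- count_trajectory(seq(0, 150, 2),
#'                          nucleation_counts(seq(0, 150, 2), kin))
#' fit_nucleation(traj)$k_hat
#' @export
fit_nucleation <- function(traj, window = c(0, 150)) {
  d <- traj[traj$time_s >= window[1] & traj$time_s <= window[2], ]
  if (nrow(d) < 5L)
    stop("need at least 5 points inside the fit window", call. = FALSE)
  if (any(d$count < 0)) stop("counts must be non-negative", call. = FALSE)
  tt <- d$time_s; yy <- d$count

  k0 <- {
    i <- seq_len(min(3L, length(tt) - 1L)) + 1L
    s <- max((yy[i] - yy[1]) / (tt[i] - tt[1]))
    if (!is.finite(s) || s <= 0) 1e-3 else s
  }
  n0s <- unique(pmax(1, c(1, 2, 10) * max(yy, 1)))

  best <- NULL
  for (n0 in n0s) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ nmax * (1 - exp(-k * tt / nmax)),
                        start = list(k = k0, nmax = n0),
                        lower = c(1e-6, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss, start = c(k = k0, nmax = n0))
  }
  if (is.null(best))
    return(structure(list(k_hat = NA_real_, n_max_hat = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          initial_guess = NULL, weakly_identified = NA,
                          n_points = nrow(d)),
                     class = "nucleation_fit"))
  est <- coef(best$fit)
  weak <- tryCatch({
    se <- sqrt(diag(vcov(best$fit)))
    any(1.96 * se / abs(est) > 1)
  }, error = function(e) TRUE)
  # a trajectory that never reaches half its fitted capacity inside the
  # window cannot pin n_max even when residuals vanish
  if (max(yy) < 0.5 * est["nmax"]) weak <- TRUE
  structure(list(k_hat = unname(est["k"]), n_max_hat = unname(est["nmax"]),
                 residual_norm = sqrt(best$rss), converged = TRUE,
                 initial_guess = best$start, weakly_identified = weak,
                 n_points = nrow(d)),
            class = "nucleation_fit")
}

#' @export
print.nucleation_fit <- function(x, ...) {
  if (!x$converged) { cat("nucleation fit: did not converge\n"); return(invisible(x)) }
  cat(sprintf("nucleation fit: k = %.4g MTs/s, n_max = %.4g%s (rss^0.5 = %.3g, n = %d)\n",
              x$k_hat, x$n_max_hat,
              if (isTRUE(x$weakly_identified)) " [n_max weakly identified]" else "",
              x$residual_norm, x$n_points))
  invisible(x)
}

#' Late-phase linear nucleation rate
#'
#' Ordinary least-squares slope of the count trajectory over a late
#' window (default 25-150 s), the residual nucleation rate after the
#' initial burst has saturated.
#'
#' @param traj a `count_trajectory`.
#' @param window `c(from, to)` in s; default `c(25, 150)`.
#' @return Slope in MTs/s.
#' @export
late_slope <- function(traj, window = c(25, 150)) {
  d <- traj[traj$time_s >= window[1] & traj$time_s <= window[2], ]
  if (nrow(d) < 3L)
    stop("need at least 3 points inside the late window", call. = FALSE)
  unname(coef(lm(count ~ time_s, data = d))[2])
}

#' Aggregate per-replicate nucleation rates
#'
#' Arithmetic mean and standard error of the fitted rate across
#' replicate reactions; the headline uncertainty of a condition is
#' this between-replicate SEM, not the per-fit covariance.
#'
#' @param fits list of converged [fit_nucleation()] results (or a
#'   numeric vector of rates).
#' @return List: `mean_k`, `sem_k` (`NA` for a single replicate), `n`.
#' @export
aggregate_replicates <- function(fits) {
  ks <- if (is.numeric(fits)) fits else {
    if (!length(fits)) stop("empty fit list", call. = FALSE)
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!all(ok)) stop("all fits must have converged", call. = FALSE)
    vapply(fits, function(f) f$k_hat, numeric(1))
  }
  if (!length(ks)) stop("empty fit list", call. = FALSE)
  list(mean_k = mean(ks),
       sem_k = if (length(ks) >= 2L) sd(ks) / sqrt(length(ks)) else NA_real_,
       n = length(ks))
}

#' Two-sample unpaired comparison of conditions
#'
#' Two-sided, unpaired Student's t-test (equal variances), the test
#' used throughout the assay's statistics; significance is declared at
#' `alpha`. Two samples with zero variance and equal means give
#' p = 1 by convention.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param alpha significance level; default 0.05.
#' @return List: `p_value`, `t`, `significant`.
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(p_value = 1, t = 0, significant = FALSE))
    return(list(p_value = 0, t = Inf, significant = TRUE))
  }
  tst <- t.test(a, b, var.equal = TRUE)
  list(p_value = unname(tst$p.value), t = unname(tst$statistic),
       significant = tst$p.value < alpha)
}

#' Normalize values by a control condition
#'
#' Divides each value by the control mean (fold change over control).
#' With `paired = TRUE`, values and controls are matched element-wise
#' (per-experiment normalization, as when every extract prep carries
#' its own buffer reaction).
#'
#' @param values numeric vector.
#' @param control_values numeric vector; its mean (or each element,
#'   when paired) must be > 0.
#' @param paired element-wise pairing; requires equal lengths.
#' @return Normalized values (dimensionless).
#' @export
normalize_condition <- function(values, control_values, paired = FALSE) {
  if (paired) {
    if (length(values) != length(control_values))
      stop("paired normalization needs equal lengths", call. = FALSE)
    if (any(control_values <= 0))
      stop("control values must be > 0", call. = FALSE)
    return(values / control_values)
  }
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0)
    stop("control mean must be > 0", call. = FALSE)
  values / m
}

#' Fit a set of trajectory files and summarize by condition
#'
#' Reads trajectory CSVs, fits each with [fit_nucleation()], and
#' aggregates per condition: mean rate with SEM, fold change over the
#' control condition, and an unpaired t-test against the control.
#'
#' @param files character vector of trajectory CSV paths.
#' @param conditions condition label per file.
#' @param control name of the control condition; default the first
#'   label.
#' @param window fit window, s.
#' @return List: `fits` (data frame: condition, file, k, n_max,
#'   converged, residual_norm, weakly_identified) and `summary` (data
#'   frame per condition: n, mean_k, sem_k, fold_change, p_value).
#' @export
fit_trajectories <- function(files, conditions, control = conditions[1],
                             window = c(0, 150)) {
  stopifnot(length(files) == length(conditions), length(files) >= 1L)
  rows <- lapply(seq_along(files), function(i) {
    f <- fit_nucleation(read_trajectory(files[i]), window = window)
    data.frame(condition = conditions[i], file = files[i],
               k = f$k_hat, n_max = f$n_max_hat, converged = f$converged,
               residual_norm = f$residual_norm,
               weakly_identified = f$weakly_identified)
  })
  fits <- do.call(rbind, rows)
  ctrl_k <- fits$k[fits$condition == control & fits$converged]
  if (!length(ctrl_k))
    stop(sprintf("no converged fits for control condition '%s'", control),
         call. = FALSE)
  summ <- do.call(rbind, lapply(unique(fits$condition), function(cn) {
    ks <- fits$k[fits$condition == cn & fits$converged]
    agg <- aggregate_replicates(ks)
    p <- if (cn == control || length(ks) < 2L || length(ctrl_k) < 2L)
      NA_real_ else compare_conditions(ks, ctrl_k)$p_value
    data.frame(condition = cn, n = agg$n, mean_k = agg$mean_k,
               sem_k = agg$sem_k,
               fold_change = agg$mean_k / mean(ctrl_k), p_value = p)
  }))
  list(fits = fits, summary = summ)
}
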