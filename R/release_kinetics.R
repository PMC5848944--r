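# Fickian plane-sheet release: dC/dt = D d2C/dZ2 on a film of thickness L,
# uniform initial loading, perfect-sink boundaries. Everything reduces to the
# nondimensional time tau = D t / L^2 (both-faces release; one-sided release
# is the half-slab, L_eff = 2 L).

#' Fickian slab release model
#'
#' Diffusion-controlled release from a polymer film: diffusivity `D`
#' (cm^2/s), film thickness (cm), and the algebraic form of the early-time
#' law. `"standard_sheet"` is the classical plane-sheet early-time solution
#' \eqn{M_t/M_\infty = (4/\delta)\sqrt{D t/\pi}}; `"as_printed"` is the
#' dimensionally inconsistent variant \eqn{4\sqrt{D t/(\pi\delta)}} that
#' appears in parts of the drug-release literature, retained only for
#' literal reproduction (see the methods vignette).
#'
#' @param diffusivity Diffusion coefficient, cm^2/s, >= 0.
#' @param thickness Film thickness, cm, > 0.
#' @param geometry_form `"standard_sheet"` (default) or `"as_printed"`.
#' @param sides `2` (default): release through both film faces; `1`:
#'   one face sealed.
#' @return An object of class `fickian_slab`.
#' @export
fickian_slab <- function(diffusivity, thickness,
                         geometry_form = c("standard_sheet", "as_printed"),
                         sides = 2) {
  geometry_form <- match.arg(geometry_form)
  diffusivity <- as.numeric(diffusivity); thickness <- as.numeric(thickness)
  if (!is.finite(diffusivity) || diffusivity < 0)
    stop("`diffusivity` must be finite and non-negative (cm^2/s)")
  if (!is.finite(thickness) || thickness <= 0)
    stop("`thickness` must be positive (cm)")
  if (!sides %in% c(1, 2)) stop("`sides` must be 1 or 2")
  structure(list(diffusivity = diffusivity, thickness = thickness,
                 geometry_form = geometry_form, sides = sides),
            class = "fickian_slab")
}

#' @export
print.fickian_slab <- function(x, ...) {
  cat(sprintf("Fickian slab: D = %g cm^2/s, thickness = %g cm (%s, %d-sided)\n",
              x$diffusivity, x$thickness, x$geometry_form, x$sides))
  invisible(x)
}

# effective thickness entering tau: one-sided release behaves as the half
# of a slab twice as thick
effective_thickness <- function(model) {
  model$thickness * if (model$sides == 1) 2 else 1
}

#' First-order release model
#'
#' \eqn{M_t/M_\infty = plateau \,(1 - e^{-rate\, t})}: exponential approach
#' to a release plateau.
#'
#' @param rate Release rate constant, 1/h, > 0.
#' @param plateau_fraction Asymptotic released fraction in (0, 1].
#' @return An object of class `first_order_model`.
#' @export
first_order_model <- function(rate, plateau_fraction = 1) {
  rate <- as.numeric(rate); plateau_fraction <- as.numeric(plateau_fraction)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be positive (1/h)")
  if (!is.finite(plateau_fraction) || plateau_fraction <= 0 ||
      plateau_fraction > 1)
    stop("`plateau_fraction` must lie in (0, 1]")
  structure(list(rate = rate, plateau_fraction = plateau_fraction),
            class = "first_order_model")
}

#' @export
print.first_order_model <- function(x, ...) {
  cat(sprintf("First-order release: rate = %g /h, plateau = %g\n",
              x$rate, x$plateau_fraction))
  invisible(x)
}

#' Cumulative release curve
#'
#' Times (strictly increasing, declared unit) with released fractions
#' \eqn{M_t/M_\infty \in [0, 1]}.
#'
#' @param times Sampling times in `time_unit`.
#' @param fractions Released fractions, same length, in `[0, 1]`
#'   (a small overshoot up to `1 + tol` is accepted for noisy data).
#' @param time_unit `"s"` or `"h"`.
#' @param tol Overshoot tolerance on fractions.
#' @return An object of class `release_curve`.
#' @export
release_curve <- function(times, fractions, time_unit = c("s", "h"),
                          tol = 0.05) {
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times); fractions <- as.numeric(fractions)
  if (length(times) != length(fractions) || length(times) == 0)
    stop("`times` and `fractions` must be non-empty and equal length")
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0))
    stop("`times` must be non-negative and strictly increasing")
  if (any(!is.finite(fractions)) || any(fractions < -tol) ||
      any(fractions > 1 + tol))
    stop("`fractions` must lie in [0, 1] (within tolerance)")
  structure(list(times = times, fractions = fractions, time_unit = time_unit),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve: %d points over [%g, %g] %s, final fraction %.3f\n",
              length(x$times), min(x$times), max(x$times), x$time_unit,
              x$fractions[length(x$fractions)]))
  invisible(x)
}

curve_times_s <- function(curve) {
  if (curve$time_unit == "h") curve$times * 3600 else curve$times
}

#' Early-time released fraction of a Fickian slab
#'
#' The square-root-of-time law valid while \eqn{M_t/M_\infty < 0.6}:
#' `standard_sheet` gives \eqn{(4/\delta)\sqrt{Dt/\pi}}, `as_printed`
#' \eqn{4\sqrt{Dt/(\pi\delta)}}. The fraction is returned untruncated (it
#' grows without bound in `t`); `valid` flags whether each point is inside
#' the law's regime.
#'
#' @param model A [fickian_slab()].
#' @param t Time(s), seconds, >= 0.
#' @return A data frame with columns `t`, `fraction` and `valid`
#'   (`fraction < 0.6`).
#' @examples
#' m <- fickian_slab(1e-8, 1e-3)
#' early_time_fraction(m, c(0, 1.2272, 4.9087))
#' @export
early_time_fraction <- function(model, t) {
  stopifnot(inherits(model, "fickian_slab"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be non-negative")
  L <- effective_thickness(model)
  f <- switch(model$geometry_form,
              standard_sheet = 4 / L * sqrt(model$diffusivity * t / pi),
              as_printed = 4 * sqrt(model$diffusivity * t / (pi * L)))
  data.frame(t = t, fraction = f, valid = f < 0.6)
}

#' Eigenfunction-series released fraction (reference solution)
#'
#' Closed-form series for the plane sheet with uniform initial loading and
#' perfect sinks at both faces:
#' \deqn{M_t/M_\infty = 1 - \sum_{n\ge0} \frac{8}{(2n+1)^2\pi^2}
#'   e^{-D(2n+1)^2\pi^2 t/L^2}.}
#' Takes nondimensional time \eqn{\tau = D t / L^2}. Serves as the
#' independent reference against which the finite-difference solver is
#' verified.
#'
#' @param tau Nondimensional time(s), >= 0.
#' @param n_terms Number of series terms (default 500; the series converges
#'   rapidly except at very small `tau`).
#' @return Released fraction(s) in `[0, 1]`.
#' @export
fick_series_fraction <- function(tau, n_terms = 500L) {
  tau <- as.numeric(tau)
  if (any(!is.finite(tau)) || any(tau < 0)) stop("`tau` must be non-negative")
  if (n_terms < 1) stop("`n_terms` must be at least 1")
  n <- 0:(n_terms - 1)
  lam <- (2 * n + 1)^2 * pi^2
  vapply(tau, function(tt) {
    if (tt == 0) return(0)
    1 - sum(8 / lam * exp(-lam * tt))
  }, numeric(1))
}

# Backward-time centred-space step on a cell-centred grid (faces at 0 and 1,
# Dirichlet zero at both faces via ghost cells), by the Thomas algorithm.
# Cell-centred finite volumes keep the discrete mass budget exactly
# consistent with the released fraction 1 - m/m0.
btcs_step <- function(u, mu) {
  n <- length(u)
  b <- rep(1 + 2 * mu, n)
  b[1] <- b[n] <- 1 + 3 * mu         # ghost u0 = -u1 puts zero on the face
  a <- -mu
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- a / b[1]
  dp[1] <- u[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a * cp[i - 1]
    cp[i] <- a / m
    dp[i] <- (u[i] - a * dp[i - 1]) / m
  }
  u[n] <- dp[n]
  for (i in (n - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  u
}

# released fraction at requested nondimensional times, by implicit FD
fick_fd_fraction <- function(tau, grid_points = 400L, steps_per_decade = 500) {
  stopifnot(all(tau >= 0), !is.unsorted(tau))
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tau_pos <- unique(tau[pos])
  tmax <- max(tau_pos)
  tmin <- min(tau_pos) / 50          # resolve the start-up transient
  nstep <- max(10L, ceiling(steps_per_decade * log10(tmax / tmin)))
  grid <- sort(unique(c(exp(seq(log(tmin), log(tmax), length.out = nstep)),
                        tau_pos)))
  n <- grid_points
  dx <- 1 / n
  u <- rep(1, n)                     # uniform initial loading, total mass 1
  frac <- numeric(length(grid))
  tprev <- 0
  for (k in seq_along(grid)) {
    dt <- grid[k] - tprev
    u <- btcs_step(u, dt / dx^2)
    frac[k] <- 1 - dx * sum(u)
    tprev <- grid[k]
  }
  out[pos] <- frac[match(tau[pos], grid)]
  out
}

#' Solve the Fickian slab release problem numerically
#'
#' Solves \eqn{\partial C/\partial t = D\,\partial^2 C/\partial Z^2} on a
#' film of the model's thickness with uniform initial concentration and
#' perfect-sink (zero-concentration) boundaries, using an unconditionally
#' stable implicit (backward-time, centred-space) finite-difference scheme
#' on a cell-centred grid with logarithmically graded time steps. Returns
#' the cumulative released fraction \eqn{1 - m(t)/m(0)} at each requested
#' time. Accuracy against [fick_series_fraction()] is better than
#' \eqn{10^{-3}} over \eqn{Dt/L^2 \in [10^{-3}, 5]} at the default grid.
#'
#' @param model A [fickian_slab()]; `geometry_form` does not affect the
#'   solver (it is an early-time-law option), `sides` does.
#' @param times Requested times, non-negative and strictly increasing.
#' @param grid_points Number of spatial cells across the film (>= 3).
#' @param time_unit `"s"` (default) or `"h"`.
#' @return A [release_curve()] (times in the requested unit).
#' @examples
#' m <- fickian_slab(2e-13, 1e-4)
#' solve_fick_slab(m, times = c(1, 2, 4, 8, 14), time_unit = "h")
#' @export
solve_fick_slab <- function(model, times, grid_points = 400L,
                            time_unit = c("s", "h")) {
  stopifnot(inherits(model, "fickian_slab"))
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0))
    stop("`times` must be non-negative")
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (grid_points < 3) stop("`grid_points` must be at least 3")
  t_s <- if (time_unit == "h") times * 3600 else times
  L <- effective_thickness(model)
  tau <- model$diffusivity * t_s / L^2
  frac <- if (model$diffusivity == 0) rep(0, length(tau)) else
    fick_fd_fraction(tau, grid_points = grid_points)
  release_curve(times, pmin(pmax(frac, 0), 1), time_unit = time_unit)
}

#' Fit a diffusivity to the early-time portion of a release curve
#'
#' Least-squares fit of the released fraction against \eqn{\sqrt{t}} through
#' the origin, restricted to points with fraction below `cutoff` (default
#' 0.6, the validity bound of the early-time law). The diffusivity follows
#' from the fitted slope \eqn{s} under the standard plane-sheet form:
#' \eqn{D = (s\,\delta/4)^2\,\pi}.
#'
#' @param curve A [release_curve()].
#' @param thickness Film thickness, cm.
#' @param cutoff Fraction cutoff for the early-time regime.
#' @param sides `2` (default) or `1`, as in [fickian_slab()].
#' @return An object of class `diffusivity_fit`: list with `diffusivity`
#'   (cm^2/s), `slope` (per sqrt(s)), `n_used`, `rss`, `residuals`.
#' @export
fit_diffusivity <- function(curve, thickness, cutoff = 0.6, sides = 2) {
  stopifnot(inherits(curve, "release_curve"))
  if (!is.finite(thickness) || thickness <= 0)
    stop("`thickness` must be positive (cm)")
  t_s <- curve_times_s(curve)
  keep <- curve$fractions < cutoff & t_s > 0
  if (sum(keep) < 2)
    stop("fewer than 2 points below the cutoff fraction ", cutoff,
         ": no early-time regime to fit")
  x <- sqrt(t_s[keep]); y <- curve$fractions[keep]
  slope <- sum(x * y) / sum(x^2)      # through-origin OLS
  res <- y - slope * x
  L <- thickness * if (sides == 1) 2 else 1
  D <- (slope * L / 4)^2 * pi
  structure(list(diffusivity = D, slope = slope, n_used = sum(keep),
                 rss = sum(res^2), residuals = res, cutoff = cutoff,
                 thickness = thickness, sides = sides),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("Fickian fit: D = %.4g cm^2/s (%d early-time points, RSS %.3g)\n",
              x$diffusivity, x$n_used, x$rss))
  invisible(x)
}

#' Fit first-order release kinetics
#'
#' Nonlinear least squares for
#' \eqn{M_t/M_\infty = plateau\,(1 - e^{-rate\,t})} (rate in 1/h),
#' initialised by a log-linearisation and refined by Levenberg-Marquardt.
#'
#' @param curve A [release_curve()] with at least 3 points.
#' @param max_iter Iteration cap for the optimiser.
#' @return An object of class `first_order_fit`: list with `rate` (1/h),
#'   `plateau`, `rss`, `fitted`, `converged`.
#' @export
fit_first_order <- function(curve, max_iter = 500) {
  stopifnot(inherits(curve, "release_curve"))
  t_h <- curve_times_s(curve) / 3600
  y <- curve$fractions
  if (length(y) < 3) stop("at least 3 points are required")
  if (max(y) - min(y) < 1e-12 || max(y) <= 0)
    stop("degenerate release curve: no rise to fit (non-convergence)")
  p0 <- min(max(y) * 1.05, 1.2)
  inside <- y > 0 & y < p0 & t_h > 0
  k0 <- if (sum(inside) >= 2) {
    z <- log(1 - y[inside] / p0)
    max(-sum(t_h[inside] * z) / sum(t_h[inside]^2), 1e-6)
  } else 1 / max(t_h)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ p * (1 - exp(-k * t_h)),
                      start = list(p = p0, k = k0),
                      lower = c(p = 1e-8, k = 1e-8),
                      control = minpack.lm::nls.lm.control(
                        maxiter = max_iter, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("first-order fit failed to converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(rate = unname(co["k"]), plateau = unname(co["p"]),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = stats::fitted(fit),
                 converged = fit$convInfo$isConv),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("First-order fit: rate = %.4g /h, plateau = %.4g (RSS %.3g)\n",
              x$rate, x$plateau, x$rss))
  invisible(x)
}

#' Qualitative shape diagnostics of a release curve
#'
#' Reports whether the curve is monotone non-decreasing and concave in time
#' (non-increasing chord slopes), the qualitative shape of
#' diffusion-controlled release (\eqn{\sqrt{t}}-like, "parabola on its
#' side"). A linear curve sits on the concavity boundary and is reported as
#' concave but not strictly so.
#'
#' @param curve A [release_curve()] with at least 3 points.
#' @param tol Numerical slack on the comparisons.
#' @return A list with `monotone`, `concave`, `strictly_concave`, and the
#'   vectors of first differences and chord slopes.
#' @export
profile_shape_check <- function(curve, tol = 1e-9) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(curve$times) < 3) stop("at least 3 points are required")
  df <- diff(curve$fractions)
  slopes <- df / diff(curve$times)
  dslope <- diff(slopes)
  list(monotone = all(df >= -tol),
       concave = all(dslope <= tol),
       strictly_concave = all(dslope < -tol),
       first_differences = df,
       chord_slopes = slopes)
}
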