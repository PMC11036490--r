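# Adaptive Rosenbrock 2(3) integrator (ode23s-type).
#
# A linearly implicit, L-stable pair with an embedded third-order error
# estimate, suitable for the stiff kinetics ODEs at fixture scale (at most a
# handful of state variables).  The steady-state solver integrates in
# log-concentration coordinates, so positivity is structural.

#' Integrate an autonomous ODE with an adaptive Rosenbrock 2(3) scheme
#'
#' @param f Right-hand side, `function(y) -> numeric`.
#' @param jac Jacobian of `f`, `function(y) -> matrix`.
#' @param y0 Initial state.
#' @param t_end Integration time.
#' @param rel_tol,abs_tol Componentwise error tolerances.
#' @param max_steps Step cap (a structured non-convergence is returned, not
#'   an error).
#' @return List with `y`, `t`, `n_steps`, `success`.
#' @keywords internal
ode_rosenbrock <- function(f, jac, y0, t_end, rel_tol = 1e-9, abs_tol = 1e-12,
                           max_steps = 20000L) {
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  n <- length(y0)
  y <- y0
  t <- 0
  f0 <- f(y)
  if (!all(is.finite(f0))) return(list(y = y, t = t, n_steps = 0L, success = FALSE))
  h <- min(t_end, 0.01 * (1 + max(abs(y))) / (max(abs(f0)) + 1e-10))
  steps <- 0L
  while (t < t_end && steps < max_steps) {
    h <- min(h, t_end - t)
    J <- jac(y)
    W <- diag(n) - h * d * J
    ok <- TRUE
    sol <- tryCatch({
      k1 <- solve(W, f0)
      f1 <- f(y + 0.5 * h * k1)
      k2 <- solve(W, f1 - k1) + k1
      ynew <- y + h * k2
      f2 <- f(ynew)
      k3 <- solve(W, f2 - e32 * (k2 - f1) - 2 * (k1 - f0))
      list(ynew = ynew, f2 = f2, err = (h / 6) * (k1 - 2 * k2 + k3))
    }, error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol$ynew)) || !all(is.finite(sol$err))) {
      ok <- FALSE
    }
    if (ok) {
      scale <- abs_tol + rel_tol * pmax(abs(y), abs(sol$ynew))
      err_norm <- max(abs(sol$err) / scale)
      if (err_norm <= 1) {
        t <- t + h
        y <- sol$ynew
        f0 <- sol$f2
        if (!all(is.finite(f0))) return(list(y = y, t = t, n_steps = steps, success = FALSE))
      }
      h <- h * min(5, max(0.2, 0.9 * err_norm^(-1 / 3)))
    } else {
      h <- h * 0.25
      if (h < 1e-14 * t_end) {
        return(list(y = y, t = t, n_steps = steps, success = FALSE))
      }
    }
    steps <- steps + 1L
  }
  list(y = y, t = t, n_steps = steps, success = t >= t_end)
}
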