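# Hybrid ODE/Newton steady-state solver and its parameter sensitivities.

# Net production rates of the balanced metabolites at log-concentrations lnC.
f_bal <- function(cm, theta, lnC) {
  drop(kin_eval_cpp(cm, matrix(theta, ncol = 1), matrix(lnC, ncol = 1), FALSE)$fbal)
}

# Jacobian d f_bal / d lnC by batched central differences through the engine.
jac_bal_lnC <- function(cm, theta, lnC, h = 1e-6) {
  nbal <- length(lnC)
  if (nbal == 0L) return(matrix(0, 0, 0))
  L <- matrix(lnC, nbal, 2L * nbal)
  for (j in seq_len(nbal)) {
    L[j, 2L * j - 1L] <- lnC[j] + h
    L[j, 2L * j] <- lnC[j] - h
  }
  Th <- matrix(theta, length(theta), 2L * nbal)
  fb <- kin_eval_cpp(cm, Th, L, FALSE)$fbal
  (fb[, seq(1L, 2L * nbal, by = 2L), drop = FALSE] -
     fb[, seq(2L, 2L * nbal, by = 2L), drop = FALSE]) / (2 * h)
}

# d f_bal / d theta_k and d v / d theta_k for selected parameter indices.
sens_batch <- function(cm, theta, lnC, idx, h_rel = 1e-6) {
  K <- length(idx)
  nbal <- length(lnC)
  Th <- matrix(theta, length(theta), 2L * K)
  hh <- numeric(K)
  for (k in seq_len(K)) {
    h <- h_rel * max(abs(theta[idx[k]]), 1e-4)
    hh[k] <- h
    Th[idx[k], 2L * k - 1L] <- theta[idx[k]] + h
    Th[idx[k], 2L * k] <- theta[idx[k]] - h
  }
  L <- matrix(lnC, nbal, 2L * K)
  r <- kin_eval_cpp(cm, Th, L, FALSE)
  odd <- seq(1L, 2L * K, by = 2L); even <- odd + 1L
  list(
    df = (r$fbal[, odd, drop = FALSE] - r$fbal[, even, drop = FALSE]) / rep(2 * hh, each = nbal),
    dv = (r$flux[, odd, drop = FALSE] - r$flux[, even, drop = FALSE]) / rep(2 * hh, each = nrow(r$flux))
  )
}

# damped Newton on S_bal v = 0 in log concentrations (C++ inner loop)
newton_polish <- function(cm, theta, lnC, tol, max_iters) {
  kin_newton_cpp(cm, theta, lnC, tol, as.integer(max_iters), 1e-6)
}

#' Solve the steady-state problem for one experiment
#'
#' Hybrid scheme: the kinetics ODE is first evolved (in log-concentration
#' coordinates, with an adaptive implicit integrator) for `t_evolve` seconds
#' from the experiment's initial guess, then Newton iteration drives the
#' balanced net production rates \eqn{S_{bal} v(C)} to zero.  On Newton
#' failure the evolution time is doubled and the scheme retried, up to
#' `max_retries` times.  Non-convergence is returned as a structured result
#' (`converged = FALSE` with the best residual), never an error: the sampler
#' treats it as a rejected proposal.
#'
#' @param model A `kin_model`.
#' @param experiment_id Experiment id.
#' @param theta Parameter values (named vector or data frame).
#' @param cfg A [solver_config()]; defaults to the model's.
#' @param init Optional named initial concentrations (mM) for the balanced
#'   metabolites, overriding the experiment's stored guess.
#' @return A list of class `kin_steady_state`: `c_star`, `v_star`,
#'   `residual_norm`, `converged`, `n_ode_steps`, `n_newton_iters`.
#' @export
solve_steady_state <- function(model, experiment_id, theta, cfg = NULL,
                               init = NULL) {
  theta <- as_theta(model, theta)
  if (is.null(cfg)) cfg <- model$solver
  cm <- model$compiled[[experiment_id]]
  if (is.null(cm)) stop("unknown experiment '", experiment_id, "'", call. = FALSE)
  bal_ids <- cm$bal_ids
  guess <- stats::setNames(rep(1, length(bal_ids)), bal_ids)
  stored <- model$experiments$init_conc[[match(experiment_id, model$experiments$id)]]
  guess[names(stored)[names(stored) %in% bal_ids]] <-
    stored[names(stored) %in% bal_ids]
  if (!is.null(init)) guess[names(init)[names(init) %in% bal_ids]] <-
    init[names(init) %in% bal_ids]
  if (any(guess <= 0)) stop("initial concentration guess must be positive", call. = FALSE)
  lnC <- log(unname(guess))

  if (length(bal_ids) == 0L) {
    v <- drop(kin_eval_cpp(cm, matrix(theta, ncol = 1),
                           matrix(numeric(0), 0, 1), FALSE)$flux)
    return(structure(list(
      experiment = experiment_id,
      c_star = stats::setNames(numeric(0), character(0)),
      v_star = stats::setNames(v, cm$rxn_ids), residual_norm = 0,
      converged = TRUE, n_ode_steps = 0L, n_newton_iters = 0L,
      lnC = numeric(0)), class = "kin_steady_state"))
  }

  t_ev <- cfg$t_evolve
  n_ode <- 0L
  n_newton <- 0L
  best <- list(lnC = lnC, residual = Inf)
  for (attempt in 0:cfg$max_retries) {
    ode <- kin_evolve_cpp(cm, theta, lnC, t_ev, cfg$rel_tol, cfg$abs_tol,
                          50000L)
    n_ode <- n_ode + ode$n_steps
    if (all(is.finite(ode$lnC))) lnC <- ode$lnC
    np <- newton_polish(cm, theta, lnC, cfg$newton_tol, cfg$max_newton_iters)
    n_newton <- n_newton + np$iters
    if (np$residual < best$residual) best <- np
    if (np$converged) break
    lnC <- np$lnC
    t_ev <- t_ev * 2
  }
  lnC <- best$lnC
  v <- drop(kin_eval_cpp(cm, matrix(theta, ncol = 1),
                         matrix(lnC, ncol = 1), FALSE)$flux)
  structure(list(
    experiment = experiment_id,
    c_star = stats::setNames(exp(lnC), bal_ids),
    v_star = stats::setNames(v, cm$rxn_ids),
    residual_norm = best$residual,
    converged = isTRUE(best$converged) && all(is.finite(lnC)),
    n_ode_steps = n_ode, n_newton_iters = n_newton,
    lnC = lnC), class = "kin_steady_state")
}

#' @export
print.kin_steady_state <- function(x, ...) {
  cat("<kin_steady_state> experiment ", x$experiment,
      if (x$converged) " (converged, " else " (NOT converged, ",
      "residual ", format(x$residual_norm, digits = 3), ")\n", sep = "")
  invisible(x)
}

# Fast path for the sampler: Newton directly from a cached solution; falls
# back to the full hybrid scheme when the warm start leaves the basin.
solve_steady_state_warm <- function(model, cm, theta, cfg, lnC_warm) {
  if (length(lnC_warm) == 0L) {
    v <- drop(kin_eval_cpp(cm, matrix(theta, ncol = 1),
                           matrix(numeric(0), 0, 1), FALSE)$flux)
    return(list(lnC = numeric(0), v = v, converged = TRUE, residual = 0))
  }
  np <- newton_polish(cm, theta, lnC_warm, cfg$newton_tol, 20L)
  if (!np$converged) {
    ss <- solve_steady_state(model, cm$experiment, stats::setNames(theta, model$params$name),
                             cfg = cfg)
    return(list(lnC = ss$lnC, v = unname(ss$v_star), converged = ss$converged,
                residual = ss$residual_norm))
  }
  v <- drop(kin_eval_cpp(cm, matrix(theta, ncol = 1),
                         matrix(np$lnC, ncol = 1), FALSE)$flux)
  list(lnC = np$lnC, v = v, converged = TRUE, residual = np$residual)
}

#' Sensitivities of the steady state to model parameters
#'
#' Implicit-function-theorem sensitivities at the solved fixed point:
#' \eqn{dC^*/d\theta = -(\partial f/\partial C)^{-1} \partial f/\partial
#' \theta} with \eqn{f(C) = S_{bal} v(C, \theta)}, and \eqn{dv^*/d\theta} by
#' the chain rule.  Exact at the fixed point; no differentiation through ODE
#' steps.
#'
#' @param model A `kin_model`.
#' @param experiment_id Experiment id.
#' @param theta Parameter values.
#' @param ss A converged [solve_steady_state()] result.
#' @param parameters Parameter names (default: all).
#' @return List with matrices `dC` (balanced metabolites x parameters) and
#'   `dv` (reactions x parameters).
#' @export
steady_state_sensitivities <- function(model, experiment_id, theta, ss,
                                       parameters = NULL) {
  theta <- as_theta(model, theta)
  if (!ss$converged) stop("steady state did not converge", call. = FALSE)
  cm <- model$compiled[[experiment_id]]
  if (is.null(parameters)) parameters <- model$params$name
  idx <- match(parameters, model$params$name)
  if (anyNA(idx)) stop("unknown parameter '", parameters[which(is.na(idx))[1]],
                       "'", call. = FALSE)
  lnC <- ss$lnC
  nbal <- length(lnC)
  sb <- sens_batch(cm, theta, lnC, idx)
  if (nbal > 0) {
    J <- jac_bal_lnC(cm, theta, lnC)
    dlnC <- tryCatch(-solve(J, sb$df), error = function(e) {
      stop("singular steady-state Jacobian: structural non-identifiability",
           call. = FALSE)
    })
    # dv*/dtheta = dv/dtheta + dv/dlnC . dlnC*/dtheta
    dv_dlnC <- local({
      h <- 1e-6
      L <- matrix(lnC, nbal, 2L * nbal)
      for (j in seq_len(nbal)) {
        L[j, 2L * j - 1L] <- lnC[j] + h
        L[j, 2L * j] <- lnC[j] - h
      }
      Th <- matrix(theta, length(theta), 2L * nbal)
      fx <- kin_eval_cpp(cm, Th, L, FALSE)$flux
      (fx[, seq(1L, 2L * nbal, by = 2L), drop = FALSE] -
         fx[, seq(2L, 2L * nbal, by = 2L), drop = FALSE]) / (2 * h)
    })
    dv <- sb$dv + dv_dlnC %*% dlnC
    dC <- sweep(dlnC, 1, exp(lnC), "*")   # dC* = C* dlnC*
  } else {
    dv <- sb$dv
    dC <- matrix(0, 0, length(idx))
  }
  dimnames(dC) <- list(cm$bal_ids, parameters)
  dimnames(dv) <- list(cm$rxn_ids, parameters)
  list(dC = dC, dv = dv)
}
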