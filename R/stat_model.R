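# Joint log density: priors over theta, likelihood of measurements given
# steady states, on the unconstrained scale used by the sampler.

#' Pack parameter values into the unconstrained vector
#'
#' Positivity-constrained parameters are log-transformed; sign-free ones
#' (formation energies, drain fluxes) pass through.
#'
#' @param model A `kin_model`.
#' @param theta Named vector or data frame of constrained values.
#' @return Unconstrained numeric vector (same length and order as
#'   `model$params`).
#' @export
pack_theta <- function(model, theta) {
  theta <- as_theta(model, theta)
  u <- theta
  pos <- model$params$positive
  u[pos] <- log(theta[pos])
  u
}

#' Unpack an unconstrained vector into constrained parameter values
#'
#' Inverse of [pack_theta()].
#' @param model A `kin_model`.
#' @param u Unconstrained vector.
#' @return Named numeric vector of constrained values.
#' @export
unpack_theta <- function(model, u) {
  theta <- u
  pos <- model$params$positive
  theta[pos] <- exp(u[pos])
  stats::setNames(theta, model$params$name)
}

#' Log prior density of a parameter set
#'
#' Sum of independent log-normal densities (positivity-constrained scalars),
#' independent normal densities (sign-free scalars), and one multivariate
#' normal density for the formation-energy vector.
#'
#' @param model A `kin_model`.
#' @param theta Constrained parameter values.
#' @return Scalar log density.
#' @export
log_prior <- function(model, theta) {
  theta <- as_theta(model, theta)
  p <- model$params
  if (length(theta) != nrow(p)) stop("theta has wrong dimension", call. = FALSE)
  fe <- model$fe_block
  scalar <- if (is.null(fe)) seq_len(nrow(p)) else setdiff(seq_len(nrow(p)), fe$idx)
  lp <- 0
  pos <- scalar[p$positive[scalar]]
  if (length(pos) > 0) {
    lp <- lp + sum(stats::dlnorm(theta[pos], p$prior_location[pos],
                                 p$prior_scale[pos], log = TRUE))
  }
  free <- scalar[!p$positive[scalar]]
  if (length(free) > 0) {
    lp <- lp + sum(stats::dnorm(theta[free], p$prior_location[free],
                                p$prior_scale[free], log = TRUE))
  }
  if (!is.null(fe)) {
    z <- theta[fe$idx] - fe$mean
    k <- length(z)
    lp <- lp - 0.5 * (k * log(2 * pi) + fe$logdet + drop(z %*% fe$prec %*% z))
  }
  lp
}

#' Log likelihood of the measurements
#'
#' Concentration and enzyme records contribute log-normal densities with
#' location `ln(modeled value)` and known sd; flux records contribute normal
#' densities centred on the steady-state flux.  Boundary-metabolite and
#' enzyme measurements are compared directly to the corresponding
#' parameters.
#'
#' @param model A `kin_model`.
#' @param steady_states Named list of [solve_steady_state()] results, one per
#'   experiment appearing in the measurements.
#' @param theta Constrained parameter values.
#' @return List with `total` and the per-record vector `per_record`.
#' @export
log_likelihood <- function(model, steady_states, theta) {
  theta <- as_theta(model, theta)
  mi <- model$measurement_index
  n <- nrow(mi)
  per <- numeric(n)
  for (i in seq_len(n)) {
    r <- mi[i, ]
    modeled <- switch(r$source,
      c_star = steady_states[[r$experiment]]$c_star[[r$slot]],
      v_star = steady_states[[r$experiment]]$v_star[[r$slot]],
      param = theta[r$slot]
    )
    per[i] <- if (r$type == "flux") {
      stats::dnorm(r$value, modeled, r$sd, log = TRUE)
    } else {
      stats::dlnorm(r$value, log(modeled), r$sd, log = TRUE)
    }
  }
  list(total = sum(per), per_record = per)
}

# --- measurement bookkeeping for the fast path ------------------------------

# per-experiment grouping of measurement records, by modeled source
measurement_groups <- function(model) {
  mi <- model$measurement_index
  exps <- unique(mi$experiment)
  out <- lapply(exps, function(ex) {
    sub <- mi[mi$experiment == ex, , drop = FALSE]
    list(
      experiment = ex,
      conc_rows = which(sub$source == "c_star"),
      conc_slot = sub$slot[sub$source == "c_star"],
      conc_value = sub$value[sub$source == "c_star"],
      conc_sd = sub$sd[sub$source == "c_star"],
      flux_rows = which(sub$source == "v_star"),
      flux_slot = sub$slot[sub$source == "v_star"],
      flux_value = sub$value[sub$source == "v_star"],
      flux_sd = sub$sd[sub$source == "v_star"],
      param_rows = which(sub$source == "param"),
      param_slot = sub$slot[sub$source == "param"],
      param_type = sub$type[sub$source == "param"],
      param_value = sub$value[sub$source == "param"],
      param_sd = sub$sd[sub$source == "param"],
      table_rows = which(mi$experiment == ex)
    )
  })
  names(out) <- exps
  out
}

# theta indices each experiment's flux function can depend on
relevant_theta_idx <- function(model) {
  lapply(model$compiled, function(cm) {
    idx <- c(cm$kcat_t, cm$enz_t, cm$drain_t, cm$L_t, cm$sub_km, cm$prod_km,
             cm$ci_t, cm$act_t, cm$inh_t, cm$dg_t, cm$p_t, cm$d_t,
             cm$met_bound_t)
    sort(unique(idx[idx >= 0])) + 1L
  })
}

# context cache built once per model for density evaluation
stat_context <- function(model) {
  list(
    groups = measurement_groups(model),
    rel_idx = relevant_theta_idx(model),
    pos = model$params$positive,
    npar = nrow(model$params)
  )
}

# prior log density and gradient on the unconstrained scale (includes the
# exp-transform Jacobian for log parameters)
log_prior_u <- function(model, u) {
  p <- model$params
  fe <- model$fe_block
  scalar <- if (is.null(fe)) seq_len(nrow(p)) else setdiff(seq_len(nrow(p)), fe$idx)
  g <- numeric(length(u))
  lp <- 0
  z <- (u[scalar] - p$prior_location[scalar]) / p$prior_scale[scalar]
  lp <- lp + sum(-0.5 * z^2 - log(p$prior_scale[scalar]) - 0.5 * log(2 * pi))
  g[scalar] <- -z / p$prior_scale[scalar]
  if (!is.null(fe)) {
    zf <- u[fe$idx] - fe$mean
    k <- length(zf)
    lp <- lp - 0.5 * (k * log(2 * pi) + fe$logdet + drop(zf %*% fe$prec %*% zf))
    g[fe$idx] <- -drop(fe$prec %*% zf)
  }
  list(value = lp, grad = g)
}

#' Joint log density with gradient
#'
#' `log_prior + log_likelihood + log-Jacobian` of the exp transform, as a
#' function of the unconstrained vector `u`.  Steady states are solved
#' internally per experiment (warm-started from `warm` when given); a solver
#' failure yields `value = -Inf`, which the sampler treats as a rejected
#' proposal.  The gradient is assembled by the adjoint of the
#' implicit-function-theorem sensitivities, so its cost is a handful of
#' batched flux evaluations per experiment.
#'
#' @param model A `kin_model`.
#' @param u Unconstrained parameter vector.
#' @param ctx Optional precomputed [stat_context] (internal cache).
#' @param warm Optional named list of log-concentration warm starts per
#'   experiment.
#' @param want_grad Compute the gradient.
#' @return List with `value`, `grad`, `steady` (per-experiment lnC), `loglik`
#'   and `per_record`.
#' @export
log_joint <- function(model, u, ctx = NULL, warm = NULL, want_grad = TRUE) {
  if (is.null(ctx)) ctx <- stat_context(model)
  if (!all(is.finite(u))) {
    return(list(value = -Inf, grad = rep(NA_real_, length(u)),
                steady = NULL, loglik = NA_real_, per_record = NULL))
  }
  pr <- log_prior_u(model, u)
  theta <- u
  theta[ctx$pos] <- exp(u[ctx$pos])
  value <- pr$value
  grad <- if (want_grad) pr$grad else NULL
  steady <- list()
  mi_n <- nrow(model$measurement_index)
  per_record <- numeric(mi_n)
  loglik <- 0
  for (gr in ctx$groups) {
    ex <- gr$experiment
    cm <- model$compiled[[ex]]
    lnC_warm <- if (!is.null(warm) && !is.null(warm[[ex]])) warm[[ex]] else NULL
    lnC <- NULL
    if (!is.null(lnC_warm) && length(lnC_warm) > 0) {
      np <- kin_newton_cpp(cm, theta, lnC_warm, model$solver$newton_tol, 20L, 1e-6)
      if (isTRUE(np$converged)) lnC <- np$lnC
    }
    if (is.null(lnC)) {
      ss <- solve_steady_state(model, ex, stats::setNames(theta, model$params$name))
      if (!ss$converged) {
        return(list(value = -Inf, grad = rep(NA_real_, length(u)),
                    steady = NULL, loglik = NA_real_, per_record = NULL))
      }
      lnC <- ss$lnC
    }
    steady[[ex]] <- lnC
    idx <- ctx$rel_idx[[ex]]
    need_grad <- want_grad && (length(gr$conc_rows) > 0 || length(gr$flux_rows) > 0)
    if (need_grad) {
      kr <- kin_grad_kernel_cpp(cm, theta, lnC, idx - 1L, ctx$pos[idx], TRUE, 1e-6)
      v <- kr$flux
    } else {
      v <- drop(kin_eval_cpp(cm, matrix(theta, ncol = 1),
                             matrix(lnC, ncol = 1), FALSE)$flux)
    }
    ll_rows <- numeric(length(gr$table_rows))
    # conc records on balanced metabolites
    if (length(gr$conc_rows) > 0) {
      lm <- lnC[gr$conc_slot]
      z <- (log(gr$conc_value) - lm) / gr$conc_sd
      ll_rows[gr$conc_rows] <- -0.5 * z^2 - log(gr$conc_sd) -
        0.5 * log(2 * pi) - log(gr$conc_value)
    }
    if (length(gr$flux_rows) > 0) {
      z <- (gr$flux_value - v[gr$flux_slot]) / gr$flux_sd
      ll_rows[gr$flux_rows] <- -0.5 * z^2 - log(gr$flux_sd) - 0.5 * log(2 * pi)
    }
    if (length(gr$param_rows) > 0) {
      lm <- log(theta[gr$param_slot])
      z <- (log(gr$param_value) - lm) / gr$param_sd
      ll_rows[gr$param_rows] <- -0.5 * z^2 - log(gr$param_sd) -
        0.5 * log(2 * pi) - log(gr$param_value)
    }
    per_record[gr$table_rows] <- ll_rows
    loglik <- loglik + sum(ll_rows)
    if (want_grad) {
      # direct parameter measurements: analytic on the unconstrained scale
      if (length(gr$param_rows) > 0) {
        for (k in seq_along(gr$param_slot)) {
          j <- gr$param_slot[k]
          grad[j] <- grad[j] + (log(gr$param_value[k]) - u[j]) / gr$param_sd[k]^2
        }
      }
      if (need_grad) {
        nbal <- length(lnC)
        # dlogL/dlnC* and dlogL/dv*
        g_lnC <- numeric(nbal)
        if (length(gr$conc_rows) > 0) {
          add <- (log(gr$conc_value) - lnC[gr$conc_slot]) / gr$conc_sd^2
          for (k in seq_along(gr$conc_slot)) {
            g_lnC[gr$conc_slot[k]] <- g_lnC[gr$conc_slot[k]] + add[k]
          }
        }
        h_v <- numeric(length(v))
        if (length(gr$flux_rows) > 0) {
          add <- (gr$flux_value - v[gr$flux_slot]) / gr$flux_sd^2
          for (k in seq_along(gr$flux_slot)) {
            h_v[gr$flux_slot[k]] <- h_v[gr$flux_slot[k]] + add[k]
          }
        }
        if (nbal > 0) {
          w <- g_lnC + drop(t(kr$Vc) %*% h_v)
          lambda <- tryCatch(solve(t(kr$J), w), error = function(e) NULL)
          if (is.null(lambda)) {
            return(list(value = -Inf, grad = rep(NA_real_, length(u)),
                        steady = NULL, loglik = NA_real_, per_record = NULL))
          }
          grad[idx] <- grad[idx] + drop(t(kr$Vu) %*% h_v) - drop(t(kr$Fu) %*% lambda)
        } else {
          grad[idx] <- grad[idx] + drop(t(kr$Vu) %*% h_v)
        }
      }
    }
  }
  value <- value + loglik
  list(value = value, grad = grad, steady = steady, loglik = loglik,
       per_record = per_record)
}

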