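# Laplace approximation: gradient-based MAP optimization, finite-difference
# Hessian, multivariate-normal approximate posterior draws.

#' Laplace approximation of the posterior
#'
#' Finds the maximum-a-posteriori point on the unconstrained scale with
#' gradient-based optimization (BFGS), approximates the posterior by a
#' multivariate normal with covariance equal to the inverse negative Hessian
#' (central finite differences of the gradient, step `1e-4`), and draws
#' `n_samples` approximate posterior samples, back-transformed to the
#' constrained scale.  Draws whose steady-state problem fails are dropped and
#' counted (`n_failed`), never silently imputed.
#'
#' @param model A `kin_model`.
#' @param n_samples Number of approximate posterior draws (0 = MAP report
#'   only).
#' @param seed RNG seed.
#' @param init_u Optional unconstrained starting point (default: prior
#'   locations).
#' @return List with `map` (unconstrained mode, constrained parameters, log
#'   density, Hessian) and `draws` (a `kin_draws` object, or `NULL` when
#'   `n_samples = 0`), plus `n_failed`.
#' @export
laplace_approximation <- function(model, n_samples = 1000L, seed = 1L,
                                  init_u = NULL) {
  ctx <- stat_context(model)
  set.seed(seed)
  u0 <- if (is.null(init_u)) model$params$prior_location else init_u
  r0 <- log_joint(model, u0, ctx = ctx)
  if (!is.finite(r0$value)) {
    for (try in 1:50) {
      u0 <- model$params$prior_location + stats::runif(length(u0), -1, 1)
      r0 <- log_joint(model, u0, ctx = ctx)
      if (is.finite(r0$value)) break
    }
    if (!is.finite(r0$value)) {
      stop("could not find a feasible starting point for MAP optimization",
           call. = FALSE)
    }
  }
  fn <- function(u) {
    v <- log_joint(model, u, ctx = ctx, want_grad = FALSE)$value
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- function(u) {
    r <- log_joint(model, u, ctx = ctx)
    if (!is.finite(r$value) || !all(is.finite(r$grad))) return(rep(0, length(u)))
    -r$grad
  }
  opt <- stats::optim(u0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0 && opt$convergence != 1) {
    stop("MAP optimization failed (code ", opt$convergence, ") at log density ",
         -opt$value, call. = FALSE)
  }
  u_map <- opt$par
  npar <- length(u_map)
  h <- 1e-4
  H <- matrix(0, npar, npar)
  for (k in seq_len(npar)) {
    up <- u_map; up[k] <- up[k] + h
    um <- u_map; um[k] <- um[k] - h
    gp <- log_joint(model, up, ctx = ctx)$grad
    gm <- log_joint(model, um, ctx = ctx)$grad
    H[, k] <- (gp - gm) / (2 * h)
  }
  H <- (H + t(H)) / 2
  A <- -H  # negative Hessian of the log density: precision of the Gaussian
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    stop("negative Hessian at the MAP is not positive definite; eigenvalues: ",
         paste(format(ev, digits = 3), collapse = ", "), call. = FALSE)
  }
  map <- list(u = stats::setNames(u_map, model$params$name),
              theta = unpack_theta(model, u_map),
              value = -opt$value, hessian = H)
  if (n_samples == 0L) {
    return(list(map = map, draws = NULL, n_failed = 0L))
  }
  Z <- matrix(stats::rnorm(npar * n_samples), npar, n_samples)
  U <- u_map + backsolve(ch, Z)   # cov = A^{-1}
  keep_u <- list(); keep_res <- list()
  n_failed <- 0L
  for (j in seq_len(n_samples)) {
    res <- log_joint(model, U[, j], ctx = ctx, want_grad = FALSE)
    if (is.finite(res$value)) {
      keep_u[[length(keep_u) + 1L]] <- U[, j]
      keep_res[[length(keep_res) + 1L]] <- res
    } else {
      n_failed <- n_failed + 1L
    }
  }
  nk <- length(keep_u)
  if (nk == 0) stop("every Laplace draw hit a steady-state failure", call. = FALSE)
  theta_draws <- array(NA_real_, c(1L, nk, npar),
                       dimnames = list(NULL, NULL, model$params$name))
  exps <- model$experiments$id
  nbal <- length(model$compiled[[1]]$bal_ids)
  steady_draws <- lapply(exps, function(e) array(NA_real_, c(1L, nk, nbal)))
  names(steady_draws) <- exps
  nrec <- nrow(model$measurement_index)
  loglik_draws <- array(NA_real_, c(1L, nk, nrec))
  lp <- numeric(nk)
  for (j in seq_len(nk)) {
    theta_draws[1L, j, ] <- unpack_theta(model, keep_u[[j]])
    lp[j] <- keep_res[[j]]$value
    for (e in names(keep_res[[j]]$steady)) {
      steady_draws[[e]][1L, j, ] <- keep_res[[j]]$steady[[e]]
    }
    if (nrec > 0) loglik_draws[1L, j, ] <- keep_res[[j]]$per_record
  }
  stats_ <- list(lp = matrix(lp, 1L), energy = matrix(NA_real_, 1L, nk),
                 divergent = matrix(0, 1L, nk),
                 tree_depth = matrix(NA_real_, 1L, nk),
                 n_leapfrog = matrix(NA_real_, 1L, nk),
                 accept_stat = matrix(NA_real_, 1L, nk),
                 step_size = matrix(NA_real_, 1L, nk))
  draws <- new_kin_draws(model, theta_draws, stats_, steady_draws, loglik_draws,
                         method = "laplace", seed = seed)
  list(map = map, draws = draws, n_failed = n_failed)
}
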