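# Adaptive Hamiltonian Monte Carlo: multinomial NUTS with dual-averaging
# step-size adaptation and a diagonal metric estimated in Stan-style
# expanding warmup windows.

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

# one leapfrog step; z carries the cached log_joint evaluation
nuts_leapfrog <- function(z, p, dir, eps, inv_metric, model, ctx) {
  e <- dir * eps
  p1 <- p + 0.5 * e * z$res$grad
  u1 <- z$u + e * inv_metric * p1
  res <- log_joint(model, u1, ctx = ctx, warm = z$res$steady)
  if (!is.finite(res$value)) {
    return(list(u = u1, res = res, p = p1, bad = TRUE))
  }
  p1 <- p1 + 0.5 * e * res$grad
  list(u = u1, res = res, p = p1, bad = FALSE)
}

kinetic_energy <- function(p, inv_metric) 0.5 * sum(p * p * inv_metric)

no_uturn <- function(p_minus, p_plus, rho, inv_metric) {
  sum(inv_metric * p_minus * rho) > 0 && sum(inv_metric * p_plus * rho) > 0
}

# Recursive multinomial NUTS subtree of 2^depth leapfrog steps taken in
# direction `dir` from state (z, p).
nuts_build_tree <- function(depth, z, p, dir, H0, eps, inv_metric, model, ctx) {
  if (depth == 0L) {
    st <- nuts_leapfrog(z, p, dir, eps, inv_metric, model, ctx)
    H <- if (st$bad) Inf else -st$res$value + kinetic_energy(st$p, inv_metric)
    dH <- H - H0
    divergent <- !is.finite(dH) || dH > 1000
    node <- list(u = st$u, res = st$res, H = H)
    return(list(
      ok = !divergent, divergent = divergent,
      z_minus = node, p_minus = st$p, z_plus = node, p_plus = st$p,
      z_cand = node, log_w = if (divergent) -Inf else -dH,
      rho = st$p, sum_a = min(1, exp(-dH)), n_lf = 1L
    ))
  }
  t1 <- nuts_build_tree(depth - 1L, z, p, dir, H0, eps, inv_metric, model, ctx)
  if (!t1$ok) return(t1)
  far_z <- if (dir == 1) t1$z_plus else t1$z_minus
  far_p <- if (dir == 1) t1$p_plus else t1$p_minus
  t2 <- nuts_build_tree(depth - 1L, far_z, far_p, dir, H0, eps, inv_metric,
                        model, ctx)
  log_w <- logsumexp2(t1$log_w, t2$log_w)
  z_cand <- if (is.finite(t2$log_w) &&
                stats::runif(1) < exp(t2$log_w - log_w)) t2$z_cand else t1$z_cand
  out <- list(
    ok = t2$ok, divergent = t1$divergent || t2$divergent,
    z_minus = if (dir == 1) t1$z_minus else t2$z_minus,
    p_minus = if (dir == 1) t1$p_minus else t2$p_minus,
    z_plus = if (dir == 1) t2$z_plus else t1$z_plus,
    p_plus = if (dir == 1) t2$p_plus else t1$p_plus,
    z_cand = z_cand, log_w = log_w, rho = t1$rho + t2$rho,
    sum_a = t1$sum_a + t2$sum_a, n_lf = t1$n_lf + t2$n_lf
  )
  if (out$ok) {
    out$ok <- no_uturn(out$p_minus, out$p_plus, out$rho, inv_metric)
  }
  out
}

# one NUTS transition; returns new state plus per-iteration statistics
nuts_transition <- function(z, eps, inv_metric, max_depth, model, ctx) {
  npar <- length(z$u)
  p0 <- stats::rnorm(npar, 0, 1) / sqrt(inv_metric)
  H0 <- -z$res$value + kinetic_energy(p0, inv_metric)
  tree <- list(z_minus = z, p_minus = p0, z_plus = z, p_plus = p0,
               rho = p0, log_w = 0)
  cand <- list(u = z$u, res = z$res, H = H0)
  divergent <- FALSE
  sum_a <- 0; n_lf <- 0L; depth <- 0L
  while (depth < max_depth) {
    dir <- if (stats::runif(1) < 0.5) -1 else 1
    from_z <- if (dir == 1) tree$z_plus else tree$z_minus
    from_p <- if (dir == 1) tree$p_plus else tree$p_minus
    sub <- nuts_build_tree(depth, from_z, from_p, dir, H0, eps, inv_metric,
                           model, ctx)
    sum_a <- sum_a + sub$sum_a
    n_lf <- n_lf + sub$n_lf
    if (sub$divergent) divergent <- TRUE
    if (!sub$ok) break
    # progressive biased sampling between the old tree and the new subtree
    if (stats::runif(1) < exp(sub$log_w - tree$log_w)) cand <- sub$z_cand
    tree$log_w <- logsumexp2(tree$log_w, sub$log_w)
    if (dir == 1) {
      tree$z_plus <- sub$z_plus; tree$p_plus <- sub$p_plus
    } else {
      tree$z_minus <- sub$z_minus; tree$p_minus <- sub$p_minus
    }
    tree$rho <- tree$rho + sub$rho
    depth <- depth + 1L
    if (!no_uturn(tree$p_minus, tree$p_plus, tree$rho, inv_metric)) break
  }
  list(z = list(u = cand$u, res = cand$res), energy = cand$H,
       accept_stat = if (n_lf > 0) sum_a / n_lf else 0,
       divergent = divergent, depth = depth, n_lf = n_lf)
}

find_initial_step_size <- function(z, inv_metric, model, ctx) {
  eps <- 1
  npar <- length(z$u)
  p0 <- stats::rnorm(npar, 0, 1) / sqrt(inv_metric)
  H0 <- -z$res$value + kinetic_energy(p0, inv_metric)
  ratio <- function(eps) {
    st <- nuts_leapfrog(list(u = z$u, res = z$res), p0, 1, eps, inv_metric, model, ctx)
    if (st$bad) return(-Inf)
    H1 <- -st$res$value + kinetic_energy(st$p, inv_metric)
    H0 - H1
  }
  r <- ratio(eps)
  dir <- if (is.finite(r) && r > log(0.8)) 1 else -1
  for (k in 1:30) {
    eps_new <- if (dir == 1) eps * 2 else eps / 2
    r <- ratio(eps_new)
    if (dir == 1 && !(is.finite(r) && r > log(0.8))) break
    if (dir == -1 && (is.finite(r) && r > log(0.8))) { eps <- eps_new; break }
    eps <- eps_new
  }
  eps
}

# Stan-style warmup schedule: fast start, expanding covariance windows, fast
# tail.  Returns the iteration indices ending each metric window.
warmup_windows <- function(n_warmup, init_buffer = 75L, term_buffer = 50L,
                           base_window = 25L) {
  if (n_warmup < init_buffer + term_buffer + base_window) {
    init_buffer <- max(1L, as.integer(0.15 * n_warmup))
    term_buffer <- max(1L, as.integer(0.1 * n_warmup))
    base_window <- n_warmup - init_buffer - term_buffer
    if (base_window < 1L) return(list(init = n_warmup, ends = integer(0)))
  }
  ends <- integer(0)
  pos <- init_buffer
  w <- base_window
  while (pos + w <= n_warmup - term_buffer) {
    # widen the final window to absorb the remainder
    if (pos + 2L * w > n_warmup - term_buffer) w <- n_warmup - term_buffer - pos
    pos <- pos + w
    ends <- c(ends, pos)
    w <- 2L * w
  }
  list(init = init_buffer, ends = ends)
}

#' Sample the posterior with adaptive Hamiltonian Monte Carlo
#'
#' Multinomial no-U-turn sampling on the unconstrained scale, with
#' dual-averaging step-size adaptation toward `target_acceptance` and a
#' diagonal metric estimated in expanding warmup windows.  Steady states are
#' warm-started along each trajectory; solver failures act as divergences of
#' the leapfrog integrator.  Identical seed and configuration give identical
#' draws.
#'
#' @param model A `kin_model`.
#' @param cfg A [sampler_config()]; defaults to the model's.
#' @param init_u Optional matrix (chains x parameters) of unconstrained
#'   initial values; by default chains start at the prior locations plus
#'   uniform (-2, 2) jitter, re-drawn until the joint density is finite.
#' @return A `kin_draws` object; run [compute_diagnostics()] or [tidy()] on
#'   it for convergence summaries.
#' @export
sample_posterior <- function(model, cfg = NULL, init_u = NULL) {
  if (is.null(cfg)) cfg <- model$sampler
  ctx <- stat_context(model)
  npar <- ctx$npar
  set.seed(cfg$seed)
  prior_loc_u <- model$params$prior_location  # lognormal location is already log-scale
  n_keep <- cfg$n_draws
  theta_draws <- array(NA_real_, c(cfg$n_chains, n_keep, npar),
                       dimnames = list(NULL, NULL, model$params$name))
  stats_names <- c("lp", "energy", "divergent", "tree_depth", "n_leapfrog",
                   "accept_stat", "step_size")
  sample_stats <- lapply(stats_names, function(s)
    matrix(NA_real_, cfg$n_chains, n_keep))
  names(sample_stats) <- stats_names
  exps <- model$experiments$id
  nbal <- length(model$compiled[[1]]$bal_ids)
  steady_draws <- lapply(exps, function(e)
    array(NA_real_, c(cfg$n_chains, n_keep, nbal)))
  names(steady_draws) <- exps
  nrec <- nrow(model$measurement_index)
  loglik_draws <- array(NA_real_, c(cfg$n_chains, n_keep, nrec))

  schedule <- warmup_windows(cfg$n_warmup)
  for (chain in seq_len(cfg$n_chains)) {
    # initialize
    z <- NULL
    if (!is.null(init_u)) {
      res <- log_joint(model, init_u[chain, ], ctx = ctx)
      if (is.finite(res$value)) z <- list(u = init_u[chain, ], res = res)
    }
    if (is.null(z)) {
      for (try in 1:100) {
        u0 <- prior_loc_u + stats::runif(npar, -2, 2)
        res <- log_joint(model, u0, ctx = ctx)
        if (is.finite(res$value)) { z <- list(u = u0, res = res); break }
      }
    }
    if (is.null(z)) {
      stop("all initialization attempts hit steady-state failures; ",
           "provide wider initial concentration guesses or init_u", call. = FALSE)
    }
    inv_metric <- rep(1, npar)
    eps <- find_initial_step_size(z, inv_metric, model, ctx)
    # dual averaging state
    mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0; da_count <- 0L
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    welford_n <- 0L
    welford_mean <- numeric(npar)
    welford_m2 <- numeric(npar)
    total <- cfg$n_warmup + n_keep
    for (iter in seq_len(total)) {
      warmup <- iter <= cfg$n_warmup
      tr <- nuts_transition(z, eps, inv_metric, cfg$max_tree_depth, model, ctx)
      z <- tr$z
      if (warmup) {
        da_count <- da_count + 1L
        frac <- 1 / (da_count + t0)
        h_bar <- (1 - frac) * h_bar + frac * (cfg$target_acceptance - tr$accept_stat)
        log_eps <- mu - sqrt(da_count) / gamma * h_bar
        w <- da_count^(-kappa)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
        eps <- exp(log_eps)
        if (iter > schedule$init && (length(schedule$ends) == 0 ||
                                     iter <= max(schedule$ends))) {
          welford_n <- welford_n + 1L
          d <- z$u - welford_mean
          welford_mean <- welford_mean + d / welford_n
          welford_m2 <- welford_m2 + d * (z$u - welford_mean)
        }
        if (iter %in% schedule$ends && welford_n > 1L) {
          v <- welford_m2 / (welford_n - 1L)
          shrink <- welford_n / (welford_n + 5)
          inv_metric <- shrink * v + 1e-3 * (1 - shrink)
          welford_n <- 0L; welford_mean[] <- 0; welford_m2[] <- 0
          eps <- find_initial_step_size(z, inv_metric, model, ctx)
          mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0; da_count <- 0L
        }
        if (iter == cfg$n_warmup) eps <- exp(log_eps_bar)
      } else {
        k <- iter - cfg$n_warmup
        theta <- z$u
        theta[ctx$pos] <- exp(z$u[ctx$pos])
        theta_draws[chain, k, ] <- theta
        sample_stats$lp[chain, k] <- z$res$value
        sample_stats$energy[chain, k] <- tr$energy
        sample_stats$divergent[chain, k] <- as.numeric(tr$divergent)
        sample_stats$tree_depth[chain, k] <- tr$depth
        sample_stats$n_leapfrog[chain, k] <- tr$n_lf
        sample_stats$accept_stat[chain, k] <- tr$accept_stat
        sample_stats$step_size[chain, k] <- eps
        for (e in names(z$res$steady)) {
          steady_draws[[e]][chain, k, ] <- z$res$steady[[e]]
        }
        if (nrec > 0) loglik_draws[chain, k, ] <- z$res$per_record
      }
    }
  }
  new_kin_draws(model, theta_draws, sample_stats, steady_draws, loglik_draws,
                method = "nuts", seed = cfg$seed)
}
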