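# Posterior draws container, derived quantities, and structured-draws I/O.

new_kin_draws <- function(model, theta, sample_stats, steady, log_lik,
                          method, seed) {
  structure(list(model = model, theta = theta, sample_stats = sample_stats,
                 steady = steady, log_lik = log_lik, method = method,
                 seed = seed, derived = NULL),
            class = "kin_draws")
}

n_chains <- function(draws) dim(draws$theta)[1]
n_draws_per_chain <- function(draws) dim(draws$theta)[2]

#' @export
print.kin_draws <- function(x, ...) {
  cat("<kin_draws> ", n_chains(x), " chains x ", n_draws_per_chain(x),
      " draws of ", dim(x$theta)[3], " parameters (", x$method, ")\n", sep = "")
  nd <- sum(x$sample_stats$divergent, na.rm = TRUE)
  cat("  post-warmup divergences: ", nd, "\n", sep = "")
  invisible(x)
}

# flatten [chain, draw] from a [chain, draw, k] array into a (chain*draw) x k
# matrix, chains stacked
flatten_cd <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(2, 1, 3)), d[1] * d[2], d[3])
}

# Ensure per-draw steady-state log-concentrations exist for an experiment,
# solving where the sampler did not store them.
steady_for_experiment <- function(draws, ex) {
  model <- draws$model
  a <- draws$steady[[ex]]
  nbal <- length(model$compiled[[ex]]$bal_ids)
  if (!is.null(a) && !anyNA(a)) return(a)
  nc <- n_chains(draws); nd <- n_draws_per_chain(draws)
  a <- array(NA_real_, c(nc, nd, nbal))
  warm <- NULL
  for (chain in seq_len(nc)) {
    for (k in seq_len(nd)) {
      theta <- stats::setNames(draws$theta[chain, k, ], model$params$name)
      ss <- if (is.null(warm)) solve_steady_state(model, ex, theta) else {
        sol <- solve_steady_state_warm(model, model$compiled[[ex]],
                                       as_theta(model, theta), model$solver, warm)
        if (!sol$converged) solve_steady_state(model, ex, theta) else
          list(lnC = sol$lnC, converged = TRUE)
      }
      if (isFALSE(ss$converged)) {
        stop("steady-state failure while deriving draws for experiment '",
             ex, "'", call. = FALSE)
      }
      a[chain, k, ] <- ss$lnC
      warm <- ss$lnC
    }
  }
  draws$steady[[ex]] <- a
  a
}

#' Derived quantities for every posterior draw
#'
#' Recomputes, per draw and experiment, the steady-state concentrations and
#' fluxes and the six-way flux decomposition, via one batched evaluation of
#' the rate law per experiment.
#'
#' @param draws A `kin_draws` object.
#' @return The `kin_draws` object with a populated `derived` field: arrays
#'   `c_star[chain, draw, exp, met]`, `v_star[chain, draw, exp, rxn]` and
#'   `factors[chain, draw, exp, rxn, factor]`.
#' @export
compute_derived <- function(draws) {
  if (!is.null(draws$derived)) return(draws)
  model <- draws$model
  exps <- model$experiments$id
  nc <- n_chains(draws); nd <- n_draws_per_chain(draws)
  cm1 <- model$compiled[[1]]
  nbal <- length(cm1$bal_ids); nrxn <- length(cm1$rxn_ids)
  factor_names <- c("enzyme", "kcat", "reversibility", "saturation",
                    "allostery", "phosphorylation")
  c_star <- array(NA_real_, c(nc, nd, length(exps), nbal),
                  dimnames = list(NULL, NULL, exps, cm1$bal_ids))
  v_star <- array(NA_real_, c(nc, nd, length(exps), nrxn),
                  dimnames = list(NULL, NULL, exps, cm1$rxn_ids))
  factors <- array(NA_real_, c(nc, nd, length(exps), nrxn, 6),
                   dimnames = list(NULL, NULL, exps, cm1$rxn_ids, factor_names))
  theta_flat <- t(flatten_cd(draws$theta))     # npar x (nc*nd)
  for (ei in seq_along(exps)) {
    ex <- exps[ei]
    lnC <- steady_for_experiment(draws, ex)
    lnC_flat <- t(flatten_cd(lnC))             # nbal x (nc*nd)
    r <- kin_eval_cpp(model$compiled[[ex]], theta_flat, lnC_flat, TRUE)
    c_star[, , ei, ] <- aperm(array(t(exp(lnC_flat)), c(nd, nc, nbal)), c(2, 1, 3))
    v_star[, , ei, ] <- aperm(array(t(r$flux), c(nd, nc, nrxn)), c(2, 1, 3))
    for (fi in seq_along(factor_names)) {
      factors[, , ei, , fi] <- aperm(array(t(r[[factor_names[fi]]]),
                                           c(nd, nc, nrxn)), c(2, 1, 3))
    }
  }
  draws$derived <- list(c_star = c_star, v_star = v_star, factors = factors)
  draws
}

measurement_record_ids <- function(model) {
  mi <- model$measurement_index
  if (nrow(mi) == 0) return(character(0))
  sprintf("%s[%s,%s,%d]", mi$type, mi$experiment, mi$target, seq_len(nrow(mi)))
}

# Group extraction used by write_draws and the round-trip reader.
as_draws_groups <- function(draws, include_predictive = TRUE) {
  model <- draws$model
  pn <- dimnames(draws$theta)[[3]]
  posterior <- lapply(seq_along(pn), function(j) draws$theta[, , j, drop = TRUE])
  names(posterior) <- pn
  if (n_chains(draws) == 1) posterior <- lapply(posterior, function(v)
    matrix(v, nrow = 1))
  sample_stats <- draws$sample_stats
  rec_ids <- measurement_record_ids(model)
  log_likelihood <- list()
  if (length(rec_ids) > 0 && !is.null(draws$log_lik)) {
    log_likelihood <- lapply(seq_along(rec_ids), function(j)
      matrix(draws$log_lik[, , j], nrow = n_chains(draws)))
    names(log_likelihood) <- rec_ids
  }
  posterior_predictive <- list()
  if (include_predictive && length(rec_ids) > 0) {
    pp <- posterior_predict(draws)
    posterior_predictive <- lapply(seq_along(rec_ids), function(j)
      matrix(pp$draws[, , j], nrow = n_chains(draws)))
    names(posterior_predictive) <- rec_ids
  }
  draws <- compute_derived(draws)
  dv <- draws$derived
  derived <- list()
  dn <- dimnames(dv$c_star)
  for (ei in seq_along(dn[[3]])) {
    for (mi_ in seq_along(dn[[4]])) {
      derived[[sprintf("c_star[%s,%s]", dn[[3]][ei], dn[[4]][mi_])]] <-
        matrix(dv$c_star[, , ei, mi_], nrow = n_chains(draws))
    }
  }
  dn <- dimnames(dv$v_star)
  for (ei in seq_along(dn[[3]])) {
    for (ri in seq_along(dn[[4]])) {
      derived[[sprintf("v_star[%s,%s]", dn[[3]][ei], dn[[4]][ri])]] <-
        matrix(dv$v_star[, , ei, ri], nrow = n_chains(draws))
    }
  }
  dn <- dimnames(dv$factors)
  for (ei in seq_along(dn[[3]])) {
    for (ri in seq_along(dn[[4]])) {
      for (fi in seq_along(dn[[5]])) {
        derived[[sprintf("factor[%s,%s,%s]", dn[[3]][ei], dn[[4]][ri], dn[[5]][fi])]] <-
          matrix(dv$factors[, , ei, ri, fi], nrow = n_chains(draws))
      }
    }
  }
  list(posterior = posterior, posterior_predictive = posterior_predictive,
       log_likelihood = log_likelihood, sample_stats = sample_stats,
       derived = derived)
}

#' Write posterior draws to a structured JSON file
#'
#' Groups mirror the InferenceData convention: `posterior` (parameter draws),
#' `posterior_predictive` (simulated measurements), `log_likelihood`
#' (per-record), `sample_stats` (divergences, energy, tree depth, ...) and
#' `derived` (steady-state concentrations and fluxes, decomposition
#' factors).  Every variable is a chains x draws array; the file round-trips
#' losslessly through [read_draws()].
#'
#' @param draws A nonempty `kin_draws` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  if (!inherits(draws, "kin_draws") || n_draws_per_chain(draws) == 0) {
    stop("draws must be a nonempty kin_draws object", call. = FALSE)
  }
  if (length(draws$sample_stats) == 0) {
    stop("sample_stats group is empty", call. = FALSE)
  }
  groups <- as_draws_groups(draws)
  # I(17) significant digits: doubles round-trip exactly
  jsonlite::write_json(groups, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read a structured draws JSON file
#'
#' @param path Path written by [write_draws()].
#' @return Named list of groups, each a named list of chains x draws
#'   matrices.
#' @export
read_draws <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(raw, function(g) lapply(g, function(v) {
    v <- if (is.matrix(v)) v else matrix(v, nrow = 1)
    storage.mode(v) <- "double"   # JSON holds no int/double distinction
    v
  }))
  if (is.null(groups$sample_stats) || length(groups$sample_stats) == 0) {
    stop("draws file has an empty sample_stats group", call. = FALSE)
  }
  groups
}

#' Posterior summary table
#'
#' @param x A `kin_draws` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, sd,
#'   2.5/50/97.5 percent quantiles, rank-normalized split R-hat and bulk/tail
#'   effective sample sizes.
#' @export
tidy.kin_draws <- function(x, ...) {
  pn <- dimnames(x$theta)[[3]]
  diag <- compute_diagnostics(x)
  rows <- lapply(seq_along(pn), function(j) {
    v <- as.vector(x$theta[, , j])
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(parameter = pn[j], mean = mean(v), sd = stats::sd(v),
                   q2.5 = q[1], median = q[2], q97.5 = q[3])
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, diag$per_parameter, by = "parameter")
}

#' One-row sampler health summary
#'
#' @param x A `kin_draws` object.
#' @param ... Unused.
#' @return A tibble with chain/draw counts, divergence count, max R-hat and
#'   min bulk/tail ESS.
#' @export
glance.kin_draws <- function(x, ...) {
  diag <- compute_diagnostics(x)
  tibble::tibble(
    n_chains = n_chains(x), n_draws = n_draws_per_chain(x),
    n_divergent = diag$n_divergent,
    max_tree_depth_hits = diag$max_tree_depth_hits,
    max_rhat = max(diag$per_parameter$rhat, na.rm = TRUE),
    min_ess_bulk = min(diag$per_parameter$ess_bulk, na.rm = TRUE),
    min_ess_tail = min(diag$per_parameter$ess_tail, na.rm = TRUE)
  )
}

#' Write the flat posterior-summary CSV
#'
#' @param draws A `kin_draws` object.
#' @param path Output CSV path.
#' @return The summary tibble, invisibly.
#' @export
write_summary_csv <- function(draws, path) {
  s <- tidy(draws)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(s)
}

#' Trace / density plot of posterior draws
#'
#' @param object A `kin_draws` object.
#' @param parameters Parameter names to show (default: first 6).
#' @param ... Unused.
#' @return A ggplot object (trace panels per parameter, colored by chain).
#' @export
autoplot.kin_draws <- function(object, parameters = NULL, ...) {
  pn <- dimnames(object$theta)[[3]]
  if (is.null(parameters)) parameters <- utils::head(pn, 6)
  idx <- match(parameters, pn)
  df <- do.call(rbind, lapply(idx, function(j) {
    data.frame(
      parameter = pn[j],
      chain = factor(rep(seq_len(n_chains(object)), n_draws_per_chain(object))),
      iteration = rep(seq_len(n_draws_per_chain(object)),
                      each = n_chains(object)),
      value = as.vector(object$theta[, , j])
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   color = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}
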