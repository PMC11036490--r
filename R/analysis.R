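# Post-sampling products: posterior predictive checks, regulatory log-ratio
# decomposition, metabolic control analysis, residual reports.

#' Posterior predictive draws for a measurement table
#'
#' Per posterior draw and measurement record: take the modeled quantity (a
#' steady-state concentration or flux, or a boundary/enzyme parameter) and
#' simulate measurement noise from the measurement model (log-normal for
#' concentrations and enzymes, normal for fluxes).  Works for training
#' measurements or for a new table referencing any declared experiment
#' (out-of-sample prediction for validation conditions).
#'
#' @param draws A `kin_draws` object.
#' @param measurements Measurement table (default: the model's own).
#' @param seed RNG seed for the measurement noise.
#' @return List with `draws` (chains x draws x records array), `summary`
#'   (tibble with central 95 percent predictive intervals and the observed
#'   values) and `n_failed` (steady-state failures, excluded from the
#'   summaries, never silently dropped).
#' @export
posterior_predict <- function(draws, measurements = NULL, seed = NULL) {
  model <- draws$model
  if (is.null(measurements)) measurements <- model$measurements
  if (is.null(seed)) seed <- draws$seed + 1000L
  mi <- index_measurements(model, measurements)
  draws <- compute_derived(draws)
  dv <- draws$derived
  nc <- n_chains(draws); nd <- n_draws_per_chain(draws)
  exps <- model$experiments$id
  set.seed(seed)
  out <- array(NA_real_, c(nc, nd, nrow(mi)))
  n_failed <- 0L
  for (i in seq_len(nrow(mi))) {
    r <- mi[i, ]
    ei <- match(r$experiment, exps)
    modeled <- switch(r$source,
      c_star = dv$c_star[, , ei, r$slot, drop = TRUE],
      v_star = dv$v_star[, , ei, r$slot, drop = TRUE],
      param = draws$theta[, , r$slot, drop = TRUE]
    )
    modeled <- matrix(modeled, nc, nd)
    bad <- !is.finite(modeled)
    n_failed <- n_failed + sum(bad)
    noise <- if (r$type == "flux") {
      modeled + stats::rnorm(nc * nd, 0, r$sd)
    } else {
      exp(log(modeled) + stats::rnorm(nc * nd, 0, r$sd))
    }
    noise[bad] <- NA_real_
    out[, , i] <- noise
  }
  summary <- dplyr::bind_rows(lapply(seq_len(nrow(mi)), function(i) {
    v <- as.vector(out[, , i])
    v <- v[is.finite(v)]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(experiment = mi$experiment[i], type = mi$type[i],
                   target = mi$target[i], observed = mi$value[i],
                   predicted_mean = mean(v), q2.5 = q[1], q97.5 = q[2],
                   covered = mi$value[i] >= q[1] & mi$value[i] <= q[2])
  }))
  structure(list(draws = out, summary = summary, n_failed = n_failed,
                 measurements = mi),
            class = "kin_predictive")
}

#' @export
print.kin_predictive <- function(x, ...) {
  cat("<kin_predictive> ", nrow(x$summary), " records; ",
      sum(x$summary$covered), " inside the central 95% interval",
      if (x$n_failed > 0) paste0("; ", x$n_failed, " failed draws excluded"),
      "\n", sep = "")
  invisible(x)
}

#' Posterior predictive check plot
#'
#' @param object A result of [posterior_predict()].
#' @param ... Unused.
#' @return A ggplot: predictive intervals vs observed values per record.
#' @export
autoplot.kin_predictive <- function(object, ...) {
  df <- object$summary
  df$record <- sprintf("%s %s (%s)", df$type, df$target, df$experiment)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$record)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                            color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$predicted_mean), shape = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, color = .data$covered)) +
    ggplot2::facet_wrap(~type, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "value", color = "covered") +
    ggplot2::theme_minimal()
}

#' Regulatory log-ratio decomposition between two conditions
#'
#' For one reaction, decomposes the posterior flux log-ratio between
#' experiments A and B into per-factor log-ratios
#' (enzyme, reversibility, saturation, allostery, phosphorylation).  Factors
#' that are structurally constant are flagged excluded: kcat is shared
#' across conditions (log-ratio identically 0), the reversibility of an
#' irreversible mechanism is identically 1, and drains expose only the flux.
#' Per draw, the included log-ratios sum exactly to the flux log-ratio.
#'
#' @param draws A `kin_draws` object.
#' @param reaction_id Reaction id.
#' @param exp_a,exp_b Experiment ids (numerator and denominator conditions).
#' @return Object of class `kin_reg_report`: `ratios` (draws x factor
#'   matrix, including `flux`), `summary` tibble with per-factor posterior
#'   mass above zero, and the excluded-factor flags.
#' @export
regulatory_log_ratios <- function(draws, reaction_id, exp_a, exp_b) {
  model <- draws$model
  net <- model$network
  ri <- match(reaction_id, net$reactions$id)
  if (is.na(ri)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  for (ex in c(exp_a, exp_b)) {
    j <- match(ex, model$experiments$id)
    if (is.na(j)) stop("unknown experiment '", ex, "'", call. = FALSE)
    enz <- net$reactions$enzyme[ri]
    if (!is.na(enz) && enz %in% model$experiments$knockouts[[j]]) {
      stop("reaction '", reaction_id, "' is knocked out in experiment '",
           ex, "'", call. = FALSE)
    }
  }
  draws <- compute_derived(draws)
  dv <- draws$derived
  ea <- match(exp_a, model$experiments$id)
  eb <- match(exp_b, model$experiments$id)
  mech <- net$reactions$mechanism[ri]
  factor_names <- c("enzyme", "kcat", "reversibility", "saturation",
                    "allostery", "phosphorylation")
  excluded <- c(
    enzyme = mech == "drain",
    kcat = TRUE,   # kcat is shared between conditions: ratio identically 1
    reversibility = mech != "reversible_modular",
    saturation = mech == "drain",
    allostery = mech == "drain",
    phosphorylation = mech == "drain"
  )
  nc <- n_chains(draws); nd <- n_draws_per_chain(draws)
  ratios <- matrix(NA_real_, nc * nd, length(factor_names) + 1,
                   dimnames = list(NULL, c(factor_names, "flux")))
  for (fi in seq_along(factor_names)) {
    fa <- as.vector(dv$factors[, , ea, ri, fi])
    fb <- as.vector(dv$factors[, , eb, ri, fi])
    ratios[, fi] <- log(fa) - log(fb)
  }
  ratios[, "flux"] <- log(as.vector(dv$v_star[, , ea, ri])) -
    log(as.vector(dv$v_star[, , eb, ri]))
  summary <- dplyr::bind_rows(lapply(colnames(ratios), function(f) {
    v <- ratios[, f]
    tibble::tibble(
      factor = f,
      excluded = if (f == "flux") FALSE else unname(excluded[f]),
      mean = mean(v), q2.5 = stats::quantile(v, 0.025, names = FALSE),
      q97.5 = stats::quantile(v, 0.975, names = FALSE),
      prob_positive = mean(v > 0), prob_negative = mean(v < 0)
    )
  }))
  structure(list(reaction = reaction_id, exp_a = exp_a, exp_b = exp_b,
                 ratios = ratios, excluded = excluded, summary = summary),
            class = "kin_reg_report")
}

#' @export
print.kin_reg_report <- function(x, ...) {
  cat("<kin_reg_report> ", x$reaction, ": ", x$exp_a, " vs ", x$exp_b, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Regulatory decomposition plot
#'
#' @param object A [regulatory_log_ratios()] result.
#' @param ... Unused.
#' @return A ggplot of the per-factor log-ratio posteriors (excluded factors
#'   dropped).
#' @export
autoplot.kin_reg_report <- function(object, ...) {
  keep <- c(names(object$excluded)[!object$excluded], "flux")
  df <- do.call(rbind, lapply(keep, function(f)
    data.frame(factor = f, log_ratio = object$ratios[, f])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_ratio, fill = .data$factor)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~factor, scales = "free") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = sprintf("ln(%s / %s)", object$exp_a, object$exp_b)) +
    ggplot2::theme_minimal()
}

#' Metabolic control analysis coefficients
#'
#' Flux-control and concentration-control coefficients with respect to the
#' activities of all reactions in one experiment: the enzyme concentration
#' for enzyme-catalyzed reactions and the drain flux parameter for drains
#' (both enter the rate law linearly, so the usual summation theorems hold in
#' generalized form: flux-control rows sum to 1, concentration-control rows
#' to 0).
#'
#' @param model A `kin_model`.
#' @param experiment_id Experiment id.
#' @param theta Constrained parameter values.
#' @param ss Optional converged steady state (solved if omitted).
#' @return Object of class `kin_control`: `flux_control` (reactions x
#'   activities) and `conc_control` (balanced metabolites x activities).
#' @export
control_coefficients <- function(model, experiment_id, theta, ss = NULL) {
  theta <- as_theta(model, theta)
  if (is.null(ss)) {
    ss <- solve_steady_state(model, experiment_id,
                             stats::setNames(theta, model$params$name))
  }
  if (!ss$converged) stop("steady state did not converge", call. = FALSE)
  p <- model$params
  act_idx <- which((p$kind == "enzyme_conc" | p$kind == "drain_flux") &
                     p$experiment == experiment_id)
  # activity labels: enzyme id or drain reaction id
  act_ids <- ifelse(p$kind[act_idx] == "enzyme_conc", p$enzyme[act_idx],
                    p$reaction[act_idx])
  sens <- steady_state_sensitivities(model, experiment_id,
                                     stats::setNames(theta, p$name), ss,
                                     parameters = p$name[act_idx])
  a <- theta[act_idx]
  v <- unname(ss$v_star)
  C <- unname(ss$c_star)
  CJ <- sweep(sens$dv, 2, a, "*") / ifelse(v == 0, NA_real_, v)
  CS <- if (length(C) > 0) sweep(sens$dC, 2, a, "*") / C else sens$dC
  dimnames(CJ) <- list(model$network$reactions$id, act_ids)
  if (length(C) > 0) dimnames(CS) <- list(names(ss$c_star), act_ids)
  structure(list(experiment = experiment_id, flux_control = CJ,
                 conc_control = CS), class = "kin_control")
}

#' @export
print.kin_control <- function(x, ...) {
  cat("<kin_control> experiment ", x$experiment, "\n", sep = "")
  cat("flux control (rows sum to 1):\n")
  print(round(x$flux_control, 4))
  if (nrow(x$conc_control) > 0) {
    cat("concentration control (rows sum to 0):\n")
    print(round(x$conc_control, 4))
  }
  invisible(x)
}

#' Control coefficients summarized over posterior draws
#'
#' @param draws A `kin_draws` object.
#' @param experiment_id Experiment id.
#' @param thin Keep every `thin`-th draw (sensitivity solves are not free).
#' @return Tibble: reaction/metabolite, activity, posterior mean and central
#'   95 percent interval of each control coefficient.
#' @export
control_coefficient_draws <- function(draws, experiment_id, thin = 10L) {
  model <- draws$model
  nc <- n_chains(draws); nd <- n_draws_per_chain(draws)
  keep <- seq(1L, nd, by = thin)
  acc <- list()
  for (chain in seq_len(nc)) {
    for (k in keep) {
      theta <- stats::setNames(draws$theta[chain, k, ], model$params$name)
      cc <- control_coefficients(model, experiment_id, theta)
      acc[[length(acc) + 1L]] <- dplyr::bind_rows(
        tibble::as_tibble(as.data.frame.table(cc$flux_control,
                                              responseName = "value")) |>
          stats::setNames(c("target", "activity", "value")) |>
          dplyr::mutate(matrix = "flux_control"),
        tibble::as_tibble(as.data.frame.table(cc$conc_control,
                                              responseName = "value")) |>
          stats::setNames(c("target", "activity", "value")) |>
          dplyr::mutate(matrix = "conc_control")
      )
    }
  }
  dplyr::bind_rows(acc) |>
    dplyr::group_by(.data$matrix, .data$target, .data$activity) |>
    dplyr::summarise(mean = mean(.data$value),
                     q2.5 = stats::quantile(.data$value, 0.025),
                     q97.5 = stats::quantile(.data$value, 0.975),
                     .groups = "drop")
}

#' Per-record residual summaries
#'
#' Concentration and enzyme residuals on the natural-log scale,
#' `ln(measured) - ln(posterior-median modeled)`; flux residuals as raw
#' differences.
#'
#' @param draws A `kin_draws` object.
#' @param measurements Measurement table (default: the model's).
#' @return Tibble with one row per record: experiment, type, target,
#'   observed, posterior-median modeled value, residual.
#' @export
residual_report <- function(draws, measurements = NULL) {
  model <- draws$model
  if (is.null(measurements)) measurements <- model$measurements
  mi <- index_measurements(model, measurements)
  draws <- compute_derived(draws)
  dv <- draws$derived
  exps <- model$experiments$id
  dplyr::bind_rows(lapply(seq_len(nrow(mi)), function(i) {
    r <- mi[i, ]
    ei <- match(r$experiment, exps)
    modeled <- switch(r$source,
      c_star = as.vector(dv$c_star[, , ei, r$slot]),
      v_star = as.vector(dv$v_star[, , ei, r$slot]),
      param = as.vector(draws$theta[, , r$slot])
    )
    med <- stats::median(modeled, na.rm = TRUE)
    resid <- if (r$type == "flux") r$value - med else log(r$value) - log(med)
    tibble::tibble(experiment = r$experiment, type = r$type, target = r$target,
                   observed = r$value, modeled_median = med, residual = resid)
  }))
}
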