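# Parameter enumeration, prior specification and model assembly.

PARAM_KINDS <- c(
  "kcat", "km", "ki", "transfer_constant", "dissociation_constant",
  "formation_energy", "enzyme_conc", "boundary_conc", "drain_flux", "phos_rate"
)
SIGN_FREE_KINDS <- c("formation_energy", "drain_flux")

#' Gas constant in kJ/(mol K)
#' @export
R_GAS <- 0.008314

#' Define the prior model
#'
#' Scalar parameters get independent normal (sign-free parameters: formation
#' energies, drain fluxes) or log-normal (positivity-constrained parameters)
#' priors; the formation-energy vector takes one multivariate normal prior
#' with a full covariance matrix.
#'
#' @param scalars Data frame with columns `parameter` (one of
#'   `r PARAM_KINDS`), the id columns relevant to that kind (`enzyme`,
#'   `metabolite`, `effector`, `reaction`, `experiment`; unused ones `NA`),
#'   `location`, `scale` and `distribution` (`"normal"` or `"lognormal"`).
#'   A row with `experiment = NA` applies to every experiment.
#' @param formation_energy Optional list with `ids` (metabolite ids), `mean`
#'   (kJ/mol) and `covariance` (kJ^2/mol^2, symmetric positive definite).
#' @return An object of class `kin_priors`.
#' @export
kin_priors <- function(scalars, formation_energy = NULL) {
  scalars <- tibble::as_tibble(scalars)
  for (col in c("enzyme", "metabolite", "effector", "reaction", "experiment")) {
    if (is.null(scalars[[col]])) scalars[[col]] <- NA_character_
  }
  if (nrow(scalars) > 0) {
    if (any(scalars$scale <= 0)) {
      bad <- which(scalars$scale <= 0)[1]
      stop("prior for '", scalars$parameter[bad], "' has non-positive scale",
           call. = FALSE)
    }
    if (!all(scalars$distribution %in% c("normal", "lognormal"))) {
      stop("prior distribution must be 'normal' or 'lognormal'", call. = FALSE)
    }
    bad <- scalars$distribution == "lognormal" &
      scalars$parameter %in% SIGN_FREE_KINDS
    if (any(bad)) {
      stop("lognormal prior assigned to sign-free parameter '",
           scalars$parameter[which(bad)[1]], "'", call. = FALSE)
    }
    bad <- scalars$distribution == "normal" &
      !scalars$parameter %in% SIGN_FREE_KINDS
    if (any(bad)) {
      stop("normal prior assigned to positivity-constrained parameter '",
           scalars$parameter[which(bad)[1]], "'; use lognormal", call. = FALSE)
    }
  }
  if (!is.null(formation_energy)) {
    cov <- as.matrix(formation_energy$covariance)
    if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-10))) {
      stop("formation-energy covariance must be symmetric", call. = FALSE)
    }
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("formation-energy covariance must be positive definite", call. = FALSE)
    }
    stopifnot(length(formation_energy$ids) == length(formation_energy$mean),
              nrow(cov) == length(formation_energy$ids))
    formation_energy$covariance <- cov
  }
  structure(list(scalars = scalars, formation_energy = formation_energy),
            class = "kin_priors")
}

param_name <- function(kind, enzyme = NA, metabolite = NA, effector = NA,
                       reaction = NA, experiment = NA, ptm_type = NA) {
  ids <- c(experiment, enzyme, metabolite, effector, reaction, ptm_type)
  paste0(kind, "[", paste(ids[!is.na(ids)], collapse = ","), "]")
}

# Enumerate every scalar unknown of the model as one row.
build_parameter_table <- function(net, experiments) {
  rows <- list()
  add <- function(kind, enzyme = NA_character_, metabolite = NA_character_,
                  effector = NA_character_, reaction = NA_character_,
                  experiment = NA_character_, ptm_type = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = param_name(kind, enzyme, metabolite, effector, reaction,
                        experiment, ptm_type),
      kind = kind, enzyme = enzyme, metabolite = metabolite,
      effector = effector, reaction = reaction, experiment = experiment,
      ptm_type = ptm_type, positive = !kind %in% SIGN_FREE_KINDS
    )
  }
  rxns <- net$reactions
  regs <- net$regulations
  seen_kcat <- character(0)
  seen_km <- character(0)
  for (i in seq_len(nrow(rxns))) {
    rx <- rxns[i, ]
    if (rx$mechanism == "drain") next
    if (!rx$enzyme %in% seen_kcat) {
      add("kcat", enzyme = rx$enzyme)
      seen_kcat <- c(seen_kcat, rx$enzyme)
    }
    st <- rx$stoichiometry[[1]]
    coef <- st$num / st$den
    participants <- if (rx$mechanism == "reversible_modular") st$ids else st$ids[coef < 0]
    for (met in participants) {
      key <- paste(rx$enzyme, met, sep = "\r")
      if (!key %in% seen_km) {
        add("km", enzyme = rx$enzyme, metabolite = met)
        seen_km <- c(seen_km, key)
      }
    }
  }
  for (i in seq_len(nrow(regs))) {
    rg <- regs[i, ]
    if (rg$type == "competitive_inhibition") {
      add("ki", enzyme = rg$enzyme, metabolite = rg$effector)
    } else if (rg$type %in% c("allosteric_activation", "allosteric_inhibition")) {
      add("dissociation_constant", enzyme = rg$enzyme, effector = rg$effector)
    }
  }
  allo_enzymes <- unique(regs$enzyme[regs$type %in%
    c("allosteric_activation", "allosteric_inhibition")])
  for (e in allo_enzymes) add("transfer_constant", enzyme = e)
  # formation energies: metabolites taking part in any reversible reaction
  fe_mets <- character(0)
  for (i in seq_len(nrow(rxns))) {
    if (rxns$mechanism[i] == "reversible_modular") {
      fe_mets <- union(fe_mets, rxns$stoichiometry[[i]]$ids)
    }
  }
  fe_mets <- net$metabolites$id[net$metabolites$id %in% fe_mets]
  for (met in fe_mets) add("formation_energy", metabolite = met)
  # per-experiment unknowns
  unbalanced <- net$metabolites$id[!net$metabolites$balanced]
  drains <- rxns$id[rxns$mechanism == "drain"]
  ptm <- regs[regs$type %in% c("phosphorylation", "dephosphorylation"), , drop = FALSE]
  for (j in seq_len(nrow(experiments))) {
    ex <- experiments$id[j]
    ko <- experiments$knockouts[[j]]
    for (e in setdiff(net$enzymes$id, ko)) add("enzyme_conc", enzyme = e, experiment = ex)
    for (met in unbalanced) add("boundary_conc", metabolite = met, experiment = ex)
    for (d in drains) add("drain_flux", reaction = d, experiment = ex)
    for (i in seq_len(nrow(ptm))) {
      add("phos_rate", enzyme = ptm$enzyme[i], effector = ptm$effector[i],
          experiment = ex, ptm_type = ptm$type[i])
    }
  }
  out <- dplyr::bind_rows(rows)
  out$index <- seq_len(nrow(out))
  out
}

# Attach prior location/scale columns to the parameter table.
match_priors <- function(params, priors) {
  sc <- priors$scalars
  used <- rep(FALSE, nrow(sc))
  loc <- scale <- rep(NA_real_, nrow(params))
  id_cols <- c("enzyme", "metabolite", "effector", "reaction")
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    if (p$kind == "formation_energy") next  # handled by the MVN block
    cand <- which(sc$parameter == p$kind)
    for (col in id_cols) {
      if (!is.na(p[[col]])) cand <- cand[!is.na(sc[[col]][cand]) & sc[[col]][cand] == p[[col]]]
      else cand <- cand[is.na(sc[[col]][cand])]
    }
    if (p$kind == "phos_rate") {
      cand <- cand[is.na(sc$experiment[cand]) | sc$experiment[cand] == p$experiment]
    }
    if (!is.na(p$experiment)) {
      specific <- cand[!is.na(sc$experiment[cand]) & sc$experiment[cand] == p$experiment]
      generic <- cand[is.na(sc$experiment[cand])]
      cand <- if (length(specific) > 0) specific else generic
    }
    if (length(cand) == 0) {
      stop("no prior found for parameter '", p$name, "'", call. = FALSE)
    }
    if (length(cand) > 1) {
      stop("ambiguous prior for parameter '", p$name, "'", call. = FALSE)
    }
    used[cand] <- TRUE
    loc[i] <- sc$location[cand]
    scale[i] <- sc$scale[cand]
  }
  # a prior row matching no parameter is a dangling reference
  for (j in which(!used)) {
    ids <- unlist(sc[j, c(id_cols, "experiment")])
    ids <- ids[!is.na(ids)]
    stop("prior for '", sc$parameter[j], "' references unknown target '",
         paste(ids, collapse = ","), "'", call. = FALSE)
  }
  params$prior_location <- loc
  params$prior_scale <- scale
  # formation energies from the MVN block
  fe_idx <- which(params$kind == "formation_energy")
  if (length(fe_idx) > 0) {
    fe <- priors$formation_energy
    if (is.null(fe)) {
      stop("model has reversible reactions but no formation-energy prior block",
           call. = FALSE)
    }
    missing <- setdiff(params$metabolite[fe_idx], fe$ids)
    if (length(missing) > 0) {
      stop("formation-energy prior block is missing metabolite '",
           missing[1], "'", call. = FALSE)
    }
    pos <- match(params$metabolite[fe_idx], fe$ids)
    params$prior_location[fe_idx] <- fe$mean[pos]
    params$prior_scale[fe_idx] <- sqrt(diag(fe$covariance))[pos]
  }
  params
}

#' Assemble a kinetic model context
#'
#' Combines the network, priors, experimental conditions, measurements and
#' solver/sampler settings into one validated, pre-compiled model object that
#' every downstream operation (steady-state solving, log-density evaluation,
#' sampling, analysis) consumes.
#'
#' @param network A [kin_network()].
#' @param priors A [kin_priors()].
#' @param experiments A [kin_experiments()] table.
#' @param measurements A [kin_measurements()] table (may be empty).
#' @param solver A [solver_config()].
#' @param sampler A [sampler_config()].
#' @param temperature Temperature in K (default 298.15).
#' @return An object of class `kin_model`.
#' @export
kin_model <- function(network, priors, experiments,
                      measurements = kin_measurements(character(0), character(0),
                                                      character(0), numeric(0), numeric(0)),
                      solver = solver_config(), sampler = sampler_config(),
                      temperature = 298.15) {
  validate_network(network)
  validate_experiments(experiments, network)
  validate_measurements(measurements, network, experiments)
  params <- build_parameter_table(network, experiments)
  params <- match_priors(params, priors)
  fe_idx <- which(params$kind == "formation_energy")
  fe_block <- NULL
  if (length(fe_idx) > 0) {
    fe <- priors$formation_energy
    pos <- match(params$metabolite[fe_idx], fe$ids)
    cov <- fe$covariance[pos, pos, drop = FALSE]
    fe_block <- list(idx = fe_idx, mean = fe$mean[pos], cov = cov,
                     chol = chol(cov), prec = solve(cov),
                     logdet = determinant(cov, logarithm = TRUE)$modulus[1])
  }
  model <- structure(
    list(network = network, priors = priors, experiments = experiments,
         measurements = measurements, params = params, fe_block = fe_block,
         solver = solver, sampler = sampler, temperature = temperature),
    class = "kin_model"
  )
  model$compiled <- compile_model(model)
  model$measurement_index <- index_measurements(model)
  model
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model> ", nrow(x$params), " parameters, ",
      nrow(x$experiments), " experiments, ",
      nrow(x$measurements), " measurements\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Steady-state solver settings
#'
#' @param t_evolve Initial ODE evolution time (s) of the hybrid solver.
#' @param rel_tol,abs_tol ODE integration tolerances.
#' @param newton_tol Convergence tolerance: infinity norm of the balanced
#'   net production rates (mM/s).
#' @param max_newton_iters Newton iteration cap.
#' @param max_retries Number of times `t_evolve` is doubled after a Newton
#'   failure before giving up.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(t_evolve = 30, rel_tol = 1e-9, abs_tol = 1e-12,
                          newton_tol = 1e-8, max_newton_iters = 50L,
                          max_retries = 4L) {
  cfg <- list(t_evolve = t_evolve, rel_tol = rel_tol, abs_tol = abs_tol,
              newton_tol = newton_tol, max_newton_iters = as.integer(max_newton_iters),
              max_retries = as.integer(max_retries))
  stopifnot(all(unlist(cfg) > 0))
  structure(cfg, class = "solver_config")
}

#' Sampler settings
#'
#' @param n_chains,n_warmup,n_draws Chain count and per-chain warmup/draw
#'   counts.
#' @param target_acceptance Dual-averaging target acceptance statistic.
#' @param max_tree_depth NUTS tree depth cap.
#' @param seed RNG seed (integer).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 1000L,
                           target_acceptance = 0.8, max_tree_depth = 10L,
                           seed = 1L) {
  stopifnot(n_chains >= 1, n_warmup >= 1, n_draws >= 1,
            target_acceptance > 0, target_acceptance < 1, max_tree_depth >= 1)
  structure(list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws), target_acceptance = target_acceptance,
                 max_tree_depth = as.integer(max_tree_depth), seed = as.integer(seed)),
            class = "sampler_config")
}

# --- engine compilation -----------------------------------------------------
#
# The model is flattened, once per experiment, into plain integer/double
# vectors (CSR-style ragged arrays, 0-based indices) consumed by the C++
# flux evaluator.  theta row indices are into the packed parameter vector.

compile_model <- function(model) {
  net <- model$network
  params <- model$params
  mets <- net$metabolites$id
  bal <- net$metabolites$balanced
  nmet <- length(mets)
  rxns <- net$reactions
  nrxn <- nrow(rxns)
  regs <- net$regulations
  S_bal <- stoich_matrix(net, balanced_only = TRUE)
  RT <- R_GAS * model$temperature

  pidx <- function(kind, ...) {
    key <- list(...)
    cand <- which(params$kind == kind)
    for (col in names(key)) {
      v <- key[[col]]
      cand <- if (is.na(v)) cand[is.na(params[[col]][cand])]
      else cand[!is.na(params[[col]][cand]) & params[[col]][cand] == v]
    }
    if (length(cand) != 1) {
      stop("internal: parameter lookup failed for ", kind, " ",
           paste(unlist(key), collapse = ","))
    }
    cand
  }

  shared <- list(
    nrxn = nrxn, nmet = nmet, nbal = sum(bal),
    met_ids = mets, bal_ids = mets[bal], rxn_ids = rxns$id,
    S = stoich_matrix(net), S_bal = S_bal, RT = RT
  )

  compile_exp <- function(ex) {
    ko <- model$experiments$knockouts[[match(ex, model$experiments$id)]]
    rxn_type <- integer(nrxn); reversible <- integer(nrxn)
    subunits <- numeric(nrxn); kcat_t <- integer(nrxn)
    enz_t <- integer(nrxn); drain_t <- integer(nrxn); L_t <- integer(nrxn)
    sub_off <- prod_off <- ci_off <- act_off <- inh_off <-
      dg_off <- q_off <- p_off <- d_off <- 0L
    sub_m <- sub_km <- prod_m <- prod_km <- ci_m <- ci_t <-
      act_m <- act_t <- inh_m <- inh_t <- dg_t <- q_m <- p_t <- d_t <- integer(0)
    sub_s <- prod_s <- dg_s <- q_s <- numeric(0)
    offs <- function(v) c(0L, cumsum(v))
    n_sub <- n_prod <- n_ci <- n_act <- n_inh <- n_dg <- n_q <- n_p <- n_d <-
      integer(nrxn)
    for (i in seq_len(nrxn)) {
      rx <- rxns[i, ]
      st <- rx$stoichiometry[[1]]
      coef <- st$num / st$den
      if (rx$mechanism == "drain") {
        rxn_type[i] <- 1L
        kcat_t[i] <- enz_t[i] <- L_t[i] <- -1L
        drain_t[i] <- pidx("drain_flux", reaction = rx$id, experiment = ex) - 1L
        next
      }
      rxn_type[i] <- 0L
      drain_t[i] <- -1L
      reversible[i] <- as.integer(rx$mechanism == "reversible_modular")
      e <- rx$enzyme
      subunits[i] <- net$enzymes$subunits[match(e, net$enzymes$id)]
      kcat_t[i] <- pidx("kcat", enzyme = e) - 1L
      enz_t[i] <- if (e %in% ko) -1L else
        pidx("enzyme_conc", enzyme = e, experiment = ex) - 1L
      subs <- which(coef < 0); prods <- which(coef > 0)
      n_sub[i] <- length(subs)
      sub_m <- c(sub_m, match(st$ids[subs], mets) - 1L)
      sub_s <- c(sub_s, abs(coef[subs]))
      sub_km <- c(sub_km, vapply(st$ids[subs], function(mm)
        pidx("km", enzyme = e, metabolite = mm) - 1L, integer(1)))
      if (reversible[i] == 1L) {
        n_prod[i] <- length(prods)
        prod_m <- c(prod_m, match(st$ids[prods], mets) - 1L)
        prod_s <- c(prod_s, abs(coef[prods]))
        prod_km <- c(prod_km, vapply(st$ids[prods], function(mm)
          pidx("km", enzyme = e, metabolite = mm) - 1L, integer(1)))
        # thermodynamics: Delta_rG0 and ln Q over all participants
        n_dg[i] <- length(st$ids)
        dg_t <- c(dg_t, vapply(st$ids, function(mm)
          pidx("formation_energy", metabolite = mm) - 1L, integer(1)))
        dg_s <- c(dg_s, coef)
        n_q[i] <- length(st$ids)
        q_m <- c(q_m, match(st$ids, mets) - 1L)
        q_s <- c(q_s, coef)
      }
      my_regs <- regs[regs$enzyme == e, , drop = FALSE]
      ci <- my_regs[my_regs$type == "competitive_inhibition", , drop = FALSE]
      n_ci[i] <- nrow(ci)
      if (nrow(ci) > 0) {
        ci_m <- c(ci_m, match(ci$effector, mets) - 1L)
        ci_t <- c(ci_t, vapply(ci$effector, function(mm)
          pidx("ki", enzyme = e, metabolite = mm) - 1L, integer(1)))
      }
      act <- my_regs[my_regs$type == "allosteric_activation", , drop = FALSE]
      inh <- my_regs[my_regs$type == "allosteric_inhibition", , drop = FALSE]
      if (nrow(act) + nrow(inh) > 0) {
        L_t[i] <- pidx("transfer_constant", enzyme = e) - 1L
        n_act[i] <- nrow(act); n_inh[i] <- nrow(inh)
        if (nrow(act) > 0) {
          act_m <- c(act_m, match(act$effector, mets) - 1L)
          act_t <- c(act_t, vapply(act$effector, function(mm)
            pidx("dissociation_constant", enzyme = e, effector = mm) - 1L, integer(1)))
        }
        if (nrow(inh) > 0) {
          inh_m <- c(inh_m, match(inh$effector, mets) - 1L)
          inh_t <- c(inh_t, vapply(inh$effector, function(mm)
            pidx("dissociation_constant", enzyme = e, effector = mm) - 1L, integer(1)))
        }
      } else {
        L_t[i] <- -1L
      }
      phos <- my_regs[my_regs$type == "phosphorylation", , drop = FALSE]
      deph <- my_regs[my_regs$type == "dephosphorylation", , drop = FALSE]
      n_p[i] <- nrow(phos); n_d[i] <- nrow(deph)
      if (nrow(phos) > 0) {
        p_t <- c(p_t, vapply(seq_len(nrow(phos)), function(k)
          pidx("phos_rate", enzyme = e, effector = phos$effector[k],
               experiment = ex, ptm_type = "phosphorylation") - 1L, integer(1)))
      }
      if (nrow(deph) > 0) {
        d_t <- c(d_t, vapply(seq_len(nrow(deph)), function(k)
          pidx("phos_rate", enzyme = e, effector = deph$effector[k],
               experiment = ex, ptm_type = "dephosphorylation") - 1L, integer(1)))
      }
    }
    met_bal_pos <- rep(-1L, nmet)
    met_bal_pos[bal] <- seq_len(sum(bal)) - 1L
    met_bound_t <- rep(-1L, nmet)
    for (j in which(!bal)) {
      met_bound_t[j] <- pidx("boundary_conc", metabolite = mets[j],
                             experiment = ex) - 1L
    }
    c(shared, list(
      experiment = ex,
      met_bal_pos = met_bal_pos, met_bound_t = met_bound_t,
      rxn_type = rxn_type, reversible = reversible, subunits = subunits,
      kcat_t = kcat_t, enz_t = enz_t, drain_t = drain_t, L_t = L_t,
      sub_off = offs(n_sub), sub_m = sub_m, sub_s = sub_s, sub_km = sub_km,
      prod_off = offs(n_prod), prod_m = prod_m, prod_s = prod_s, prod_km = prod_km,
      ci_off = offs(n_ci), ci_m = ci_m, ci_t = ci_t,
      act_off = offs(n_act), act_m = act_m, act_t = act_t,
      inh_off = offs(n_inh), inh_m = inh_m, inh_t = inh_t,
      dg_off = offs(n_dg), dg_t = dg_t, dg_s = dg_s,
      q_off = offs(n_q), q_m = q_m, q_s = q_s,
      p_off = offs(n_p), p_t = p_t, d_off = offs(n_d), d_t = d_t
    ))
  }
  cms <- lapply(model$experiments$id, compile_exp)
  names(cms) <- model$experiments$id
  cms
}

# Resolve each measurement row to a modeled quantity: a steady-state
# concentration/flux or a parameter.
index_measurements <- function(model, ms = model$measurements) {
  net <- model$network
  if (nrow(ms) == 0) {
    return(tibble::tibble(experiment = character(0), type = character(0),
                          target = character(0), value = numeric(0),
                          sd = numeric(0), source = character(0),
                          slot = integer(0)))
  }
  bal_ids <- net$metabolites$id[net$metabolites$balanced]
  source <- character(nrow(ms)); slot <- integer(nrow(ms))
  for (i in seq_len(nrow(ms))) {
    r <- ms[i, ]
    if (r$type == "conc") {
      if (r$target %in% bal_ids) {
        source[i] <- "c_star"; slot[i] <- match(r$target, bal_ids)
      } else {
        source[i] <- "param"
        slot[i] <- which(model$params$kind == "boundary_conc" &
                         model$params$metabolite == r$target &
                         model$params$experiment == r$experiment)[1]
        if (is.na(slot[i])) stop("measurement of unmodeled boundary '", r$target,
                                 "' in experiment '", r$experiment, "'", call. = FALSE)
      }
    } else if (r$type == "enzyme") {
      source[i] <- "param"
      slot[i] <- which(model$params$kind == "enzyme_conc" &
                       model$params$enzyme == r$target &
                       model$params$experiment == r$experiment)[1]
      if (is.na(slot[i])) stop("enzyme measurement of '", r$target,
                               "' in experiment '", r$experiment,
                               "' has no modeled concentration (knocked out?)",
                               call. = FALSE)
    } else {
      source[i] <- "v_star"; slot[i] <- match(r$target, net$reactions$id)
    }
  }
  out <- tibble::as_tibble(ms)
  out$source <- source
  out$slot <- slot
  out
}
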