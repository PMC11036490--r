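# Reading and writing the plain-text input directory:
# model.toml, priors.toml, experiments.toml, config.toml.

rat_to_input <- function(num, den) {
  if (den == 1) num else paste0(num, "/", den)
}

#' Parse a model input directory
#'
#' Reads `model.toml` (network topology, mechanisms, regulation),
#' `priors.toml`, `experiments.toml` (conditions and measurements) and
#' `config.toml` (solver and sampler settings), validates all
#' cross-references and returns the assembled model.  Units: concentrations
#' mM, fluxes mM/s, energies kJ/mol, temperature K.
#'
#' @param path Directory containing the four files.
#' @return A `kin_model`.
#' @export
parse_input <- function(path) {
  for (f in c("model.toml", "priors.toml", "experiments.toml", "config.toml")) {
    if (!file.exists(file.path(path, f))) {
      stop("missing input file '", f, "' in ", path, call. = FALSE)
    }
  }
  m <- parse_toml(file.path(path, "model.toml"))
  pr <- parse_toml(file.path(path, "priors.toml"))
  ex <- parse_toml(file.path(path, "experiments.toml"))
  cfg <- parse_toml(file.path(path, "config.toml"))

  metabolites <- dplyr::bind_rows(lapply(m$metabolites, function(r)
    tibble::tibble(id = r$id, compartment = r$compartment %||% "c",
                   balanced = isTRUE(r$balanced))))
  enzymes <- if (length(m$enzymes %||% list()) > 0) {
    dplyr::bind_rows(lapply(m$enzymes, function(r)
      tibble::tibble(id = r$id, subunits = as.integer(r$subunits %||% 1L))))
  } else tibble::tibble(id = character(0), subunits = integer(0))
  reactions <- dplyr::bind_rows(lapply(m$reactions, function(r)
    tibble::tibble(id = r$id, mechanism = r$mechanism,
                   enzyme = r$enzyme %||% NA_character_,
                   stoichiometry = list(unlist(r$stoichiometry)))))
  # inline-table values may arrive as a list mixing numbers and "p/q" strings
  reactions$stoichiometry <- lapply(m$reactions, function(r) {
    s <- r$stoichiometry
    stats::setNames(lapply(names(s), function(k) s[[k]]), names(s))
  })
  regulations <- if (length(m$regulations %||% list()) > 0) {
    dplyr::bind_rows(lapply(m$regulations, function(r)
      tibble::tibble(type = r$type, enzyme = r$enzyme, effector = r$effector)))
  } else NULL
  net <- kin_network(metabolites, enzymes, reactions, regulations)

  scalars <- dplyr::bind_rows(lapply(pr$priors %||% list(), function(r)
    tibble::tibble(
      parameter = r$parameter,
      enzyme = r$enzyme %||% NA_character_,
      metabolite = r$metabolite %||% NA_character_,
      effector = r$effector %||% NA_character_,
      reaction = r$reaction %||% NA_character_,
      experiment = r$experiment %||% NA_character_,
      location = as.numeric(r$location), scale = as.numeric(r$scale),
      distribution = r$distribution
    )))
  fe <- NULL
  if (!is.null(pr$formation_energy)) {
    fe <- list(ids = pr$formation_energy$ids,
               mean = as.numeric(pr$formation_energy$mean),
               covariance = do.call(rbind, lapply(pr$formation_energy$covariance,
                                                  as.numeric)))
  }
  priors <- kin_priors(scalars, fe)

  experiments <- kin_experiments(
    id = vapply(ex$experiments, `[[`, character(1), "id"),
    role = vapply(ex$experiments, function(r) r$role %||% "train", character(1)),
    knockouts = lapply(ex$experiments, function(r)
      as.character(r$knockouts %||% character(0))),
    init_conc = lapply(ex$experiments, function(r) {
      ic <- r$initial_concentration %||% list()
      stats::setNames(as.numeric(unlist(ic) %||% numeric(0)),
                      names(ic) %||% character(0))
    })
  )
  ms_list <- ex$measurements %||% list()
  measurements <- if (length(ms_list) > 0) {
    kin_measurements(
      experiment = vapply(ms_list, `[[`, character(1), "experiment"),
      type = vapply(ms_list, `[[`, character(1), "type"),
      target = vapply(ms_list, `[[`, character(1), "target"),
      value = vapply(ms_list, function(r) as.numeric(r$value), numeric(1)),
      sd = vapply(ms_list, function(r) as.numeric(r$sd), numeric(1))
    )
  } else {
    kin_measurements(character(0), character(0), character(0), numeric(0),
                     numeric(0))
  }
  solver <- do.call(solver_config, cfg$solver %||% list())
  sampler <- do.call(sampler_config, cfg$sampler %||% list())
  kin_model(net, priors, experiments, measurements, solver = solver,
            sampler = sampler, temperature = cfg$temperature %||% 298.15)
}

#' Write a model to an input directory
#'
#' Inverse of [parse_input()]: emits `model.toml`, `priors.toml`,
#' `experiments.toml` and `config.toml` such that re-parsing reproduces an
#' equivalent model.
#'
#' @param model A `kin_model`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_input <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  net <- model$network
  m <- list(
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i)
      list(id = net$metabolites$id[i],
           compartment = net$metabolites$compartment[i],
           balanced = net$metabolites$balanced[i])),
    enzymes = lapply(seq_len(nrow(net$enzymes)), function(i)
      list(id = net$enzymes$id[i],
           subunits = as.integer(net$enzymes$subunits[i]))),
    reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
      rx <- net$reactions[i, ]
      st <- rx$stoichiometry[[1]]
      rec <- list(id = rx$id, mechanism = rx$mechanism)
      if (!is.na(rx$enzyme)) rec$enzyme <- rx$enzyme
      rec$stoichiometry <- stats::setNames(
        lapply(seq_along(st$ids), function(k) rat_to_input(st$num[k], st$den[k])),
        st$ids)
      rec
    })
  )
  if (nrow(net$regulations) > 0) {
    m$regulations <- lapply(seq_len(nrow(net$regulations)), function(i)
      as.list(net$regulations[i, ]))
  }
  write_toml(m, file.path(path, "model.toml"))

  sc <- model$priors$scalars
  pr <- list(priors = lapply(seq_len(nrow(sc)), function(i) {
    r <- as.list(sc[i, ])
    r[!vapply(r, function(v) is.na(v) || is.null(v), logical(1))]
  }))
  if (!is.null(model$priors$formation_energy)) {
    fe <- model$priors$formation_energy
    pr$formation_energy <- list(
      ids = fe$ids, mean = fe$mean,
      covariance = lapply(seq_len(nrow(fe$covariance)), function(i)
        unname(fe$covariance[i, ]))
    )
  }
  write_toml(pr, file.path(path, "priors.toml"))

  exl <- list(experiments = lapply(seq_len(nrow(model$experiments)), function(i) {
    r <- model$experiments[i, ]
    rec <- list(id = r$id, role = r$role, knockouts = r$knockouts[[1]])
    ic <- r$init_conc[[1]]
    if (length(ic) > 0) rec$initial_concentration <- as.list(ic)
    rec
  }))
  if (nrow(model$measurements) > 0) {
    exl$measurements <- lapply(seq_len(nrow(model$measurements)), function(i)
      as.list(model$measurements[i, c("experiment", "type", "target", "value", "sd")]))
  }
  write_toml(exl, file.path(path, "experiments.toml"))

  write_toml(list(
    temperature = model$temperature,
    solver = unclass(model$solver),
    sampler = unclass(model$sampler)
  ), file.path(path, "config.toml"))
  invisible(path)
}
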