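config_top_keys <- c("states", "adjacency", "transitions", "utilities",
                     "drugs", "weight_kg", "cost_multiplier", "economics",
                     "psa", "owsa")

#' Serialize model parameters to a config list / file
#'
#' The config mirrors the parameter object block-for-block: `states`,
#' `adjacency` (map from-state to allowed targets), `transitions`
#' (`mono`/`combo` entry lists), `utilities`, `drugs`, `weight_kg`,
#' `cost_multiplier`, `economics`, `psa`, `owsa`. YAML and JSON are supported
#' interchangeably (chosen by file extension); numbers are written at full
#' precision so a load/dump/load round trip reproduces the parameters exactly.
#'
#' @param params A `gd_params`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  cfg <- params_to_config(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(cfg, precision = 22), path)
  }
  invisible(path)
}

params_to_config <- function(params) {
  adj <- lapply(params$states, function(s) {
    as.list(params$states[params$adjacency[s, ]])
  })
  names(adj) <- params$states
  entries_list <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(from = df$from[i], to = df$to[i], prob = df$prob[i])
    })
  }
  sched <- function(s) {
    out <- s[c("pack_size", "pack_price", "dose_per_admin", "admins_per_week",
               "daily_dose_per_kg")]
    out[!vapply(out, is.null, logical(1))]
  }
  list(
    states = as.list(params$states),
    adjacency = adj,
    transitions = list(mono = entries_list(params$transitions$mono),
                       combo = entries_list(params$transitions$combo)),
    utilities = as.list(params$utilities),
    drugs = lapply(params$drugs, sched),
    weight_kg = params$weight_kg,
    cost_multiplier = as.list(params$cost_multiplier),
    economics = params$economics,
    psa = params$psa,
    owsa = list(fraction = params$owsa$fraction,
                parameters = as.list(params$owsa$parameters))
  )
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON config, rejects unknown keys with a field-level
#' message, fills omitted blocks from [default_parameters()], and checks every
#' model invariant at load time: utilities in [0, 1] with death at 0, positive
#' prices and weight, nonnegative discount rate, transition probabilities in
#' [0, 1] on structurally allowed moves with feasible row closure.
#'
#' @param path Config file path.
#' @return A validated `gd_params`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_to_params(cfg)
}

config_to_params <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), config_top_keys)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  params <- default_parameters()
  if (!is.null(cfg$states)) {
    states <- as.character(unlist(cfg$states))
    if (!identical(states, params$states)) {
      # custom state space: rebuild dependent defaults
      params$states <- states
      params$adjacency <- gd_adjacency(states)
      params$utilities <- stats::setNames(rep(NA_real_, length(states)),
                                          states)
    }
  }
  if (!is.null(cfg$adjacency)) {
    adj <- matrix(FALSE, length(params$states), length(params$states),
                  dimnames = list(params$states, params$states))
    check_keys(names(cfg$adjacency), params$states, "adjacency")
    for (from in names(cfg$adjacency)) {
      tos <- as.character(unlist(cfg$adjacency[[from]]))
      check_keys(tos, params$states, sprintf("adjacency.%s", from))
      adj[from, tos] <- TRUE
    }
    params$adjacency <- adj
  }
  if (!is.null(cfg$utilities)) {
    check_keys(names(cfg$utilities), params$states, "utilities")
    for (s in names(cfg$utilities)) {
      params$utilities[[s]] <- as.numeric(cfg$utilities[[s]])
    }
  }
  if (!is.null(cfg$transitions)) {
    check_keys(names(cfg$transitions), c("mono", "combo"), "transitions")
    for (arm in names(cfg$transitions)) {
      rows <- cfg$transitions[[arm]]
      df <- if (length(rows) == 0) empty_entries() else do.call(rbind, lapply(rows, function(r) {
        check_keys(names(r), c("from", "to", "prob"),
                   sprintf("transitions.%s[]", arm))
        data.frame(from = r$from, to = r$to, prob = as.numeric(r$prob),
                   stringsAsFactors = FALSE)
      }))
      params$transitions[[arm]] <- df
    }
  }
  if (!is.null(cfg$drugs)) {
    check_keys(names(cfg$drugs), c("imiglucerase", "ambroxol"), "drugs")
    for (drug in names(cfg$drugs)) {
      d <- cfg$drugs[[drug]]
      check_keys(names(d), c("pack_size", "pack_price", "dose_per_admin",
                             "admins_per_week", "daily_dose_per_kg"),
                 sprintf("drugs.%s", drug))
      params$drugs[[drug]] <- do.call(dose_schedule, c(list(drug_name = drug),
                                                       lapply(d, as.numeric)))
    }
  }
  if (!is.null(cfg$weight_kg)) params$weight_kg <- as.numeric(cfg$weight_kg)
  if (!is.null(cfg$cost_multiplier)) {
    check_keys(names(cfg$cost_multiplier), arm_names(), "cost_multiplier")
    for (arm in names(cfg$cost_multiplier)) {
      params$cost_multiplier[[arm]] <- as.numeric(cfg$cost_multiplier[[arm]])
    }
  }
  for (block in c("economics", "psa", "owsa")) {
    if (!is.null(cfg[[block]])) {
      check_keys(names(cfg[[block]]), names(params[[block]]), block)
      for (key in names(cfg[[block]])) {
        v <- cfg[[block]][[key]]
        params[[block]][[key]] <- if (key == "parameters") {
          as.character(unlist(v))
        } else if (is.logical(params[[block]][[key]])) {
          as.logical(v)
        } else {
          as.numeric(unlist(v))
        }
      }
    }
  }
  validate_params(params)
  params
}

check_keys <- function(keys, allowed, where) {
  bad <- setdiff(keys, allowed)
  if (length(bad) > 0) {
    stop(sprintf("%s: unknown key(s) %s", where, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
}

#' Validate a full parameter object
#'
#' @param params A `gd_params`.
#' @return `params`, invisibly; errors with a field-level message on any
#'   invariant violation.
#' @export
validate_params <- function(params) {
  u <- params$utilities
  if (any(is.na(u))) {
    stop(sprintf("utilities missing for: %s",
                 paste(names(u)[is.na(u)], collapse = ", ")), call. = FALSE)
  }
  if (any(u < 0 | u > 1)) {
    bad <- names(u)[u < 0 | u > 1][1]
    stop(sprintf("utilities.%s: value %g outside [0, 1]", bad, u[[bad]]),
         call. = FALSE)
  }
  if ("death" %in% params$states && u[["death"]] != 0) {
    stop("utilities.death: must be 0", call. = FALSE)
  }
  if (params$weight_kg <= 0) stop("weight_kg: must be > 0", call. = FALSE)
  if (params$economics$discount_rate < 0) {
    stop("economics.discount_rate: must be >= 0", call. = FALSE)
  }
  if (any(params$cost_multiplier <= 0)) {
    stop("cost_multiplier: must be > 0", call. = FALSE)
  }
  if (is.unsorted(params$economics$wtp_multipliers, strictly = TRUE)) {
    stop("economics.wtp_multipliers: must be strictly increasing",
         call. = FALSE)
  }
  if (params$psa$n_draws < 1) stop("psa.n_draws: must be >= 1", call. = FALSE)
  if (params$psa$se_fraction < 0) {
    stop("psa.se_fraction: must be >= 0", call. = FALSE)
  }
  if (params$owsa$fraction <= 0 || params$owsa$fraction >= 1) {
    stop("owsa.fraction: must lie in (0, 1)", call. = FALSE)
  }
  # building both matrices exercises adjacency, [0, 1] bounds and row closure
  for (arm in c("mono", "combo")) {
    tr <- params$transitions[[arm]]
    if (any(tr$prob < 0 | tr$prob > 1)) {
      stop(sprintf("transitions.%s: probabilities outside [0, 1]", arm),
           call. = FALSE)
    }
    build_transition_matrix(tr, params$states, adjacency = params$adjacency)
  }
  invisible(params)
}
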