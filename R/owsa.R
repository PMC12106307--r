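#' Address scalar model parameters by name
#'
#' Scalar parameters of a `gd_params` object are addressed by a flat name so
#' sensitivity analyses can perturb them uniformly:
#' \describe{
#'   \item{`imiglucerase_price`, `ambroxol_price`}{pack prices (CNY)}
#'   \item{`weight_kg`}{mean patient weight}
#'   \item{`discount_rate`}{annual discount rate}
#'   \item{`utility.<state>`}{a state utility weight}
#'   \item{`tp.<arm>.<from>.<to>`}{a transition-probability entry
#'     (`arm` is `mono` or `combo`)}
#' }
#'
#' @param params A `gd_params`.
#' @param name Parameter name.
#' @return `param_get` returns the scalar value; `param_set` returns the
#'   modified `gd_params`.
#' @export
param_get <- function(params, name) {
  p <- parse_param_name(params, name)
  switch(p$kind,
    price = params$drugs[[p$drug]]$pack_price,
    weight = params$weight_kg,
    discount = params$economics$discount_rate,
    utility = unname(params$utilities[[p$state]]),
    tp = params$transitions[[p$arm]]$prob[p$row]
  )
}

#' @rdname param_get
#' @param value New scalar value.
#' @export
param_set <- function(params, name, value) {
  p <- parse_param_name(params, name)
  switch(p$kind,
    price = { params$drugs[[p$drug]]$pack_price <- value },
    weight = { params$weight_kg <- value },
    discount = { params$economics$discount_rate <- value },
    utility = { params$utilities[[p$state]] <- value },
    tp = { params$transitions[[p$arm]]$prob[p$row] <- value }
  )
  params
}

parse_param_name <- function(params, name) {
  if (name %in% c("imiglucerase_price", "ambroxol_price")) {
    return(list(kind = "price", drug = sub("_price$", "", name)))
  }
  if (name == "weight_kg") return(list(kind = "weight"))
  if (name == "discount_rate") return(list(kind = "discount"))
  if (startsWith(name, "utility.")) {
    state <- sub("^utility\\.", "", name)
    if (!state %in% params$states) {
      stop(sprintf("unknown state in parameter '%s'", name), call. = FALSE)
    }
    return(list(kind = "utility", state = state))
  }
  if (startsWith(name, "tp.")) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    if (length(parts) != 4 || !parts[2] %in% c("mono", "combo")) {
      stop(sprintf("malformed transition parameter '%s'", name), call. = FALSE)
    }
    tr <- params$transitions[[parts[2]]]
    row <- which(tr$from == parts[3] & tr$to == parts[4])
    if (length(row) != 1) {
      stop(sprintf("no transition entry for '%s'", name), call. = FALSE)
    }
    return(list(kind = "tp", arm = parts[2], row = row))
  }
  stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
}

#' Perturb one named parameter multiplicatively
#'
#' Multiplies the parameter by `1 + direction * fraction`. A utility pushed
#' above 1 is clamped to 1 with a warning; a perturbed transition probability
#' is re-closed onto the row diagonal when the matrix is next built, and an
#' infeasible row (diagonal below zero) errors there.
#'
#' @param params A `gd_params`.
#' @param name Parameter name (see [param_get()]).
#' @param direction `+1` or `-1`.
#' @param fraction Relative perturbation (default 0.10).
#' @param clamp_utility Clamp out-of-range utilities to 1 (default TRUE);
#'   when FALSE an out-of-range utility errors.
#'
#' @return The perturbed `gd_params`.
#' @export
perturb_parameter <- function(params, name, direction, fraction = 0.1,
                              clamp_utility = TRUE) {
  stopifnot(direction %in% c(-1, 1), fraction > 0, fraction < 1)
  value <- param_get(params, name) * (1 + direction * fraction)
  kind <- parse_param_name(params, name)$kind
  if (kind == "utility" && value > 1) {
    if (!clamp_utility) {
      stop(sprintf("perturbed utility '%s' exceeds 1", name), call. = FALSE)
    }
    warning(sprintf("perturbed utility '%s' clamped from %.4f to 1", name,
                    value), call. = FALSE)
    value <- 1
  }
  param_set(params, name, value)
}

#' One-way sensitivity analysis with tornado ordering
#'
#' Re-runs the full base case with each parameter perturbed up and down by the
#' given fraction (all other parameters at base values) and records both
#' ICERs. Entries are sorted by the width of the ICER interval, descending;
#' ties break lexicographically by parameter name, so the output is
#' deterministic.
#'
#' @param params A `gd_params` with per-arm transitions.
#' @param parameters Character vector of parameter names; defaults to the
#'   `params$owsa$parameters` roster (both drug prices, the seven live-state
#'   utilities, the discount rate).
#' @param fraction Relative perturbation; defaults to `params$owsa$fraction`.
#'
#' @return A data.frame of class `tornado` with columns `parameter`,
#'   `icer_low` (parameter down), `icer_high` (parameter up), `icer_min`,
#'   `icer_max`, `range`.
#' @export
tornado_analysis <- function(params, parameters = params$owsa$parameters,
                             fraction = params$owsa$fraction) {
  base <- run_base_case(params)
  if (is.na(base$icer)) {
    stop("base-case ICER is undefined; tornado analysis needs a defined ICER",
         call. = FALSE)
  }
  icer_at <- function(name, direction) {
    p <- suppressWarnings(
      perturb_parameter(params, name, direction, fraction)
    )
    run_base_case(p)$icer
  }
  low <- vapply(parameters, icer_at, numeric(1), direction = -1)
  high <- vapply(parameters, icer_at, numeric(1), direction = 1)
  out <- data.frame(
    parameter = parameters,
    icer_low = unname(low),
    icer_high = unname(high),
    row.names = NULL
  )
  out$icer_min <- pmin(out$icer_low, out$icer_high)
  out$icer_max <- pmax(out$icer_low, out$icer_high)
  out$range <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$range, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  attr(out, "fraction") <- fraction
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
print.tornado <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis (+/- %.0f%%), base ICER %.2f\n",
              100 * attr(x, "fraction"), attr(x, "base_icer")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) sprintf("%.2f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a tornado table as CSV
#'
#' Columns `parameter,icer_low,icer_high,range`, sorted as displayed
#' (descending range).
#'
#' @param tornado A `tornado` data.frame from [tornado_analysis()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(tornado, path) {
  stopifnot(inherits(tornado, "tornado"))
  df <- as.data.frame(tornado)[, c("parameter", "icer_low", "icer_high",
                                   "range")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
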