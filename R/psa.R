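#' Beta distribution parameters by method of moments
#'
#' Solves for the shape parameters of a beta distribution with the requested
#' mean and standard error: `nu = mean (1 - mean) / se^2 - 1`,
#' `alpha = mean nu`, `beta = (1 - mean) nu`. Used for utilities and
#' transition probabilities, whose uncertainty is specified as SE = 10% of the
#' mean.
#'
#' @param mean Target mean, in (0, 1).
#' @param se Target standard error; must satisfy `se^2 < mean (1 - mean)`.
#' @param what Parameter label used in error messages.
#'
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' beta_from_mean_se(0.5, 0.1) # alpha = beta = 12
beta_from_mean_se <- function(mean, se, what = "parameter") {
  if (mean <= 0 || mean >= 1) {
    stop(sprintf("%s: beta mean must lie in (0, 1), got %g", what, mean),
         call. = FALSE)
  }
  if (se <= 0 || se^2 >= mean * (1 - mean)) {
    stop(sprintf("%s: infeasible beta variance (se^2 = %g >= mean(1-mean) = %g)",
                 what, se^2, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Sample a nonnegative normal quantity
#'
#' Draws from Normal(mean, se) and rejects negative values, redrawing until
#' all draws are nonnegative (truncation at 0 by rejection, preserving the
#' shape of the distribution above 0). Used for cost parameters.
#'
#' @param n Number of draws.
#' @param mean Mean of the untruncated normal.
#' @param se Standard deviation; must be > 0.
#' @param max_redraws Redraw budget before giving up.
#'
#' @return Numeric vector of `n` nonnegative draws.
#' @export
rnorm_nonneg <- function(n, mean, se, max_redraws = 1000) {
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  x <- stats::rnorm(n, mean, se)
  tries <- 0
  while (any(bad <- x < 0)) {
    tries <- tries + 1
    if (tries > max_redraws) {
      stop("truncated-normal rejection budget exhausted", call. = FALSE)
    }
    x[bad] <- stats::rnorm(sum(bad), mean, se)
  }
  x
}

sample_beta_ms <- function(mean, se, what) {
  ab <- beta_from_mean_se(mean, se, what)
  stats::rbeta(1, ab[["alpha"]], ab[["beta"]])
}

#' Draw one sampled parameter set for the PSA
#'
#' Samples, in a fixed documented order: the two drug pack prices (normal,
#' truncated at 0 by rejection), the seven live-state utilities (beta), and —
#' when `sample_transitions` is on — every transition-probability entry of
#' each arm (beta). Standard errors are `se_fraction` times the mean (default
#' 10%). A sampled transition row whose off-diagonal sum exceeds 1 (so the
#' "remain" diagonal would go negative) is redrawn, up to `max_redraws` times.
#' Parameters shared between arms (prices, utilities) receive a single common
#' draw.
#'
#' @param params Base `gd_params`.
#' @param se_fraction SE as a fraction of the mean; defaults to
#'   `params$psa$se_fraction`.
#' @param sample_transitions Sample transition probabilities too; defaults to
#'   `params$psa$sample_transitions`.
#' @param max_redraws Row-feasibility redraw budget.
#'
#' @return A `gd_params` with sampled values in place of the means.
#' @export
sample_parameter_set <- function(params,
                                 se_fraction = params$psa$se_fraction,
                                 sample_transitions = params$psa$sample_transitions,
                                 max_redraws = 1000) {
  if (se_fraction < 0) stop("se_fraction must be >= 0", call. = FALSE)
  if (se_fraction == 0) return(params)
  out <- params
  for (drug in c("imiglucerase", "ambroxol")) {
    mu <- params$drugs[[drug]]$pack_price
    out$drugs[[drug]]$pack_price <- rnorm_nonneg(1, mu, se_fraction * mu)
  }
  live <- setdiff(params$states, "death")
  for (s in live) {
    u <- params$utilities[[s]]
    out$utilities[[s]] <- sample_beta_ms(u, se_fraction * u,
                                         paste0("utility.", s))
  }
  if (sample_transitions) {
    for (arm in c("mono", "combo")) {
      tr <- params$transitions[[arm]]
      if (nrow(tr) == 0) next
      for (s in unique(tr$from)) {
        rows <- which(tr$from == s)
        for (try in seq_len(max_redraws + 1)) {
          drawn <- vapply(rows, function(i) {
            sample_beta_ms(tr$prob[i], se_fraction * tr$prob[i],
                           sprintf("tp.%s.%s.%s", arm, tr$from[i], tr$to[i]))
          }, numeric(1))
          if (sum(drawn) <= 1) break
          if (try > max_redraws) {
            stop(sprintf("row '%s' (%s arm) infeasible after %d redraws",
                         s, arm, max_redraws), call. = FALSE)
          }
        }
        tr$prob[rows] <- drawn
      }
      out$transitions[[arm]] <- tr
    }
  }
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: for each draw, one
#' sampled parameter set is generated (common random values for parameters
#' shared between arms) and the full cohort model is evaluated for both arms.
#' Reproducible given `seed`.
#'
#' @param params Base `gd_params` with per-arm transitions.
#' @param n_draws Number of draws; defaults to `params$psa$n_draws` (1,000).
#' @param seed Optional integer seed.
#' @param se_fraction,sample_transitions Passed to [sample_parameter_set()].
#'
#' @return A data.frame of class `psa_draws` with columns `draw`, `cost_mono`,
#'   `qalys_mono`, `cost_combo`, `qalys_combo`, `incr_cost`, `incr_qalys`.
#' @export
run_psa <- function(params, n_draws = params$psa$n_draws, seed = NULL,
                    se_fraction = params$psa$se_fraction,
                    sample_transitions = params$psa$sample_transitions) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    sp <- sample_parameter_set(params, se_fraction = se_fraction,
                               sample_transitions = sample_transitions)
    res <- run_base_case(sp)
    rows[[i]] <- data.frame(
      draw = i,
      cost_mono = res$arms$cost[1], qalys_mono = res$arms$qalys[1],
      cost_combo = res$arms$cost[2], qalys_combo = res$arms$qalys[2],
      incr_cost = res$incr_cost, incr_qalys = res$incr_qalys
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("psa_draws", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the combination
#' arm is cost-effective is the fraction of draws with strictly positive
#' incremental net monetary benefit, `wtp * incr_qalys - incr_cost > 0`.
#'
#' @param draws A `psa_draws` data.frame.
#' @param wtp_grid Numeric vector of WTP thresholds; defaults to 21 equally
#'   spaced points from 1x to 3x GDP per capita.
#'
#' @return A data.frame of class `ceac_curve` with columns `wtp`,
#'   `prob_combo_ce`.
#' @export
ceac <- function(draws, wtp_grid = default_wtp_grid()) {
  if (nrow(draws) == 0) stop("no PSA draws supplied", call. = FALSE)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * draws$incr_qalys - draws$incr_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_combo_ce = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Default willingness-to-pay grid
#'
#' @param params A `gd_params`.
#' @param points Number of grid points; defaults to `params$psa$wtp_points`.
#' @return Equally spaced thresholds from the smallest to the largest WTP
#'   multiple of GDP per capita (default 21 points from 1x to 3x).
#' @export
default_wtp_grid <- function(params = default_parameters(),
                             points = params$psa$wtp_points) {
  thr <- wtp_thresholds(params)
  seq(min(thr), max(thr), length.out = points)
}

#' Cost-effectiveness plane summary
#'
#' Classifies each draw's (incremental QALYs, incremental cost) pair into a
#' plane quadrant (NE: more effective and more costly, etc.), and summarizes
#' the cloud by its mean and a confidence ellipse from the sample covariance
#' at the chi-square (2 df) quantile.
#'
#' @param draws A `psa_draws` data.frame with at least 3 rows.
#' @param confidence Ellipse coverage (default 0.95).
#'
#' @return A list of class `ce_plane_summary`: `quadrants` (named counts
#'   NE/NW/SE/SW), `mean_incr_cost`, `mean_incr_qalys`, and `ellipse`
#'   (`center`, `axes`, `angle_rad`; NULL with a warning when the covariance
#'   is degenerate).
#' @export
ce_plane_summary <- function(draws, confidence = 0.95) {
  n <- nrow(draws)
  if (n < 3) stop("need at least 3 draws", call. = FALSE)
  de <- draws$incr_qalys
  dc <- draws$incr_cost
  quadrants <- c(
    NE = sum(de > 0 & dc > 0),
    NW = sum(de <= 0 & dc > 0),
    SE = sum(de > 0 & dc <= 0),
    SW = sum(de <= 0 & dc <= 0)
  )
  S <- stats::cov(cbind(de, dc))
  ellipse <- NULL
  if (all(is.finite(S)) && det(S) > .Machine$double.eps) {
    eg <- eigen(S, symmetric = TRUE)
    r2 <- stats::qchisq(confidence, df = 2)
    ellipse <- list(
      center = c(incr_qalys = mean(de), incr_cost = mean(dc)),
      axes = sqrt(pmax(eg$values, 0) * r2),
      angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1])
    )
  } else {
    warning("degenerate covariance; confidence ellipse omitted", call. = FALSE)
  }
  structure(
    list(quadrants = quadrants, mean_incr_cost = mean(dc),
         mean_incr_qalys = mean(de), confidence = confidence,
         ellipse = ellipse),
    class = "ce_plane_summary"
  )
}

#' @export
print.ce_plane_summary <- function(x, ...) {
  cat("Cost-effectiveness plane summary\n")
  cat("  quadrant counts:",
      paste(sprintf("%s=%d", names(x$quadrants), x$quadrants),
            collapse = " "), "\n")
  cat(sprintf("  mean incremental cost %.2f, mean incremental QALYs %.4f\n",
              x$mean_incr_cost, x$mean_incr_qalys))
  if (!is.null(x$ellipse)) {
    cat(sprintf("  %.0f%% ellipse semi-axes: %.4g, %.4g\n",
                100 * x$confidence, x$ellipse$axes[1], x$ellipse$axes[2]))
  }
  invisible(x)
}

#' Export PSA draws or a CEAC as CSV
#'
#' @param draws A `psa_draws` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(draws, path) {
  stopifnot(inherits(draws, "psa_draws"))
  utils::write.csv(as.data.frame(draws), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @param curve A `ceac_curve` data.frame.
#' @export
write_ceac_csv <- function(curve, path) {
  stopifnot(inherits(curve, "ceac_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
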