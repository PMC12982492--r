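#' Configuration for the Monte-Carlo iterative convergence estimator
#'
#' Free parameters of the grid-deformation loop. Defaults scale with the
#' number of grid nodes and converge on the scenarios shipped with the
#' package in seconds (the hot loop is compiled).
#'
#' @param budget total proposal budget; default `200 * n_nodes` (set when the
#'   grid is known, see [match_velocity()]).
#' @param proposal_scale Gaussian proposal standard deviation as a fraction
#'   of the local grid-cell size (default 0.25).
#' @param lambda dimensionless weight of the shear penalty (default 1).
#' @param stall_limit consecutive rejected proposals before stopping; default
#'   `20 * n_nodes`.
#' @param seed integer RNG seed (default 1).
#' @return An object of class `match_config`.
#' @export
match_config <- function(budget = NULL, proposal_scale = 0.25, lambda = 1,
                         stall_limit = NULL, seed = 1L) {
  if (!is.null(budget) && budget <= 0) stop("budget must be positive")
  if (proposal_scale <= 0) stop("proposal_scale must be positive")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(budget = budget, proposal_scale = proposal_scale,
                 lambda = lambda, stall_limit = stall_limit,
                 seed = as.integer(seed)),
            class = "match_config")
}

#' MATCH climate velocity (Monte-Carlo iterative convergence)
#'
#' Estimates the climate-velocity field by registering the initial
#' decadal-mean field onto the final one. A per-node displacement field D
#' (km), initialized at zero, is refined by repeatedly proposing a random
#' Gaussian perturbation of one node's displacement and keeping the proposal
#' iff it strictly decreases the objective
#' `misfit(D) + lambda * shear(D)`:
#' the misfit measures how far the warped initial field is from the final one
#' (backward bilinear warp, nearest-edge values outside the grid), and the
#' shear term sums squared displacement differences over 4-neighbour pairs,
#' favouring a regular (low-shear) velocity field over the down-gradient
#' direction assumption. The final displacement of each node divided by the
#' period offset is the velocity at that node. All nodes are valid: the
#' displacement is bounded by construction, so no blow-up guard is needed.
#'
#' Accepted-move objective values form a strictly decreasing sequence
#' (returned in `attr(, "diagnostics")$objective_trace`); a fixed seed gives
#' bit-identical output.
#'
#' @inheritParams gradient_velocity
#' @param config a [match_config()].
#' @return A [velocity_field()] with `method = "match"` and an attribute
#'   `diagnostics` (objective trace, acceptance count, initial/final misfit).
#' @export
match_velocity <- function(f0, f1, config = match_config()) {
  stopifnot(inherits(f0, "gridded_field"), inherits(f1, "gridded_field"),
            inherits(config, "match_config"))
  if (!.same_grid(f0, f1)) stop("grid mismatch between fields")
  if (!all(is.finite(f0$values)) || !all(is.finite(f1$values)))
    stop("non-finite field values")
  dt <- period_midpoint(f1) - period_midpoint(f0)
  if (dt <= 0) stop("dt must be positive (distinct, ordered period labels)")
  n <- length(f0$values)
  budget <- if (is.null(config$budget)) 200L * n else as.integer(config$budget)
  stall <- if (is.null(config$stall_limit)) 20L * n else as.integer(config$stall_limit)
  msd0 <- mean((f1$values - f0$values)^2)
  if (msd0 == 0) msd0 <- 1  # identical fields: objective minimal at D = 0
  set.seed(config$seed)
  fit <- .match_core(f0$values, f1$values, f0$lat, f0$lon,
                     config$lambda, config$proposal_scale,
                     budget, stall, msd0, KM_PER_DEG)
  out <- velocity_field(fit$De / dt, fit$Dn / dt, f0$lat, f0$lon,
                        method = "match", dt = dt)
  attr(out, "diagnostics") <- list(
    objective_trace = fit$objective_trace,
    n_accepted = fit$n_accepted,
    misfit_initial = fit$misfit_initial,
    misfit_final = fit$misfit_final,
    budget = budget, stall_limit = stall, seed = config$seed)
  out
}

#' Fit a climate-velocity field by either estimator
#'
#' Front door of the package: computes the climate-change velocity between
#' two decadal-mean fields with the method of choice.
#'
#' @inheritParams gradient_velocity
#' @param method `"gradient"` or `"match"`.
#' @param min_grad blow-up guard threshold for the gradient method.
#' @param config [match_config()] for the MATCH method.
#' @return A [velocity_field()].
#' @examples
#' sc <- field_scenario("parallel", years = 1960:1979)
#' series <- make_temperature_series(sc)
#' f0 <- decadal_mean(series, c(1960, 1970))
#' f1 <- decadal_mean(series, c(1970, 1980))
#' v <- climate_velocity(f0, f1, method = "gradient")
#' v$v_north[5, 5]  # b/a = 0.02 / 0.01 = 2 km/yr northward
#' @export
climate_velocity <- function(f0, f1, method = c("gradient", "match"),
                             min_grad = 1e-4, config = match_config()) {
  method <- match.arg(method)
  if (method == "gradient") gradient_velocity(f0, f1, min_grad = min_grad)
  else match_velocity(f0, f1, config = config)
}
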