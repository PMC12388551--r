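#' Flux balance analysis
#'
#' Maximizes the objective (biomass) reaction flux subject to steady-state
#' mass balance `S v = 0` and the reaction bounds, by linear programming.
#'
#' @param model a `metabolic_model`.
#' @param objective optional reaction id overriding the model objective.
#' @param maximize maximize (default) or minimize the objective flux.
#' @return object of class `flux_vector`: list with `fluxes` (named numeric,
#'   mmol/gDW/h), `objective_value`, `objective`, `status`.
#' @export
fba <- function(model, objective = NULL, maximize = TRUE) {
  objective <- objective %||% model$objective
  if (!objective %in% model$reactions$id)
    stop("objective reaction '", objective, "' is not in the model")
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  obj <- as.numeric(model$reactions$id == objective)
  res <- solve_lp(obj, S, rep(0, nrow(S)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = maximize)
  if (res$status == "infeasible")
    stop("FBA: model is infeasible (no flux distribution satisfies mass ",
         "balance and bounds)", call. = FALSE)
  if (res$status != "optimal")
    stop("FBA: solver returned status '", res$status, "'", call. = FALSE)
  structure(list(
    fluxes = stats::setNames(res$x, model$reactions$id),
    objective_value = res$objective,
    objective = objective,
    status = "optimal"), class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat(sprintf("<flux_vector: %d reactions; %s = %.6g>\n",
              length(x$fluxes), x$objective, x$objective_value))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction, minimizes and maximizes its flux subject to the FBA
#' constraints, optionally with the objective held at a fraction of its
#' optimum (imposed by raising the objective reaction's lower bound).
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum in `[0, 1]`; 1 (default) fixes the objective at
#'   its optimum, 0 explores the whole feasible polytope.
#' @param reactions reaction ids to analyze (default: all).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, fraction_of_optimum = 1.0, reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  reactions <- reactions %||% model$reactions$id
  stopifnot(all(reactions %in% model$reactions$id))
  sol <- fba(model)
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (fraction_of_optimum > 0) {
    i <- match(model$objective, model$reactions$id)
    # tiny slack guards against cutting off the optimum by round-off
    lb[i] <- max(lb[i], fraction_of_optimum * sol$objective_value - 1e-9)
  }
  b0 <- rep(0, nrow(S))
  res <- lapply(reactions, function(r) {
    obj <- as.numeric(model$reactions$id == r)
    lo <- solve_lp(obj, S, b0, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, S, b0, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA: subproblem for reaction '", r, "' returned status '",
           lo$status, "'/'", hi$status, "'")
    c(lo$objective, hi$objective)
  })
  out <- data.frame(reaction = reactions,
                    min = vapply(res, `[`, numeric(1), 1),
                    max = vapply(res, `[`, numeric(1), 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# bounds with the objective reaction's lower bound raised to a fraction of
# the FBA optimum (with a 1e-9 slack against round-off)
objective_constrained_bounds <- function(model, fraction_of_optimum) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (fraction_of_optimum > 0) {
    i <- match(model$objective, model$reactions$id)
    opt <- fba(model)$objective_value
    lb[i] <- max(lb[i], fraction_of_optimum * opt - 1e-9)
  }
  list(lb = lb, ub = ub)
}

#' Reactions carrying flux
#'
#' A reaction is considered inactive when its absolute flux falls below
#' `tol` (default 1e-6 mmol/gDW/h); the threshold is applied to `|flux|`
#' because reversible fluxes are signed. A flux of exactly `tol` counts as
#' active.
#'
#' @param v a `flux_vector` or named numeric vector of fluxes.
#' @param tol inactivity threshold.
#' @return character vector of active reaction ids.
#' @export
active_reactions <- function(v, tol = 1e-6) {
  fluxes <- if (inherits(v, "flux_vector")) v$fluxes else v
  names(fluxes)[abs(fluxes) >= tol]
}
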