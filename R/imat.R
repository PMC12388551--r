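#' Map a sample's tri-state gene levels onto reactions
#'
#' Each reaction's state is its GPR evaluated under the sample's gene levels
#' (`and` = min, `or` = max); reactions with an empty GPR, and genes absent
#' from the profile, are moderate (0).
#'
#' @param model a `metabolic_model`.
#' @param profile genes x samples integer matrix from [discretize()].
#' @param sample column name (or index) identifying the sample.
#' @return named integer vector, reaction id -> state in `{-1, 0, 1}`.
#' @export
reaction_states <- function(model, profile, sample) {
  levels <- profile[, sample]
  if (is.null(names(levels))) names(levels) <- rownames(profile)
  vapply(stats::setNames(model$reactions$gpr, model$reactions$id),
         function(g) evaluate_tristate(parse_gpr(g), levels),
         integer(1))
}

#' Solve the iMAT mixed-integer program
#'
#' Maximizes the number of expression-consistent reactions: a high-state
#' reaction counts when it carries flux of magnitude at least `eps` (in
#' either direction), a low-state reaction when its flux is forced to zero.
#' High states get direction binaries y+ (`y+ = 1` forces `v >= eps`) and
#' y- (`y- = 1` forces `v <= -eps`) with `y+ + y- <= 1`; low states get y0
#' (`y0 = 1` forces `v = 0`). The indicator linking uses the tightest valid
#' per-reaction big-M coefficients (derived from the reaction's own
#' bounds), which leaves the integer solutions of the conventional global
#' big-M formulation unchanged while keeping the LP relaxation strong.
#'
#' @param model a `metabolic_model` with all bounds within `bigM` in
#'   magnitude.
#' @param states named vector from [reaction_states()] (missing reactions are
#'   treated as moderate).
#' @param eps minimum activation flux for a high reaction (default 1).
#' @param bigM big-M constant (default 1000, matching the conventional
#'   default bounds).
#' @return object of class `imat_solution`: list with `fluxes`, `active`
#'   (named logical over high-state reactions), `off` (named logical over
#'   low-state reactions), `objective` (integer agreement count), `eps`,
#'   `bigM`, `states`.
#' @export
imat_optimize <- function(model, states, eps = 1.0, bigM = 1000) {
  stopifnot(eps > 1e-6)
  rxn <- model$reactions$id
  bad <- setdiff(names(states), rxn)
  if (length(bad) > 0)
    stop("states refer to unknown reaction(s): ", paste(bad, collapse = ", "))
  st <- stats::setNames(rep(0L, length(rxn)), rxn)
  st[names(states)] <- as.integer(states)
  if (max(abs(c(model$reactions$lower_bound, model$reactions$upper_bound))) >
      bigM + 1e-9)
    stop("model bounds exceed bigM; increase bigM")

  hi <- rxn[st == 1L]
  lo <- rxn[st == -1L]
  S <- stoichiometric_matrix(model)
  n <- length(rxn)
  nh <- length(hi); nl <- length(lo)
  nv <- n + 2L * nh + nl
  ih <- match(hi, rxn); il <- match(lo, rxn)
  yp <- n + seq_len(nh)                 # y+ columns
  ym <- n + nh + seq_len(nh)            # y- columns
  y0 <- n + 2L * nh + seq_len(nl)       # y0 columns

  Aeq <- cbind(S, matrix(0, nrow(S), nv - n))
  beq <- rep(0, nrow(S))

  lbr <- model$reactions$lower_bound
  ubr <- model$reactions$upper_bound

  # per-reaction big-M constants (the tightest valid linking coefficients;
  # same integer solutions as a global bigM, far stronger LP relaxation)
  n_ub <- 3L * nh + 2L * nl
  Aub <- matrix(0, n_ub, nv)
  bub <- numeric(n_ub)
  row <- 0L
  for (k in seq_len(nh)) {
    r <- ih[k]
    Aub[row + 1L, r] <- -1; Aub[row + 1L, yp[k]] <- eps - lbr[r]
    bub[row + 1L] <- -lbr[r]                    # y+ = 1  =>  v >= eps
    Aub[row + 2L, r] <- 1; Aub[row + 2L, ym[k]] <- eps + ubr[r]
    bub[row + 2L] <- ubr[r]                     # y- = 1  =>  v <= -eps
    Aub[row + 3L, yp[k]] <- 1; Aub[row + 3L, ym[k]] <- 1
    bub[row + 3L] <- 1                          # at most one direction
    row <- row + 3L
  }
  for (k in seq_len(nl)) {
    r <- il[k]
    Aub[row + 1L, r] <- 1; Aub[row + 1L, y0[k]] <- ubr[r]
    bub[row + 1L] <- ubr[r]                     # y0 = 1  =>  v <= 0
    Aub[row + 2L, r] <- -1; Aub[row + 2L, y0[k]] <- -lbr[r]
    bub[row + 2L] <- -lbr[r]                    # y0 = 1  =>  v >= 0
    row <- row + 2L
  }

  obj <- c(numeric(n), rep(1, 2L * nh), rep(1, nl))
  lbv <- c(lbr, numeric(2L * nh + nl))
  ubv <- c(ubr, rep(1, 2L * nh + nl))
  # directions a reaction's bounds cannot support are fixed off
  ubv[yp][ubr[ih] < eps] <- 0
  ubv[ym][lbr[ih] > -eps] <- 0
  res <- solve_milp(obj, Aeq, beq, lbv, ubv, A_ub = Aub, b_ub = bub,
                    int_idx = if (nv > n) (n + 1L):nv else integer(0),
                    maximize = TRUE, int_obj = TRUE)
  if (res$status != "optimal")
    stop("iMAT MILP returned status '", res$status,
         "' (should be impossible with free indicators)")
  fluxes <- stats::setNames(res$x[seq_len(n)], rxn)
  active <- stats::setNames(res$x[yp] + res$x[ym] > 0.5, hi)
  off <- stats::setNames(res$x[y0] > 0.5, lo)
  structure(list(fluxes = fluxes, active = active, off = off,
                 objective = as.integer(round(res$objective)),
                 eps = eps, bigM = bigM, states = st),
            class = "imat_solution")
}

#' @export
print.imat_solution <- function(x, ...) {
  cat(sprintf(
    "<imat_solution: objective %d (%d/%d high active, %d/%d low off)>\n",
    x$objective, sum(x$active), length(x$active), sum(x$off), length(x$off)))
  invisible(x)
}

#' Extract a context-specific model from an iMAT solution
#'
#' Removes the low-state reactions that the optimal iMAT assignment switched
#' off; every other reaction is retained with its original bounds (moderate
#' zero-flux reactions are kept, since iMAT only provides evidence of absence
#' for low-state reactions). If the pruned model cannot reach a biomass flux
#' of at least `min_biomass`, removed reactions are restored greedily (at
#' each step the one whose restoration raises the attainable biomass most)
#' until it can.
#'
#' @param model the parent `metabolic_model`.
#' @param solution an `imat_solution` for this model.
#' @param min_biomass minimum biomass flux the context model must attain
#'   (default 1e-6, the inactivity threshold).
#' @return a validated `metabolic_model` whose reactions are a subset of the
#'   parent's.
#' @export
extract_context_model <- function(model, solution, min_biomass = 1e-6) {
  stopifnot(inherits(solution, "imat_solution"))
  removed <- names(solution$off)[solution$off]
  removed <- setdiff(removed, model$objective)
  build <- function(drop) {
    keep <- !model$reactions$id %in% drop
    metabolic_model(model$metabolites,
                    model$reactions[keep, , drop = FALSE],
                    model$stoichiometry[model$reactions$id[keep]],
                    model$objective, id = model$id)
  }
  biomass_of <- function(m) {
    v <- tryCatch(fba(m), error = function(e) NULL)
    if (is.null(v)) -Inf else v$objective_value
  }
  ctx <- build(removed)
  while (biomass_of(ctx) < min_biomass) {
    if (length(removed) == 0)
      stop("context model cannot attain biomass flux even with all ",
           "reactions restored; inputs are inconsistent")
    # greedy: restore the removed reaction that raises biomass the most
    gains <- vapply(seq_along(removed), function(i)
      biomass_of(build(removed[-i])), numeric(1))
    removed <- removed[-which.max(gains)]
    ctx <- build(removed)
  }
  ctx
}
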