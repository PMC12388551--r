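#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over [solve_lp()] relaxations. Integer
#' variables are branched on their most fractional relaxation value; with an
#' all-integer objective (the iMAT indicator count) the bound is floored,
#' which prunes aggressively.
#'
#' @param obj,A,b,lb,ub,A_ub,b_ub,maximize as in [solve_lp()].
#' @param int_idx indices of integer-constrained variables.
#' @param int_obj set `TRUE` when the objective is integral for every integer-
#'   feasible point, enabling floor-based pruning.
#' @param int_tol integrality tolerance.
#' @param node_limit abort past this many branch-and-bound nodes.
#' @return list with `status`, `x`, `objective`, `nodes`.
#' @keywords internal
solve_milp <- function(obj, A, b, lb, ub, A_ub = NULL, b_ub = NULL,
                       int_idx = integer(0), maximize = TRUE,
                       int_obj = FALSE, int_tol = 1e-6, node_limit = 200000L) {
  if (length(int_idx) == 0)
    return(c(solve_lp(obj, A, b, lb, ub, A_ub, b_ub, maximize), nodes = 1L))
  sgn <- if (maximize) 1 else -1
  best <- list(objective = -Inf, x = NULL)
  nodes <- 0L
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit)
      stop("branch-and-bound node limit exceeded")
    rel <- solve_lp(obj, A, b, node$lb, node$ub, A_ub, b_ub, maximize)
    if (rel$status != "optimal") next
    bound <- sgn * rel$objective          # bound in maximize-space
    if (int_obj) bound <- floor(bound + 1e-6)
    inc <- if (is.null(best$x)) -Inf else sgn * best$objective
    if (bound <= inc + 1e-9) next
    xi <- rel$x[int_idx]
    frac <- abs(xi - round(xi))
    if (all(frac <= int_tol)) {
      if (sgn * rel$objective > inc + 1e-9)
        best <- list(objective = rel$objective, x = rel$x)
      next
    }
    j <- int_idx[which.max(frac)]
    v <- rel$x[j]
    lo <- node; hi <- node
    lo$ub[j] <- floor(v)
    hi$lb[j] <- ceiling(v)
    # explore the nearer child first (pushed last => popped first)
    if (v - floor(v) < 0.5) {
      stack[[length(stack) + 1L]] <- hi
      stack[[length(stack) + 1L]] <- lo
    } else {
      stack[[length(stack) + 1L]] <- lo
      stack[[length(stack) + 1L]] <- hi
    }
  }
  if (is.null(best$x))
    return(list(status = "infeasible", x = NULL, objective = NA_real_, nodes = nodes))
  best$x[int_idx] <- round(best$x[int_idx])
  list(status = "optimal", x = best$x, objective = best$objective, nodes = nodes)
}
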